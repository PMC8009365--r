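test_that("a single-biome system degenerates to a 2-state chain with identity cladogenesis", {
  av <- biome_availability("Forest")
  proc <- build_process(model_spec("DEC", d = 0.4, e = 0.2), av)
  Q <- proc$strata[[1]]$Q
  expect_equal(dim(Q), c(2L, 2L))
  expect_equal(Q[2, 1], 0.2)       # loss of the last biome -> null
  expect_equal(Q[1, ], c(0, 0))    # null absorbing
  cl <- proc$strata[[1]]$clado
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$left, cl$anc)
  expect_equal(cl$right, cl$anc)
  expect_equal(cl$w, 1)
})

test_that("DEC cladogenesis for a two-biome ancestor has the six canonical outcomes at 1/6", {
  proc <- build_process(model_spec("DEC", d = 0.1, e = 0.1), nz_availability())
  cl <- proc$strata[[1]]$clado
  row <- cl[cl$anc == 3L, ]  # {Forest, Open}
  expect_equal(nrow(row), 6L)
  expect_equal(row$w, rep(1 / 6, 6))
  got <- sort(paste(row$left, row$right))
  expect_equal(got, sort(c("1 2", "2 1", "1 3", "3 1", "2 3", "3 2")))
  expect_setequal(unique(row$cls), c("vicariance", "subset"))
})

test_that("BAYAREALIKE cladogenesis is a point mass on full inheritance", {
  proc <- build_process(model_spec("BAYAREALIKE", d = 0.1, e = 0.1),
                        nz_availability())
  for (s in seq_along(proc$strata)) {
    cl <- proc$strata[[s]]$clado
    expect_true(all(cl$left == cl$anc & cl$right == cl$anc))
    expect_true(all(cl$w == 1))
  }
})

test_that("DIVALIKE allows sympatry for specialists and only vicariant splits for widespread ranges", {
  proc <- build_process(model_spec("DIVALIKE", d = 0.1, e = 0.1),
                        nz_availability())
  cl <- proc$strata[[1]]$clado
  single <- cl[cl$anc %in% c(1L, 2L, 4L), ]
  expect_true(all(single$cls == "sympatry"))
  wide2 <- cl[cl$anc == 3L, ]
  expect_equal(nrow(wide2), 2L)    # ({F},{O}) and ({O},{F})
  full <- cl[cl$anc == 7L, ]
  expect_equal(nrow(full), 6L)     # all ordered splits of {F,O,A}
  expect_true(all(full$cls == "vicariance"))
  expect_true(all(bitwAnd(full$left, full$right) == 0L))
  expect_true(all(bitwOr(full$left, full$right) == 7L))
})

test_that("founder-event weights compete with unit base weights and respect availability", {
  avFO <- av2()
  proc <- build_process(model_spec("DEC", jump = TRUE, d = 0.1, e = 0.1,
                                   j = 0.5), avFO)
  cl <- proc$strata[[1]]$clado
  row <- cl[cl$anc == 1L, ]  # {Forest}: sympatry (w 1) + 2 ordered jumps (w 0.5)
  expect_equal(sort(row$w), c(0.25, 0.25, 0.5))
  expect_equal(sum(row$cls == "jump"), 2L)
  # in the oldest stratum only Forest exists: no jump targets
  proc3 <- build_process(model_spec("DEC", jump = TRUE, d = 0.1, e = 0.1,
                                    j = 0.5), nz_availability())
  oldest <- proc3$strata[[3]]$clado
  expect_false(any(oldest$cls == "jump"))
})

test_that("rate matrices satisfy DEC bookkeeping across strata", {
  proc <- build_process(model_spec("DEC", d = 0.3, e = 0.07),
                        nz_availability())
  for (s in 1:3) {
    Q <- proc$strata[[s]]$Q
    expect_equal(rowSums(Q), rep(0, nrow(Q)), tolerance = 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
    expect_equal(Q[1, ], rep(0, 8))  # null state absorbing
    cl <- proc$strata[[s]]$clado
    sums <- tapply(cl$w, cl$anc, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
  # dispersal into a biome before its appearance is impossible
  Q3 <- proc$strata[[3]]$Q  # only Forest available
  expect_equal(Q3[2, 4], 0)  # {F} -> {F,O}
  expect_equal(Q3[2, 6], 0)  # {F} -> {F,A}
  # rate of each allowed gain scales with the number of occupied sources
  Q1 <- proc$strata[[1]]$Q
  expect_equal(Q1[2, 4], 0.3)       # {F} -> {F,O}: one source
  expect_equal(Q1[4, 8], 2 * 0.3)   # {F,O} -> {F,O,A}: two sources
})

test_that("matrix exponentials are row-stochastic and match an independent implementation", {
  skip_if_not_installed("Matrix")
  set.seed(3)
  for (rep in 1:5) {
    d <- runif(1, 0.01, 2); e <- runif(1, 0.01, 2); dt <- runif(1, 0.1, 6)
    proc <- build_process(model_spec("DEC", d = d, e = e), nz_availability())
    for (s in 1:3) {
      Q <- proc$strata[[s]]$Q
      P <- biomeshift:::expm_pade(Q * dt)
      ok <- proc$space$allowed[[s]]
      expect_equal(rowSums(P[ok, , drop = FALSE]),
                   rep(1, sum(ok)), tolerance = 1e-10)
      expect_equal(P, as.matrix(Matrix::expm(Q * dt)), tolerance = 1e-11,
                   ignore_attr = TRUE)
    }
  }
})
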