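test_that("tree simulation hits the target tip count deterministically", {
  tr <- simulate_tree(8, birth = 1, death = 0, seed = 3)
  expect_equal(length(tr$tip.label), 8L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::is.binary(tr))
  tr2 <- simulate_tree(8, birth = 1, death = 0, seed = 3)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # with extinction the surviving tip count is still exact
  tr3 <- simulate_tree(6, birth = 1, death = 0.4, seed = 9)
  expect_equal(length(tr3$tip.label), 6L)
})

test_that("pure-birth crown ages match the closed-form expectation", {
  # crown age of a Yule clade stopped just before the (n+1)th event:
  # E[T] = (H_n - 1) / lambda
  n <- 8; lambda <- 1
  depths <- vapply(1:400, function(i) {
    max(ape::node.depth.edgelength(simulate_tree(n, birth = lambda, seed = i)))
  }, numeric(1))
  expected <- (sum(1 / (1:n)) - 1) / lambda
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("a zero-rate history inherits the root state everywhere", {
  tr <- simulate_tree(10, seed = 2)
  truth <- simulate_history(tr, nz_availability(),
                            model_spec("DEC", d = 0, e = 0),
                            root_state = "Forest", seed = 4)
  expect_equal(nrow(truth$history$events), 0L)
  expect_true(all(unclass(truth$occ)[, "Forest"] == 1L))
  expect_true(all(rowSums(truth$occ) == 1L))
  cls <- classify_transitions(truth)
  expect_equal(cls$transitions, 0L)
})

test_that("single-branch gain frequencies match the two-state closed form", {
  # nearly-star tree: the 2 Ma branch to C is a two-state chain with e = 0;
  # P(tip C multi-biome) = 1 - exp(-d * 2)
  tr <- read_biome_newick(text = "((A:0.01,B:0.01):1.99,C:2);")
  d <- 0.35
  hits <- vapply(1:2000, function(i) {
    truth <- simulate_history(tr, av2(), model_spec("DEC", d = d, e = 0),
                              root_state = "Forest", seed = i)
    sum(unclass(truth$occ)["C", ]) > 1L
  }, logical(1))
  p_hat <- mean(hits)
  p_true <- 1 - exp(-d * 2)
  se <- sqrt(p_true * (1 - p_true) / length(hits))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("modal weights are Dirichlet over occupied biomes with the right moments", {
  m <- rbind(A = c(1, 1, 1), B = c(1, 1, 0), C = c(1, 0, 0))
  colnames(m) <- c("Forest", "Open", "Alpine")
  occ <- occupancy_matrix(m)
  w <- make_modal_weights(occ, concentration = 1, seed = 1)
  expect_equal(unname(rowSums(w)), rep(1, 3))
  expect_equal(unname(w["C", ]), c(1, 0, 0))  # specialist: weight 1
  expect_equal(unname(w["B", "Alpine"]), 0)   # no weight off-range
  # equal weights in the infinite-concentration limit, tie broken by order
  wInf <- make_modal_weights(occ, concentration = Inf, seed = 1)
  expect_equal(unname(wInf["A", ]), rep(1 / 3, 3))
  expect_equal(unname(unclass(collapse_to_modal(occ, wInf))["A", ]),
               c(1, 0, 0))
  # empirical mean weight 1/k over repeated draws
  draws <- vapply(1:3000, function(s)
    make_modal_weights(occ, 1, seed = s)["A", "Open"], numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1 / 3), 3 * se)
})

test_that("transition classification follows the detection typology and conserves tallies", {
  base <- data.frame(edge = 1:5, parent = 1, child = 2,
                     from_state = c(1L, 1L, 3L, 3L, 3L),
                     to_state   = c(2L, 3L, 3L, 1L, 3L),
                     from_modal = c(1L, 1L, 1L, 1L, 1L),
                     to_modal   = c(2L, 1L, 2L, 1L, 1L))
  truth <- list(per_branch = base)
  cls <- classify_transitions(truth)
  got <- cls$per_branch$class
  expect_equal(got[1], "true_positive_switch")         # {F} -> {O}
  expect_equal(got[2], "false_negative_expansion")     # {F} -> {F,O}, modal F
  expect_equal(got[3], "false_positive_modal_change")  # modal flip only
  expect_equal(got[4], "false_negative_reduction")     # {F,O} -> {F}, modal F
  expect_equal(got[5], "unchanged")
  expect_equal(cls$transitions + cls$unchanged, 5L)
  expect_equal(sum(cls$tallies), cls$transitions)
  # modal-changing expansion is a true positive under both codings
  exp_modal <- list(per_branch = data.frame(edge = 1, parent = 1, child = 2,
                                            from_state = 1L, to_state = 3L,
                                            from_modal = 1L, to_modal = 2L))
  expect_equal(classify_transitions(exp_modal)$per_branch$class,
               "true_positive_expansion_modal")
  # simulated truths always classify every branch
  for (s in 1:5) {
    truth <- simulate_biome_clade(n_tips = 8, d = 0.25, e = 0.08, seed = s)
    cls <- classify_transitions(truth)
    expect_equal(cls$transitions + cls$unchanged, nrow(truth$per_branch))
  }
})

test_that("synthetic meta tables honour the specialists-only limit and calibrate the paired test", {
  tb1 <- make_meta_table(12, specialist_range = c(1, 1),
                         b_decline_mean = 0.4, seed = 2)
  expect_equal(tb1$count_single, tb1$count_multiple)
  expect_true(all(tb1$b_decline_true == 0))
  # zero effect: one-tailed paired rejection frequency ~ alpha
  rej <- vapply(1:500, function(i) {
    tb <- make_meta_table(9, b_decline_mean = 0, noise_sd = 0.1,
                          seed = 1000 + i)
    paired_one_tailed(tb$rate_single, tb$rate_multiple)$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
  # a configured decline of 0.3 with no noise is detected at n = 9
  tb3 <- make_meta_table(9, b_decline_mean = 0.3, noise_sd = 0, seed = 4)
  expect_lt(paired_one_tailed(tb3$rate_single, tb3$rate_multiple)$p, 0.05)
})

test_that("parametric simulation from a fitted model returns valid occupancy data", {
  sim <- simulate_biome_clade(n_tips = 8, d = 0.2, e = 0.05, seed = 61)
  fit <- structure(list(tree = sim$tree, occ = sim$occ,
                        avail = nz_availability(),
                        spec = model_spec("DEC", d = 0.2, e = 0.05),
                        root_prior = NULL, n_tip = 8L),
                   class = "range_fit")
  occs <- simulate(fit, nsim = 3, seed = 5)
  expect_length(occs, 3L)
  for (o in occs) {
    expect_s3_class(o, "occupancy_matrix")
    expect_identical(sort(rownames(o)), sort(sim$tree$tip.label))
    expect_true(all(rowSums(o) >= 1))
  }
  occs2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(lapply(occs, unclass), lapply(occs2, unclass))
})
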