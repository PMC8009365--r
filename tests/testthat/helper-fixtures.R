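# Shared fixtures and independent oracles for the test suite.

av2 <- function() biome_availability(c("Forest", "Open"))

tree3 <- function() read_biome_newick(text = "((A:1,B:1):1,C:2);")

occ3 <- function(rows, biomes = c("Forest", "Open"),
                 taxa = c("A", "B", "C")) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(taxa, biomes)
  occupancy_matrix(m)
}

balanced_tree <- function(n = 32) {
  tr <- ape::compute.brlen(ape::stree(n, "balanced"), method = "Grafen")
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Independent likelihood oracle: explicit enumeration over internal-node
# states and cladogenetic events, recursive over a nested-list topology,
# transition probabilities from Matrix::expm. No stratification, no masking.
# `node` is either a tip state bitmask or list(left=, right=, llen=, rlen=).
oracle_lik <- function(node, proc) {
  Q <- proc$strata[[1]]$Q
  cl <- proc$strata[[1]]$clado
  n <- nrow(Q)
  below <- function(nd, state_top, len) {
    P <- as.matrix(Matrix::expm(Q * len))
    if (!is.list(nd)) return(P[state_top + 1L, nd + 1L])
    tot <- 0
    for (s in 1:(n - 1L)) {
      p_anc <- P[state_top + 1L, s + 1L]
      if (p_anc == 0) next
      tb <- cl[cl$anc == s, , drop = FALSE]
      acc <- 0
      for (r in seq_len(nrow(tb))) {
        acc <- acc + tb$w[r] * below(nd$left, tb$left[r], nd$llen) *
          below(nd$right, tb$right[r], nd$rlen)
      }
      tot <- tot + p_anc * acc
    }
    tot
  }
  states <- 1:(n - 1L)
  lik <- 0
  for (s in states) {
    tb <- cl[cl$anc == s, , drop = FALSE]
    acc <- 0
    for (r in seq_len(nrow(tb))) {
      acc <- acc + tb$w[r] * below(node$left, tb$left[r], node$llen) *
        below(node$right, tb$right[r], node$rlen)
    }
    lik <- lik + acc / length(states)
  }
  log(lik)
}

# Brute-force two-sample Welch formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = pt(t, df, lower.tail = FALSE))
}

oracle_paired <- function(single, multiple) {
  d <- multiple - single
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, df = length(d) - 1,
       p = pt(t, length(d) - 1, lower.tail = FALSE))
}

# Closed-form normal-equation OLS
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r2 = r2)
}

# Expected number of transitions of a CTMC bridge, by numerical integration:
# E[N | X0 = a, Xt = b] = sum_{i != j} q_ij int_0^t P_ai(s) P_jb(t-s) ds / P_ab(t)
oracle_bridge_events <- function(Q, a, b, t) {
  P <- function(s) as.matrix(Matrix::expm(Q * s))
  Pab <- P(t)[a, b]
  tot <- 0
  for (i in seq_len(nrow(Q))) {
    for (j in seq_len(nrow(Q))) {
      if (i == j || Q[i, j] <= 0) next
      f <- Vectorize(function(s) P(s)[a, i] * P(t - s)[j, b])
      tot <- tot + Q[i, j] * integrate(f, 0, t, rel.tol = 1e-9)$value
    }
  }
  tot / Pab
}

# Minimal hand-built event history for counting tests
manual_history <- function(event_edges, n_edges, n_tip = 4) {
  n <- length(event_edges)
  ev <- data.frame(edge = event_edges,
                   age = as.numeric(seq_len(n)),
                   type = rep("gain", n), biome = rep("Open", n),
                   from = rep(1L, n), to = rep(3L, n))
  structure(list(events = ev,
                 clado = data.frame(node = integer(0), edge_left = integer(0),
                                    edge_right = integer(0), anc = integer(0),
                                    left = integer(0), right = integer(0),
                                    cls = character(0)),
                 node_states = integer(0), n_tip = n_tip, n_edges = n_edges,
                 biomes = c("Forest", "Open")),
            class = "event_history")
}

fake_fit <- function(family, jump, lnL, k = if (jump) 3L else 2L) {
  structure(list(spec = model_spec(family, jump, d = 0.1, e = 0.1,
                                   j = if (jump) 0.1 else 0),
                 lnL = lnL, k = k, AIC = 2 * k - 2 * lnL, n_tip = 10L),
            class = "range_fit")
}
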