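# Phylogenetic signal for binary biome occupancy: the D statistic, scaled so
# that 1 is the expectation under a phylogenetically random tip arrangement
# and 0 under a threshold-Brownian (clumped) model. Low or negative values
# indicate conservatism; values above 1 indicate over-dispersion.

# Sum of sister-clade differences for each column of a tip-value matrix.
# Nodal values by the branch-length-weighted down-pass (contrast-style
# weights with branch-length extension), or plain averaging when
# weighted = FALSE. X rows must follow the tree's tip order.
d_sum <- function(tree, X, weighted = TRUE) {
  X <- as.matrix(X)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  elen_node <- numeric(n_all)
  elen_node[edges[, 2L]] <- po$edge.length
  val <- matrix(0, n_all, ncol(X))
  val[seq_len(n_tip), ] <- X
  ext <- numeric(n_all)
  acc <- numeric(ncol(X))
  kids <- vector("list", n_all)
  for (k in seq_len(nrow(edges)))
    kids[[edges[k, 1L]]] <- c(kids[[edges[k, 1L]]], edges[k, 2L])
  seen <- rep(FALSE, n_all)
  for (k in seq_len(nrow(edges))) {
    z <- edges[k, 1L]
    if (seen[z]) next
    seen[z] <- TRUE
    ch <- kids[[z]]
    c1 <- ch[1L]; c2 <- ch[2L]
    v1 <- val[c1, ]; v2 <- val[c2, ]
    acc <- acc + abs(v1 - v2)
    if (!weighted) {
      val[z, ] <- (v1 + v2) / 2
      next
    }
    b1 <- elen_node[c1] + ext[c1]
    b2 <- elen_node[c2] + ext[c2]
    if (b1 == 0 && b2 == 0) {
      val[z, ] <- (v1 + v2) / 2
    } else if (b1 == 0) {
      val[z, ] <- v1
    } else if (b2 == 0) {
      val[z, ] <- v2
    } else {
      val[z, ] <- (v1 / b1 + v2 / b2) / (1 / b1 + 1 / b2)
      ext[z] <- b1 * b2 / (b1 + b2)
    }
  }
  acc
}

# Tip values of Brownian simulations: one column per simulation, unit rate.
simulate_brownian_tips <- function(tree, n_sim) {
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  n_edge <- nrow(po$edge)
  inc <- matrix(stats::rnorm(n_edge * n_sim), n_edge, n_sim) *
    sqrt(po$edge.length)
  # accumulate increments from the root down (reverse postorder = preorder)
  vals <- matrix(0, n_tip + tree$Nnode, n_sim)
  for (k in rev(seq_len(n_edge))) {
    vals[po$edge[k, 2L], ] <- vals[po$edge[k, 1L], ] + inc[k, ]
  }
  vals[seq_len(n_tip), , drop = FALSE]
}

#' D statistic for a binary trait on a phylogeny
#'
#' Computes the observed sum of sister-clade differences of a binary trait,
#' compares it with the expectations under (i) random shuffling of the trait
#' across tips and (ii) a Brownian threshold model (a continuous Brownian
#' trait simulated on the tree and thresholded to match the observed
#' prevalence exactly), and scales it as
#' \deqn{D = (d_{obs} - \bar d_{Brownian}) / (\bar d_{random} - \bar
#' d_{Brownian}).}
#' An invariant trait (all 0 or all 1) has no defined D and is returned with
#' the \code{undefined} flag set (\code{D = NA}).
#'
#' @param tree a rooted bifurcating \code{"phylo"} with branch lengths.
#' @param trait binary 0/1 vector, named by tip label (or in tip order).
#' @param n_perm permutations for the random reference.
#' @param n_sim Brownian simulations for the clumped reference.
#' @param seed integer seed.
#' @param weighted branch-length-weighted nodal estimation (default) or
#'   equal-weights averaging.
#' @param smoothing add-one smoothing of the p-value proportions (default
#'   off, mirroring raw proportions).
#' @param alpha significance level for the conservatism call.
#' @return an object of class \code{"dstat"} with \code{d_obs}, reference
#'   means, \code{D}, \code{p_random} (fraction of permutation d values <=
#'   observed; low = clumped), \code{p_brownian} (fraction of Brownian d
#'   values >= observed), \code{undefined} and \code{conservatism}
#'   (\code{p_random < alpha} together with \code{D < 1}).
#' @export
d_statistic <- function(tree, trait, n_perm = 1000L, n_sim = 1000L,
                        seed = 1L, weighted = TRUE, smoothing = FALSE,
                        alpha = 0.05) {
  validate_phylogeny(tree)
  n_tip <- length(tree$tip.label)
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), tree$tip.label))
      stop("trait names do not match tip labels")
    trait <- trait[tree$tip.label]
  } else if (length(trait) != n_tip) {
    stop("trait length does not match number of tips")
  }
  trait <- as.integer(trait)
  if (anyNA(trait) || !all(trait %in% c(0L, 1L))) stop("trait must be binary 0/1")
  n1 <- sum(trait)
  out <- list(n_tip = n_tip, prevalence = n1, n_perm = n_perm, n_sim = n_sim,
              alpha = alpha)
  if (n1 == 0L || n1 == n_tip) {
    out <- c(out, list(d_obs = NA_real_, mean_d_random = NA_real_,
                       mean_d_brownian = NA_real_, D = NA_real_,
                       p_random = NA_real_, p_brownian = NA_real_,
                       undefined = TRUE, conservatism = NA))
    return(structure(out, class = "dstat"))
  }
  set.seed(seed)
  d_obs <- d_sum(tree, matrix(trait, ncol = 1L), weighted)[1L]
  perm <- vapply(seq_len(n_perm), function(i) sample(trait), integer(n_tip))
  d_perm <- d_sum(tree, perm, weighted)
  bm <- simulate_brownian_tips(tree, n_sim)
  # prevalence-matched threshold; sign-canonicalised so that D is exactly
  # invariant under relabelling 0 <-> 1
  if (2L * n1 > n_tip) bm <- -bm
  thr <- apply(bm, 2L, function(x) {
    y <- integer(n_tip)
    y[order(x, decreasing = TRUE)[seq_len(n1)]] <- 1L
    y
  })
  d_bm <- d_sum(tree, thr, weighted)
  denom <- mean(d_perm) - mean(d_bm)
  D <- if (abs(denom) < .Machine$double.eps) NA_real_ else
    (d_obs - mean(d_bm)) / denom
  sm <- if (smoothing) 1 else 0
  p_random <- (sum(d_perm <= d_obs) + sm) / (n_perm + sm)
  p_brownian <- (sum(d_bm >= d_obs) + sm) / (n_sim + sm)
  out <- c(out, list(d_obs = d_obs, mean_d_random = mean(d_perm),
                     mean_d_brownian = mean(d_bm), D = D,
                     p_random = p_random, p_brownian = p_brownian,
                     undefined = is.na(D),
                     conservatism = !is.na(D) && p_random < alpha && D < 1))
  structure(out, class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("D statistic: NA (invariant or degenerate trait, prevalence ",
        x$prevalence, "/", x$n_tip, ")\n", sep = "")
    return(invisible(x))
  }
  cat("D statistic: ", round(x$D, 2), "  (d_obs ", round(x$d_obs, 3),
      "; random ", round(x$mean_d_random, 3), ", Brownian ",
      round(x$mean_d_brownian, 3), ")\n", sep = "")
  cat("  p(random) = ", round(x$p_random, 4), ", p(Brownian) = ",
      round(x$p_brownian, 4),
      if (isTRUE(x$conservatism)) "  *biome conservatism*", "\n", sep = "")
  invisible(x)
}

#' D statistics for every biome under both coding approaches
#'
#' Convenience batch over the columns of a multiple-biome occupancy matrix
#' and its modal (single) collapse, reproducing the layout of a
#' per-clade-by-biome phylogenetic signal table.
#'
#' @param tree \code{"phylo"}.
#' @param occ_multiple multiple-biome \code{"occupancy_matrix"}.
#' @param occ_single single-biome \code{"occupancy_matrix"} (e.g. from
#'   \code{\link{collapse_to_modal}}).
#' @param ... passed to \code{\link{d_statistic}}.
#' @return data.frame with one row per biome and columns \code{D_single},
#'   \code{p_single}, \code{D_multiple}, \code{p_multiple}.
#' @export
d_statistic_table <- function(tree, occ_multiple, occ_single, ...) {
  biomes <- colnames(occ_multiple)
  rows <- lapply(biomes, function(b) {
    ds <- d_statistic(tree, unclass(occ_single)[tree$tip.label, b], ...)
    dm <- d_statistic(tree, unclass(occ_multiple)[tree$tip.label, b], ...)
    data.frame(biome = b, D_single = ds$D, p_single = ds$p_random,
               D_multiple = dm$D, p_multiple = dm$p_random)
  })
  do.call(rbind, rows)
}
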