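# Felsenstein pruning for the time-stratified range-evolution process.
#
# Branches are segmented at stratum boundaries; each segment is propagated
# with the matrix exponential of its stratum's Q. When the conditional
# likelihood vector crosses into an older stratum, entries of states
# containing then-unavailable biomes are set to 0 (no renormalisation).
# Internal nodes combine daughters through the cladogenesis table of the
# node's stratum; the root likelihood is the mean over non-null states
# allowed at the root's age (uniform root prior) unless overridden.

# Geometry + tip data preparation, independent of rate parameters.
prepare_pruning <- function(tree, occ, avail) {
  validate_phylogeny(tree)
  if (!is_ultrametric_tol(tree))
    warning("tree is not ultrametric; strata assigned from absolute node ages")
  occ <- align_occupancy(occ, tree)
  space <- range_state_space(avail)
  strata <- space$strata
  ages <- node_ages(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  elen <- po$edge.length
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seg <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges))) {
    a0 <- ages[edges[k, 2L]]; a1 <- ages[edges[k, 1L]]
    if (a1 < a0) a1 <- a0  # numerical guard on tiny negative spans
    bks <- strata$upper[is.finite(strata$upper) & strata$upper > a0 & strata$upper < a1]
    cuts <- c(a0, bks, a1)
    dt <- diff(cuts)
    keep <- dt > 0
    seg[[k]] <- data.frame(dt = dt[keep],
                           age_bot = cuts[-length(cuts)][keep],
                           age_top = cuts[-1L][keep],
                           stratum = stratum_at(strata, cuts[-1L][keep]))
  }
  tip_state <- occ_states(occ, space$biomes)
  tip_stratum <- stratum_at(strata, ages[seq_len(n_tip)])
  for (i in seq_len(n_tip)) {
    if (!space$allowed[[tip_stratum[i]]][tip_state[i] + 1L])
      stop("tip \"", tree$tip.label[i], "\" occupies state ",
           state_label(tip_state[i], space$biomes),
           " which is not allowed at its age")
  }
  node_stratum <- stratum_at(strata, ages)
  list(tree = tree, occ = occ, avail = avail, space = space, strata = strata,
       ages = ages, edges = edges, elen = elen, seg = seg, root = root,
       n_tip = n_tip, tip_state = tip_state, node_stratum = node_stratum)
}

# Per-stratum propagators and cladogenesis index tables for given parameters.
make_propagators <- function(prep, proc) {
  n <- prep$space$n_states
  n_str <- nrow(prep$strata)
  # P for every unique (stratum, dt) segment, rows/cols of disallowed states
  # zeroed so crossing into an older stratum re-masks the vector
  segP <- vector("list", length(prep$seg))
  for (k in seq_along(prep$seg)) {
    sg <- prep$seg[[k]]
    Ps <- vector("list", nrow(sg))
    for (i in seq_len(nrow(sg))) {
      s <- sg$stratum[i]
      ok <- prep$space$allowed[[s]]
      P <- expm_pade(proc$strata[[s]]$Q * sg$dt[i])
      P[!ok, ] <- 0
      P[, !ok] <- 0
      Ps[[i]] <- P
    }
    segP[[k]] <- Ps
  }
  # cladogenesis tables as flat index vectors per stratum
  cl <- vector("list", n_str)
  for (s in seq_len(n_str)) {
    tb <- proc$strata[[s]]$clado
    cl[[s]] <- list(anc = tb$anc + 1L, l = tb$left + 1L, r = tb$right + 1L,
                    w = tb$w, cls = tb$cls)
  }
  list(segP = segP, clado = cl)
}

# Propagate a conditional likelihood vector from the bottom (young end) of an
# edge to its top (old end).
edge_up <- function(v, Ps) {
  for (P in Ps) v <- P %*% v
  as.vector(v)
}

combine_clado <- function(cl, vL, vR) {
  vals <- cl$w * vL[cl$l] * vR[cl$r]
  out <- numeric(length(vL))
  agg <- rowsum(vals, cl$anc)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# Full pruning pass; returns per-node combined conditionals, per-edge
# top-of-branch conditionals and the log-likelihood.
prune_all <- function(prep, props, root_prior = NULL) {
  n <- prep$space$n_states
  n_tip <- prep$n_tip
  n_all <- n_tip + prep$tree$Nnode
  L <- matrix(0, n, n_all)       # conditionals at node (tips: indicator)
  Ltop <- matrix(0, n, nrow(prep$edges))  # conditional at top of each edge
  logscale <- 0
  for (i in seq_len(n_tip)) L[prep$tip_state[i] + 1L, i] <- 1
  child_edges <- vector("list", n_all)
  for (k in seq_len(nrow(prep$edges)))
    child_edges[[prep$edges[k, 1L]]] <- c(child_edges[[prep$edges[k, 1L]]], k)
  done <- rep(FALSE, n_all)
  done[seq_len(n_tip)] <- TRUE
  failed <- FALSE
  combine_node <- function(node) {
    ks <- child_edges[[node]]
    cl <- props$clado[[prep$node_stratum[node]]]
    v <- combine_clado(cl, Ltop[, ks[1L]], Ltop[, ks[2L]])
    sc <- sum(v)
    if (sc <= 0 || !is.finite(sc)) {
      failed <<- TRUE
      sc <- 1
    }
    L[, node] <<- v / sc
    logscale <<- logscale + log(sc)
    done[node] <<- TRUE
  }
  # postorder edge order guarantees a node's child edges precede its own edge
  for (k in seq_len(nrow(prep$edges))) {
    child <- prep$edges[k, 2L]
    if (!done[child]) combine_node(child)
    if (failed) break
    Ltop[, k] <- edge_up(L[, child], props$segP[[k]])
  }
  if (!failed && !done[prep$root]) combine_node(prep$root)
  if (failed) return(list(loglik = -Inf, L = L, Ltop = Ltop, logscale = -Inf))
  ok <- prep$space$allowed[[prep$node_stratum[prep$root]]]
  prior <- numeric(n)
  if (is.null(root_prior)) {
    idx <- which(ok)[-1L]  # drop null state
    prior[idx] <- 1 / length(idx)
  } else {
    stopifnot(length(root_prior) == n)
    prior <- root_prior
  }
  lik <- sum(prior * L[, prep$root])
  list(loglik = if (lik > 0) log(lik) + logscale else -Inf,
       L = L, Ltop = Ltop, logscale = logscale, prior = prior)
}

#' Log-likelihood of tip biome occupancies under a range-evolution model
#'
#' Computes the pruning log-likelihood of an occupancy matrix on a dated tree
#' under the time-stratified DEC-family process. Each tip's conditional
#' likelihood is 1 for its exact observed occupancy set and 0 otherwise.
#'
#' @param tree a dated \code{"phylo"} (branch lengths in Ma).
#' @param occ an \code{"occupancy_matrix"} whose taxa match the tips.
#' @param spec a \code{"model_spec"} (family, jump, d, e, j).
#' @param avail a \code{"biome_availability"}.
#' @param root_prior \code{NULL} for the default uniform prior over non-null
#'   states allowed at the root's age, or a numeric vector of length
#'   \code{2^B} over state bitmask order.
#' @return the natural-log likelihood (scalar; \code{-Inf} for impossible
#'   data).
#' @examples
#' tr <- read_biome_newick(text = "((A:1,B:1):1,C:2);")
#' occ <- occupancy_matrix(matrix(c(1, 1, 1, 0, 1, 0), 3, 2,
#'   dimnames = list(c("A", "B", "C"), c("Forest", "Open"))))
#' av <- biome_availability(c("Forest", "Open"))
#' range_loglik(tr, occ, model_spec("DEC", d = 0.1, e = 0.05), av)
#' @export
range_loglik <- function(tree, occ, spec, avail, root_prior = NULL) {
  prep <- prepare_pruning(tree, occ, avail)
  proc <- build_process(spec, avail)
  props <- make_propagators(prep, proc)
  prune_all(prep, props, root_prior)$loglik
}
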