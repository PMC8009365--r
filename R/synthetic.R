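# Synthetic-data generators: birth-death trees, forward simulation of
# biome-occupancy histories with full truth retained, modal-biome weights,
# the shift-detection typology classifier, and synthetic meta-analysis
# tables. Everything is seed-reproducible so the whole pipeline can be
# exercised with known truth.

#' Simulate a birth-death tree conditioned on a tip count
#'
#' Forward Gillespie simulation from a single lineage, stopped immediately
#' before the event that would change the number of living lineages away
#' from \code{n_tips}; extinct lineages are pruned and the crown tree of the
#' survivors returned. Simulations in which the clade dies out (or fails to
#' reach \code{n_tips}) are rejected and rerun, up to \code{max_tries}.
#'
#' @param n_tips target number of surviving tips (>= 3).
#' @param birth speciation rate (per lineage per Ma).
#' @param death extinction rate (must be < birth).
#' @param seed integer seed.
#' @param max_tries rejection cap for extinct clades.
#' @return an ultrametric \code{"phylo"} with exactly \code{n_tips} tips.
#' @export
simulate_tree <- function(n_tips, birth = 0.3, death = 0, seed = 1L,
                          max_tries = 100L) {
  stopifnot(n_tips >= 3L, birth > death, death >= 0)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    parent <- c(NA_integer_)   # lineage records
    t_birth <- c(0)
    t_death <- c(NA_real_)     # NA = alive
    alive <- 1L
    t <- 0
    ok <- TRUE
    repeat {
      k <- length(alive)
      rate <- (birth + death) * k
      dt <- stats::rexp(1L, rate)
      if (k == n_tips) { t <- t + dt; break }  # stop just before next event
      t <- t + dt
      lin <- alive[sample.int(k, 1L)]
      if (stats::runif(1L) < birth / (birth + death)) {
        id1 <- length(parent) + 1L; id2 <- id1 + 1L
        parent <- c(parent, lin, lin)
        t_birth <- c(t_birth, t, t)
        t_death <- c(t_death, NA_real_, NA_real_)
        t_death[lin] <- t
        alive <- c(setdiff(alive, lin), id1, id2)
      } else {
        t_death[lin] <- t
        alive <- setdiff(alive, lin)
        if (!length(alive)) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    tr <- build_phylo_from_lineages(parent, t_birth, t_death, t)
    if (length(tr$tip.label) == n_tips) return(tr)
  }
  stop("failed to simulate a surviving ", n_tips, "-tip clade in ",
       max_tries, " attempts")
}

# Assemble an ape tree from lineage records; extinct lineages pruned, stem
# removed, branch lengths in time units (tips at the present).
build_phylo_from_lineages <- function(parent, t_birth, t_death, t_end) {
  end <- ifelse(is.na(t_death), t_end, t_death)
  kids <- split(seq_along(parent)[-1L], parent[-1L])
  surv <- is.na(t_death)
  has_surv <- logical(length(parent))
  ord <- order(t_birth, decreasing = TRUE)
  for (i in ord) {
    ch <- kids[[as.character(i)]]
    has_surv[i] <- surv[i] || (length(ch) && any(has_surv[ch]))
  }
  nwk <- function(i) {
    ch <- kids[[as.character(i)]]
    ch <- if (is.null(ch)) integer(0) else ch[has_surv[ch]]
    len <- end[i] - t_birth[i]
    if (!length(ch)) {
      sprintf("t%d:%.10f", i, len)
    } else if (length(ch) == 1L) {
      # extinct sister pruned: splice the child through
      inner <- nwk(ch)
      # add this lineage's length onto the child's terminal length
      sub <- sub(":([0-9.eE+-]+)$", "", inner)
      l2 <- as.numeric(sub(".*:", "", inner))
      sprintf("%s:%.10f", sub, l2 + len)
    } else {
      sprintf("(%s,%s):%.10f", nwk(ch[1L]), nwk(ch[2L]), len)
    }
  }
  txt <- paste0(nwk(1L), ";")
  tr <- ape::read.tree(text = txt)
  tr$root.edge <- NULL
  tr$tip.label <- paste0("t", seq_along(tr$tip.label))
  tr
}

#' Forward-simulate a biome occupancy history on a tree
#'
#' Gillespie simulation of the range-evolution process along a dated tree
#' under stratified biome availability: gains at rate d per occupied source
#' biome into each available unoccupied biome, losses at rate e per occupied
#' biome, and cladogenetic outcomes drawn from the family's normalised event
#' table at each node. A lineage losing its last biome (null range) causes
#' the whole clade to be resimulated (up to \code{max_tries}), keeping tip
#' counts fixed. Modal-biome weights are drawn for every node from a
#' symmetric Dirichlet over its occupied biomes, so the truth record carries
#' both the occupancy history and the modal-biome history.
#'
#' @param tree dated \code{"phylo"}.
#' @param avail \code{"biome_availability"}.
#' @param spec \code{"model_spec"} with the generating parameters.
#' @param root_state biome-set bitmask or character vector of biome names for
#'   the root state (must be allowed at the root's age).
#' @param concentration symmetric Dirichlet concentration for modal weights
#'   (\code{Inf} = exactly equal weights).
#' @param seed integer seed.
#' @param max_tries resimulation cap for clades hitting the null range.
#' @param allow_null \code{"reject"} (default): losses to the null range are
#'   possible and a clade in which any lineage empties its range is thrown
#'   away and resimulated — exact conditioning on survival, practical for
#'   small and mid-sized clades; \code{"forbid"}: the loss of a lineage's
#'   last biome is censored (rate 0), so every lineage stays occupied —
#'   the approximate conditioning needed for large clades, where whole-clade
#'   rejection is hopeless because the expected number of null hits grows
#'   with total branch length.
#' @return a list (truth record): \code{occ} (multiple-biome
#'   \code{"occupancy_matrix"}), \code{weights} (tip modal weights),
#'   \code{occ_single} (modal collapse), \code{history} (an
#'   \code{"event_history"}), \code{node_modal} (modal biome index per
#'   node), and \code{per_branch} (data.frame of per-branch true states and
#'   modal biomes at both ends).
#' @export
simulate_history <- function(tree, avail, spec, root_state = 1L,
                             concentration = 1, seed = 1L, max_tries = 100L,
                             allow_null = c("reject", "forbid")) {
  allow_null <- match.arg(allow_null)
  validate_phylogeny(tree)
  if (is.character(root_state))
    root_state <- sum(2L^(match(root_state, avail$biomes) - 1L))
  root_state <- as.integer(root_state)
  proc <- build_process(spec, avail)
  space <- proc$space
  strata <- space$strata
  ages <- node_ages(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  root_stratum <- stratum_at(strata, ages[root])
  if (!space$allowed[[root_stratum]][root_state + 1L])
    stop("root state not allowed at the root's age")
  child_edges <- vector("list", n_tip + tree$Nnode)
  for (k in seq_len(nrow(edges)))
    child_edges[[edges[k, 1L]]] <- c(child_edges[[edges[k, 1L]]], k)
  clado_rows <- function(s, anc) {
    tb <- proc$strata[[s]]$clado
    tb[tb$anc == anc, , drop = FALSE]
  }
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    failed <- FALSE
    node_state <- integer(n_tip + tree$Nnode)
    node_state[root] <- root_state
    events <- list()
    clado <- list()
    stack <- root
    while (length(stack) && !failed) {
      node <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      s_node <- stratum_at(strata, ages[node])
      tb <- clado_rows(s_node, node_state[node])
      ev <- tb[sample.int(nrow(tb), 1L, prob = tb$w), ]
      ks <- child_edges[[node]]
      clado[[length(clado) + 1L]] <-
        data.frame(node = node, edge_left = ks[1L], edge_right = ks[2L],
                   anc = node_state[node], left = ev$left, right = ev$right,
                   cls = ev$cls)
      for (side in 1:2) {
        k <- ks[side]
        st <- if (side == 1L) ev$left else ev$right
        child <- edges[k, 2L]
        a <- ages[node]
        a_end <- ages[child]
        while (a > a_end) {
          s <- stratum_at(strata, a)
          # a tiny step below the boundary keeps the stratum assignment of
          # the open interval (lower, a)
          seg_lo <- max(a_end, strata$lower[s])
          q <- proc$strata[[s]]$Q[st + 1L, ]
          q[st + 1L] <- 0
          if (allow_null == "forbid") q[1L] <- 0
          tot <- sum(q)
          if (tot <= 0) { a <- seg_lo; if (a <= a_end) break else next }
          dt <- stats::rexp(1L, tot)
          if (a - dt <= seg_lo) { a <- seg_lo; if (a <= a_end) break else next }
          a <- a - dt
          to <- sample.int(length(q), 1L, prob = q) - 1L
          delta <- bitwXor(st, to)
          events[[length(events) + 1L]] <-
            data.frame(edge = k, age = a,
                       type = if (bitwAnd(to, delta) == delta) "gain" else "loss",
                       biome = space$biomes[round(log2(delta)) + 1L],
                       from = st, to = to)
          st <- to
          if (st == 0L) { failed <- TRUE; break }
        }
        if (failed) break
        node_state[child] <- st
        if (child > n_tip) stack <- c(stack, child)
      }
    }
    if (!failed) {
      return(assemble_truth(tree, avail, space, edges, node_state, events,
                            clado, concentration))
    }
  }
  stop("clade hit the null range in all ", max_tries, " simulation attempts")
}

# Build the truth record: occupancy matrices, modal weights/biomes, and the
# per-branch transition table used by classify_transitions.
assemble_truth <- function(tree, avail, space, edges, node_state, events,
                           clado, concentration) {
  n_tip <- length(tree$tip.label)
  B <- length(space$biomes)
  occ <- matrix(0L, n_tip, B, dimnames = list(tree$tip.label, space$biomes))
  for (i in seq_len(n_tip)) occ[i, bits_of(node_state[i], B) + 1L] <- 1L
  occ <- occupancy_matrix(occ, mode = "multiple")
  # modal weights at every node (tips + internal), Dirichlet per occupied set
  n_all <- n_tip + tree$Nnode
  node_modal <- integer(n_all)
  weights <- matrix(0, n_tip, B, dimnames = dimnames(occ))
  for (v in seq_len(n_all)) {
    bits <- bits_of(node_state[v], B) + 1L
    w <- dirichlet_draw(length(bits), concentration)
    node_modal[v] <- bits[which.max(w)]
    if (v <= n_tip) weights[v, bits] <- w
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(edge = integer(0), age = numeric(0), type = character(0),
               biome = character(0), from = integer(0), to = integer(0))
  cl <- do.call(rbind, clado)
  history <- structure(list(events = ev, clado = cl, node_states = node_state,
                            n_tip = n_tip, n_edges = nrow(edges),
                            biomes = space$biomes),
                       class = "event_history")
  per_branch <- data.frame(
    edge = seq_len(nrow(edges)),
    parent = edges[, 1L], child = edges[, 2L],
    from_state = node_state[edges[, 1L]],
    to_state = node_state[edges[, 2L]],
    from_modal = node_modal[edges[, 1L]],
    to_modal = node_modal[edges[, 2L]])
  occ_single <- collapse_to_modal(occ, weights)
  list(occ = occ, weights = weights, occ_single = occ_single,
       history = history, node_modal = node_modal, per_branch = per_branch,
       tree = tree, avail = avail)
}

dirichlet_draw <- function(k, concentration) {
  if (k == 1L) return(1)
  if (is.infinite(concentration)) return(rep(1 / k, k))
  g <- stats::rgamma(k, shape = concentration)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Draw modal-biome weights for an occupancy matrix
#'
#' Symmetric Dirichlet proportions over each taxon's occupied biomes,
#' supplying the "largest proportion of range" input for
#' \code{\link{collapse_to_modal}}. Specialists get weight 1 on their biome.
#'
#' @param occ \code{"occupancy_matrix"}.
#' @param concentration Dirichlet concentration (> 0; \code{Inf} = exactly
#'   equal weights, leaving the modal biome to the fixed-order tie-break).
#' @param seed integer seed.
#' @return numeric weights matrix matching \code{occ}.
#' @export
make_modal_weights <- function(occ, concentration = 1, seed = 1L) {
  stopifnot(concentration > 0)
  set.seed(seed)
  m <- unclass(occ)
  w <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    bits <- which(m[i, ] == 1L)
    w[i, bits] <- dirichlet_draw(length(bits), concentration)
  }
  w
}

#' Classify true lineage transitions by detectability under each coding
#'
#' Applies the shift-detection typology to each branch of a simulated truth
#' record, comparing the occupancy set and modal biome at the two ends of
#' the branch: biome switches and modal-changing expansions are detectable
#' under both codings (true positives for the single-biome approach);
#' expansions into a minor (non-modal) biome and reductions that leave the
#' modal biome unchanged are invisible to single-biome coding (false
#' negatives); a modal change with no true gain or loss is a single-coding
#' false positive. Reductions that do change the modal biome are grouped
#' with the switch-like true positives.
#'
#' @param truth a truth record from \code{\link{simulate_history}}.
#' @param single_detected,multiple_detected optional integer vectors of edge
#'   ids detected as shifted by the two pipelines, cross-tabulated against
#'   the typology when given.
#' @return a list with \code{tallies} (named counts per category,
#'   \code{transitions} total and \code{unchanged}), \code{per_branch}
#'   classification, and optional \code{detection} cross-tabulation.
#' @export
classify_transitions <- function(truth, single_detected = NULL,
                                 multiple_detected = NULL) {
  pb <- truth$per_branch
  gained <- bitwAnd(pb$to_state, bitwNot(pb$from_state))
  lost <- bitwAnd(pb$from_state, bitwNot(pb$to_state))
  modal_change <- pb$from_modal != pb$to_modal
  cls <- character(nrow(pb))
  for (i in seq_len(nrow(pb))) {
    g <- gained[i] > 0L; l <- lost[i] > 0L; m <- modal_change[i]
    cls[i] <- if (!g && !l && !m) "unchanged"
    else if (g && l) "true_positive_switch"
    else if (g && !l && m) "true_positive_expansion_modal"
    else if (g && !l && !m) "false_negative_expansion"
    else if (!g && l && !m) "false_negative_reduction"
    else if (!g && l && m) "true_positive_switch"  # modal biome lost
    else "false_positive_modal_change"             # modal flip, no gain/loss
  }
  cats <- c("true_positive_switch", "true_positive_expansion_modal",
            "false_negative_expansion", "false_negative_reduction",
            "false_positive_modal_change")
  tallies <- vapply(cats, function(cc) sum(cls == cc), integer(1))
  out <- list(tallies = tallies,
              transitions = sum(cls != "unchanged"),
              unchanged = sum(cls == "unchanged"),
              per_branch = data.frame(edge = pb$edge, class = cls))
  if (!is.null(single_detected) || !is.null(multiple_detected)) {
    out$detection <- data.frame(
      edge = pb$edge, class = cls,
      single = pb$edge %in% single_detected,
      multiple = pb$edge %in% multiple_detected)
  }
  out
}

#' Simulate a complete clade dataset
#'
#' Convenience wrapper: birth-death tree + forward occupancy history +
#' modal weights + single-biome collapse, with all truth retained.
#'
#' @param n_tips tips in the simulated clade.
#' @param d,e,j generating rates (see \code{\link{model_spec}}).
#' @param family cladogenetic family.
#' @param jump founder-event component in the generating model?
#' @param birth,death tree simulation rates.
#' @param avail \code{"biome_availability"} (default the three-biome
#'   Forest/Open/Alpine system).
#' @param root_state root biome set (name(s) or bitmask).
#' @param concentration modal-weight Dirichlet concentration.
#' @param seed integer seed.
#' @param allow_null passed to \code{\link{simulate_history}}.
#' @return the truth record of \code{\link{simulate_history}} (with
#'   \code{tree} attached).
#' @export
simulate_biome_clade <- function(n_tips, d = 0.1, e = 0.03, family = "DEC",
                                 jump = FALSE, j = 0, birth = 0.3, death = 0,
                                 avail = nz_availability(),
                                 root_state = "Forest", concentration = 1,
                                 seed = 1L, allow_null = "reject") {
  tree <- simulate_tree(n_tips, birth = birth, death = death,
                        seed = derive_seed(seed, 1L))
  spec <- model_spec(family, jump, d = d, e = e, j = j)
  simulate_history(tree, avail, spec, root_state = root_state,
                   concentration = concentration,
                   seed = derive_seed(seed, 2L), allow_null = allow_null)
}

#' @export
simulate.range_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(2^30, 1L)
  lapply(seq_len(nsim), function(i) {
    truth <- simulate_history(object$tree, object$avail, object$spec,
                              root_state = default_root_state(object$avail),
                              seed = derive_seed(seed, i))
    truth$occ
  })
}

default_root_state <- function(avail) {
  2L^(which(is.infinite(avail$appearance))[1L] - 1L)
}

#' Generate a synthetic meta-analysis table
#'
#' Clade records (size, specialists, shift counts under both codings) drawn
#' with a configurable proportional decline in shift rate between multiple-
#' and single-biome coding, for calibrating and power-testing the
#' meta-analysis statistics. Counts are floored to whole numbers as in the
#' compiled published table; a clade of pure specialists has identical
#' counts under both codings.
#'
#' @param n_clades rows to generate.
#' @param size_range clade-size range (inclusive).
#' @param specialist_range range of the specialist fraction.
#' @param rate_range range of the multiple-coding shift rate.
#' @param b_decline_mean mean proportional decline (0 = no effect).
#' @param noise_sd SD of the per-clade decline noise.
#' @param seed integer seed.
#' @return data.frame with columns clade, clade_size, specialists_n,
#'   specialists_pct, count_multiple, rate_multiple, count_single,
#'   rate_single, b_decline_true.
#' @export
make_meta_table <- function(n_clades, size_range = c(7L, 55L),
                            specialist_range = c(0.3, 0.8),
                            rate_range = c(0.3, 1.3),
                            b_decline_mean = 0, noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  size <- sample(size_range[1L]:size_range[2L], n_clades, replace = TRUE)
  sf <- stats::runif(n_clades, specialist_range[1L], specialist_range[2L])
  rm_ <- stats::runif(n_clades, rate_range[1L], rate_range[2L])
  decl <- b_decline_mean + stats::rnorm(n_clades, 0, noise_sd)
  cm <- floor(rm_ * size)
  cs <- ifelse(sf >= 1, cm, floor(pmax(0, rm_ * (1 - decl)) * size))
  data.frame(clade = paste0("clade", seq_len(n_clades)),
             clade_size = size,
             specialists_n = round(sf * size),
             specialists_pct = 100 * round(sf * size) / size,
             count_multiple = cm, rate_multiple = cm / size,
             count_single = cs, rate_single = cs / size,
             b_decline_true = ifelse(sf >= 1, 0, decl))
}
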