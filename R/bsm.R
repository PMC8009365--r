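# Biogeographic stochastic mapping: sampling full biome-occupancy histories
# conditional on the tip data and a fitted model, and counting biome shifts.
#
# Node states are drawn root-to-tips from the pruning conditionals, branch
# paths by endpoint-conditioned uniformization within each stratum segment
# (with a rejection-sampling fallback), and cladogenetic outcomes from the
# cladogenesis table weighted by the daughter subtree conditionals.

# Build the sampling engine: pruning pass + per-stratum uniformization
# pieces. `base` (a previous engine on the same tree/avail/spec) lets the
# geometry, propagators and uniformization tables be reused when only the
# tip occupancies change, e.g. across null replicates.
make_bsm_engine <- function(tree, occ, avail, spec, root_prior = NULL,
                            base = NULL) {
  if (!is.null(base)) {
    prep <- base$prep
    occ <- align_occupancy(occ, tree)
    tip_state <- occ_states(occ, prep$space$biomes)
    tip_stratum <- stratum_at(prep$strata, prep$ages[seq_len(prep$n_tip)])
    for (i in seq_len(prep$n_tip)) {
      if (!prep$space$allowed[[tip_stratum[i]]][tip_state[i] + 1L])
        stop("tip \"", tree$tip.label[i], "\" occupies a state not allowed ",
             "at its age")
    }
    prep$tip_state <- tip_state
    prep$occ <- occ
    pr <- prune_all(prep, base$props, root_prior)
    if (!is.finite(pr$loglik))
      stop("data have zero likelihood under the model; cannot sample histories")
    out <- base
    out$prep <- prep
    out$pruned <- pr
    return(out)
  }
  prep <- prepare_pruning(tree, occ, avail)
  proc <- build_process(spec, avail)
  props <- make_propagators(prep, proc)
  pr <- prune_all(prep, props, root_prior)
  if (!is.finite(pr$loglik))
    stop("data have zero likelihood under the model; cannot sample histories")
  n_str <- nrow(prep$strata)
  unif <- vector("list", n_str)
  clado_by_anc <- vector("list", n_str)
  for (s in seq_len(n_str)) {
    ok <- which(prep$space$allowed[[s]])
    Qs <- proc$strata[[s]]$Q[ok, ok, drop = FALSE]
    mu <- max(-diag(Qs), 0)
    R <- if (mu > 0) diag(length(ok)) + Qs / mu else diag(length(ok))
    map <- integer(prep$space$n_states); map[ok] <- seq_along(ok)
    unif[[s]] <- list(ok = ok, map = map, Q = Qs, mu = mu, R = R)
    cl <- props$clado[[s]]
    by_anc <- split(seq_along(cl$anc), cl$anc)
    clado_by_anc[[s]] <- list(idx = by_anc, cl = cl)
  }
  child_edges <- vector("list", prep$n_tip + tree$Nnode)
  for (k in seq_len(nrow(prep$edges))) {
    p <- prep$edges[k, 1L]
    child_edges[[p]] <- c(child_edges[[p]], k)
  }
  list(prep = prep, proc = proc, props = props, pruned = pr, unif = unif,
       clado_by_anc = clado_by_anc, child_edges = child_edges)
}

sample_discrete <- function(p) {
  if (length(p) == 1L) return(1L)
  s <- sum(p)
  if (s <= 0) stop("degenerate sampling distribution in stochastic mapping")
  sample.int(length(p), 1L, prob = p)
}

# Endpoint-conditioned path in one stratum segment via uniformization.
# a, b are global state indices; returns a data.frame of real transitions
# (age, from, to) with ages in (age_bot, age_top], ordered old -> young.
sample_segment_path <- function(u, a, b, dt, age_bot, Pab, retry_cap = 1e5) {
  if (u$mu == 0 || dt == 0) {
    if (a != b) stop("impossible endpoint pair on a zero-rate segment")
    return(NULL)
  }
  ai <- u$map[a]; bi <- u$map[b]
  lam <- u$mu * dt
  uu <- stats::runif(1)
  cum <- 0
  n <- -1L
  Rpow <- list(diag(nrow(u$R)))  # Rpow[[m+1]] = R^m
  nmax <- max(50L, ceiling(lam + 12 * sqrt(lam) + 20))
  found <- FALSE
  while (n < nmax) {
    n <- n + 1L
    if (n + 1L > length(Rpow)) Rpow[[n + 1L]] <- Rpow[[n]] %*% u$R
    term <- stats::dpois(n, lam) * Rpow[[n + 1L]][ai, bi] / Pab
    cum <- cum + term
    if (uu <= cum) { found <- TRUE; break }
  }
  if (!found) {
    return(reject_segment_path(u, a, b, dt, age_bot, retry_cap))
  }
  if (n == 0L) return(NULL)
  # state sequence under the uniformized chain
  states <- integer(n + 1L)
  states[1L] <- ai; states[n + 1L] <- bi
  if (n > 1L) {
    for (i in 2L:n) {
      pr <- u$R[states[i - 1L], ] * Rpow[[n - i + 2L]][, bi]
      states[i] <- sample_discrete(pr)
    }
  } else {
    # single jump: must go straight a -> b (virtual if a == b)
  }
  times <- sort(stats::runif(n, 0, dt), decreasing = TRUE)  # from top
  ages <- age_bot + times
  real <- which(states[-1L] != states[-(n + 1L)])
  if (!length(real)) return(NULL)
  data.frame(age = ages[real],
             from = u$ok[states[real]], to = u$ok[states[real + 1L]])
}

# Fallback: forward Gillespie over the segment, rejected until the endpoint
# matches.
reject_segment_path <- function(u, a, b, dt, age_bot, retry_cap) {
  ai <- u$map[a]; bi <- u$map[b]
  for (try in seq_len(retry_cap)) {
    s <- ai; t <- 0
    ev <- list()
    repeat {
      rate <- -u$Q[s, s]
      if (rate <= 0) break
      t <- t + stats::rexp(1, rate)
      if (t >= dt) break
      pr <- u$Q[s, ]; pr[s] <- 0
      s2 <- sample_discrete(pr)
      ev[[length(ev) + 1L]] <- c(age = age_bot + (dt - t), from = u$ok[s],
                                 to = u$ok[s2])
      s <- s2
    }
    if (s == bi) {
      if (!length(ev)) return(NULL)
      df <- as.data.frame(do.call(rbind, ev))
      return(df[order(-df$age), , drop = FALSE])
    }
  }
  stop("endpoint-conditioned path sampling exhausted ", retry_cap,
       " proposals on a segment")
}

# One stochastic map using the current RNG state.
bsm_draw <- function(eng) {
  prep <- eng$prep
  n_states <- prep$space$n_states
  n_all <- prep$n_tip + prep$tree$Nnode
  node_state <- integer(n_all)           # state bitmask at node (pre-clado)
  events <- list()
  clado <- list()
  pr <- eng$pruned
  root <- prep$root
  ri <- sample_discrete(pr$prior * pr$L[, root])
  node_state[root] <- ri - 1L
  stack <- root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    anc <- node_state[node] + 1L
    ks <- eng$child_edges[[node]]
    strat <- prep$node_stratum[node]
    cb <- eng$clado_by_anc[[strat]]
    rows <- cb$idx[[as.character(anc)]]
    if (is.null(rows))
      stop("sampled ancestor state has no cladogenetic row (stratum ", strat, ")")
    cl <- cb$cl
    w <- cl$w[rows] * pr$Ltop[cl$l[rows], ks[1L]] * pr$Ltop[cl$r[rows], ks[2L]]
    ev <- rows[sample_discrete(w)]
    dl <- cl$l[ev]; dr <- cl$r[ev]
    clado[[length(clado) + 1L]] <-
      data.frame(node = node, edge_left = ks[1L], edge_right = ks[2L],
                 anc = anc - 1L, left = dl - 1L, right = dr - 1L,
                 cls = cl$cls[ev])
    for (side in 1:2) {
      k <- ks[side]
      top <- if (side == 1L) dl else dr
      child <- prep$edges[k, 2L]
      sg <- prep$seg[[k]]
      m <- nrow(sg)
      # sample boundary states from the top down
      cur <- top
      if (m > 0) {
        below <- vector("list", m)  # below[[i]]: conditional at bottom of seg i
        below[[1L]] <- pr$L[, child]
        if (m > 1L) {
          for (i in 2L:m) {
            below[[i]] <- as.vector(eng$props$segP[[k]][[i - 1L]] %*% below[[i - 1L]])
          }
        }
        for (i in m:1L) {
          P <- eng$props$segP[[k]][[i]]
          pvec <- P[cur, ] * below[[i]]
          bot <- sample_discrete(pvec)
          u <- eng$unif[[sg$stratum[i]]]
          path <- sample_segment_path(u, cur, bot, sg$dt[i], sg$age_bot[i],
                                      P[cur, bot])
          if (!is.null(path)) {
            path$edge <- k
            events[[length(events) + 1L]] <- path
          }
          cur <- bot
        }
      }
      if (child <= prep$n_tip) {
        if (cur != prep$tip_state[child] + 1L)
          stop("sampled tip state disagrees with data at tip ", child)
        node_state[child] <- cur - 1L
      } else {
        node_state[child] <- cur - 1L
        stack <- c(stack, child)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(age = numeric(0), from = integer(0), to = integer(0),
               edge = integer(0))
  ev$from <- ev$from - 1L; ev$to <- ev$to - 1L   # back to bitmasks
  if (nrow(ev)) {
    delta <- bitwXor(ev$from, ev$to)
    ev$type <- ifelse(bitwAnd(ev$to, delta) == delta, "gain", "loss")
    ev$biome <- prep$space$biomes[as.integer(round(log2(delta))) + 1L]
  } else {
    ev$type <- character(0); ev$biome <- character(0)
  }
  cl <- if (length(clado)) do.call(rbind, clado) else
    data.frame(node = integer(0), edge_left = integer(0),
               edge_right = integer(0), anc = integer(0), left = integer(0),
               right = integer(0), cls = character(0))
  structure(list(events = ev[order(ev$edge, -ev$age), , drop = FALSE],
                 clado = cl, node_states = node_state,
                 n_tip = prep$n_tip, n_edges = nrow(prep$edges),
                 biomes = prep$space$biomes),
            class = "event_history")
}

#' Sample one biome-occupancy history by stochastic mapping
#'
#' Draws a complete anagenetic + cladogenetic history consistent with the tip
#' occupancies under a fitted range-evolution model. Reproducible from
#' \code{seed}.
#'
#' @param fit a \code{"range_fit"}.
#' @param seed integer seed.
#' @return an \code{"event_history"}: per-branch anagenetic events (edge, age,
#'   gain/loss, biome, from/to state bitmasks), per-node cladogenetic outcomes
#'   with event classes, and sampled node states.
#' @seealso \code{\link{count_shifts}}, \code{\link{bsm_rates}}
#' @export
sample_history <- function(fit, seed = 1L) {
  eng <- make_bsm_engine(fit$tree, fit$occ, fit$avail, fit$spec,
                         fit$root_prior)
  set.seed(seed)
  bsm_draw(eng)
}

#' @export
print.event_history <- function(x, ...) {
  cat("Stochastic biome-shift history: ", nrow(x$events),
      " anagenetic events, ", sum(x$clado$left != x$clado$anc) +
        sum(x$clado$right != x$clado$anc),
      " range-changing cladogenetic outcomes\n", sep = "")
  invisible(x)
}

#' Count biome shifts in a sampled history
#'
#' A shift event is any anagenetic gain or loss, plus any cladogenetic outcome
#' in which a daughter's range differs from the ancestral range (attributed to
#' the daughter's branch). \code{mode = "simplified"} counts at most one shift
#' per branch, matching the convention of counting multiple shifts on the same
#' branch as a single shift.
#'
#' @param history an \code{"event_history"}.
#' @param mode \code{"simplified"} or \code{"raw"}; which count feeds
#'   \code{rate}.
#' @param clade_size divisor for the shift rate (defaults to the number of
#'   tips).
#' @param include_losses count extirpation (loss) events?
#' @param include_cladogenetic count range-changing cladogenetic outcomes?
#' @return a list with \code{raw}, \code{simplified}, and \code{rate}
#'   (chosen count / clade size).
#' @export
count_shifts <- function(history, mode = c("simplified", "raw"),
                         clade_size = history$n_tip,
                         include_losses = TRUE, include_cladogenetic = TRUE) {
  mode <- match.arg(mode)
  ev <- history$events
  if (!include_losses) ev <- ev[ev$type != "loss", , drop = FALSE]
  per_edge <- integer(history$n_edges)
  if (nrow(ev)) {
    t <- table(ev$edge)
    per_edge[as.integer(names(t))] <- as.integer(t)
  }
  if (include_cladogenetic && nrow(history$clado)) {
    cl <- history$clado
    chL <- cl$left != cl$anc
    chR <- cl$right != cl$anc
    per_edge[cl$edge_left[chL]] <- per_edge[cl$edge_left[chL]] + 1L
    per_edge[cl$edge_right[chR]] <- per_edge[cl$edge_right[chR]] + 1L
  }
  raw <- sum(per_edge)
  simplified <- sum(per_edge > 0L)
  list(raw = raw, simplified = simplified,
       rate = (if (mode == "simplified") simplified else raw) / clade_size,
       mode = mode, per_edge = per_edge)
}

#' Biome shift rates over repeated stochastic maps
#'
#' Runs \code{n_runs} biogeographic stochastic mapping draws and summarises
#' per-run shift counts and rates (mean and SD), with per-run seeds derived
#' deterministically from the master seed.
#'
#' @param fit a \code{"range_fit"}.
#' @param n_runs number of stochastic maps (100 for a full analysis).
#' @param seed master seed.
#' @param mode,include_losses,include_cladogenetic passed to
#'   \code{\link{count_shifts}}.
#' @return an object of class \code{"bsm_counts"}: data.frame \code{runs}
#'   (run, raw, simplified, rate) plus \code{mean}, \code{sd} of the rate.
#' @export
bsm_rates <- function(fit, n_runs = 100L, seed = 1L,
                      mode = c("simplified", "raw"),
                      include_losses = TRUE, include_cladogenetic = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_runs >= 1L)
  eng <- make_bsm_engine(fit$tree, fit$occ, fit$avail, fit$spec,
                         fit$root_prior)
  bsm_rates_engine(eng, n_runs, seed, mode, include_losses,
                   include_cladogenetic, clade_size = fit$n_tip)
}

bsm_rates_engine <- function(eng, n_runs, seed, mode = "simplified",
                             include_losses = TRUE,
                             include_cladogenetic = TRUE,
                             clade_size = eng$prep$n_tip) {
  runs <- data.frame(run = seq_len(n_runs), raw = NA_integer_,
                     simplified = NA_integer_, rate = NA_real_)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, r))
    h <- bsm_draw(eng)
    ct <- count_shifts(h, mode = mode, clade_size = clade_size,
                       include_losses = include_losses,
                       include_cladogenetic = include_cladogenetic)
    runs$raw[r] <- ct$raw
    runs$simplified[r] <- ct$simplified
    runs$rate[r] <- ct$rate
  }
  structure(list(runs = runs, mean = mean(runs$rate),
                 sd = stats::sd(runs$rate), n_runs = n_runs, mode = mode,
                 clade_size = clade_size),
            class = "bsm_counts")
}

#' @export
print.bsm_counts <- function(x, ...) {
  cat("Biogeographic stochastic mapping: ", x$n_runs, " runs (",
      x$mode, " counting)\n", sep = "")
  cat("  mean shift rate ", round(x$mean, 3), " (± ",
      round(x$sd, 3), ")\n", sep = "")
  invisible(x)
}
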