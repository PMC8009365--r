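# Time-stratified CTMC over biome-occupancy sets.
#
# States are all subsets of the biome set encoded as bitmasks; index = mask+1,
# so index 1 is the null (empty) range, which is anagenetically absorbing and
# excluded from cladogenesis and the root prior. A state is allowed in a
# stratum iff every member biome is available there.

#' Specify a range-evolution model
#'
#' @param family cladogenetic family: \code{"DEC"}, \code{"DIVALIKE"} or
#'   \code{"BAYAREALIKE"}.
#' @param jump include founder-event (jump) cladogenesis (+J)?
#' @param d anagenetic dispersal rate (biome gains, events/Ma per
#'   source-sink biome pair).
#' @param e anagenetic extirpation rate (biome losses, events/Ma per occupied
#'   biome).
#' @param j founder-event weight (dimensionless, competing with unit base
#'   weights; 0 <= j <= 3). Must be 0 when \code{jump = FALSE}.
#' @return an object of class \code{"model_spec"}.
#' @export
model_spec <- function(family = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                       jump = FALSE, d = 0.01, e = 0.01, j = 0) {
  family <- match.arg(family)
  stopifnot(d >= 0, e >= 0, j >= 0, j <= 3)
  if (!jump && j != 0) stop("j must be 0 when jump = FALSE")
  structure(list(family = family, jump = jump, d = d, e = e, j = j),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(x$family, if (x$jump) "+J" else "", "  d=", signif(x$d, 4),
      " e=", signif(x$e, 4), if (x$jump) paste0(" j=", signif(x$j, 4)), "\n", sep = "")
  invisible(x)
}

#' Range state space over a biome set
#'
#' All 2^B subsets of the biome set (including the null range), with the
#' per-stratum mask of allowed states implied by biome availability.
#'
#' @param avail a \code{"biome_availability"}.
#' @return a list with elements \code{biomes}, \code{n_states}, \code{strata}
#'   (data.frame of age intervals and availability bitmasks) and
#'   \code{allowed} (list of logical vectors, one per stratum; the null state
#'   is marked allowed since it is used anagenetically).
#' @export
range_state_space <- function(avail) {
  B <- length(avail$biomes)
  if (B > 6L) stop("more than 6 biomes not supported (dense state space)")
  strata <- strata_of(avail)
  masks <- 0:(2L^B - 1L)
  allowed <- lapply(strata$avail, function(am) bitwAnd(masks, am) == masks)
  list(biomes = avail$biomes, n_biomes = B, n_states = 2L^B,
       strata = strata, allowed = allowed, masks = masks)
}

# Anagenetic rate matrix for one stratum. Gains: biome b (available, not in
# range) is added at rate d per occupied source biome, i.e. d * |range|.
# Losses: each occupied biome is lost at rate e (loss of the last biome leads
# to the null state, which is absorbing). Rows of disallowed states are zero.
build_Q <- function(space, d, e, stratum) {
  n <- space$n_states
  B <- space$n_biomes
  am <- space$strata$avail[stratum]
  ok <- space$allowed[[stratum]]
  Q <- matrix(0, n, n)
  for (mask in space$masks) {
    if (mask == 0L || !ok[mask + 1L]) next
    k <- popcount(mask)
    for (b in 0:(B - 1L)) {
      bit <- 2L^b
      if (bitwAnd(mask, bit) == 0L) {
        if (bitwAnd(am, bit) == bit) Q[mask + 1L, mask + bit + 1L] <- d * k
      } else {
        Q[mask + 1L, mask - bit + 1L] <- e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Enumerate cladogenetic events for one ancestral state in one stratum.
# Returns a data.frame(left, right, w, cls) of ordered daughter pairs with
# unnormalised weights (base events weight 1, jumps weight j).
clado_events <- function(mask, family, jump, j, am, B) {
  stopifnot(mask > 0L)
  bits <- bits_of(mask, B)
  k <- length(bits)
  L <- integer(0); R <- integer(0); W <- numeric(0); C <- character(0)
  add <- function(l, r, w, cls) {
    L <<- c(L, l); R <<- c(R, r); W <<- c(W, w); C <<- c(C, cls)
  }
  if (family == "BAYAREALIKE") {
    add(mask, mask, 1, "inheritance")
  } else if (k == 1L) {
    add(mask, mask, 1, "sympatry")
  } else if (family == "DEC") {
    for (b in bits) {
      s <- 2L^b; comp <- mask - s
      # narrow vicariance: one daughter a single biome, the other the
      # complement; when the complement is itself single, looping over b
      # already yields both orders, so avoid double-adding
      add(s, comp, 1, "vicariance")
      if (popcount(comp) > 1L) add(comp, s, 1, "vicariance")
      add(s, mask, 1, "subset"); add(mask, s, 1, "subset")
    }
  } else { # DIVALIKE: all ordered splits into two disjoint non-empty subsets
    subs <- 0:(2L^k - 1L)
    for (ss in subs[-c(1L, length(subs))]) {
      part <- sum(2L^bits[bit_in(ss, seq_len(k) - 1L)])
      add(part, mask - part, 1, "vicariance")
    }
  }
  if (jump && j > 0) {
    outside <- setdiff(bits_of(am, B), bits)
    for (b in outside) {
      add(mask, 2L^b, j, "jump"); add(2L^b, mask, j, "jump")
    }
  }
  data.frame(left = L, right = R, w = W, cls = C, stringsAsFactors = FALSE)
}

#' Build the time-stratified range-evolution process
#'
#' Constructs, for each stratum, the anagenetic rate matrix Q over allowed
#' biome-occupancy states and the normalised cladogenesis table for the chosen
#' family (with founder-event jumps when \code{jump = TRUE}).
#'
#' @param spec a \code{"model_spec"}.
#' @param avail a \code{"biome_availability"}.
#' @return an object of class \code{"range_process"}: the state space plus,
#'   per stratum, \code{Q} and a cladogenesis table \code{clado} (data.frame
#'   with columns \code{anc}, \code{left}, \code{right} as state bitmasks,
#'   normalised probability \code{w} and event class \code{cls}).
#' @export
build_process <- function(spec, avail) {
  space <- range_state_space(avail)
  n_str <- nrow(space$strata)
  strata <- vector("list", n_str)
  for (s in seq_len(n_str)) {
    am <- space$strata$avail[s]
    Q <- build_Q(space, spec$d, spec$e, s)
    ok_masks <- space$masks[space$allowed[[s]] & space$masks > 0L]
    tabs <- lapply(ok_masks, function(mask) {
      ev <- clado_events(mask, spec$family, spec$jump, spec$j, am, space$n_biomes)
      if (nrow(ev) == 0L || sum(ev$w) <= 0)
        stop("no allowed cladogenetic outcome for state ",
             state_label(mask, space$biomes), " in stratum ", s)
      ev$w <- ev$w / sum(ev$w)
      cbind(anc = mask, ev)
    })
    clado <- do.call(rbind, tabs)
    strata[[s]] <- list(Q = Q, clado = clado, avail = am)
  }
  structure(list(space = space, spec = spec, strata = strata),
            class = "range_process")
}

#' @export
print.range_process <- function(x, ...) {
  cat("Time-stratified range process: ", x$spec$family,
      if (x$spec$jump) "+J", "\n", sep = "")
  cat("  biomes:", paste(x$space$biomes, collapse = ", "), "\n")
  cat("  states:", x$space$n_states, "(incl. null), strata:",
      nrow(x$space$strata), "\n")
  invisible(x)
}
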