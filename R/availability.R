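#' Biome availability through time
#'
#' Defines the ordered set of biomes and the time (Ma before present) at which
#' each first became available. Biomes only appear, never vanish: a biome with
#' appearance time \code{t} is available at all ages \code{<= t}. At least one
#' biome must always be available (\code{NA} or \code{Inf} appearance). The
#' biome order given here is fixed and used for every tie-break downstream.
#'
#' @param biomes character vector of biome names, in fixed order.
#' @param appearance numeric vector of appearance times in Ma before present,
#'   aligned with \code{biomes}; \code{NA} or \code{Inf} means always
#'   available.
#' @return an object of class \code{"biome_availability"}.
#' @examples
#' nz_availability() # Forest always, Open from 4 Ma, Alpine from 1.9 Ma
#' @export
biome_availability <- function(biomes, appearance = rep(Inf, length(biomes))) {
  stopifnot(is.character(biomes), length(biomes) >= 1L,
            length(appearance) == length(biomes))
  if (anyDuplicated(biomes)) stop("duplicate biome names")
  appearance <- as.numeric(appearance)
  appearance[is.na(appearance)] <- Inf
  if (any(appearance < 0)) stop("appearance times must be >= 0")
  if (!any(is.infinite(appearance))) stop("at least one biome must always be available")
  structure(list(biomes = biomes, appearance = appearance),
            class = "biome_availability")
}

#' New Zealand biome availability
#'
#' The three-biome New Zealand system: Forest always available, Open since
#' 4 Ma, Alpine since 1.9 Ma.
#'
#' @return a \code{"biome_availability"} object.
#' @export
nz_availability <- function() {
  biome_availability(c("Forest", "Open", "Alpine"), c(Inf, 4, 1.9))
}

#' @export
print.biome_availability <- function(x, ...) {
  cat("Biome availability (", length(x$biomes), " biomes)\n", sep = "")
  app <- ifelse(is.infinite(x$appearance), "always",
                paste0("from ", x$appearance, " Ma"))
  for (i in seq_along(x$biomes)) cat("  ", x$biomes[i], ": ", app[i], "\n", sep = "")
  invisible(x)
}

# Strata are the maximal age intervals with constant availability, youngest
# first: (b0=0, b1], (b1, b2], ..., (bk, Inf]. A biome is available throughout
# stratum (lo, hi] iff its appearance time >= hi. Returns a data.frame with
# columns lower, upper, and avail (integer bitmask over the biome order).
strata_of <- function(avail) {
  bks <- sort(unique(avail$appearance[is.finite(avail$appearance)]))
  lower <- c(0, bks)
  upper <- c(bks, Inf)
  mask <- vapply(upper, function(hi) {
    sum(2L^(which(avail$appearance >= hi) - 1L))
  }, numeric(1))
  data.frame(lower = lower, upper = upper, avail = as.integer(mask))
}

# Stratum index containing age a (ages live in (lower, upper]; an age exactly
# on a boundary belongs to the younger stratum).
stratum_at <- function(strata, age) {
  vapply(age, function(a) which(a <= strata$upper)[1L], integer(1L))
}

biome_available_at <- function(avail, biome_idx, age) {
  age <= avail$appearance[biome_idx]
}
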