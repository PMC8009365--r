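# Internal numerical utilities: dense matrix exponential and bitmask helpers
# for biome-set states. States are encoded as integer bitmasks (bit i-1 set =
# biome i occupied); state index in vectors/matrices is bitmask + 1, so index 1
# is the null (empty) range.

#' Dense matrix exponential
#'
#' Scaling-and-squaring with a (6,6) Pade approximant, adequate to ~1e-13 for
#' the small (at most 2^B x 2^B, B <= 6) rate matrices used here.
#'
#' @param A square numeric matrix.
#' @return \code{exp(A)} as a dense matrix.
#' @keywords internal
#' @noRd
expm_pade <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  if (nrm == 0) return(diag(n))
  s <- max(0L, ceiling(log2(nrm)) + 1L)
  A <- A / 2^s
  # Pade (6,6) coefficients
  c_ <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A4 %*% A2
  U <- A %*% (c_[2] * I + c_[4] * A2 + c_[6] * A4)
  V <- c_[1] * I + c_[3] * A2 + c_[5] * A4 + c_[7] * A6
  P <- solve(V - U, V + U)
  for (i in seq_len(s)) P <- P %*% P
  P
}

# number of set bits for each of 0:(2^B-1); small lookup built on demand
popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

bit_in <- function(state, bit) (state %/% 2L^bit) %% 2L == 1L

bits_of <- function(state, n_bits) {
  which(bit_in(state, seq_len(n_bits) - 1L)) - 1L
}

# deterministic per-run seed derivation, kept below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

state_label <- function(state, biomes) {
  if (state == 0L) return("()")
  paste(biomes[bits_of(state, length(biomes)) + 1L], collapse = "+")
}
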