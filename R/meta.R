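# Meta-analysis and hypothesis-testing arithmetic for comparing biome shift
# rates between single- and multiple-biome occupancy coding.

#' Biome shift rate of a clade
#'
#' Shifts per species: the shift count (floored to a whole number, matching
#' the convention for censored/fractional published counts) divided by clade
#' size. Full precision is retained; display is conventionally 2 dp.
#'
#' @param count shift count (floored to integer).
#' @param clade_size number of taxa (>= 1).
#' @return the rate, full precision.
#' @examples
#' round(shift_rate(23, 22), 2) # 1.04
#' @export
shift_rate <- function(count, clade_size) {
  if (any(count < 0) || any(clade_size < 1)) stop("negative input")
  floor(count) / clade_size
}

#' Percentage of biome specialists in a clade
#'
#' @param specialists number of single-biome species.
#' @param clade_size number of taxa.
#' @return percentage (0-100), full precision (display rounds to integer).
#' @export
specialists_pct <- function(specialists, clade_size) {
  if (any(specialists < 0) || any(specialists > clade_size))
    stop("specialists must be between 0 and clade_size")
  100 * specialists / clade_size
}

#' Median and quartiles of a rate vector
#'
#' Type-7 (linear interpolation) quantiles, the default convention.
#'
#' @param rates numeric vector, no NAs.
#' @return list with \code{median}, \code{q1}, \code{q3}, \code{n}.
#' @export
group_summary <- function(rates) {
  if (length(rates) < 1L || anyNA(rates)) stop("rates must be non-empty and NA-free")
  q <- stats::quantile(rates, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2L], q1 = q[1L], q3 = q[3L], n = length(rates))
}

#' One-tailed Welch two-sample t-test
#'
#' Tests the directional alternative mean(b) > mean(a) with unequal
#' variances (Welch); the Welch-Satterthwaite df is returned at full
#' precision with a nearest-integer display value.
#'
#' @param a,b numeric vectors (each n >= 2). \code{a} is the group expected
#'   to be lower (e.g. single-biome coding rates).
#' @return list with \code{statistic}, \code{df}, \code{df_display},
#'   \code{p}, \code{tails = "one"}, \code{paired = FALSE}.
#' @export
welch_one_tailed <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  tt <- stats::t.test(b, a, alternative = "greater", var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       df_display = round(unname(tt$parameter)), p = tt$p.value,
       tails = "one", paired = FALSE)
}

#' One-tailed paired t-test of single- vs multiple-coding rates
#'
#' Tests whether rates are lower under single-biome coding: t on the paired
#' differences multiple - single, df = n - 1, upper-tail p. When every
#' difference is identical the t statistic is unbounded; the test then
#' returns \code{statistic = Inf} (or \code{-Inf}) with p 0 (or 1), and p =
#' 0.5 for identical vectors, rather than failing.
#'
#' @param single,multiple equal-length paired rate vectors.
#' @return list with \code{statistic}, \code{df}, \code{p}, \code{tails},
#'   \code{paired = TRUE}.
#' @export
paired_one_tailed <- function(single, multiple) {
  stopifnot(length(single) == length(multiple), length(single) >= 2L)
  d <- multiple - single
  n <- length(d)
  if (stats::sd(d) < .Machine$double.eps * max(1, max(abs(d)))) {
    m <- mean(d)
    stat <- if (m > 0) Inf else if (m < 0) -Inf else 0
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(list(statistic = stat, df = n - 1L, p = p, tails = "one",
                paired = TRUE))
  }
  tt <- stats::t.test(multiple, single, paired = TRUE, alternative = "greater")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, tails = "one", paired = TRUE)
}

#' Simple linear regression with assumption diagnostics
#'
#' Ordinary least squares of y on x, returning the slope, intercept, R
#' squared, overall F and p, plus the residual diagnostics (residuals,
#' fitted values and normal-quantile pairs) as data rather than plots.
#'
#' @param x,y numeric vectors, n >= 3.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{F}, \code{df} (c(1, n-2)), \code{p}, \code{residuals},
#'   \code{fitted}, and \code{qq} (data.frame of theoretical and sample
#'   quantiles of the residuals).
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  n <- length(x)
  Fstat <- if (r2 >= 1) Inf else (r2 / (1 - r2)) * (n - 2)
  p <- if (is.infinite(Fstat)) 0 else
    stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  qq <- stats::qqnorm(stats::residuals(fit), plot.it = FALSE)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, F = Fstat, df = c(1L, n - 2L), p = p,
       residuals = unname(stats::residuals(fit)),
       fitted = unname(stats::fitted(fit)),
       qq = data.frame(theoretical = qq$x, sample = qq$y))
}

#' Proportional decline in biome shift rate under single-biome coding
#'
#' \deqn{B_{decline} = (B_{multiple} - B_{single}) / B_{multiple}}
#' the proportional drop in the estimated shift rate when modal (single)
#' coding replaces multiple-biome coding.
#'
#' @param B_multiple shift rate under multiple-biome coding (> 0).
#' @param B_single shift rate under single-biome coding.
#' @return list with \code{B_single}, \code{B_multiple}, \code{B_decline}
#'   and \code{percent} (rounded for display).
#' @examples
#' b_decline(0.72, 0.62)$percent # 14
#' @export
b_decline <- function(B_multiple, B_single) {
  if (any(B_multiple <= 0)) stop("B_multiple must be > 0")
  bd <- (B_multiple - B_single) / B_multiple
  list(B_single = B_single, B_multiple = B_multiple, B_decline = bd,
       percent = round(100 * bd))
}

#' Net diversification rate from clade size and age
#'
#' The method-of-moments estimator for species per Ma given a clade's extant
#' richness and its stem or crown age, with an assumed relative extinction
#' fraction epsilon. With epsilon = 0 this reduces to \code{log(n)/t} (stem)
#' and \code{(log(n) - log(2))/t} (crown).
#'
#' @param n_taxa extant species count (>= 1 for stem, >= 2 for crown).
#' @param t age in Ma (> 0).
#' @param mode \code{"stem"} or \code{"crown"}.
#' @param epsilon relative extinction fraction in [0, 1).
#' @return rate in species per Ma.
#' @examples
#' round(diversification_rate(124, 10.21, "stem"), 2)  # 0.47
#' round(diversification_rate(7, 2, "crown"), 2)       # 0.63
#' @export
diversification_rate <- function(n_taxa, t, mode = c("stem", "crown"),
                                 epsilon = 0) {
  mode <- match.arg(mode)
  stopifnot(t > 0, epsilon >= 0, epsilon < 1)
  if (mode == "stem") {
    stopifnot(n_taxa >= 1)
    log(n_taxa * (1 - epsilon) + epsilon) / t
  } else {
    stopifnot(n_taxa >= 2)
    n <- n_taxa
    inner <- 0.5 * n * (1 - epsilon^2) + 2 * epsilon +
      0.5 * (1 - epsilon) * sqrt(n * (n * epsilon^2 - 8 * epsilon +
                                        2 * n * epsilon + n) + 4 * epsilon^2)
    (log(inner) - log(2)) / t
  }
}
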