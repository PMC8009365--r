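#' Randomise biome occupancy across tips
#'
#' The null model for the biome-conservatism test: whole occupancy rows
#' (biome sets) are permuted uniformly at random across taxa, preserving the
#' multiset of occupancy vectors exactly (and hence the number of
#' specialists and every biome's tip frequency).
#'
#' @param occ an \code{"occupancy_matrix"}.
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @return a shuffled \code{"occupancy_matrix"} with the same taxa.
#' @export
randomise_tips <- function(occ, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(occ)
  perm <- sample.int(nrow(m))
  out <- m[perm, , drop = FALSE]
  rownames(out) <- rownames(m)
  occupancy_matrix(out, mode = attr(occ, "mode"))
}

#' Tip-randomisation test for biome conservatism
#'
#' Compares the observed biome shift rate (mean simplified rate over
#' \code{n_bsm_obs} stochastic maps) against shift rates from \code{n_null}
#' tip-randomised replicates, each mapped \code{n_bsm_per_null} times under
#' the same fitted model (or refitted per replicate when \code{refit}).
#' Biome conservatism is flagged when the proportion of null rates strictly
#' greater than the observed rate reaches \code{alpha_proportion}.
#'
#' @param fit a \code{"range_fit"} for the observed data (the selected best
#'   model).
#' @param n_null number of null replicates (1000 for a full analysis).
#' @param alpha_proportion significance proportion (0.95).
#' @param refit re-estimate d, e, j on every null replicate? Defaults to
#'   FALSE: null maps reuse the parameters fitted to the observed data.
#' @param n_bsm_obs stochastic maps for the observed rate (100 for a full
#'   analysis).
#' @param n_bsm_per_null stochastic maps per null replicate.
#' @param mode shift counting mode, \code{"simplified"} (default, matching
#'   the meta-analysis convention) or \code{"raw"}.
#' @param strict declare significance only when the proportion is strictly
#'   greater than \code{alpha_proportion} (default FALSE: \code{>=}, matching
#'   the reported starring rule).
#' @param seed master seed.
#' @return an object of class \code{"conservatism_test"} with
#'   \code{observed_rate}, \code{null_rates}, \code{proportion_greater} and
#'   \code{significant}.
#' @export
conservatism_test <- function(fit, n_null = 1000L, alpha_proportion = 0.95,
                              refit = FALSE, n_bsm_obs = 100L,
                              n_bsm_per_null = 1L,
                              mode = c("simplified", "raw"),
                              strict = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_null >= 1L, alpha_proportion > 0, alpha_proportion < 1)
  eng0 <- make_bsm_engine(fit$tree, fit$occ, fit$avail, fit$spec,
                          fit$root_prior)
  obs <- bsm_rates_engine(eng0, n_bsm_obs, derive_seed(seed, 0L), mode)
  null_rates <- numeric(n_null)
  for (i in seq_len(n_null)) {
    si <- derive_seed(seed, i)
    occ_i <- randomise_tips(fit$occ, seed = si)
    eng_i <- if (refit) {
      f <- fit_range_model(fit$tree, occ_i, fit$avail, fit$spec$family,
                           jump = fit$spec$jump, root_prior = fit$root_prior)
      make_bsm_engine(f$tree, f$occ, f$avail, f$spec, f$root_prior)
    } else {
      # same tree and parameters: reuse the propagators, replace tip data
      make_bsm_engine(fit$tree, occ_i, fit$avail, fit$spec, fit$root_prior,
                      base = eng0)
    }
    b <- bsm_rates_engine(eng_i, n_bsm_per_null, derive_seed(si, 1L), mode)
    null_rates[i] <- b$mean
  }
  prop <- mean(null_rates > obs$mean)
  structure(list(observed_rate = obs$mean, observed_sd = obs$sd,
                 null_rates = null_rates, proportion_greater = prop,
                 significant = if (strict) prop > alpha_proportion
                               else prop >= alpha_proportion,
                 n_null = n_null, alpha_proportion = alpha_proportion,
                 refit = refit, mode = mode),
            class = "conservatism_test")
}

#' @export
print.conservatism_test <- function(x, ...) {
  cat("Biome conservatism test (", x$n_null, " tip-randomised nulls, ",
      x$mode, " counting)\n", sep = "")
  cat("  observed shift rate: ", round(x$observed_rate, 3),
      " (± ", round(x$observed_sd, 3), ")\n", sep = "")
  cat("  proportion of nulls greater: ", round(x$proportion_greater, 3),
      if (x$significant) "  *biome conservatism*", "\n", sep = "")
  invisible(x)
}

#' Change in tendency towards biome conservatism between coding approaches
#'
#' Given the proportion of null simulations exceeding the observed shift rate
#' under single-biome coding (\code{p_single}) and multiple-biome coding
#' (\code{p_multiple}), returns the absolute change \code{p_multiple -
#' p_single} (positive = greater tendency towards conservatism under
#' multiple-biome coding) and the percentage change relative to
#' \code{p_single} (undefined, \code{NA}, when \code{p_single} is 0).
#'
#' @param p_single,p_multiple proportions in [0, 1].
#' @return list with \code{absolute_change}, \code{percent_change} (rounded
#'   to the nearest integer for display; \code{NA} if undefined) and a
#'   formatted \code{label}.
#' @export
tendency_change <- function(p_single, p_multiple) {
  stopifnot(p_single >= 0, p_single <= 1, p_multiple >= 0, p_multiple <= 1)
  abs_ch <- p_multiple - p_single
  pct <- if (p_single == 0) NA_real_ else abs(abs_ch) / p_single * 100
  label <- sprintf("%+.2f (%s)", abs_ch,
                   if (is.na(pct)) "N/A" else paste0(round(pct), "%"))
  if (abs_ch == 0) label <- sprintf("0.00 (%s)",
                                    if (is.na(pct)) "N/A" else paste0(round(pct), "%"))
  list(absolute_change = abs_ch, percent_change = pct, label = label)
}
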