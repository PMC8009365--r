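#' Fit a range-evolution model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) maximisation of the stratified pruning
#' likelihood over the anagenetic rates d (dispersal) and e (extirpation),
#' plus the founder-event weight j when \code{jump = TRUE}. Optimisation runs
#' from a fixed multi-start grid and is fully deterministic.
#'
#' @param tree dated \code{"phylo"}.
#' @param occ \code{"occupancy_matrix"} aligned to the tips.
#' @param avail \code{"biome_availability"}.
#' @param family \code{"DEC"}, \code{"DIVALIKE"} or \code{"BAYAREALIKE"}.
#' @param jump include the +J founder-event component?
#' @param bounds list with elements \code{d}, \code{e}, \code{j}, each a
#'   length-2 numeric range.
#' @param starts matrix of (d, e) starting values, one row per start.
#' @param j_starts starting values for j when \code{jump = TRUE}.
#' @param root_prior passed to \code{\link{range_loglik}}.
#' @param control passed to \code{\link[stats]{optim}}.
#' @return an object of class \code{"range_fit"} with components \code{spec}
#'   (fitted \code{"model_spec"}), \code{lnL}, \code{k} (free parameters),
#'   \code{AIC}, \code{convergence} metadata, and the data used.
#' @examples
#' \donttest{
#' sim <- simulate_biome_clade(n_tips = 12, d = 0.15, e = 0.05, seed = 1)
#' fit <- fit_range_model(sim$tree, sim$occ, nz_availability(), "DEC")
#' coef(fit); logLik(fit)
#' }
#' @seealso \code{\link{fit_biogeo_models}}, \code{\link{select_best}},
#'   \code{\link{bsm_rates}}
#' @export
fit_range_model <- function(tree, occ, avail,
                            family = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                            jump = FALSE,
                            bounds = list(d = c(1e-12, 5), e = c(1e-12, 5),
                                          j = c(0, 3)),
                            starts = rbind(c(0.01, 0.01), c(0.1, 0.1), c(1, 1)),
                            j_starts = c(0.01, 0.5),
                            root_prior = NULL,
                            control = list()) {
  family <- match.arg(family)
  prep <- prepare_pruning(tree, occ, avail)
  negll <- function(par) {
    spec <- model_spec(family, jump, d = par[1L], e = par[2L],
                       j = if (jump) par[3L] else 0)
    proc <- build_process(spec, avail)
    ll <- prune_all(prep, make_propagators(prep, proc), root_prior)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  lo <- c(bounds$d[1L], bounds$e[1L], if (jump) bounds$j[1L])
  hi <- c(bounds$d[2L], bounds$e[2L], if (jump) bounds$j[2L])
  start_grid <- if (jump) {
    do.call(rbind, lapply(j_starts, function(js) cbind(starts, js)))
  } else starts
  best <- NULL
  conv <- list()
  ctrl <- utils::modifyList(list(factr = 1e9), control)
  for (i in seq_len(nrow(start_grid))) {
    p0 <- pmin(pmax(start_grid[i, ], lo), hi)
    op <- tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = ctrl),
      error = function(e) NULL)
    if (is.null(op)) next
    conv[[length(conv) + 1L]] <- list(start = p0, value = -op$value,
                                      convergence = op$convergence,
                                      counts = op$counts,
                                      message = op$message)
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    err <- simpleError("optimisation failed to find a finite likelihood")
    err$best_so_far <- best
    stop(err)
  }
  par <- unname(best$par)
  spec <- model_spec(family, jump, d = par[1L], e = par[2L],
                     j = if (jump) par[3L] else 0)
  k <- if (jump) 3L else 2L
  lnL <- -best$value
  structure(list(spec = spec, lnL = lnL, k = k, AIC = 2 * k - 2 * lnL,
                 convergence = list(code = best$convergence,
                                    counts = best$counts, starts = conv),
                 tree = tree, occ = occ, avail = avail,
                 root_prior = root_prior, n_tip = length(tree$tip.label)),
            class = "range_fit")
}

#' @export
print.range_fit <- function(x, digits = 4, ...) {
  cat("Range-evolution model fit: ", x$spec$family,
      if (x$spec$jump) "+J", "\n", sep = "")
  cat("  tips: ", x$n_tip, ", biomes: ", paste(x$avail$biomes, collapse = "/"),
      "\n", sep = "")
  cat("  d = ", signif(x$spec$d, digits), ", e = ", signif(x$spec$e, digits),
      if (x$spec$jump) paste0(", j = ", signif(x$spec$j, digits)),
      "\n  lnL = ", signif(x$lnL, 8), ", k = ", x$k,
      ", AIC = ", signif(x$AIC, 8), "\n", sep = "")
  invisible(x)
}

#' @export
coef.range_fit <- function(object, ...) {
  if (object$spec$jump)
    c(d = object$spec$d, e = object$spec$e, j = object$spec$j)
  else c(d = object$spec$d, e = object$spec$e)
}

#' @export
logLik.range_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = object$n_tip,
            class = "logLik")
}

#' @export
summary.range_fit <- function(object, ...) {
  object
}

#' One-tailed likelihood-ratio test of a +J model against its base family
#'
#' The statistic is 2(lnL_J - lnL_base), clipped at 0, referred to the upper
#' tail of a chi-squared distribution with 1 degree of freedom. The
#' boundary-mixture variant (half chi-squared 0, half chi-squared 1) is
#' available via \code{mixture = TRUE}.
#'
#' @param fit_base \code{"range_fit"} without jump.
#' @param fit_j \code{"range_fit"} of the same family with jump.
#' @param mixture use the 50:50 boundary mixture null?
#' @return a list with \code{statistic}, \code{df} and \code{p}.
#' @export
lrt_plus_j <- function(fit_base, fit_j, mixture = FALSE) {
  if (fit_base$spec$family != fit_j$spec$family)
    stop("fits are from different families")
  if (fit_base$spec$jump || !fit_j$spec$jump)
    stop("expected a base fit and its +J counterpart")
  if (fit_j$lnL < fit_base$lnL - 1e-6)
    warning("+J likelihood below base likelihood; optimisation artefact")
  stat <- max(0, 2 * (fit_j$lnL - fit_base$lnL))
  p <- if (stat == 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (stat == 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p = p)
}

#' Fit all six biogeographic models
#'
#' Fits DEC, DEC+J, DIVALIKE, DIVALIKE+J, BAYAREALIKE and BAYAREALIKE+J and
#' applies the selection rule: within each family the +J variant is kept only
#' if the one-tailed likelihood-ratio test rejects at \code{alpha}; the best
#' surviving model is then chosen by minimum AIC (ties towards fewer
#' parameters, then family order DEC < DIVALIKE < BAYAREALIKE).
#'
#' @inheritParams fit_range_model
#' @param alpha LRT significance level for keeping +J.
#' @param mixture use the boundary-mixture LRT null?
#' @param ... passed to \code{\link{fit_range_model}}.
#' @return an object of class \code{"range_fit_set"}: a list of the six fits
#'   plus a summary table and the index of the selected fit.
#' @export
fit_biogeo_models <- function(tree, occ, avail, alpha = 0.05, mixture = FALSE,
                              ...) {
  fams <- c("DEC", "DIVALIKE", "BAYAREALIKE")
  fits <- list()
  for (fam in fams) {
    fits[[fam]] <- fit_range_model(tree, occ, avail, fam, jump = FALSE, ...)
    fits[[paste0(fam, "+J")]] <- fit_range_model(tree, occ, avail, fam,
                                                 jump = TRUE, ...)
  }
  sel <- select_best(fits, alpha = alpha, mixture = mixture)
  sel
}

#' Select the best model among the six fits
#'
#' @param fits named list of six \code{"range_fit"} objects (families with and
#'   without +J).
#' @param alpha LRT level.
#' @param mixture use the boundary-mixture LRT null?
#' @return a \code{"range_fit_set"}.
#' @export
select_best <- function(fits, alpha = 0.05, mixture = FALSE) {
  fams <- c("DEC", "DIVALIKE", "BAYAREALIKE")
  tab <- data.frame(model = names(fits),
                    family = vapply(fits, function(f) f$spec$family, ""),
                    jump = vapply(fits, function(f) f$spec$jump, TRUE),
                    d = vapply(fits, function(f) f$spec$d, 1),
                    e = vapply(fits, function(f) f$spec$e, 1),
                    j = vapply(fits, function(f) f$spec$j, 1),
                    lnL = vapply(fits, function(f) f$lnL, 1),
                    k = vapply(fits, function(f) f$k, 1L),
                    AIC = vapply(fits, function(f) f$AIC, 1),
                    lrt_p = NA_real_, survivor = FALSE,
                    selected = FALSE, row.names = NULL)
  survivors <- character(0)
  for (fam in fams) {
    base <- which(tab$family == fam & !tab$jump)
    plus <- which(tab$family == fam & tab$jump)
    if (!length(base) || !length(plus)) next
    lrt <- lrt_plus_j(fits[[base]], fits[[plus]], mixture = mixture)
    tab$lrt_p[plus] <- lrt$p
    keep <- if (lrt$p < alpha) plus else base
    tab$survivor[keep] <- TRUE
    survivors <- c(survivors, tab$model[keep])
  }
  sv <- which(tab$survivor)
  # min AIC; ties (to 1e-9) towards fewer parameters, then family order
  aic <- tab$AIC[sv]
  cand <- sv[aic <= min(aic) + 1e-9]
  if (length(cand) > 1L) {
    cand <- cand[order(tab$k[cand], match(tab$family[cand], fams))]
  }
  tab$selected[cand[1L]] <- TRUE
  structure(list(fits = fits, table = tab, best = fits[[cand[1L]]],
                 best_name = tab$model[cand[1L]]),
            class = "range_fit_set")
}

#' @export
print.range_fit_set <- function(x, digits = 4, ...) {
  cat("Biogeographic model selection (", x$table$model[x$table$selected],
      " selected)\n", sep = "")
  tb <- x$table
  tb$d <- signif(tb$d, digits); tb$e <- signif(tb$e, digits)
  tb$j <- signif(tb$j, digits)
  tb$lnL <- round(tb$lnL, 3); tb$AIC <- round(tb$AIC, 3)
  tb$lrt_p <- signif(tb$lrt_p, 3)
  print(tb[, c("model", "d", "e", "j", "lnL", "k", "AIC", "lrt_p", "selected")],
        row.names = FALSE)
  invisible(x)
}
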