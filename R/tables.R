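# Packaged study tables: the compiled meta-analysis of published biome shift
# studies, the New Zealand clade ages, and the New Zealand conservatism-test
# summaries. Shipped as plain TSV under extdata and read on demand.

#' Read a clade summary table
#'
#' Reads one of the three packaged table schemas (or a user file in the same
#' layout): \code{"studies"} — published biome shift studies with clade size,
#' specialist counts, coding approach and shift counts/rates (censored
#' "10+"-style counts carry their floor and a censoring flag);
#' \code{"ages"} — clade sizes and stem/crown ages; \code{"conservatism"} —
#' per-clade mean shift rates and null-test proportions under both coding
#' approaches.
#'
#' @param path TSV file path.
#' @param schema one of \code{"studies"}, \code{"ages"},
#'   \code{"conservatism"}.
#' @return a data.frame.
#' @export
read_clade_table <- function(path, schema = c("studies", "ages",
                                              "conservatism")) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- switch(schema,
    studies = c("lineage", "clade_size", "specialists_n", "specialists_pct",
                "multiple_biomes", "shift_count", "censored", "shift_rate",
                "nz"),
    ages = c("clade", "n_total", "stem_age", "crown_age", "age_basis"),
    conservatism = c("clade", "rate_single", "rate_multiple", "p_single",
                     "p_multiple"))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("table lacks required column(s): ", paste(missing, collapse = ", "))
  if (schema == "studies") {
    df$multiple_biomes <- df$multiple_biomes == "yes"
    df$censored <- df$censored == "yes"
    df$nz <- df$nz == "yes"
    if (any(df$shift_count != floor(df$shift_count)))
      stop("shift counts must be whole numbers (floor censored counts)")
    bad <- !is.na(df$specialists_n) & (df$specialists_n < 0 |
                                         df$specialists_n > df$clade_size)
    if (any(bad)) stop("specialists outside [0, clade_size]: ",
                       paste(df$lineage[bad], collapse = ", "))
  }
  df
}

#' Published biome shift studies (meta-analysis table)
#' @return data.frame of the 25 compiled lineages.
#' @export
biome_shift_studies <- function() {
  read_clade_table(system.file("extdata", "biome_shift_studies.tsv",
                               package = "biomeshift"), "studies")
}

#' New Zealand clade sizes and ages
#' @return data.frame of the nine focal clades.
#' @export
nz_clade_ages <- function() {
  read_clade_table(system.file("extdata", "nz_clade_ages.tsv",
                               package = "biomeshift"), "ages")
}

#' New Zealand conservatism-test summaries
#' @return data.frame of per-clade rates and null proportions under both
#'   coding approaches.
#' @export
nz_conservatism <- function() {
  read_clade_table(system.file("extdata", "nz_conservatism.tsv",
                               package = "biomeshift"), "conservatism")
}

#' Meta-analysis report comparing single- and multiple-biome coding
#'
#' Recomputes the meta-analysis statistics from the packaged (or supplied)
#' tables: group summaries of shift rates under each coding approach, the
#' one-tailed Welch test (all multiple-coding clades, and restricted to the
#' non-New Zealand ones), the one-tailed paired test on the per-clade rates
#' estimated under both codings, the proportional decline in shift rate per
#' clade with its range, the tendency-towards-conservatism changes, the
#' shift-rate vs specialist-percentage regressions, and diversification
#' rates from clade sizes and ages.
#'
#' Group convention (as in the source compilation): the single-coding group
#' uses rates as published (2 dp); the multiple-coding group uses full
#' precision count/size rates.
#'
#' @param studies data.frame in the \code{"studies"} schema.
#' @param conservatism data.frame in the \code{"conservatism"} schema.
#' @param ages data.frame in the \code{"ages"} schema.
#' @return an object of class \code{"meta_report"}.
#' @export
meta_report <- function(studies = biome_shift_studies(),
                        conservatism = nz_conservatism(),
                        ages = nz_clade_ages()) {
  st <- studies
  st$rate_exact <- shift_rate(st$shift_count, st$clade_size)
  single <- st[!st$multiple_biomes, ]
  multi <- st[st$multiple_biomes, ]
  rates_single <- single$shift_rate          # as published
  rates_multi <- multi$rate_exact            # full precision
  welch_all <- welch_one_tailed(single$shift_rate, multi$shift_rate)
  welch_non_nz <- welch_one_tailed(single$shift_rate,
                                   multi$shift_rate[!multi$nz])
  cs <- conservatism
  paired <- paired_one_tailed(cs$rate_single, cs$rate_multiple)
  bd <- b_decline(cs$rate_multiple, cs$rate_single)
  decline <- data.frame(clade = cs$clade, B_single = cs$rate_single,
                        B_multiple = cs$rate_multiple,
                        B_decline = bd$B_decline, percent = bd$percent)
  tend <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
    tc <- tendency_change(cs$p_single[i], cs$p_multiple[i])
    data.frame(clade = cs$clade[i], p_single = cs$p_single[i],
               p_multiple = cs$p_multiple[i],
               absolute_change = tc$absolute_change,
               percent_change = tc$percent_change, label = tc$label)
  }))
  has_spec <- !is.na(st$specialists_pct)
  reg_rate <- ols_fit(st$specialists_pct[has_spec], st$rate_exact[has_spec])
  spec_nz <- st$specialists_pct[match(cs$clade, st$lineage)]
  reg_decline <- ols_fit(spec_nz, decline$B_decline)
  div <- data.frame(
    clade = ages$clade,
    rate = vapply(seq_len(nrow(ages)), function(i) {
      t <- if (ages$age_basis[i] == "crown") ages$crown_age[i] else ages$stem_age[i]
      diversification_rate(ages$n_total[i], t, ages$age_basis[i])
    }, numeric(1)))
  structure(list(
    summary_single = group_summary(rates_single),
    summary_multiple = group_summary(rates_multi),
    welch_all = welch_all, welch_non_nz = welch_non_nz, paired = paired,
    decline = decline,
    decline_range = range(decline$percent),
    tendency = tend,
    regression_rate_vs_specialists = reg_rate,
    regression_decline_vs_specialists = reg_decline,
    diversification = div,
    n_single = nrow(single), n_multiple = nrow(multi)),
    class = "meta_report")
}

#' @export
print.meta_report <- function(x, ...) {
  ss <- x$summary_single; sm <- x$summary_multiple
  cat("Biome shift rate meta-analysis\n")
  cat(sprintf("  single-coding rates  (n=%d): median %.2f (Q1 %.2f, Q3 %.2f)\n",
              ss$n, ss$median, ss$q1, ss$q3))
  cat(sprintf("  multiple-coding rates (n=%d): median %.2f (Q1 %.2f, Q3 %.2f)\n",
              sm$n, sm$median, sm$q1, sm$q3))
  cat(sprintf("  Welch one-tailed (non-NZ multiple vs single): t(%d) = %.2f, p = %.4g\n",
              x$welch_non_nz$df_display, x$welch_non_nz$statistic,
              x$welch_non_nz$p))
  cat(sprintf("  paired one-tailed (NZ clades): t(%d) = %.3f, p = %.4g\n",
              x$paired$df, x$paired$statistic, x$paired$p))
  cat(sprintf("  proportional decline in shift rate: %d%% - %d%%\n",
              x$decline_range[1L], x$decline_range[2L]))
  cat("  tendency changes:\n")
  for (i in seq_len(nrow(x$tendency)))
    cat(sprintf("    %-16s %s\n", x$tendency$clade[i], x$tendency$label[i]))
  invisible(x)
}
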