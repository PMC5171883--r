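#' Drift 95% interval half-width for a standardized line divergence
#'
#' Half-width of the central interval within which the standardized
#' divergence `D_y` of a neutral trait is expected to fall when the two
#' lines differ only by genetic drift and finite family sampling:
#'
#' \deqn{CI = z_{1-\alpha/2} \sqrt{2\,(2 F h^2 + 2/n)}}
#'
#' interpreted as per-line drift variance `2 F h2` (between-line variance of
#' the standardized genetic mean after inbreeding has accumulated to `F`)
#' plus per-line family-sampling variance `2/n`, doubled for the difference
#' of two independent lines, with a normal quantile. The closed form is
#' reverse-engineered from the published intervals of the motivating
#' selection experiment (it reproduces all of them to the printed
#' precision); it is a fixed, documented model, not an estimate.
#'
#' @param h2 Narrow-sense heritability in \[0, 1\] (vectorized).
#' @param F Pedigree inbreeding coefficient in \[0, 1).
#' @param n_families Number of families represented in the measurement
#'   (integer >= 2).
#' @param alpha Significance level; default 0.05 gives the 95% interval.
#' @return Interval half-width in pooled phenotypic SD units.
#' @examples
#' drift_ci(0.33, 0.06217, 12)  # 1.26 at 2 dp
#' drift_ci(0.39, 0.06217, 18)  # 1.11
#' @export
drift_ci <- function(h2, F, n_families, alpha = 0.05) {
  if (any(!is.finite(h2)) || any(h2 < 0) || any(h2 > 1))
    ld_abort("`h2` must lie in [0, 1]", "linedrift_domain")
  if (any(!is.finite(F)) || any(F < 0) || any(F >= 1))
    ld_abort("`F` must lie in [0, 1)", "linedrift_domain")
  if (any(!is.finite(n_families)) || any(n_families < 2) ||
      any(n_families != round(n_families)))
    ld_abort("`n_families` must be an integer >= 2", "linedrift_domain")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    ld_abort("`alpha` must lie in (0, 1)", "linedrift_domain")
  stats::qnorm(1 - alpha / 2) * sqrt(2 * (2 * F * h2 + 2 / n_families))
}

#' Drift test for a single trait
#'
#' Combines [standardized_divergence()] and [drift_ci()]: a trait exceeds
#' drift when `|D_y|` is larger than the interval half-width, in which case
#' the line difference is interpreted as a correlated response to selection
#' rather than drift. Traits without a heritability estimate or family
#' count are returned with `testable = FALSE` (the dash convention of the
#' published table). The comparison uses full precision, never the rounded
#' display values.
#'
#' @param record A [trait_record].
#' @param F Inbreeding coefficient of the colony pedigree.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `drift_test`: a list with `trait_name`,
#'   `experiment`, `testable`, `d_y`, `ci95`, `exceeds_drift`, and the
#'   `F`, `h2`, `n_families` used.
#' @export
evaluate_trait <- function(record, F, alpha = 0.05) {
  stopifnot(inherits(record, "trait_record"))
  if (is.na(record$h2) || is.na(record$n_families)) {
    out <- list(trait_name = record$trait_name, experiment = record$experiment,
                testable = FALSE, d_y = NA_real_, ci95 = NA_real_,
                exceeds_drift = NA, F = F, h2 = record$h2,
                n_families = record$n_families)
    return(structure(out, class = "drift_test"))
  }
  d <- standardized_divergence(record)
  ci <- drift_ci(record$h2, F, record$n_families, alpha)
  structure(list(trait_name = record$trait_name, experiment = record$experiment,
                 testable = TRUE, d_y = d, ci95 = ci,
                 exceeds_drift = abs(d) > ci, F = F, h2 = record$h2,
                 n_families = record$n_families),
            class = "drift_test")
}

#' @export
print.drift_test <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("<drift_test> %s (expt %s): not testable (no h2/n)\n",
                x$trait_name, x$experiment))
  } else {
    cat(sprintf(
      "<drift_test> %s (expt %s): D_y = %.2f, 95%% drift CI = ±%.2f -> %s\n",
      x$trait_name, x$experiment, x$d_y, x$ci95,
      if (x$exceeds_drift) "exceeds drift" else "within drift"))
  }
  invisible(x)
}

#' Drift-test report over a table of traits
#'
#' Runs the drift test on every row of a trait-summary table and returns a
#' report in the layout of the published line-comparison table: per-line
#' mean and SEM, t-test p-value, `h2`, `F`, `n`, interval half-width, `D_y`
#' and an exceeds marker. Values are carried at full precision; rounding to
#' 2 decimals happens only in [write_drift_report()] / formatting.
#'
#' @param records A list of [trait_record]s or a data.frame in the
#'   [read_trait_table()] layout.
#' @param F Inbreeding coefficient applied to every row.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of class `drift_report` with one row per trait;
#'   not-testable rows carry `NA` in the test columns.
#' @export
drift_table <- function(records, F, alpha = 0.05) {
  if (is.data.frame(records)) records <- as_trait_records(records)
  if (!length(records)) {
    out <- data.frame(trait_name = character(), experiment = character(),
                      ha_mean = numeric(), ha_sem = numeric(), ha_n = integer(),
                      c_mean = numeric(), c_sem = numeric(), c_n = integer(),
                      p_value = numeric(), h2 = numeric(), F = numeric(),
                      n_families = integer(), ci95 = numeric(),
                      d_y = numeric(), exceeds_drift = logical())
    class(out) <- c("drift_report", "data.frame")
    return(out)
  }
  rows <- lapply(records, function(rec) {
    tt <- tryCatch(unpaired_t(rec$high_active, rec$control),
                   linedrift_error = function(e) list(p_value = NA_real_))
    res <- evaluate_trait(rec, F, alpha)
    data.frame(trait_name = rec$trait_name, experiment = rec$experiment,
               ha_mean = rec$high_active$mean, ha_sem = rec$high_active$sem,
               ha_n = rec$high_active$n,
               c_mean = rec$control$mean, c_sem = rec$control$sem,
               c_n = rec$control$n,
               p_value = tt$p_value,
               h2 = if (res$testable) rec$h2 else NA_real_,
               F = if (res$testable) F else NA_real_,
               n_families = if (res$testable) rec$n_families else NA_integer_,
               ci95 = res$ci95, d_y = res$d_y,
               exceeds_drift = res$exceeds_drift,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("drift_report", "data.frame")
  out
}

fmt2 <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))

#' Write a drift-test report as TSV
#'
#' Tab-separated report with `ci95` and `d_y` rounded to 2 decimals and
#' not-testable cells written as dashes, mirroring the published layout.
#' The exceeds flag is computed from full precision before rounding.
#'
#' @param report A `drift_report` from [drift_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_drift_report <- function(report, path) {
  stopifnot(inherits(report, "drift_report"))
  out <- data.frame(
    trait = report$trait_name, expt = report$experiment,
    high_active = sprintf("%.4g (±%.4g)", report$ha_mean, report$ha_sem),
    control = sprintf("%.4g (±%.4g)", report$c_mean, report$c_sem),
    p_value = ifelse(is.na(report$p_value), "-",
                     signif(report$p_value, 2)),
    h2 = ifelse(is.na(report$h2), "-", report$h2),
    F = ifelse(is.na(report$F), "-", report$F),
    n = ifelse(is.na(report$n_families), "-", report$n_families),
    ci95 = fmt2(report$ci95),
    d_y = fmt2(report$d_y),
    exceeds = ifelse(is.na(report$exceeds_drift), "-",
                     ifelse(report$exceeds_drift, "*", "")),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format a drift-test report as markdown
#'
#' @param report A `drift_report` from [drift_table()].
#' @return A character vector of markdown lines; exceeding divergences are
#'   shown in bold, as in the published table.
#' @export
format_drift_report_md <- function(report) {
  stopifnot(inherits(report, "drift_report"))
  hdr <- "| Trait | Expt | High-Active | Control | h2 | n | 95% CI | D_y |"
  sep <- "|---|---|---|---|---|---|---|---|"
  rows <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    dy <- if (is.na(r$d_y)) "-" else if (isTRUE(r$exceeds_drift))
      sprintf("**%.2f**", r$d_y) else sprintf("%.2f", r$d_y)
    sprintf("| %s | %s | %.4g (±%.4g) | %.4g (±%.4g) | %s | %s | %s | %s |",
            r$trait_name, r$experiment, r$ha_mean, r$ha_sem, r$c_mean,
            r$c_sem, ifelse(is.na(r$h2), "-", r$h2),
            ifelse(is.na(r$n_families), "-", r$n_families),
            fmt2(r$ci95), dy)
  }, character(1))
  c(hdr, sep, rows)
}
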