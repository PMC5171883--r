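#' Group summary of a trait in one line
#'
#' Container for the per-line summary statistics that selection-experiment
#' papers print: a mean, its standard error, and the number of individuals
#' measured. These are the only ingredients the standardized divergence
#' needs, so the whole analysis can run from a published table.
#'
#' @param label Text label for the group (e.g. `"High-Active"`).
#' @param mean Group mean, in trait units.
#' @param sem Standard error of the mean, in trait units; must be >= 0.
#' @param n Number of individuals the mean is based on (positive integer).
#' @return An object of class `group_summary`.
#' @examples
#' group_summary("High-Active", 0.92, 0.10, 14)
#' @export
group_summary <- function(label, mean, sem, n) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.numeric(sem) || length(sem) != 1L || !is.finite(sem) || sem < 0)
    ld_abort("`sem` must be a single non-negative number", "linedrift_domain")
  if (!is_count(n))
    ld_abort("`n` must be a positive integer", "linedrift_invalid_group_size")
  structure(list(label = label, mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: %.4g (±%.4g SEM), n = %d\n",
              x$label, x$mean, x$sem, x$n))
  invisible(x)
}

#' Paired line summaries for one trait
#'
#' The row unit of a line-comparison table: the selected ("high") and
#' control group summaries for one trait, together with the literature
#' heritability and the number of families represented in the measurement,
#' which the drift test needs. `h2` and `n_families` may be `NA` when no
#' heritability estimate exists; such traits are carried through reporting
#' but marked not testable.
#'
#' @param trait_name Trait label.
#' @param experiment Experiment/cohort label.
#' @param high_active [group_summary] for the selected line.
#' @param control [group_summary] for the control line.
#' @param h2 Narrow-sense heritability in \[0, 1\], or `NA`.
#' @param n_families Number of families represented, >= 2, or `NA`.
#' @param direction_note Optional free-text note on the expected direction.
#' @return An object of class `trait_record`.
#' @export
trait_record <- function(trait_name, experiment, high_active, control,
                         h2 = NA_real_, n_families = NA_integer_,
                         direction_note = "") {
  stopifnot(inherits(high_active, "group_summary"),
            inherits(control, "group_summary"))
  if (!is.na(h2) && (!is.numeric(h2) || h2 < 0 || h2 > 1))
    ld_abort("`h2` must lie in [0, 1]", "linedrift_domain")
  if (!is.na(n_families) && (!is_count(n_families) || n_families < 2))
    ld_abort("`n_families` must be an integer >= 2", "linedrift_domain")
  structure(list(trait_name = trait_name, experiment = as.character(experiment),
                 high_active = high_active, control = control,
                 h2 = as.numeric(h2),
                 n_families = if (is.na(n_families)) NA_integer_ else as.integer(n_families),
                 direction_note = direction_note),
            class = "trait_record")
}

#' Convert a standard error of the mean to a standard deviation
#'
#' Published tables usually print SEMs; the pooled-SD standardization needs
#' SDs. `sd = sem * sqrt(n)`.
#'
#' @param sem Standard error(s) of the mean, >= 0.
#' @param n Group size(s); every element must be >= 2 (an SD is undefined
#'   for a single observation).
#' @return Standard deviation(s), same length as the inputs.
#' @examples
#' sd_from_sem(0.10, 14)
#' @export
sd_from_sem <- function(sem, n) {
  if (any(!is.finite(n)) || any(n < 2) || any(n != round(n)))
    ld_abort("group size `n` must be an integer >= 2",
             "linedrift_invalid_group_size")
  if (any(!is.finite(sem)) || any(sem < 0))
    ld_abort("`sem` must be non-negative", "linedrift_domain")
  sem * sqrt(n)
}

#' Pooled standard deviation of two summarized groups
#'
#' Degrees-of-freedom-weighted (Cohen's-d style) pooling:
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`, with each `s` obtained
#' from the printed SEM via [sd_from_sem()].
#'
#' @param g1,g2 [group_summary] objects.
#' @return The pooled standard deviation (trait units).
#' @examples
#' pooled_sd(group_summary("HA", 0.92, 0.10, 14),
#'           group_summary("C",  0.44, 0.06, 14))
#' @export
pooled_sd <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  if (g1$n + g2$n < 4)
    ld_abort("pooled SD needs a combined group size of at least 4",
             "linedrift_insufficient_data")
  s1 <- sd_from_sem(g1$sem, g1$n)
  s2 <- sd_from_sem(g2$sem, g2$n)
  sqrt(((g1$n - 1) * s1^2 + (g2$n - 1) * s2^2) / (g1$n + g2$n - 2))
}

#' Standardized line divergence D_y
#'
#' The between-line difference in trait means expressed in pooled phenotypic
#' standard deviation units: `D_y = (mean_high - mean_control) / s_pooled`.
#' The sign is preserved (negative when the selected line scores lower).
#'
#' @param record A [trait_record].
#' @return Signed dimensionless divergence.
#' @examples
#' rec <- trait_record("Home Cage Activity", "1",
#'                     group_summary("High-Active", 0.92, 0.10, 14),
#'                     group_summary("Control", 0.44, 0.06, 14),
#'                     h2 = 0.33, n_families = 12)
#' standardized_divergence(rec)  # ~1.56, printed as 1.54
#' @export
standardized_divergence <- function(record) {
  stopifnot(inherits(record, "trait_record"))
  sp <- pooled_sd(record$high_active, record$control)
  if (sp == 0)
    ld_abort("pooled SD is zero; divergence undefined",
             "linedrift_degenerate_variance")
  (record$high_active$mean - record$control$mean) / sp
}

#' Drug-effect trait from individual responses
#'
#' Builds an "effect of drug on X" trait by subtracting the saline group
#' mean from each individual drug-condition value. The mean and SEM of the
#' result summarize the derived trait for a line.
#'
#' @param individual_drug_values Numeric vector of individual responses
#'   under the drug condition.
#' @param saline_group_mean Mean response of the saline group (scalar).
#' @return Numeric vector of individual effect values.
#' @examples
#' amph_effect(c(5, 6, 7), 4)
#' @export
amph_effect <- function(individual_drug_values, saline_group_mean) {
  if (length(individual_drug_values) == 0)
    ld_abort("no drug-condition values supplied", "linedrift_empty_input")
  stopifnot(is.numeric(individual_drug_values),
            is.numeric(saline_group_mean), length(saline_group_mean) == 1L)
  individual_drug_values - saline_group_mean
}

#' Summarize a drug-effect trait as a group summary
#'
#' Convenience wrapper: applies [amph_effect()] and returns the
#' [group_summary] (mean, SEM, n) of the effect values.
#'
#' @inheritParams amph_effect
#' @param label Group label for the derived summary.
#' @return A [group_summary].
#' @export
amph_effect_summary <- function(individual_drug_values, saline_group_mean,
                                label = "drug effect") {
  eff <- amph_effect(individual_drug_values, saline_group_mean)
  if (length(eff) < 2)
    ld_abort("need at least 2 values to summarize", "linedrift_invalid_group_size")
  group_summary(label, mean(eff), stats::sd(eff) / sqrt(length(eff)),
                length(eff))
}

#' Unpaired two-sample t-test from group summaries
#'
#' Pooled-variance two-sided t-test computed from means, SEMs and group
#' sizes alone, with `df = n1 + n2 - 2`. This is the line-comparison test
#' printed alongside each trait row.
#'
#' @param g1,g2 [group_summary] objects.
#' @return A list with `statistic`, `df` and `p_value`.
#' @examples
#' unpaired_t(group_summary("a", 10, 1, 5), group_summary("b", 10, 1, 5))
#' @export
unpaired_t <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  sp <- pooled_sd(g1, g2)
  se <- sp * sqrt(1 / g1$n + 1 / g2$n)
  df <- g1$n + g2$n - 2L
  diff <- g1$mean - g2$mean
  if (se == 0) {
    if (diff == 0) return(list(statistic = 0, df = df, p_value = 1))
    ld_abort("zero pooled variance with unequal means",
             "linedrift_degenerate_variance")
  }
  t <- diff / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

trait_table_columns <- c("trait_name", "experiment", "ha_mean", "ha_sem",
                         "ha_n", "c_mean", "c_sem", "c_n", "h2", "n_families")

#' Read a trait-summary table
#'
#' Reads the CSV dialect with one row per trait: columns `trait_name,
#' experiment, ha_mean, ha_sem, ha_n, c_mean, c_sem, c_n, h2, n_families`
#' (`h2` / `n_families` may be blank for traits without a literature
#' heritability estimate).
#'
#' @param path Path to a CSV file.
#' @return A data.frame with the columns above.
#' @seealso [write_trait_table()], [as_trait_records()]
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trait_table_columns, names(df))
  if (length(missing))
    ld_abort(paste0("trait table is missing column(s): ",
                    paste(missing, collapse = ", ")), "linedrift_format")
  num <- c("ha_mean", "ha_sem", "c_mean", "c_sem", "h2")
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in c("ha_n", "c_n", "n_families")) df[[cc]] <- as.integer(df[[cc]])
  df$experiment <- as.character(df$experiment)
  df[trait_table_columns]
}

#' Write a trait-summary table
#'
#' Emits the same CSV dialect that [read_trait_table()] accepts, with blank
#' cells for missing `h2` / `n_families`.
#'
#' @param df Data.frame of trait summaries.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(df, path) {
  missing <- setdiff(trait_table_columns, names(df))
  if (length(missing))
    ld_abort(paste0("trait table is missing column(s): ",
                    paste(missing, collapse = ", ")), "linedrift_format")
  utils::write.csv(df[trait_table_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Convert a trait-summary data.frame to trait records
#'
#' @param df Data.frame in the [read_trait_table()] layout.
#' @return A list of [trait_record] objects.
#' @export
as_trait_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    trait_record(r$trait_name, r$experiment,
                 group_summary("High-Active", r$ha_mean, r$ha_sem, r$ha_n),
                 group_summary("Control", r$c_mean, r$c_sem, r$c_n),
                 h2 = r$h2, n_families = r$n_families)
  })
}
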