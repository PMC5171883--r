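#' Run the full drift-test pipeline from a config file
#'
#' Reads a YAML config, executes summaries -> drift test -> report, and
#' writes `report.tsv`, `report.md` and `manifest.json` into the output
#' directory. Config schema:
#' \preformatted{
#' traits: path/to/traits.csv     # trait-summary CSV, or instead:
#' simulation:                    #   keys passed to sim_config()
#'   n_families: 10
#'   generations: 16
#' inbreeding: 0.06217            # F value, or instead:
#' pedigree: path/to/ped.csv      #   F = mean over the last generation
#' alpha: 0.05                    # optional
#' seed: 1                        # optional, used for simulation configs
#' out_dir: results               # may be overridden by `out_dir` argument
#' }
#'
#' @param config Path to a YAML config file.
#' @param out_dir Output directory (overrides the config; created if
#'   needed).
#' @param quiet Suppress progress messages (logged to stderr).
#' @return Invisibly, a list with the `report`, the `manifest`, and the
#'   output `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (!file.exists(config))
    ld_abort(paste0("config file not found: ", config), "linedrift_config")
  cf <- yaml::read_yaml(config)
  say <- function(...) if (!quiet) message(...)

  missing <- character(0)
  if (is.null(cf$traits) && is.null(cf$simulation))
    missing <- c(missing, "traits (or simulation)")
  if (is.null(cf$inbreeding) && is.null(cf$pedigree) &&
      is.null(cf$simulation))
    missing <- c(missing, "inbreeding (or pedigree)")
  if (length(missing))
    ld_abort(paste0("config is missing field(s): ",
                    paste(missing, collapse = "; ")), "linedrift_config")

  out_dir <- out_dir %||% cf$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- config

  if (!is.null(cf$traits)) {
    say("reading trait table: ", cf$traits)
    traits <- read_trait_table(cf$traits)
    inputs <- c(inputs, cf$traits)
  } else {
    say("simulating trait table")
    args <- cf$simulation
    if (!is.null(cf$seed)) args$seed <- cf$seed
    if (!is.null(args$genetic_correlation))
      args$genetic_correlation <- matrix(unlist(args$genetic_correlation),
                                         length(args$h2), length(args$h2))
    sim <- simulate_breeding(do.call(sim_config, args))
    traits <- generate_trait_table(sim)
  }
  if (!nrow(traits)) say("trait table is empty; report will be empty")

  if (!is.null(cf$inbreeding)) {
    Fval <- as.numeric(cf$inbreeding)
  } else if (!is.null(cf$pedigree)) {
    say("computing F from pedigree: ", cf$pedigree)
    ped <- read_pedigree(cf$pedigree)
    Fval <- mean_line_F(ped, max(ped$generation))
    inputs <- c(inputs, cf$pedigree)
  } else {
    Fval <- mean(sim$realized_F$F[sim$realized_F$generation ==
                                    sim$config$generations])
  }
  alpha <- cf$alpha %||% 0.05

  report <- drift_table(traits, Fval, alpha)
  nt <- sum(!is.na(report$d_y))
  say(sprintf("drift test: %d/%d rows testable, %d exceed drift",
              nt, nrow(report), sum(report$exceeds_drift, na.rm = TRUE)))

  paths <- file.path(out_dir, c("report.tsv", "report.md", "manifest.json"))
  write_drift_report(report, paths[1])
  writeLines(format_drift_report_md(report), paths[2])
  manifest <- run_manifest("run", config, seed = cf$seed,
                           input_paths = inputs, output_paths = paths)
  jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, manifest = manifest, paths = paths))
}

# provenance record written next to every pipeline output
run_manifest <- function(command, config_path, seed = NULL,
                         input_paths = character(), output_paths = character()) {
  list(command = command,
       config_hash = unname(tools::md5sum(config_path)),
       seed = seed,
       input_paths = as.character(input_paths),
       output_paths = as.character(output_paths),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("linedrift")))
}

#' Validate a data file against its expected schema
#'
#' Schema checks with line-numbered messages for the five file kinds the
#' package reads: `traits`, `pedigree`, `eventlog`, `arms`, `rotarod`.
#' Line numbers refer to the file (header = line 1; commented metadata
#' lines in event logs are counted).
#'
#' @param path File to validate.
#' @param kind One of `"traits"`, `"pedigree"`, `"eventlog"`, `"arms"`,
#'   `"rotarod"`.
#' @return A data.frame of class `format_validation` with columns `line`
#'   and `message`; zero rows means the file is valid (see `attr(x, "ok")`).
#' @export
validate_formats <- function(path, kind = c("traits", "pedigree", "eventlog",
                                            "arms", "rotarod")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    ld_abort(paste0("cannot read file: ", path), "linedrift_io")
  errs <- data.frame(line = integer(), message = character(),
                     stringsAsFactors = FALSE)
  add <- function(line, msg)
    errs <<- rbind(errs, data.frame(line = line, message = msg,
                                    stringsAsFactors = FALSE))
  lines <- readLines(path)
  n_comment <- if (kind == "eventlog") sum(grepl("^#", lines)) else 0L
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(utils::read.csv(text = body, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || !nrow(df) && !length(names(df))) {
    add(1L, "file is not parseable CSV")
    return(validation_result(errs, path, kind))
  }
  # row i of df sits on file line: header(1) + comments + i
  fl <- function(i) n_comment + 1L + i
  need <- switch(kind,
    traits = trait_table_columns,
    pedigree = pedigree_columns,
    eventlog = c("t_seconds", "kind", "detail"),
    arms = "arm",
    rotarod = c("animal", "day", "trial", "latency", "is_extra"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    add(1L, paste0("missing column(s): ", paste(miss, collapse = ", ")))
    return(validation_result(errs, path, kind))
  }
  if (kind == "traits") {
    for (cc in c("ha_mean", "ha_sem", "ha_n", "c_mean", "c_sem", "c_n")) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))
      for (i in bad) add(fl(i), paste0("non-numeric `", cc, "`"))
    }
    bad <- which(suppressWarnings(as.numeric(df$ha_sem)) < 0 |
                   suppressWarnings(as.numeric(df$c_sem)) < 0)
    for (i in bad) add(fl(i), "negative SEM")
  } else if (kind == "pedigree") {
    ids <- as.character(df$id)
    dup <- which(duplicated(ids))
    for (i in dup) add(fl(i), paste0("duplicate id `", ids[i], "`"))
    for (cc in c("sire", "dam")) {
      p <- as.character(df[[cc]])
      known <- is.na(p) | p %in% c("", "0")
      bad <- which(!known & !p %in% ids)
      for (i in bad)
        add(fl(i), paste0(cc, " `", p[i], "` not present in pedigree"))
      self <- which(!known & p == ids)
      for (i in self) add(fl(i), "individual is its own parent")
    }
  } else if (kind == "eventlog") {
    tt <- suppressWarnings(as.numeric(df$t_seconds))
    bad <- which(is.na(tt))
    for (i in bad) add(fl(i), "non-numeric t_seconds")
    dec <- which(diff(tt) < 0) + 1L
    if (length(dec)) add(fl(dec[1]), "decreasing timestamp")
    bad <- which(!df$kind %in% event_kinds)
    for (i in bad) add(fl(i), paste0("unknown event kind `", df$kind[i], "`"))
  } else if (kind == "arms") {
    bad <- which(!df$arm %in% c("A", "B", "C"))
    for (i in bad) add(fl(i), paste0("invalid arm label `", df$arm[i], "`"))
  } else if (kind == "rotarod") {
    bad <- which(is.na(suppressWarnings(as.numeric(df$latency))))
    for (i in bad) add(fl(i), "non-numeric latency")
  }
  validation_result(errs, path, kind)
}

validation_result <- function(errs, path, kind) {
  attr(errs, "path") <- path
  attr(errs, "kind") <- kind
  attr(errs, "ok") <- nrow(errs) == 0L
  class(errs) <- c("format_validation", "data.frame")
  errs
}

#' @export
print.format_validation <- function(x, ...) {
  if (attr(x, "ok")) {
    cat(sprintf("%s: valid %s file\n", attr(x, "path"), attr(x, "kind")))
  } else {
    cat(sprintf("%s: %d error(s) as a %s file\n", attr(x, "path"), nrow(x),
                attr(x, "kind")))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  line %d: %s\n", x$line[i], x$message[i]))
  }
  invisible(x)
}
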