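pedigree_columns <- c("id", "sire", "dam", "sex", "generation", "family",
                      "line")

# Validate a raw pedigree data.frame and return it topologically sorted
# (parents before offspring) with class "pedigree".
as_pedigree <- function(df) {
  missing <- setdiff(pedigree_columns, names(df))
  if (length(missing))
    ld_abort(paste0("pedigree is missing column(s): ",
                    paste(missing, collapse = ", ")), "linedrift_format")
  df$id <- as.character(df$id)
  for (cc in c("sire", "dam")) {
    x <- as.character(df[[cc]])
    x[x %in% c("", "0", "NA") | is.na(x)] <- NA_character_
    df[[cc]] <- x
  }
  df$sex <- as.character(df$sex)
  df$generation <- as.integer(df$generation)
  df$family <- as.character(df$family)
  df$line <- as.character(df$line)

  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    ld_abort(paste0("duplicate id(s): ", paste(dup, collapse = ", ")),
             "linedrift_duplicate_id")
  }
  known <- c(df$sire, df$dam)
  known <- known[!is.na(known)]
  dangling <- setdiff(known, df$id)
  if (length(dangling))
    ld_abort(paste0("parent id(s) not in pedigree: ",
                    paste(dangling, collapse = ", ")),
             "linedrift_dangling_reference")

  idx <- setNames(seq_len(nrow(df)), df$id)
  si <- ifelse(is.na(df$sire), 0L, idx[df$sire])
  di <- ifelse(is.na(df$dam), 0L, idx[df$dam])

  # sex consistency where recorded
  psex <- function(pi) {
    s <- rep(NA_character_, nrow(df))
    s[pi > 0] <- df$sex[pi[pi > 0]]
    s
  }
  bad <- which(psex(si) == "F")
  if (length(bad))
    ld_abort(paste0("sire of ", df$id[bad[1]], " is recorded as female"),
             "linedrift_sex_mismatch")
  bad <- which(psex(di) == "M")
  if (length(bad))
    ld_abort(paste0("dam of ", df$id[bad[1]], " is recorded as male"),
             "linedrift_sex_mismatch")

  # Kahn topological sort; failure to place every animal means a cycle
  nparents <- (si > 0) + (di > 0)
  children <- split(rep(seq_len(nrow(df)), 2L), c(si, di))
  children[["0"]] <- NULL
  order <- integer(nrow(df))
  queue <- which(nparents == 0L)
  k <- 0L
  remaining <- nparents
  while (length(queue)) {
    nxt <- integer(0)
    for (i in queue) {
      k <- k + 1L
      order[k] <- i
      kids <- children[[as.character(i)]]
      if (!is.null(kids)) {
        remaining[kids] <- remaining[kids] - 1L
        nxt <- c(nxt, kids[remaining[kids] == 0L])
      }
    }
    queue <- unique(nxt)
  }
  if (k < nrow(df))
    ld_abort("pedigree contains a cycle (an animal is its own ancestor)",
             "linedrift_pedigree_cycle")

  pgen <- function(pi) {
    g <- rep(-1L, nrow(df))
    g[pi > 0] <- df$generation[pi[pi > 0]]
    g
  }
  gen_bad <- which(pgen(si) >= df$generation | pgen(di) >= df$generation)
  if (length(gen_bad))
    ld_abort(paste0("parents of ", df$id[gen_bad[1]],
                    " do not precede it in generation order"),
             "linedrift_generation_order")

  out <- df[order, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree CSV
#'
#' Columns: `id, sire, dam, sex, generation, family, line`; unknown parents
#' are coded `0` or left blank. The pedigree is validated (unique ids, no
#' dangling parent references, no cycles, sexes consistent with parental
#' roles, parents in earlier generations) and returned topologically
#' sorted so parents precede offspring.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of class `pedigree`.
#' @export
read_pedigree <- function(path) {
  as_pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character"))
}

#' Write a pedigree CSV
#'
#' Emits the dialect accepted by [read_pedigree()], with unknown parents
#' written as `0`.
#'
#' @param ped A `pedigree` (or compatible data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)[pedigree_columns]
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Inbreeding coefficients for every individual in a pedigree
#'
#' Exact pedigree inbreeding `F` (probability that an individual's two
#' alleles are identical by descent): `F(x) = a(sire, dam) / 2`, the half
#' additive relationship of the parents, computed with the Meuwissen-Luo
#' algorithm. Founders and individuals with an unknown parent have `F = 0`
#' (unknown parents are treated as unrelated, non-inbred founders).
#'
#' @param ped A `pedigree` from [read_pedigree()] / [simulate_breeding()],
#'   or a compatible data.frame.
#' @return Named numeric vector of inbreeding coefficients, in pedigree
#'   order.
#' @export
inbreeding_coefficients <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire]))
  di <- ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  setNames(inbreeding_ml(as.integer(si), as.integer(di)), ped$id)
}

#' Mean inbreeding coefficient of a line at a generation
#'
#' Arithmetic mean of individual `F` over the individuals of one line in
#' one generation; this is the colony-level `F` that the drift test takes
#' as input.
#'
#' @param ped A `pedigree`.
#' @param generation Generation number.
#' @param line Line label (e.g. `"selected"`, `"control"`), or `NULL` to
#'   average over both lines.
#' @return Mean inbreeding coefficient.
#' @export
mean_line_F <- function(ped, generation, line = NULL) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  keep <- ped$generation == generation
  if (!is.null(line)) keep <- keep & ped$line == line
  if (!any(keep))
    ld_abort("no individuals match the requested generation/line",
             "linedrift_no_individuals")
  Fv <- inbreeding_coefficients(ped)
  mean(Fv[keep])
}
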