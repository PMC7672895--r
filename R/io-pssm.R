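#' Read a PSI-BLAST ASCII PSSM (`-out_ascii_pssm` dialect)
#'
#' Expects the standard layout: header lines, a column-label line with 40
#' residue letters (20 log-odds columns then 20 weighted-percentage columns),
#' one line per position with the position index, the query residue, 40
#' numeric score fields and optionally 2 trailing per-line statistics, then an
#' ignored footer. Only the log-odds block is kept; columns are re-mapped to
#' [PSSM_COLUMN_ORDER] whatever order the header declares. Rows whose query
#' residue is not one of the 20 standard letters are dropped with a warning
#' and the corresponding position removed from the returned sequence.
#'
#' @param path Path to the PSSM file.
#' @param id Identifier for the returned profile.
#' @return A [pssm_profile()].
#' @export
read_pssm_ascii <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header_i <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(toks) >= 20L && all(toks %in% AA_ALPHABET)) {
      header_i <- i
      col_order <- toks[1:20]
      break
    }
  }
  if (is.na(header_i))
    stop("no PSSM column-header line found in ", path)
  if (anyDuplicated(col_order) || !setequal(col_order, PSSM_COLUMN_ORDER))
    stop("PSSM header does not declare all 20 residue columns in ", path)

  residues <- character(0)
  rows <- list()
  for (i in (header_i + 1L):length(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(toks) < 2L || is.na(suppressWarnings(as.integer(toks[[1]]))))
      break  # footer reached (or blank line); footer is optional
    aa <- toks[[2]]
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (length(vals) < 40L || anyNA(vals[1:40]))
      stop("PSSM row ", toks[[1]], " in ", path,
           " does not contain 40 numeric score fields")
    if (!aa %in% AA_ALPHABET) {
      warning("read_pssm_ascii: dropped position ", toks[[1]],
              " with non-standard residue '", aa, "'")
      next
    }
    residues <- c(residues, aa)
    rows[[length(rows) + 1L]] <- vals[1:20]
  }
  if (!length(rows)) stop("no PSSM matrix rows found in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  scores <- scores[, PSSM_COLUMN_ORDER, drop = FALSE]
  pssm_profile(aa_sequence(id, paste(residues, collapse = "")), scores)
}

#' Write a profile in the PSI-BLAST ASCII PSSM dialect
#'
#' Emits integer log-odds in canonical column order plus a zero-filled
#' weighted-percentage block and per-line statistics, so the output is
#' readable both by [read_pssm_ascii()] and by standard tooling.
#'
#' @param profile A [pssm_profile()] (scores are rounded to integers on write).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm_ascii <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", c(PSSM_COLUMN_ORDER, PSSM_COLUMN_ORDER)),
                          collapse = "")), con)
  res <- strsplit(profile$sequence$residues, "")[[1]]
  sc <- round(profile$scores)
  for (k in seq_along(res)) {
    writeLines(paste0(sprintf("%5d %s ", k, res[[k]]),
                      paste(sprintf("%3d", sc[k, ]), collapse = ""),
                      paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
                      sprintf("  %.2f %.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda", "PSI Ungapped 0.1 0.1"), con)
  invisible(path)
}
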