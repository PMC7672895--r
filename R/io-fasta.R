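#' Read a FASTA file of protein sequences
#'
#' Residues are upper-cased and sanitized: gaps and non-standard letters are
#' removed (never remapped) and the number of removals per record is reported
#' through a message. A record that is empty after sanitization raises a
#' warning of class `deepfragk_record_error` naming the offending id and is
#' dropped; the remaining records are still returned.
#'
#' @param path Path to a FASTA file.
#' @return List of [aa_sequence()] objects, one per surviving record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank) || !startsWith(nonblank[[1]], ">"))
    stop("not a FASTA file (no '>' header): ", path)
  set <- Biostrings::readBStringSet(path)
  out <- list()
  for (i in seq_along(set)) {
    id <- strsplit(names(set)[[i]], "[[:space:]]+")[[1]][1]
    san <- sanitize_residues(as.character(set[[i]]))
    if (san$removed > 0L)
      message("read_fasta: removed ", san$removed,
              " non-standard character(s) from record '", id, "'")
    if (!nchar(san$residues)) {
      warning(warningCondition(
        sprintf("record '%s' is empty after sanitization and was dropped", id),
        class = "deepfragk_record_error"))
      next
    }
    out[[length(out) + 1L]] <- aa_sequence(id, san$residues)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [aa_sequence()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    L <- nchar(s$residues)
    starts <- seq(1L, L, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, L)), con)
  }
  invisible(path)
}
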