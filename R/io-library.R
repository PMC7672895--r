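#' Write a fragment library to a directory store
#'
#' Layout: `manifest.tsv` (id, class_label, class_name, fasta, pssm) plus one
#' FASTA and one ASCII PSSM file per record under `records/`, so the library
#' is inspectable with standard tools.
#'
#' @param library A [fragment_library()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fragment_library <- function(library, dir) {
  rec_dir <- file.path(dir, "records")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- character(length(library$records))
  for (i in seq_along(library$records)) {
    r <- library$records[[i]]
    fa <- file.path("records", paste0(r$sequence$id, ".fasta"))
    ps <- file.path("records", paste0(r$sequence$id, ".pssm"))
    write_fasta(list(r$sequence), file.path(dir, fa))
    write_pssm_ascii(r$profile, file.path(dir, ps))
    rows[[i]] <- paste(r$sequence$id, r$class_label,
                       library$class_names[[r$class_label + 1L]], fa, ps,
                       sep = "\t")
  }
  writeLines(c("id\tclass_label\tclass_name\tfasta\tpssm", rows),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Write a fold dataset to a directory
#'
#' Layout consumed by the training/prediction configs: `sequences.fasta`,
#' `pssm/<id>.pssm`, and `labels.tsv` (id, fold_label).
#'
#' @param dataset List of records as produced by [make_fold_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fold_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(lapply(dataset, `[[`, "sequence"), file.path(dir, "sequences.fasta"))
  for (rec in dataset)
    write_pssm_ascii(rec$profile,
                     file.path(dir, "pssm", paste0(rec$sequence$id, ".pssm")))
  writeLines(c("id\tfold_label",
               vapply(dataset, function(r)
                 paste(r$sequence$id, r$fold_label, sep = "\t"), character(1))),
             file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Read a fragment library from a directory store
#'
#' @param dir Directory written by [write_fragment_library()].
#' @return A [fragment_library()].
#' @export
read_fragment_library <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv in ", dir)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(man)), function(i) {
    seqs <- read_fasta(file.path(dir, man$fasta[[i]]))
    prof <- read_pssm_ascii(file.path(dir, man$pssm[[i]]), id = man$id[[i]])
    fragment_record(aa_sequence(man$id[[i]], seqs[[1]]$residues),
                    man$class_label[[i]], prof)
  })
  n_classes <- max(man$class_label) + 1L
  class_names <- vapply(seq_len(n_classes) - 1L, function(cl) {
    nm <- unique(man$class_name[man$class_label == cl])
    if (length(nm)) nm[[1]] else sprintf("frag%03d", cl)
  }, character(1))
  fragment_library(records, n_classes, class_names)
}
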