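#' Write a feature matrix with its block layout
#'
#' Tab-separated text: comment lines declaring each block's name and column
#' span, a header row of column names, then one row per fragment. Values are
#' printed with 17 significant digits so the paired reader recovers them
#' bit-exactly.
#'
#' @param features List of `FragmentFeatureSet`s (or a numeric matrix with
#'   [feature_column_names()] columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path) {
  layout <- feature_layout()
  if (is.matrix(features)) {
    x <- features
    ids <- rownames(x)
    if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(x)))
  } else {
    ref <- NULL
    for (i in seq_along(features)) {
      dims <- vapply(features[[i]]$blocks, `[[`, integer(1), "dim")
      if (is.null(ref)) ref <- dims
      else if (!identical(dims, ref))
        stop("inconsistent block layout at record ",
             features[[i]]$fragment_id %||% i)
    }
    x <- do.call(rbind, lapply(features, feature_vector))
    ids <- vapply(features, `[[`, character(1), "fragment_id")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (b in names(layout$blocks))
    writeLines(sprintf("# block\t%s\t%d\t%d", b, layout$starts[[b]], layout$ends[[b]]), con)
  writeLines(paste(c("id", feature_column_names()), collapse = "\t"), con)
  if (length(ids))
    writeLines(vapply(seq_along(ids), function(i)
      paste(c(ids[[i]], sprintf("%.17g", x[i, ])), collapse = "\t"),
      character(1)), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Input path.
#' @return List with `x` (numeric matrix, row names = ids) and `layout`
#'   (block name / start / end data frame from the file header).
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blk <- grepl("^# block\t", lines)
  layout <- do.call(rbind, lapply(strsplit(lines[blk], "\t"), function(t)
    data.frame(block = t[2], start = as.integer(t[3]), end = as.integer(t[4]))))
  body <- lines[!blk]
  header <- strsplit(body[[1]], "\t")[[1]]
  rows <- strsplit(body[-1], "\t")
  x <- matrix(0, length(rows), length(header) - 1L,
              dimnames = list(vapply(rows, `[[`, character(1), 1L), header[-1]))
  for (i in seq_along(rows))
    x[i, ] <- as.numeric(rows[[i]][-1])
  list(x = x, layout = layout)
}
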