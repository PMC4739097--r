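#' Write a TSV with fixed, locale-independent formatting
#'
#' Results files use tab separation, '.' as decimal separator and no
#' quoting, so repeated runs on identical inputs are byte-identical.
#'
#' @param df data.frame.
#' @param path output path; the file is written atomically (temporary file
#'   in the same directory, then renamed).
#' @param digits decimal places for numeric (double) columns (default 4).
#' @export
writeTsv <- function(df, path, digits = 4L) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = digits, format = "f", decimal.mark = ".")
    out[is.na(x)] <- "NA"
    out
  })
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

#' Read a genes-by-samples TSV matrix
#'
#' First column = gene id (rownames), remaining columns numeric per-sample
#' values; header required.
#'
#' @param path input TSV.
#' @return numeric matrix with gene rownames.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
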