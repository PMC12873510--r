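#' Write result tables as deterministic TSV files
#'
#' Writes each table in a named list to `<out_dir>/<name>.tsv` with a fixed
#' column order (as given), rows sorted lexicographically over all columns,
#' and doubles formatted at 6 significant digits, so re-running on the same
#' inputs yields byte-identical files. List-columns (e.g. orthogroup sets) are
#' collapsed with `";"`.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) abort(paste0("cannot create output directory: ", out_dir))
  }
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_result_tsv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a single result table as a deterministic TSV
#'
#' @param tbl A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(tbl, path) {
  tbl <- as_tibble(tbl)
  fmt <- lapply(tbl, function(col) {
    if (is.list(col)) {
      vapply(col, function(x) paste(as.character(x), collapse = ";"), character(1))
    } else if (is.double(col)) {
      formatC(col, digits = 6, format = "g")
    } else {
      as.character(col)
    }
  })
  fmt <- as_tibble(fmt, .name_repair = "minimal")
  if (nrow(fmt) > 1) {
    ord <- do.call(order, c(unname(as.list(fmt)), list(method = "radix")))
    fmt <- fmt[ord, , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(fmt), collapse = "\t"), con)
  if (nrow(fmt)) {
    writeLines(do.call(paste, c(unname(as.list(fmt)), list(sep = "\t"))), con)
  }
  invisible(path)
}
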