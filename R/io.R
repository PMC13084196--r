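# Delimited-text instrument files: two numeric columns, comment lines
# prefixed "#", metadata as "# key=value" header lines. The same layout
# serves spectra (wavelength_nm, value), titrations (urea_M, signal) and
# kinetic traces (time_s, intensity).

parse_meta_value <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

#' Read a two-column instrument table with key=value header metadata
#'
#' Lines starting with `#` are comments; lines of the form `# key=value`
#' are collected into a metadata list (values that parse as numbers are
#' converted). The remainder must be two whitespace- or tab-delimited
#' numeric columns.
#'
#' @param path File path.
#' @return A list with elements `x`, `y` (numeric vectors) and `meta`
#'   (named list).
#' @keywords internal
read_xy_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "cyclofit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(trimws(lines), "#")
  meta <- list()
  for (ln in lines[is_comment]) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      if (nzchar(key)) meta[[key]] <- parse_meta_value(val)
    }
  }
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(data_lines) == 0L) {
    abort(sprintf("no data rows in %s", path), "cyclofit_io_error")
  }
  tab <- utils::read.table(text = data_lines, header = FALSE,
                           colClasses = "numeric")
  if (ncol(tab) != 2L) {
    abort(sprintf("expected 2 columns in %s, found %d", path, ncol(tab)),
          "cyclofit_io_error")
  }
  list(x = tab[[1]], y = tab[[2]], meta = meta)
}

#' Write a two-column instrument table with key=value header metadata
#'
#' Inverse of [read_xy_file()]; numbers are serialized with
#' `format(..., digits = 17)` so a read/write cycle round-trips the text
#' representation bit-identically.
#' @keywords internal
write_xy_file <- function(path, x, y, meta = list(), columns = c("x", "y")) {
  hdr <- sprintf("# %s", paste(columns, collapse = "\t"))
  meta_lines <- vapply(
    names(meta),
    function(k) {
      v <- meta[[k]]
      v <- if (is.numeric(v)) format(v, digits = 17) else as.character(v)
      sprintf("# %s=%s", k, v)
    },
    character(1)
  )
  rows <- paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                format(y, digits = 17, trim = TRUE, scientific = FALSE),
                sep = "\t")
  writeLines(c(meta_lines, hdr, rows), path)
  invisible(path)
}
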