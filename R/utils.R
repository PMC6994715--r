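# Shared helpers: validation and TSV io.

# stop with the caller-facing class used throughout the package
fusil_stop <- function(msg, class = "fusil_error") {
  rlang::abort(msg, class = class)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    fusil_stop(sprintf("`%s` must be a probability in [0, 1]", name),
               class = "fusil_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != floor(x))) {
    fusil_stop(sprintf("`%s` must be an integer count >= %d", name, min),
               class = "fusil_config_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    fusil_stop(sprintf("%s is missing required column(s): %s",
                       what, paste(missing, collapse = ", ")),
               class = "fusil_schema_error")
  }
  invisible(df)
}

#' Read and write the package's TSV tables
#'
#' Thin wrappers around [readr::read_tsv()] / [readr::write_tsv()] that
#' validate required columns on the way in.  All pipeline tables are plain
#' TSV with a header row.
#'
#' @param path file path.
#' @param required character vector of required column names (optional).
#' @param x data frame to write.
#' @return `read_fusil_tsv()` returns a tibble; `write_fusil_tsv()` returns
#'   `x` invisibly.
#' @export
read_fusil_tsv <- function(path, required = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(required)) check_columns(df, required, basename(path))
  df
}

#' @rdname read_fusil_tsv
#' @export
write_fusil_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}
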