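# shared internal helpers

# round half away from zero; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# derive a reproducible child seed from (seed, index); stays below 2^31
child_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header row, no quoting, no row names;
#' the dialect every reader in the package expects.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, col_names) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fill = FALSE,
                          encoding = "UTF-8")
  if (!missing(col_names)) {
    if (!identical(tolower(names(df)), tolower(col_names))) {
      stop_fmt("expected columns (%s) in %s, found (%s)",
               paste(col_names, collapse = ", "), path,
               paste(names(df), collapse = ", "))
    }
    names(df) <- col_names
  }
  df
}
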