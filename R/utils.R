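`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("'%s' must be a probability in [0, 1], got %s", name,
                paste(format(x), collapse = ","))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' Format a p-value in 2-significant-figure scientific notation
#'
#' Formats p-values the way scan reports print them, e.g. `"2.6E-12"`.
#'
#' @param p numeric vector of p-values.
#' @return character vector, uppercase scientific notation with one digit
#'   after the decimal point (two significant figures).
#' @export
#' @examples
#' format_p_sci(c(2.557e-12, 1))
format_p_sci <- function(p) {
  toupper(sprintf("%.1E", p))
}

#' Significance stars for a p-value
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise.
#' @export
sig_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- ""
  out
}

write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA, comment.char = "")
}
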