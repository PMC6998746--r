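## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Polynomial rolling hash (base 31, mod 2^31 - 1) over a character vector.
## Used for panel fingerprints; stable across platforms, no external deps.
.polyHash <- function(x) {
  s <- paste(x, collapse = "\x1f")
  v <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    for (ch in chunk) h <- (h * 31 + ch) %% m
  }
  sprintf("%010d:%d", as.integer(h), length(v))
}

.readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

## The paper-style percent display: one decimal, e.g. 0.98030 -> "98.0%".
#' Format a proportion as a percentage string
#'
#' @param x proportion in [0, 1] (may be NA).
#' @param digits decimal places (default 1).
#' @return character, e.g. \code{"98.0\%"}.
#' @export
formatPercent <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f%%"), 100 * x))
}

## Validation-stage errors: always classed so callers/CLI can map them to
## exit code 2.
.inputError <- function(...) {
  stop(errorCondition(paste0(...), class = c("panelCNV_input_error", "error")))
}
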