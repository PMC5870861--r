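#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange bind_rows distinct left_join
#' @importFrom rlang .data abort warn
NULL

# Render a number the way it appears in ISA cells / range strings:
# fixed notation, trailing zeros (and a trailing ".") stripped.
fmt_num <- function(x) {
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

is_iso8601 <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}(T\\d{2}:\\d{2}(:\\d{2})?)?$", x)
}

# accession prefix ("MS:1000031" -> "MS")
acc_prefix <- function(accession) sub(":.*$", "", accession)

# vocabulary id used in Term Source REF columns, keyed by accession prefix
PREFIX_TO_SOURCE <- c(MS = "MS", IMS = "IMS", NMR = "NMRCV")

stopf <- function(fmt, ..., class = NULL) {
  rlang::abort(sprintf(fmt, ...), class = class)
}
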