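#' Nucleotide alphabet used throughout the package
#'
#' Bases are stored internally as integer codes 1-4 in the fixed order
#' A, C, G, T.
#' @keywords internal
BASES <- c("A", "C", "G", "T")

base_to_code <- function(b) {
  code <- match(toupper(b), BASES)
  if (anyNA(code)) stop("non-ACGT base: ", paste(b[is.na(code)], collapse = ", "))
  code
}

code_to_base <- function(code) BASES[code]

`%||%` <- function(x, y) if (is.null(x)) y else x

## stopifnot() with a readable message
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## Format a rate at 2 significant figures the way results sections print
## them, e.g. 2.8125e-09 -> "2.8e-09".
format_rate <- function(x) formatC(signif(x, 2), format = "e", digits = 1)

## Draw one sub-seed per task from a master seed, staying within the
## 32-bit integer range.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
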