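#' @keywords internal
"_PACKAGE"

#' @useDynLib strcaller, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rpois runif rlnorm setNames aggregate
#' @importFrom methods is
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    !grepl("[^ACGT]", x)
}

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Reverse complement of a DNA string
#' @param x a character string over ACGT
#' @return the reverse complement string
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Round half away from zero
#'
#' Clinical tables round 83.95 to 84.0; base [round()] rounds half to even.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic seeded pseudo-random DNA used for synthetic flanks/padding
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
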