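# internal helpers shared across modules

#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# deterministic sub-seed derivation; keeps results < 2^31 for R's 32-bit ints
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%theninvisible%` <- function(x, y) invisible(x)

stop_tn <- function(...) stop(..., call. = FALSE)

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_tn(sprintf("`%s` must be a single proportion in [0, 1]", name))
  }
}
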