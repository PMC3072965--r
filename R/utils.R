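# Shared numeric helpers. All code lengths are in bits (log base 2) and use
# the convention 0 * log2(0) = 0.

#' @keywords internal
#' @noRd
plogp <- function(x) {
  y <- numeric(length(x))
  nz <- x > 0
  y[nz] <- x[nz] * log2(x[nz])
  y
}

# Weighted-entropy contribution of one codebook whose codewords are used at
# (unnormalized) rates x: sum(x) * H(x / sum(x)) = plogp(sum(x)) - sum(plogp(x)).
#' @keywords internal
#' @noRd
codebook_bits <- function(x) {
  s <- sum(x)
  if (s <= 0) return(0)
  plogp(s) - sum(plogp(x))
}

#' Shannon entropy (bits) of a probability vector
#' @keywords internal
#' @noRd
entropy_bits <- function(p) {
  s <- sum(p)
  if (s <= 0) return(0)
  p <- p / s
  -sum(plogp(p))
}

#' @keywords internal
#' @noRd
stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
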