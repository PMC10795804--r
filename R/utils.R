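# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-away-from-zero; base round() rounds half to even which is the
# wrong convention for grid-size arithmetic here.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# derive a child seed from a base seed; keeps results within 32-bit range
derive_seed <- function(base_seed, ...) {
  idx <- c(...)
  s <- as.double(base_seed)
  for (k in idx) s <- (s * 69069 + 12345 + as.double(k)) %% 2147483647
  as.integer(s)
}

stop_hybridpcr <- function(msg, class) {
  stop(structure(
    class = c(class, "hybridpcr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# numerically safe log2 with 0 * log(0) := 0 convention
xlog2x_sum <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

is_binary01 <- function(x) all(x %in% c(0, 1))
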