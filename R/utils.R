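#' @keywords internal
"_PACKAGE"

# Deterministic integer seed derivation. Children of a root seed are spread by
# a Weyl-style multiplicative hash so that streams for (cohort, subject,
# hemisphere, map) never collide for desk-scale index ranges and adding
# subjects never perturbs existing ones. All values stay below 2^31 - 1.
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  ((s * 48271 + as.numeric(index) * 16807 + 12345) %% m)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Area-weighted mean.
wmean <- function(x, w) {
  sum(x * w) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(TRUE)
}
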