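#' Derive a child RNG seed from a master seed
#'
#' Every stochastic stage of the package draws its own seed from one master
#' seed through this splittable counter scheme, so that a single integer
#' reproduces a whole pipeline run while stages stay independent of each
#' other's consumption of the RNG stream.
#'
#' The scheme is a Lehmer-style hash modulo 2^31 - 1: the master seed, a
#' polynomial hash of the component label, and the index are combined with
#' small multipliers so all intermediate products stay exactly representable
#' in doubles. The result is always a positive 32-bit integer.
#'
#' @param master Integer master seed.
#' @param component Character label of the consuming component
#'   (e.g. `"pool"`, `"power"`).
#' @param index Non-negative integer counter for repeated draws within a
#'   component.
#' @return A positive integer seed, strictly below 2^31.
#' @examples
#' child_seed(1, "pool")
#' child_seed(1, "power", 37)
#' @export
child_seed <- function(master, component, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.character(component), length(component) == 1L)
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 31 + ch) %% m
  s <- ((abs(master) %% m) * 48271 + h * 8121 + index * 7919 + 1) %% m
  as.integer(if (s == 0) 1 else s)
}

# Stop with a message naming the offending argument if x is not a finite
# scalar in [lo, hi].
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Bin values in [0, 1] into 1/bin_width half-open bins [lo, hi), final bin
# closed. Returns integer bin index in 1..n_bins.
beta_bin_index <- function(x, bin_width) {
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-9)
    stop("'bin_width' must divide 1 evenly", call. = FALSE)
  pmin.int(floor(x / bin_width) + 1L, n_bins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
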