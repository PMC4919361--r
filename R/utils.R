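#' @useDynLib neuromkl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft rnorm runif
#' @importFrom rlang abort warn %||%
#' @keywords internal
"_PACKAGE"

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Euclidean projection of v onto the probability simplex {b : b >= 0, sum b = 1}
# (sort-and-threshold algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Round half away from zero, as in the tabulated percentages of clinical
# classification reports (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_neuromkl <- function(...) abort(paste0(...), class = "neuromkl_error")

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_neuromkl(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

# Deterministic substream seed for a pipeline stage, derived from the master
# seed; kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, extract = 29L, evaluate = 47L, maps = 71L)
  as.integer((as.numeric(seed) * 97L + offsets[[stage]]) %% 2147483647)
}
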