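# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is half-open at the lower end
  y[y <= -pi + 1e-15] <- pi
  y
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# Boltzmann constant in kJ/(mol K); internal unit system is
# nm / ps / amu / kJ/mol (Gromacs-consistent: 1 kJ/mol = 1 amu nm^2/ps^2).
.kB <- 0.008314462618
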