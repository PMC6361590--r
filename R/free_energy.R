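#' Classical nucleation free energy
#'
#' The free-energy change (in units of \eqn{k_B T}) for assembling a cluster
#' of dimensionless size \eqn{n} from the dispersed phase,
#' \deqn{\Delta G(n) = a\,n^{2/3} - b\,n,}
#' where `a` is the (positive) dimensionless surface-energy coefficient and
#' `b` the signed bulk coefficient. `b > 0` corresponds to a super-saturated
#' system (the bulk term lowers the free energy and a nucleation barrier
#' exists); `b < 0` to a sub-saturated system where the same expression
#' becomes \eqn{a n^{2/3} + |b| n} and grows without bound.
#'
#' @param n cluster size(s), dimensionless (`n = (R / 1 nm)^3` for
#'   super-resolution data, or the estimated molecule count `N` for live-cell
#'   intensity data).
#' @param a surface coefficient, must be positive.
#' @param b bulk coefficient, signed; positive means super-saturated.
#' @return numeric vector of free energies in \eqn{k_B T}.
#' @export
#' @examples
#' delta_g(c(1e4, 1e5, 1e6), a = 1.07e-3, b = 4.3e-6)
delta_g <- function(n, a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop_nucfit("'a' must be a single positive number", "nucfit_parameter_error")
  }
  a * n^(2 / 3) - b * n
}
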