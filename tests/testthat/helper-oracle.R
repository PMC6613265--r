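`%||%` <- function(x, y) if (is.null(x)) y else x

# Integrating-factor quadrature oracle for the forced linear ODE
#   dc/dt = F(t) - delta * c,  c(0) = c0
# c(t) = c0 exp(-delta t) + int_0^t exp(-delta (t - s)) F(s) ds,
# evaluated by adaptive quadrature, independent of the package's integrator.
quadrature_state <- function(t, delta, params, c0 = 0) {
  vapply(t, function(ti) {
    if (ti == 0) return(c0)
    c0 * exp(-delta * ti) +
      stats::integrate(function(s) exp(-delta * (ti - s)) * forcing(s, params),
                       lower = 0, upper = ti,
                       rel.tol = 1e-12, subdivisions = 2000L)$value
  }, numeric(1))
}

# trapezoid mean over a uniform grid (last point dropped to avoid
# double-counting the period endpoint)
period_mean <- function(x) mean(x[-length(x)])

# complex Fourier coefficient of the fundamental at angular frequency omega
fundamental_coef <- function(t, y, omega) {
  (2 / length(y)) * sum(y * exp(-1i * omega * t))
}
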