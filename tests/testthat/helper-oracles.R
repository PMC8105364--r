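rel_err <- function(x, truth) abs(x - truth) / abs(truth)

# independent oracle for the eluting simulator: adaptive quadrature of
# C(t) = (area/V) * [M(t) - k * int_0^t M(s) e^{-k(t-s)} ds]
# (integration by parts of the convolution of the release rate with decay;
# the integrand here is bounded, unlike the t = 0 power-law rate)
quadrature_concentration <- function(t, K, n, m_inf, area, volume, k) {
  M <- function(s) m_inf * pmin(1, K * s^n)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    I <- stats::integrate(function(s) M(s) * exp(-k * (ti - s)),
                          0, ti, rel.tol = 1e-12,
                          subdivisions = 2000L)$value
    area / volume * (M(ti) - k * I)
  }, numeric(1))
}
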