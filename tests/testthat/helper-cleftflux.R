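# Shared fixtures: the standard neuromuscular-junction parameter set used
# throughout (Lx = Ly = 500 nm, Lz = 50 nm, R = 20 nm, a = 10 nm,
# D = 1e5 nm^2/ms, t0 = 1 ms).
nmj_geometry <- function(a = 10) cleft_geometry(500, 500, 50, 20, a)
nmj_params <- function(D = 1e5, t0 = 1) transport_params(D = D, t0 = t0)

# Brute-force 2-D quadrature of the disk cosine-transform integral in polar
# coordinates (smooth integrand, tensor Gauss-Legendre). Independent of both
# production routes.
brute_force_disk_coefficient <- function(l, m, radius, geometry,
                                         n_r = 120, n_th = 240) {
  gr <- pracma::gaussLegendre(n_r, 0, radius)
  gt <- pracma::gaussLegendre(n_th, 0, 2 * pi)
  x <- outer(gr$x, cos(gt$x))
  y <- outer(gr$x, sin(gt$x))
  integrand <- cos(2 * l * pi * x / geometry$Lx) *
    cos(2 * m * pi * y / geometry$Ly) * gr$x
  eps_l <- if (l == 0) 0.5 else 1
  eps_m <- if (m == 0) 0.5 else 1
  4 * eps_l * eps_m / (geometry$Lx * geometry$Ly) *
    as.numeric(t(gr$w) %*% integrand %*% gt$w)
}
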