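#' Decay constant of a lateral cosine mode in Laplace space
#'
#' For mode (l, m) at Laplace variable s, the z-direction decay constant of
#' the cosine-series solution is
#' \deqn{\gamma_{lm}(s) = \sqrt{s/D + (2\pi l/L_x)^2 + (2\pi m/L_y)^2}.}
#'
#' @param l,m Nonnegative mode indices (vectorised).
#' @param s Laplace variable (1/ms), real and >= 0.
#' @param D Diffusion constant (nm^2/ms).
#' @param geometry A [cleft_geometry()].
#' @return gamma in 1/nm. `s = 0` with `l = m = 0` is a domain error: callers
#'   needing the s -> 0 limit use the analytic limit instead.
#' @examples
#' geom <- cleft_geometry()
#' gamma_lm(0, 0, s = 1, D = 1e5, geom)   # sqrt(s/D)
#' gamma_lm(1, 0, s = 0, D = 1e5, geom)   # 2*pi/Lx
#' @export
gamma_lm <- function(l, m, s, D, geometry) {
  stopifnot(inherits(geometry, "cleft_geometry"))
  if (any(s < 0)) stop("s must be >= 0", call. = FALSE)
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  if (any(s == 0 & l == 0 & m == 0)) {
    stop("gamma_lm is zero at s = 0, l = m = 0; use the analytic s -> 0 limit",
         call. = FALSE)
  }
  sqrt(s / D + (2 * pi * l / geometry$Lx)^2 + (2 * pi * m / geometry$Ly)^2)
}

#' Laplace transform of the exponential release flux
#'
#' The release of ligand through the source disk is modelled as the transient
#' flux u(t) = exp(-t/t0), whose Laplace transform is
#' \eqn{\hat u(s) = 1/(s + 1/t_0)}; at s = 0 this is t0. The amplitude of
#' u(t) is arbitrary (set to 1); all fluxes carry the same arbitrary
#' amplitude factor.
#'
#' @param s Laplace variable (1/ms), >= 0 (vectorised).
#' @param t0 Release decay constant (ms).
#' @return uhat(s) in ms.
#' @examples
#' uhat_exponential(0, t0 = 1)        # t0
#' uhat_exponential(1, t0 = 1)        # t0/2
#' @export
uhat_exponential <- function(s, t0) {
  if (t0 <= 0) stop("t0 must be > 0", call. = FALSE)
  if (any(s < 0)) stop("s must be >= 0", call. = FALSE)
  1 / (s + 1 / t0)
}

# Static pieces of the flux formula that depend only on geometry, tables and
# truncation -- precomputed once and closed over by jhat_evaluator(). The
# epsilon weights enter the flux formula as an explicit division (the stored
# tables carry 4*eps_l*eps_m/(Lx*Ly) times the bare integral).
jhat_static <- function(geometry, q, p) {
  if (q$lmax != p$lmax) stop("q and p tables must share lmax", call. = FALSE)
  lmax <- q$lmax
  idx <- 0:lmax
  eps <- c(0.5, rep(1, lmax))
  epsmat <- outer(eps, eps)
  k2 <- outer((2 * pi * idx / geometry$Lx)^2, (2 * pi * idx / geometry$Ly)^2, `+`)
  list(lmax = lmax,
       k2 = k2,
       pq_over_eps = p$values * q$values / epsmat,
       p2_over_eps = p$values * p$values / epsmat,
       epsmat = epsmat)
}

# Evaluate the two lattice sums of the constant-flux closure at real s > 0:
#   S1 = sum p q / (eps eps gamma sinh(gamma Lz))
#   S2 = sum p^2 cosh(gamma Lz) / (eps eps gamma sinh(gamma Lz))
# Hyperbolic ratios are formed from e^{-x} only, so no overflow occurs for
# arbitrarily large gamma*Lz.
jhat_sums <- function(s, D, Lz, st) {
  gam <- sqrt(s / D + st$k2)
  x <- gam * Lz
  em <- exp(-x)
  em2 <- em * em
  inv_sinh <- 2 * em / (1 - em2)
  coth <- (1 + em2) / (1 - em2)
  S1 <- sum(st$pq_over_eps * inv_sinh / gam)
  S2 <- sum(st$p2_over_eps * coth / gam)
  list(S1 = S1, S2 = S2, gamma = gam)
}

#' Build a fast evaluator of the Laplace-space flux
#'
#' Returns a function `f(s)` evaluating \eqn{\hat J(s) = \pi a^2 Q(s)} with
#' all s-independent work (coefficient-table products, lateral wavenumbers)
#' hoisted out. This is the workhorse behind [Qhat()], [Jhat()] and
#' [response_curve()].
#'
#' @param geometry A [cleft_geometry()].
#' @param params A [transport_params()].
#' @param q,p Coefficient tables for the source (radius R) and sink
#'   (radius a); built with [disk_cosine_coefficients()] if omitted.
#' @param config A [series_config()].
#' @param uhat Release transform: a function of s returning uhat(s).
#'   Defaults to the exponential model with the `t0` in `params`.
#' @return A function of a scalar s > 0 returning Jhat(s).
#' @export
jhat_evaluator <- function(geometry, params, q = NULL, p = NULL,
                           config = series_config(), uhat = NULL) {
  stopifnot(inherits(geometry, "cleft_geometry"),
            inherits(params, "transport_params"))
  if (is.null(q)) q <- disk_cosine_coefficients(geometry$R, geometry,
                                                config$lmax, config$quad_order)
  if (is.null(p)) p <- disk_cosine_coefficients(geometry$a, geometry,
                                                config$lmax, config$quad_order)
  if (is.null(uhat)) {
    t0 <- params$t0
    uhat <- function(s) uhat_exponential(s, t0)
  }
  st <- jhat_static(geometry, q, p)
  D <- params$D; Lz <- geometry$Lz; a <- geometry$a
  function(s) {
    if (s <= 0) stop("Jhat is evaluated at real s > 0", call. = FALSE)
    sums <- jhat_sums(s, D, Lz, st)
    if (sums$S2 <= 0) {
      stop("internal consistency failure: non-positive denominator in Q(s)",
           call. = FALSE)
    }
    pi * a^2 * uhat(s) * sums$S1 / sums$S2
  }
}

#' Laplace-space flux density on the sink disk
#'
#' The constant-flux closure replaces the exact absorbing condition on the
#' sink disk by a uniform unknown flux density Q(s), fixed by requiring the
#' disk-averaged Laplace concentration to vanish. The closed form is
#' \deqn{Q(s) = \hat u(s)\,
#'   \frac{\sum_{l,m} p_{lm}q_{lm}/[\epsilon_l\epsilon_m\gamma_{lm}\sinh(\gamma_{lm}L_z)]}
#'        {\sum_{l,m} p_{lm}^2\cosh(\gamma_{lm}L_z)/[\epsilon_l\epsilon_m\gamma_{lm}\sinh(\gamma_{lm}L_z)]}}
#' with both sums truncated at `config$lmax`. The diffusion constant cancels
#' between numerator and denominator (both inherit a factor 1/(D gamma) from
#' the series coefficients), so it does not appear explicitly.
#'
#' @inheritParams jhat_evaluator
#' @param s Laplace variable (1/ms), real and > 0.
#' @return Q(s), the uniform sink flux density in Laplace space.
#' @examples
#' geom <- cleft_geometry(); par <- transport_params()
#' cfg <- series_config(lmax = 20)
#' # small-s limit: pi*a^2*Q -> pi*R^2*uhat (ligand conservation)
#' pi * geom$a^2 * Qhat(1e-8, geom, par, config = cfg)
#' pi * geom$R^2 * uhat_exponential(1e-8, par$t0)
#' @export
Qhat <- function(s, geometry, params, q = NULL, p = NULL,
                 config = series_config(), uhat = NULL) {
  f <- jhat_evaluator(geometry, params, q, p, config, uhat)
  vapply(s, f, numeric(1)) / (pi * geometry$a^2)
}

#' Laplace-space total flux through the sink disk
#'
#' \eqn{\hat J(s) = \pi a^2 Q(s)}: the Laplace transform of the response
#' function J(t), the total ligand flux absorbed by the sink disk of one
#' unit cell.
#'
#' @inheritParams Qhat
#' @return Jhat(s) (amplitude x nm^2 x ms).
#' @export
Jhat <- function(s, geometry, params, q = NULL, p = NULL,
                 config = series_config(), uhat = NULL) {
  f <- jhat_evaluator(geometry, params, q, p, config, uhat)
  vapply(s, f, numeric(1))
}

#' Series coefficients of the Laplace concentration field
#'
#' Solves the two boundary-condition identities
#' \deqn{D\gamma_{lm}(\alpha_{lm}-\beta_{lm}) = \hat u(s)q_{lm}, \qquad
#'   D\gamma_{lm}(\alpha_{lm}e^{\gamma L_z}-\beta_{lm}e^{-\gamma L_z}) = Q(s)p_{lm}}
#' for every mode. The state stores, besides raw alpha and beta, the scaled
#' right-hand sides U = uhat*q/(D gamma) and P = Q*p/(D gamma) from which
#' z-profiles are reassembled in overflow-free exponential form.
#'
#' @inheritParams Qhat
#' @param s Laplace variable, scalar > 0.
#' @param Qvalue Optional precomputed Q(s); computed via [Qhat()] if omitted.
#' @return An object of class `laplace_state` with fields `s`, `gamma`,
#'   `alpha`, `beta`, `U`, `P`, `uhat_s`, `Q` and the geometry.
#' @export
solve_series_coefficients <- function(s, geometry, params, q = NULL, p = NULL,
                                      config = series_config(), uhat = NULL,
                                      Qvalue = NULL) {
  stopifnot(length(s) == 1, s > 0)
  if (is.null(q)) q <- disk_cosine_coefficients(geometry$R, geometry,
                                                config$lmax, config$quad_order)
  if (is.null(p)) p <- disk_cosine_coefficients(geometry$a, geometry,
                                                config$lmax, config$quad_order)
  if (is.null(uhat)) {
    t0 <- params$t0
    uhat <- function(ss) uhat_exponential(ss, t0)
  }
  if (is.null(Qvalue)) {
    Qvalue <- Qhat(s, geometry, params, q, p, config, uhat)
  }
  st <- jhat_static(geometry, q, p)
  gam <- sqrt(s / params$D + st$k2)
  us <- uhat(s)
  U <- us * q$values / (params$D * gam)
  P <- Qvalue * p$values / (params$D * gam)
  x <- gam * geometry$Lz
  em <- exp(-x)
  # alpha = (P - U e^{-gLz}) e^{-gLz} / (1 - e^{-2gLz});  beta = alpha - U
  alpha <- (P - U * em) * em / (1 - em * em)
  beta <- alpha - U
  structure(list(s = s, gamma = gam, alpha = alpha, beta = beta,
                 U = U, P = P, uhat_s = us, Q = Qvalue,
                 geometry = geometry, lmax = q$lmax),
            class = "laplace_state")
}

#' @export
print.laplace_state <- function(x, ...) {
  cat(sprintf("Laplace state at s = %g /ms (lmax = %d), Q(s) = %.6g\n",
              x$s, x$lmax, x$Q))
  invisible(x)
}

# z-profile of mode (l,m): alpha e^{g z} + beta e^{-g z}
#   = [P cosh(g z) - U cosh(g (Lz - z))] / sinh(g Lz)
# evaluated with negative exponents only (stable for arbitrarily large g Lz).
mode_profile <- function(state, z) {
  gam <- state$gamma
  Lz <- state$geometry$Lz
  e2 <- exp(-2 * gam * Lz)
  coshz_over_sinh <- (exp(gam * (z - Lz)) + exp(-gam * (z + Lz))) / (1 - e2)
  coshLzmz_over_sinh <- (exp(-gam * z) + exp(gam * (z - 2 * Lz))) / (1 - e2)
  state$P * coshz_over_sinh - state$U * coshLzmz_over_sinh
}

#' Laplace-space concentration field
#'
#' Evaluates the truncated cosine series for the Laplace transform of the
#' concentration, \eqn{\hat C(\mathbf r, s)}, at a point of the unit cell.
#'
#' @param x,y Lateral position (nm), measured from the common disk centre.
#' @param z Depth (nm), 0 at the release face, `Lz` at the sink face.
#' @param state A `laplace_state` from [solve_series_coefficients()].
#' @return Chat(x, y, z, s).
#' @export
concentration_hat <- function(x, y, z, state) {
  stopifnot(inherits(state, "laplace_state"))
  geom <- state$geometry
  if (z < 0 || z > geom$Lz) stop("z must lie in [0, Lz]", call. = FALSE)
  idx <- 0:state$lmax
  prof <- mode_profile(state, z)
  cx <- cos(2 * idx * pi * x / geom$Lx)
  cy <- cos(2 * idx * pi * y / geom$Ly)
  as.numeric(cx %*% prof %*% cy)
}

#' Disk-averaged Laplace concentration at a given depth
#'
#' Average of \eqn{\hat C} over a centred disk of the given radius at depth
#' z. Used for the self-consistency check of the constant-flux closure: the
#' average over the sink disk at z = Lz must vanish to series-truncation
#' accuracy.
#'
#' @param radius Averaging-disk radius (nm).
#' @param z Depth (nm).
#' @param state A `laplace_state`.
#' @return The disk-averaged transform value.
#' @export
disk_average_concentration_hat <- function(radius, z, state) {
  stopifnot(inherits(state, "laplace_state"))
  geom <- state$geometry
  if (z < 0 || z > geom$Lz) stop("z must lie in [0, Lz]", call. = FALSE)
  idx <- 0:state$lmax
  # disk average of cos*cos = (closed-form coefficient) * LxLy/(4 eps eps pi r^2)
  cf <- outer(idx, idx, function(ll, mm)
    closed_form_disk_coefficient(ll, mm, radius, geom))
  eps <- c(0.5, rep(1, state$lmax))
  avg <- cf * geom$Lx * geom$Ly / (4 * outer(eps, eps) * pi * radius^2)
  prof <- mode_profile(state, z)
  sum(prof * avg)
}

#' Disk-averaged normal derivative of the Laplace concentration
#'
#' Average of \eqn{D\,\partial\hat C/\partial z} over a centred disk at depth
#' z, obtained by term-wise differentiation of the series. At z = 0 over the
#' source disk this recovers uhat(s); at z = Lz over the sink disk it
#' recovers Q(s) (both to truncation accuracy) -- the two boundary
#' conditions of the model.
#'
#' @inheritParams disk_average_concentration_hat
#' @param D Diffusion constant (nm^2/ms).
#' @return The disk-averaged flux density D dChat/dz.
#' @export
disk_average_flux_hat <- function(radius, z, state, D) {
  stopifnot(inherits(state, "laplace_state"))
  geom <- state$geometry
  gam <- state$gamma
  Lz <- geom$Lz
  e2 <- exp(-2 * gam * Lz)
  # d/dz of mode_profile: [P g sinh(g z) + U g sinh(g (Lz - z))] / sinh(g Lz)
  sinhz_over_sinh <- (exp(gam * (z - Lz)) - exp(-gam * (z + Lz))) / (1 - e2)
  sinhLzmz_over_sinh <- (exp(-gam * z) - exp(gam * (z - 2 * Lz))) / (1 - e2)
  dprof <- gam * (state$P * sinhz_over_sinh + state$U * sinhLzmz_over_sinh)
  idx <- 0:state$lmax
  cf <- outer(idx, idx, function(ll, mm)
    closed_form_disk_coefficient(ll, mm, radius, geom))
  eps <- c(0.5, rep(1, state$lmax))
  avg <- cf * geom$Lx * geom$Ly / (4 * outer(eps, eps) * pi * radius^2)
  D * sum(dprof * avg)
}
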