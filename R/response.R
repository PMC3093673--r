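#' Default log-spaced time grid
#'
#' 200 logarithmically spaced times over 1e-3 to 1e2 ms, covering the rise,
#' peak and decay of the response for the whole physiological parameter
#' range explored here.
#'
#' @param n Number of points.
#' @param t_min,t_max Range (ms).
#' @return Strictly increasing time vector (ms).
#' @export
default_time_grid <- function(n = 200, t_min = 1e-3, t_max = 1e2) {
  if (t_min <= 0 || t_max <= t_min) stop("need 0 < t_min < t_max", call. = FALSE)
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Time-domain response function J(t)
#'
#' The central quantity of the model: the total flux of ligand absorbed by
#' the sink disk of one unit cell as a function of time, obtained by
#' Stehfest inversion of the Laplace-space flux \eqn{\hat J(s)}. For the
#' exponential release the curve rises from ~0, peaks, and decays to zero.
#'
#' @param times Strictly positive evaluation times (ms).
#' @param geometry A [cleft_geometry()].
#' @param params A [transport_params()].
#' @param config A [series_config()].
#' @param uhat Optional release transform function of s; defaults to the
#'   exponential model.
#' @return An object of class `response_curve`: a data.frame with columns
#'   `time_ms` and `flux`, carrying the inputs and run provenance as
#'   attributes.
#' @examples
#' rc <- response_curve(default_time_grid(50), cleft_geometry(),
#'                      transport_params(), series_config(lmax = 20))
#' head(rc)
#' @export
response_curve <- function(times, geometry = cleft_geometry(),
                           params = transport_params(),
                           config = series_config(), uhat = NULL) {
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all times must be finite and > 0", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  f <- jhat_evaluator(geometry, params, config = config, uhat = uhat)
  flux <- invert_laplace(f, times, N = config$stehfest_N)
  structure(data.frame(time_ms = times, flux = flux),
            geometry = geometry, params = params, config = config,
            method = "analytic",
            provenance = list(
              package = "cleftflux",
              version = as.character(utils::packageVersion("cleftflux")),
              created = format(Sys.time(), tz = "UTC", usetz = TRUE)),
            class = c("response_curve", "data.frame"))
}

#' @export
print.response_curve <- function(x, ...) {
  g <- attr(x, "geometry"); p <- attr(x, "params")
  ipk <- which.max(x$flux)
  cat(sprintf(
    "Response curve (%s): %d times in [%g, %g] ms; peak J = %.4g at t = %.4g ms\n",
    attr(x, "method") %||% "analytic", nrow(x), min(x$time_ms), max(x$time_ms),
    x$flux[ipk], x$time_ms[ipk]))
  if (!is.null(g)) cat(sprintf("  a = %g nm, R = %g nm, D = %g nm^2/ms, t0 = %g ms\n",
                               g$a, g$R, p$D, p$t0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total accumulated flux (ligand conservation)
#'
#' The time-integral of the response function equals the total ligand
#' released: \eqn{I = \hat J(0) = \pi R^2 \hat u(0)}, independent of the
#' sink radius a. For the exponential release this is \eqn{\pi R^2 t_0}.
#' Evaluated analytically, never by the series at s = 0.
#'
#' @param geometry A [cleft_geometry()].
#' @param params A [transport_params()].
#' @param uhat0 Optional value of uhat at s = 0 for a non-default release
#'   model; defaults to t0.
#' @return I in amplitude x nm^2 x ms.
#' @examples
#' total_accumulated_flux(cleft_geometry(R = 20), transport_params(t0 = 1))
#' # = 400 * pi
#' @export
total_accumulated_flux <- function(geometry, params, uhat0 = NULL) {
  stopifnot(inherits(geometry, "cleft_geometry"),
            inherits(params, "transport_params"))
  if (is.null(uhat0)) uhat0 <- params$t0
  pi * geometry$R^2 * uhat0
}

#' Numerical conservation integral of a response curve
#'
#' Integrates J(t) over an adaptively extended log-spaced grid: the grid is
#' lengthened until J falls below `tail_frac` of its peak, then a trapezoid
#' rule is applied and the remaining tail is estimated by exponential
#' extrapolation from the last two points. Used to verify ligand
#' conservation, \eqn{\int_0^\infty J\,dt = \pi R^2 t_0}.
#'
#' @inheritParams response_curve
#' @param n_per_decade Grid resolution of the integration grid.
#' @param t_start Start of the grid (ms); the missing (0, t_start] sliver is
#'   closed with a triangle through J(t_start) (J(0) = 0 by the initial
#'   condition).
#' @param tail_frac Stop once J < tail_frac * peak.
#' @param max_t Hard cap on grid extension (ms).
#' @return A list with `integral`, `expected` (pi R^2 uhat(0)),
#'   `rel_error`, and the grid actually used.
#' @export
conservation_integral <- function(geometry = cleft_geometry(),
                                  params = transport_params(),
                                  config = series_config(),
                                  uhat = NULL, n_per_decade = 80,
                                  t_start = 1e-3, tail_frac = 1e-6,
                                  max_t = 1e5) {
  f <- jhat_evaluator(geometry, params, config = config, uhat = uhat)
  t_hi <- 10 * params$t0
  repeat {
    times <- exp(seq(log(t_start), log(t_hi),
                     length.out = max(50, ceiling(n_per_decade *
                                                    log10(t_hi / t_start)))))
    J <- invert_laplace(f, times, N = config$stehfest_N)
    if (J[length(J)] < tail_frac * max(J) || t_hi >= max_t) break
    t_hi <- t_hi * 4
  }
  integral <- sum(diff(times) * (J[-1] + J[-length(J)]) / 2)
  # leading sliver: J(0) = 0, linear rise to the first grid point
  integral <- integral + 0.5 * t_start * J[1]
  # exponential tail beyond the last grid point
  n <- length(J)
  if (J[n] > 0 && J[n - 1] > J[n]) {
    rate <- log(J[n - 1] / J[n]) / (times[n] - times[n - 1])
    integral <- integral + J[n] / rate
  }
  expected <- if (is.null(uhat)) total_accumulated_flux(geometry, params) else
    pi * geometry$R^2 * uhat(config$small_s)
  list(integral = integral, expected = expected,
       rel_error = abs(integral - expected) / expected,
       times = times, flux = J)
}

#' Locate the peak of the response function
#'
#' Finds the maximum of J(t) by golden-section refinement around the best
#' point of a coarse log grid.
#'
#' @inheritParams response_curve
#' @param t_range Bracket for the search (ms).
#' @return List with `t_peak` (ms) and `J_peak`.
#' @export
response_peak <- function(geometry = cleft_geometry(),
                          params = transport_params(),
                          config = series_config(), uhat = NULL,
                          t_range = c(1e-3, 1e2)) {
  f <- jhat_evaluator(geometry, params, config = config, uhat = uhat)
  Jt <- function(tt) invert_laplace(f, tt, N = config$stehfest_N)
  grid <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = 80))
  Jg <- Jt(grid)
  i <- which.max(Jg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(Jt, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6 * grid[i])
  list(t_peak = opt$maximum, J_peak = opt$objective)
}

#' Verify the diffusion/release-time scaling identity
#'
#' Two parameter sets (D1, t01) and (D2, t02) with D1*t01 = D2*t02 produce
#' response functions related by J1(D2 t) = J2(D1 t). Returns the maximum
#' relative discrepancy of the two sides over a common time grid, scaled by
#' the curve maximum.
#'
#' @param geometry A [cleft_geometry()].
#' @param config A [series_config()].
#' @param D1,t01,D2,t02 The two (diffusivity, release-time) pairs; the
#'   products D1*t01 and D2*t02 must agree to machine precision.
#' @param times Dimensionless base grid; side 1 is evaluated at D2*times and
#'   side 2 at D1*times. Defaults to [default_time_grid()] divided by the
#'   geometric mean of D1 and D2 so both sides land in the usual ms range.
#' @return Maximum of |J1(D2 t) - J2(D1 t)| / max(J) over the grid.
#' @export
verify_scaling_law <- function(geometry = cleft_geometry(),
                               config = series_config(),
                               D1 = 1e5, t01 = 2, D2 = 2e5, t02 = 1,
                               times = NULL) {
  if (abs(D1 * t01 - D2 * t02) > 1e-9 * abs(D1 * t01)) {
    stop("scaling law requires D1*t01 == D2*t02", call. = FALSE)
  }
  if (is.null(times)) times <- default_time_grid() / sqrt(D1 * D2)
  f1 <- jhat_evaluator(geometry, transport_params(D = D1, t0 = t01),
                       config = config)
  f2 <- jhat_evaluator(geometry, transport_params(D = D2, t0 = t02),
                       config = config)
  J1 <- invert_laplace(f1, D2 * times, N = config$stehfest_N)
  J2 <- invert_laplace(f2, D1 * times, N = config$stehfest_N)
  max(abs(J1 - J2)) / max(abs(J1), abs(J2))
}

#' Write a response curve to CSV
#'
#' Two columns `time_ms, flux` with a header row, full double precision.
#'
#' @param curve A `response_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  df <- data.frame(time_ms = format(curve$time_ms, digits = 17, trim = TRUE),
                   flux = format(curve$flux, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write run metadata to JSON
#'
#' Records the geometry, transport parameters, series configuration, method
#' tag and (optionally) the conservation-check result of a run.
#'
#' @param curve A `response_curve`.
#' @param path Output file path.
#' @param extra Optional named list merged into the record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(curve, path, extra = NULL) {
  stopifnot(inherits(curve, "response_curve"))
  g <- attr(curve, "geometry"); p <- attr(curve, "params")
  cfg <- attr(curve, "config")
  rec <- list(method = attr(curve, "method") %||% "analytic",
              geometry = unclass(g), params = unclass(p),
              config = if (!is.null(cfg)) unclass(cfg),
              n_times = nrow(curve),
              provenance = attr(curve, "provenance"))
  if (!is.null(extra)) rec <- c(rec, extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
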