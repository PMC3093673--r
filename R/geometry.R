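#' Geometry of the periodic two-membrane cleft
#'
#' One unit cell of the laterally periodic cleft model: a release disk of
#' radius `R` centred on the pre-synaptic face (z = 0) and an absorbing sink
#' disk of radius `a` centred on the post-synaptic face (z = `Lz`). Both
#' disks sit at the lateral centre of the cell; lengths are in nanometres
#' throughout the package.
#'
#' @param Lx,Ly Lateral periodicities of the unit cell (nm).
#' @param Lz Cleft depth, the membrane-to-membrane distance (nm).
#' @param R Radius of the release (source) disk (nm).
#' @param a Radius of the absorbing (sink) disk (nm).
#'
#' @return An object of class `cleft_geometry`: a named list with fields
#'   `Lx`, `Ly`, `Lz`, `R`, `a`.
#'
#' @examples
#' geom <- cleft_geometry()          # neuromuscular-junction defaults
#' geom
#' cleft_geometry(a = 40)            # larger receptor patch
#' @export
cleft_geometry <- function(Lx = 500, Ly = 500, Lz = 50, R = 20, a = 10) {
  vals <- c(Lx = Lx, Ly = Ly, Lz = Lz, R = R, a = a)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all cleft_geometry dimensions must be finite and strictly positive",
         call. = FALSE)
  }
  if (2 * R > min(Lx, Ly)) {
    stop("release disk does not fit in the unit cell: 2*R must be <= min(Lx, Ly)",
         call. = FALSE)
  }
  if (2 * a > min(Lx, Ly)) {
    stop("sink disk does not fit in the unit cell: 2*a must be <= min(Lx, Ly)",
         call. = FALSE)
  }
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz, R = R, a = a),
            class = "cleft_geometry")
}

#' @export
print.cleft_geometry <- function(x, ...) {
  cat("Periodic cleft unit cell (nm):\n")
  cat(sprintf("  Lx = %g, Ly = %g, Lz = %g\n", x$Lx, x$Ly, x$Lz))
  cat(sprintf("  release disk R = %g, sink disk a = %g\n", x$R, x$a))
  invisible(x)
}

#' Transport parameters of the ligand
#'
#' Diffusion constant and release kinetics of the diffusing ligand, plus an
#' optional surface reactivity used only by the receptor-patch calculators
#' (see [binding_rate_constant()]). Units are nm and ms package-wide.
#'
#' @param D Diffusion constant (nm^2/ms).
#' @param t0 Decay constant of the exponential release flux u(t) = exp(-t/t0)
#'   (ms).
#' @param kappa Optional reactivity of a partially absorbing receptor disk
#'   (nm/ms); `Inf` means fully absorbing. Not used by the series solution,
#'   which treats the sink as perfectly absorbing.
#'
#' @return An object of class `transport_params`.
#' @examples
#' transport_params()                     # D = 1e5 nm^2/ms, t0 = 1 ms
#' transport_params(D = 4e4, t0 = 3)
#' @export
transport_params <- function(D = 1e5, t0 = 1, kappa = NULL) {
  if (!is.finite(D) || D <= 0) stop("D must be finite and > 0", call. = FALSE)
  if (!is.finite(t0) || t0 <= 0) stop("t0 must be finite and > 0", call. = FALSE)
  if (!is.null(kappa)) {
    if (is.na(kappa) || kappa < 0) stop("kappa must be >= 0 (Inf allowed)",
                                        call. = FALSE)
  }
  structure(list(D = D, t0 = t0, kappa = kappa), class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("Transport: D = %g nm^2/ms, t0 = %g ms", x$D, x$t0))
  if (!is.null(x$kappa)) cat(sprintf(", kappa = %g nm/ms", x$kappa))
  cat("\n")
  invisible(x)
}

#' Numerical configuration of the series solution
#'
#' Controls the truncation and quadrature of the cosine-series solution and
#' the Stehfest inversion.
#'
#' @param lmax Truncation order of the double cosine series; the sums over
#'   (l, m) run over 0..lmax in each index. Default 40.
#' @param quad_order Number of Gauss-Legendre nodes for the x-integration of
#'   the disk cosine coefficients. Default 64.
#' @param stehfest_N Even number of terms in the Stehfest inversion.
#'   Default 14.
#' @param small_s The small positive Laplace variable (1/ms) used when a
#'   quantity calls for the s -> 0 limit. Default 1e-8.
#' @param rel_tol Generic relative tolerance for internal self-checks.
#'   Default 1e-6.
#'
#' @return An object of class `series_config`.
#' @examples
#' series_config()
#' series_config(lmax = 80)   # doubled truncation, for convergence checks
#' @export
series_config <- function(lmax = 40, quad_order = 64, stehfest_N = 14,
                          small_s = 1e-8, rel_tol = 1e-6) {
  if (lmax < 0 || lmax != round(lmax)) stop("lmax must be a nonnegative integer",
                                            call. = FALSE)
  if (quad_order < 2 || quad_order != round(quad_order)) {
    stop("quad_order must be an integer >= 2", call. = FALSE)
  }
  if (stehfest_N %% 2 != 0 || stehfest_N < 2) {
    stop("stehfest_N must be a positive even integer", call. = FALSE)
  }
  if (small_s <= 0 || rel_tol <= 0) stop("small_s and rel_tol must be > 0",
                                         call. = FALSE)
  structure(list(lmax = as.integer(lmax), quad_order = as.integer(quad_order),
                 stehfest_N = as.integer(stehfest_N), small_s = small_s,
                 rel_tol = rel_tol),
            class = "series_config")
}

#' @export
print.series_config <- function(x, ...) {
  cat(sprintf("Series config: lmax = %d, quad_order = %d, stehfest_N = %d\n",
              x$lmax, x$quad_order, x$stehfest_N))
  invisible(x)
}
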