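#' Cosine-transform coefficients of a centred disk indicator
#'
#' Computes the 2-D cosine-series coefficients of the indicator function of a
#' disk of the given radius centred in the unit cell,
#' \deqn{c_{lm} = \frac{4\epsilon_l\epsilon_m}{L_x L_y}
#'   \iint_{\rho<\mathrm{radius}} \cos(2l\pi x/L_x)\cos(2m\pi y/L_y)\,dx\,dy,}
#' with \eqn{\epsilon_0 = 1/2} and \eqn{\epsilon_l = 1} for \eqn{l > 0}.
#' These are the source coefficients q_lm (radius = R) and sink coefficients
#' p_lm (radius = a) of the series solution.
#'
#' The y-integration is done analytically; the remaining x-integral over
#' \[0, radius\] (4-fold symmetry) is evaluated by Gauss-Legendre quadrature
#' with `quad_order` nodes.
#'
#' @param radius Disk radius (nm).
#' @param geometry A [cleft_geometry()].
#' @param lmax Truncation order; coefficients are returned for
#'   0 <= l, m <= lmax.
#' @param quad_order Number of Gauss-Legendre nodes over x.
#'
#' @return An object of class `coefficient_table`: a list with `values`
#'   (an (lmax+1) x (lmax+1) matrix, row l, column m, both 0-based in meaning),
#'   `lmax`, `radius`, and the geometry it was built for. The epsilon weights
#'   are folded into the stored values exactly as the defining integral above
#'   prescribes (they are divided back out where the flux formula requires
#'   the bare integrals).
#'
#' @seealso [closed_form_disk_coefficient()] for the independent Bessel
#'   closed form of the same integral.
#' @examples
#' geom <- cleft_geometry()
#' q <- disk_cosine_coefficients(geom$R, geom, lmax = 10)
#' q$values[1, 1] * geom$Lx * geom$Ly   # recovers the disk area pi*R^2
#' @export
disk_cosine_coefficients <- function(radius, geometry, lmax = 40,
                                     quad_order = 64) {
  stopifnot(inherits(geometry, "cleft_geometry"))
  if (!is.finite(radius) || radius <= 0) {
    stop("radius must be finite and > 0", call. = FALSE)
  }
  if (2 * radius > min(geometry$Lx, geometry$Ly)) {
    stop("disk does not fit in the unit cell", call. = FALSE)
  }
  if (lmax < 0 || lmax != round(lmax)) {
    stop("lmax must be a nonnegative integer", call. = FALSE)
  }
  if (quad_order < 2) stop("quad_order must be >= 2", call. = FALSE)

  Lx <- geometry$Lx; Ly <- geometry$Ly
  # substitute x = radius*sin(theta): removes the sqrt(radius^2 - x^2)
  # endpoint singularity, making the integrand analytic so Gauss-Legendre
  # converges exponentially
  gl <- pracma::gaussLegendre(quad_order, 0, pi / 2)
  x <- radius * sin(gl$x)
  w <- gl$w * radius * cos(gl$x)
  half_chord <- radius * cos(gl$x)  # y extent at abscissa x

  l <- 0:lmax; m <- 0:lmax
  # inner (analytic) y-integral over [0, half_chord]: rows = x nodes, cols = m
  inner <- outer(half_chord, m, function(h, mm) {
    ifelse(mm == 0, h, Ly / (2 * mm * pi) * sin(2 * mm * pi * h / Ly))
  })
  # cosine factor in x: rows = l, cols = x nodes
  cosx <- outer(l, x, function(ll, xx) cos(2 * ll * pi * xx / Lx))
  # quarter-disk integral; full disk is 4x by symmetry
  quarter <- cosx %*% (w * inner)
  eps <- c(0.5, rep(1, lmax))
  values <- (4 * outer(eps, eps)) / (Lx * Ly) * (4 * quarter)

  structure(list(values = values, lmax = as.integer(lmax), radius = radius,
                 Lx = Lx, Ly = Ly, quad_order = as.integer(quad_order)),
            class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat(sprintf(
    "Disk cosine-coefficient table: radius = %g nm, lmax = %d, c00 = %.6g\n",
    x$radius, x$lmax, x$values[1, 1]))
  invisible(x)
}

#' Closed-form disk cosine coefficient (Bessel oracle)
#'
#' Independent closed form of the integral computed by
#' [disk_cosine_coefficients()]. Writing the product of cosines as a sum of
#' plane waves and using
#' \eqn{\iint_{\rho<R} \cos(\mathbf{k}\cdot\mathbf{r})\,dA = 2\pi R J_1(kR)/k},
#' the coefficient is
#' \deqn{c_{lm} = \frac{8\pi\epsilon_l\epsilon_m R\,J_1(k_{lm}R)}{L_xL_y\,k_{lm}},
#'   \qquad k_{lm} = \sqrt{(2\pi l/L_x)^2 + (2\pi m/L_y)^2},}
#' and \eqn{\pi R^2/(L_xL_y)} at (l, m) = (0, 0). Used as the accuracy oracle
#' for the quadrature route.
#'
#' @param l,m Nonnegative integer mode indices (vectorised).
#' @param radius Disk radius (nm).
#' @param geometry A [cleft_geometry()].
#' @return The coefficient value(s).
#' @examples
#' geom <- cleft_geometry()
#' closed_form_disk_coefficient(0, 0, 20, geom)   # area fraction pi*20^2/500^2
#' @export
closed_form_disk_coefficient <- function(l, m, radius, geometry) {
  stopifnot(inherits(geometry, "cleft_geometry"))
  if (any(l < 0) || any(m < 0)) stop("l and m must be >= 0", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  k <- sqrt((2 * pi * l / geometry$Lx)^2 + (2 * pi * m / geometry$Ly)^2)
  eps_l <- ifelse(l == 0, 0.5, 1)
  eps_m <- ifelse(m == 0, 0.5, 1)
  out <- numeric(length(k))
  zero <- k == 0
  out[zero] <- pi * radius^2 / (geometry$Lx * geometry$Ly)
  kk <- k[!zero]
  out[!zero] <- 8 * pi * eps_l[!zero] * eps_m[!zero] * radius *
    besselJ(kk * radius, 1) / (geometry$Lx * geometry$Ly * kk)
  out
}

#' Full closed-form coefficient table
#'
#' Convenience wrapper evaluating [closed_form_disk_coefficient()] on the
#' whole (l, m) grid; returned in the same `coefficient_table` form so it can
#' be swapped against the quadrature table in tests.
#'
#' @inheritParams disk_cosine_coefficients
#' @return A `coefficient_table`.
#' @keywords internal
closed_form_coefficient_table <- function(radius, geometry, lmax = 40) {
  l <- 0:lmax
  values <- outer(l, l, function(ll, mm)
    closed_form_disk_coefficient(ll, mm, radius, geometry))
  structure(list(values = values, lmax = as.integer(lmax), radius = radius,
                 Lx = geometry$Lx, Ly = geometry$Ly, quad_order = NA_integer_),
            class = "coefficient_table")
}
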