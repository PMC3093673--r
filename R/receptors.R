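#' Receptor patch on the post-synaptic face
#'
#' Describes N_rec identical receptor disks of radius a0 and reactivity
#' kappa on one unit cell of area S = Lx*Ly, with coverage fraction
#' f_rec = N_rec * pi * a0^2 / S. Feeds the closed-form calculators that
#' translate receptor microphysics into the model's single-sink parameters.
#'
#' @param N_rec Number of receptors per unit cell (>= 1).
#' @param a0 Single-receptor disk radius (nm).
#' @param kappa Reactivity of one receptor disk (nm/ms); `Inf` = fully
#'   absorbing.
#' @param S Area of the post-synaptic face of one unit cell (nm^2).
#' @return An object of class `receptor_patch` with the derived `f_rec`.
#' @examples
#' receptor_patch(N_rec = 10, a0 = 2.5, kappa = Inf, S = 500^2)
#' @export
receptor_patch <- function(N_rec, a0, kappa = Inf, S) {
  if (N_rec < 1 || N_rec != round(N_rec)) stop("N_rec must be an integer >= 1",
                                               call. = FALSE)
  if (a0 <= 0) stop("a0 must be > 0", call. = FALSE)
  if (is.na(kappa) || kappa < 0) stop("kappa must be >= 0 (Inf allowed)",
                                      call. = FALSE)
  if (S <= 0) stop("S must be > 0", call. = FALSE)
  f_rec <- N_rec * pi * a0^2 / S
  if (f_rec >= 1) {
    stop("receptor coverage fraction f_rec must be < 1", call. = FALSE)
  }
  structure(list(N_rec = as.integer(N_rec), a0 = a0, kappa = kappa, S = S,
                 f_rec = f_rec),
            class = "receptor_patch")
}

#' @export
print.receptor_patch <- function(x, ...) {
  cat(sprintf(
    "Receptor patch: N_rec = %d, a0 = %g nm, kappa = %g nm/ms, f_rec = %.4g\n",
    x$N_rec, x$a0, x$kappa, x$f_rec))
  invisible(x)
}

#' Bimolecular rate constant of a partially absorbing disk
#'
#' Steady-state capture rate constant of a disk-shaped receptor of radius a
#' and reactivity kappa embedded in a reflecting plane:
#' \deqn{1/k = 1/(4Da) + 1/(\pi\kappa a^2).}
#' kappa -> Inf gives the classic absorbing-disk result k = 4Da; kappa = 0
#' gives k = 0 (a reflecting disk cannot bind). Matching k against a
#' measured ligand-receptor binding rate constant is the practical way to
#' parameterise a and kappa.
#'
#' @param D Diffusion constant (nm^2/ms).
#' @param a Disk radius (nm).
#' @param kappa Reactivity (nm/ms); `Inf` allowed.
#' @return k in nm^3/ms.
#' @examples
#' binding_rate_constant(1e5, 10, Inf)    # 4*D*a = 4e6
#' binding_rate_constant(1e5, 10, 1e3)
#' @export
binding_rate_constant <- function(D, a, kappa) {
  if (D <= 0 || a <= 0) stop("D and a must be > 0", call. = FALSE)
  if (is.na(kappa) || kappa < 0) stop("kappa must be >= 0 (Inf allowed)",
                                      call. = FALSE)
  if (kappa == 0) return(0)
  # kappa = Inf handled by the 1/(pi kappa a^2) -> 0 limit, not a branch
  1 / (1 / (4 * D * a) + 1 / (pi * kappa * a^2))
}

#' Equivalent single-sink radius for N_rec receptors
#'
#' Radius of the single absorbing disk whose capture rate 4Da matches that
#' of N_rec small absorbing disks of radius a0, in the dilute (small N_rec)
#' regime where k ~ 4 N_rec D a0: a = N_rec * a0. The growth of the
#' equivalent radius saturates at large N_rec, for which no closed form is
#' implemented; a warning is emitted when the linear rule approaches the
#' cell size.
#'
#' @param N_rec Number of receptors (>= 1).
#' @param a0 Single-receptor radius (nm).
#' @param L_min Optional smallest lateral cell dimension (nm) used for the
#'   validity warning.
#' @return Equivalent sink radius a = N_rec * a0 (nm).
#' @examples
#' equivalent_disk_radius(4, 2.5)   # 10 nm
#' @export
equivalent_disk_radius <- function(N_rec, a0, L_min = NULL) {
  if (N_rec < 1 || N_rec != round(N_rec)) stop("N_rec must be an integer >= 1",
                                               call. = FALSE)
  if (a0 <= 0) stop("a0 must be > 0", call. = FALSE)
  a <- N_rec * a0
  if (!is.null(L_min) && 2 * a > 0.5 * L_min) {
    warning(paste("equivalent radius approaches the unit-cell size;",
                  "the linear rule a = N_rec * a0 is a small-N_rec",
                  "approximation and saturates in this regime"), call. = FALSE)
  }
  a
}

#' Effective reactivity of a uniformly receptor-covered face
#'
#' Alternative homogenised description of N_rec receptors: the whole
#' post-synaptic face is treated as partially absorbing with reactivity
#' \deqn{K = N_{rec} k_0 / [S(1 - f_{rec})], \qquad
#'   1/k_0 = 1/(4Da_0) + 1/[\pi\kappa a_0^2(1 - f_{rec})].}
#'
#' @param patch A [receptor_patch()].
#' @param D Diffusion constant (nm^2/ms).
#' @return K in nm/ms.
#' @examples
#' K <- effective_reactivity(receptor_patch(10, 2.5, Inf, 500^2), D = 1e5)
#' @export
effective_reactivity <- function(patch, D) {
  stopifnot(inherits(patch, "receptor_patch"))
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  inv_k0 <- 1 / (4 * D * patch$a0)
  if (patch$kappa == 0) return(0)
  if (is.finite(patch$kappa)) {
    inv_k0 <- inv_k0 + 1 / (pi * patch$kappa * patch$a0^2 * (1 - patch$f_rec))
  }
  k0 <- 1 / inv_k0
  patch$N_rec * k0 / (patch$S * (1 - patch$f_rec))
}
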