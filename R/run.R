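#' Assemble a run configuration
#'
#' Bundles geometry, transport parameters, series configuration, the run
#' mode and output options into a single validated object, optionally
#' seeded from a YAML file (explicit arguments override file values).
#' Units are fixed package-wide as nm and ms; configs declaring any other
#' `units` are rejected rather than converted.
#'
#' @param geometry A [cleft_geometry()].
#' @param params A [transport_params()].
#' @param series A [series_config()].
#' @param mode One of `"analytic"`, `"fd"`, `"both"`, `"validate"`.
#' @param times Evaluation time grid (ms); default [default_time_grid()].
#' @param grid A [grid_spec()] for the FD modes; a moderate default is
#'   built from `times` if omitted.
#' @param output_dir Directory for CSV/JSON outputs.
#' @param yaml_file Optional YAML file with any of the scalar fields
#'   `Lx, Ly, Lz, R, a, D, t0, lmax, quad_order, stehfest_N, mode,
#'   t_min, t_max, n_times, output_dir`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = NULL, params = NULL, series = NULL,
                       mode = "analytic", times = NULL, grid = NULL,
                       output_dir = ".", yaml_file = NULL) {
  y <- list()
  if (!is.null(yaml_file)) {
    y <- yaml::read_yaml(yaml_file)
    if (!is.null(y$units) &&
        !identical(tolower(unlist(y$units)), c("nm", "ms")) &&
        !identical(tolower(paste(unlist(y$units), collapse = ",")), "nm,ms")) {
      stop("units are fixed as nm and ms; remove or fix the 'units' entry",
           call. = FALSE)
    }
  }
  pick <- function(nm, default) y[[nm]] %||% default
  if (is.null(geometry)) {
    geometry <- cleft_geometry(Lx = pick("Lx", 500), Ly = pick("Ly", 500),
                               Lz = pick("Lz", 50), R = pick("R", 20),
                               a = pick("a", 10))
  }
  if (is.null(params)) {
    params <- transport_params(D = pick("D", 1e5), t0 = pick("t0", 1))
  }
  if (is.null(series)) {
    series <- series_config(lmax = pick("lmax", 40),
                            quad_order = pick("quad_order", 64),
                            stehfest_N = pick("stehfest_N", 14))
  }
  mode <- match.arg(pick("mode", mode), c("analytic", "fd", "both", "validate"))
  if (is.null(times)) {
    times <- default_time_grid(n = pick("n_times", 200),
                               t_min = pick("t_min", 1e-3),
                               t_max = pick("t_max", 1e2))
  }
  output_dir <- pick("output_dir", output_dir)
  structure(list(geometry = geometry, params = params, series = series,
                 mode = mode, times = times, grid = grid,
                 output_dir = output_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: mode = %s, %d times, output_dir = %s\n",
              x$mode, length(x$times), x$output_dir))
  print(x$geometry); print(x$params); print(x$series)
  invisible(x)
}

default_fd_grid <- function(config) {
  t_end <- min(max(config$times), 10 * config$params$t0)
  grid_spec(64, 64, 16, t_end = t_end)
}

#' Execute a configured run
#'
#' Dispatches on the run mode:
#' \describe{
#'   \item{analytic}{writes `response_analytic.csv` and metadata JSON.}
#'   \item{fd}{writes `response_fd.csv` and metadata JSON.}
#'   \item{both}{both curves plus a comparison summary (max relative
#'     deviation over the common time range) in the metadata.}
#'   \item{validate}{runs the model's internal invariant checks (ligand
#'     conservation, scaling law, coefficient quadrature vs closed form,
#'     Stehfest transform pairs, constant-flux self-consistency, FD
#'     agreement) and writes a plain-text report.}
#' }
#' Partial outputs are removed if the run fails.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the produced file paths and (for
#'   `validate`) the per-check results; `ok` is `TRUE` when every check
#'   passed.
#' @export
run_cleft <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- tryCatch({
    res <- list(ok = TRUE, files = character(0))
    if (config$mode %in% c("analytic", "both")) {
      say("analytic series solution: %d times", length(config$times))
      rc <- response_curve(config$times, config$geometry, config$params,
                           config$series)
      f1 <- file.path(config$output_dir, "response_analytic.csv")
      f2 <- file.path(config$output_dir, "response_analytic.json")
      write_response_csv(rc, f1)
      cons <- conservation_integral(config$geometry, config$params,
                                    config$series)
      write_run_metadata(rc, f2, extra = list(
        conservation = list(integral = cons$integral,
                            expected = cons$expected,
                            rel_error = cons$rel_error)))
      written <- c(written, f1, f2)
      res$analytic <- rc
      res$conservation <- cons[c("integral", "expected", "rel_error")]
    }
    if (config$mode %in% c("fd", "both")) {
      grid <- config$grid %||% default_fd_grid(config)
      say("finite-difference solution: %d x %d x %d grid to t = %g ms",
          grid$nx, grid$ny, grid$nz, grid$t_end)
      rf <- fd_response_curve(config$geometry, config$params, grid)
      f1 <- file.path(config$output_dir, "response_fd.csv")
      f2 <- file.path(config$output_dir, "response_fd.json")
      write_response_csv(rf, f1)
      write_run_metadata(rf, f2,
                         extra = list(conservation = attr(rf, "conservation")))
      written <- c(written, f1, f2)
      res$fd <- rf
    }
    if (config$mode == "both") {
      cmp <- compare_curves(res$analytic, res$fd)
      res$comparison <- cmp
      say("max relative deviation analytic vs fd: %.3g", cmp$max_rel_dev)
      f <- file.path(config$output_dir, "comparison.json")
      jsonlite::write_json(cmp, f, auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    }
    if (config$mode == "validate") {
      res <- validate_model(config, quiet = quiet)
      f <- file.path(config$output_dir, "validation_report.txt")
      writeLines(res$report, f)
      written <- c(written, f)
    }
    res$files <- written
    res
  }, error = on_fail)
  invisible(out)
}

#' Compare two response curves on their common time range
#'
#' Interpolates the second curve onto the first curve's times (restricted to
#' the overlap) and reports the maximum absolute deviation relative to the
#' peak, plus the deviation at the peak.
#'
#' @param curve_a,curve_b `response_curve` objects.
#' @return List with `max_rel_dev`, `peak_rel_dev`, `t_peak_a`, `t_peak_b`.
#' @export
compare_curves <- function(curve_a, curve_b) {
  lo <- max(min(curve_a$time_ms), min(curve_b$time_ms))
  hi <- min(max(curve_a$time_ms), max(curve_b$time_ms))
  ta <- curve_a$time_ms[curve_a$time_ms >= lo & curve_a$time_ms <= hi]
  Ja <- curve_a$flux[curve_a$time_ms >= lo & curve_a$time_ms <= hi]
  Jb <- stats::approx(curve_b$time_ms, curve_b$flux, xout = ta)$y
  pk <- max(Ja)
  ipk_a <- which.max(curve_a$flux)
  ipk_b <- which.max(curve_b$flux)
  list(max_rel_dev = max(abs(Ja - Jb)) / pk,
       peak_rel_dev = abs(max(curve_a$flux) - max(curve_b$flux)) /
         max(curve_a$flux),
       t_peak_a = curve_a$time_ms[ipk_a],
       t_peak_b = curve_b$time_ms[ipk_b])
}

#' Run the model's invariant checks
#'
#' Self-contained validation battery: ligand conservation of the analytic
#' curve, independence of the accumulated flux from the sink radius, the
#' diffusion/release-time scaling identity, agreement of the quadrature
#' coefficients with the Bessel closed form, Stehfest inversion of known
#' transform pairs, the disk-averaged-concentration closure residual, and
#' agreement with the finite-difference solver on a moderate grid.
#'
#' @param config A [run_config()]; its geometry/params are the anchor case.
#' @param quiet Suppress per-check messages.
#' @return List with `ok`, `checks` (named list of value/threshold/pass) and
#'   a plain-text `report`.
#' @export
validate_model <- function(config = run_config(), quiet = FALSE) {
  g <- config$geometry; p <- config$params; cfg <- config$series
  checks <- list()
  add <- function(name, value, threshold) {
    checks[[name]] <<- list(value = value, threshold = threshold,
                            pass = is.finite(value) && value <= threshold)
  }

  cons <- conservation_integral(g, p, cfg)
  add("conservation_rel_error", cons$rel_error, 0.01)

  ja <- vapply(c(2.5, 40), function(a) {
    gg <- cleft_geometry(g$Lx, g$Ly, g$Lz, g$R, a)
    Jhat(cfg$small_s, gg, p, config = cfg)
  }, numeric(1))
  add("accumulated_flux_a_independence", abs(diff(ja)) / ja[1], 1e-3)

  add("scaling_law_discrepancy",
      verify_scaling_law(g, cfg, D1 = p$D, t01 = 2 * p$t0,
                         D2 = 2 * p$D, t02 = p$t0), 1e-4)

  qtab <- disk_cosine_coefficients(g$R, g, cfg$lmax, cfg$quad_order)
  ctab <- closed_form_coefficient_table(g$R, g, cfg$lmax)
  scale <- max(abs(ctab$values))
  add("coefficient_oracle_max_dev",
      max(abs(qtab$values - ctab$values) / pmax(abs(ctab$values),
                                                1e-2 * scale)), 1e-10)

  # the inversion is accurate to ~1e-5 relative while t <= t0; deeper into
  # the exponential tail the method error of any fixed-N Stehfest rule grows
  ts <- p$t0 * c(0.005, 0.05, 0.5, 1)
  add("stehfest_exponential_error",
      max(abs(invert_laplace(function(s) 1 / (s + 1 / p$t0), ts,
                             cfg$stehfest_N) - exp(-ts / p$t0)) /
            exp(-ts / p$t0)), 1e-5)

  st <- solve_series_coefficients(1, g, p, config = cfg)
  c_sink <- disk_average_concentration_hat(g$a, g$Lz, st)
  c_src <- disk_average_concentration_hat(g$a, 0, st)
  add("constant_flux_closure_residual", abs(c_sink / c_src), 1e-6)

  grid <- config$grid %||% grid_spec(64, 64, 16,
                                     t_end = min(2, 2 * p$t0))
  rf <- suppressWarnings(fd_response_curve(g, p, grid))
  ra <- response_curve(rf$time_ms[rf$time_ms > 0], g, p, cfg)
  cmp <- compare_curves(ra, rf)
  add("fd_peak_rel_dev", cmp$peak_rel_dev, 0.10)
  add("fd_balance_error", attr(rf, "conservation")$balance_error, 1e-3)

  ok <- all(vapply(checks, `[[`, logical(1), "pass"))
  report <- c("cleftflux validation report",
              sprintf("geometry: Lx=%g Ly=%g Lz=%g R=%g a=%g (nm)",
                      g$Lx, g$Ly, g$Lz, g$R, g$a),
              sprintf("params:   D=%g nm^2/ms, t0=%g ms", p$D, p$t0),
              "",
              vapply(names(checks), function(nm) {
                ch <- checks[[nm]]
                sprintf("%-34s %-4s value=%.3e  threshold=%.0e",
                        nm, if (ch$pass) "PASS" else "FAIL",
                        ch$value, ch$threshold)
              }, character(1)),
              "",
              if (ok) "all checks passed" else "SOME CHECKS FAILED")
  if (!quiet) message(paste(report, collapse = "\n"))
  list(ok = ok, checks = checks, report = report)
}
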