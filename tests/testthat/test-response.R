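test_that("total accumulated flux is pi R^2 t0, independent of a", {
  expect_equal(total_accumulated_flux(nmj_geometry(), nmj_params()), 400 * pi)
  expect_equal(total_accumulated_flux(nmj_geometry(a = 2.5), nmj_params()),
               total_accumulated_flux(nmj_geometry(a = 40), nmj_params()))
  expect_equal(total_accumulated_flux(nmj_geometry(), nmj_params(t0 = 2)),
               2 * total_accumulated_flux(nmj_geometry(), nmj_params(t0 = 1)))
})

test_that("the time integral of J(t) conserves the released ligand", {
  for (cb in list(c(a = 10, D = 1e5, t0 = 1),
                  c(a = 2.5, D = 4e4, t0 = 3),
                  c(a = 40, D = 4e5, t0 = 10))) {
    cons <- conservation_integral(nmj_geometry(cb["a"]),
                                  nmj_params(cb["D"], cb["t0"]))
    expect_lt(cons$rel_error, 0.01)
  }
})

test_that("the response rises from zero, peaks once and decays", {
  rc <- response_curve(default_time_grid(120), nmj_geometry(), nmj_params())
  expect_true(all(is.finite(rc$flux)))
  ipk <- which.max(rc$flux)
  expect_gt(ipk, 5)
  expect_lt(ipk, nrow(rc) - 5)
  # before any ligand has crossed the cleft the flux is zero to within the
  # inversion noise floor (|J| ~ 1e-5 of the peak)
  early <- response_curve(1e-4, nmj_geometry(), nmj_params())
  expect_lt(abs(early$flux), 1e-5 * rc$flux[ipk])
  # late flux decays essentially to zero
  expect_lt(abs(rc$flux[nrow(rc)]), 1e-3 * rc$flux[ipk])
  # decay is monotone wherever the flux is resolved above the noise floor
  tail_part <- rc$flux[(ipk + 1):nrow(rc)]
  resolved <- tail_part > 1e-4 * rc$flux[ipk]
  expect_true(all(diff(tail_part[resolved]) <= 0))
})

test_that("peak height grows and peak time shrinks with the sink radius", {
  pks <- lapply(c(2.5, 5, 10, 20, 40), function(a)
    response_peak(nmj_geometry(a), nmj_params(), series_config(lmax = 40)))
  heights <- vapply(pks, `[[`, numeric(1), "J_peak")
  times <- vapply(pks, `[[`, numeric(1), "t_peak")
  expect_true(all(diff(heights) > 0))
  expect_true(all(diff(times) < 0))
})

test_that("slower release shifts and broadens the t0-scaled response", {
  stats <- lapply(c(1, 3, 10), function(t0) {
    g <- nmj_geometry(); p <- nmj_params(D = 2e5, t0 = t0)
    pk <- response_peak(g, p)
    f <- jhat_evaluator(g, p)
    # time to decay to half the peak, a width proxy for J(t)/t0
    th <- stats::uniroot(function(tt)
      invert_laplace(f, tt) - pk$J_peak / 2,
      lower = pk$t_peak, upper = 400)$root
    list(t_peak = pk$t_peak, t_half = th, J_scaled = pk$J_peak / t0)
  })
  expect_true(all(diff(vapply(stats, `[[`, numeric(1), "t_peak")) > 0))
  expect_true(all(diff(vapply(stats, `[[`, numeric(1), "t_half")) > 0))
  # scaling by t0 fixes the released amount, so the scaled peak drops
  expect_true(all(diff(vapply(stats, `[[`, numeric(1), "J_scaled")) < 0))
})

test_that("the D-t0 scaling identity holds and is enforced", {
  expect_lt(verify_scaling_law(nmj_geometry(), series_config(lmax = 40),
                               D1 = 1e5, t01 = 2, D2 = 2e5, t02 = 1), 1e-4)
  expect_identical(verify_scaling_law(nmj_geometry(), series_config(lmax = 20),
                                      D1 = 1e5, t01 = 1, D2 = 1e5, t02 = 1), 0)
  expect_error(verify_scaling_law(nmj_geometry(), series_config(lmax = 20),
                                  D1 = 1e5, t01 = 1, D2 = 2e5, t02 = 1),
               "D1\\*t01")
})

test_that("response curves serialize to CSV and JSON round-trippably", {
  rc <- response_curve(default_time_grid(20), nmj_geometry(), nmj_params(),
                       series_config(lmax = 10))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_response_csv(rc, csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("time_ms", "flux"))
  expect_equal(back$flux, rc$flux, tolerance = 1e-15)
  write_run_metadata(rc, js, extra = list(note = "unit-test"))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$geometry$R, 20)
  expect_identical(meta$method, "analytic")
  unlink(c(csv, js))
})

test_that("non-positive or unsorted times are rejected", {
  expect_error(response_curve(c(0, 1), nmj_geometry(), nmj_params()), "> 0")
  expect_error(response_curve(c(2, 1), nmj_geometry(), nmj_params()),
               "increasing")
})
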