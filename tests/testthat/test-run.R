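test_that("run_config reads YAML, applies defaults and rejects foreign units", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("a: 5", "t0: 3", "mode: analytic", "n_times: 25"), yml)
  cfg <- run_config(yaml_file = yml)
  expect_equal(cfg$geometry$a, 5)
  expect_equal(cfg$params$t0, 3)
  expect_length(cfg$times, 25)
  # defaults fill the rest: the standard parameter set
  expect_equal(cfg$geometry$Lx, 500)
  expect_equal(cfg$series$lmax, 40)
  writeLines(c("a: 5", "units: [um, s]"), yml)
  expect_error(run_config(yaml_file = yml), "units")
  unlink(yml)
})

test_that("analytic runs write deterministic CSV plus metadata", {
  out1 <- tempfile(); out2 <- tempfile()
  cfg <- run_config(series = series_config(lmax = 20),
                    times = default_time_grid(30),
                    output_dir = out1)
  res <- run_cleft(cfg, quiet = TRUE)
  expect_true(file.exists(file.path(out1, "response_analytic.csv")))
  expect_true(file.exists(file.path(out1, "response_analytic.json")))
  expect_lt(res$conservation$rel_error, 0.01)
  cfg2 <- run_config(series = series_config(lmax = 20),
                     times = default_time_grid(30),
                     output_dir = out2)
  run_cleft(cfg2, quiet = TRUE)
  # the method has no randomness: identical config, byte-identical CSV
  expect_identical(readLines(file.path(out1, "response_analytic.csv")),
                   readLines(file.path(out2, "response_analytic.csv")))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("mode 'both' adds the FD curve and a comparison summary", {
  out <- tempfile()
  cfg <- run_config(times = default_time_grid(40, 1e-2, 2),
                    grid = grid_spec(32, 32, 8, t_end = 2),
                    mode = "both", output_dir = out)
  res <- suppressWarnings(run_cleft(cfg, quiet = TRUE))
  expect_true(file.exists(file.path(out, "response_fd.csv")))
  expect_true(file.exists(file.path(out, "comparison.json")))
  expect_lt(res$comparison$max_rel_dev, 0.15)
  unlink(out, recursive = TRUE)
})

test_that("validate mode passes all internal checks on the defaults", {
  out <- tempfile()
  cfg <- run_config(mode = "validate", output_dir = out)
  res <- suppressWarnings(run_cleft(cfg, quiet = TRUE))
  expect_true(res$ok)
  expect_true(all(vapply(res$checks, `[[`, logical(1), "pass")))
  expect_true(file.exists(file.path(out, "validation_report.txt")))
  unlink(out, recursive = TRUE)
})

test_that("invalid parameter combinations name the violated invariant", {
  expect_error(run_config(geometry = cleft_geometry(a = -2)), "positive")
  yml <- tempfile(fileext = ".yaml")
  writeLines("R: 400", yml)
  expect_error(run_config(yaml_file = yml), "does not fit")
  unlink(yml)
})
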