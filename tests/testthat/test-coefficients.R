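test_that("DC coefficient is the disk area fraction", {
  geom <- nmj_geometry()
  q <- disk_cosine_coefficients(20, geom, lmax = 5)
  expect_equal(q$values[1, 1], pi * 20^2 / (500 * 500), tolerance = 1e-12)
  expect_equal(q$values[1, 1] * geom$Lx * geom$Ly, pi * 20^2,
               tolerance = 1e-12)
})

test_that("closed form agrees with brute-force 2-D quadrature", {
  geom <- nmj_geometry()
  for (lm in list(c(0, 0), c(1, 0), c(1, 1), c(3, 2), c(7, 5))) {
    bf <- brute_force_disk_coefficient(lm[1], lm[2], 20, geom)
    cf <- closed_form_disk_coefficient(lm[1], lm[2], 20, geom)
    expect_equal(cf, bf, tolerance = 1e-10)
  }
  # explicit value at (1,0): 8 pi eps1 eps0 R J1(kR) / (Lx Ly k), k = 2pi/500
  k <- 2 * pi / 500
  expect_equal(closed_form_disk_coefficient(1, 0, 20, geom),
               8 * pi * 1 * 0.5 * 20 * besselJ(k * 20, 1) / (500 * 500 * k),
               tolerance = 1e-14)
})

test_that("quadrature coefficients match the Bessel closed form", {
  geom <- nmj_geometry()
  for (radius in c(10, 20)) {
    q <- disk_cosine_coefficients(radius, geom, lmax = 40, quad_order = 64)
    cl <- outer(0:40, 0:40, function(l, m)
      closed_form_disk_coefficient(l, m, radius, geom))
    scale <- max(abs(cl))
    big <- abs(cl) > 1e-2 * scale
    expect_lt(max(abs(q$values - cl)[big] / abs(cl)[big]), 1e-10)
    # near Bessel zeros the comparison is absolute
    expect_lt(max(abs(q$values - cl)[!big]), 1e-12 * scale * 100)
  }
})

test_that("coefficients vanish as the disk shrinks and decay with mode order", {
  geom <- nmj_geometry()
  tiny <- disk_cosine_coefficients(1e-6, geom, lmax = 10)
  expect_lt(max(abs(tiny$values)), 1e-11)
  q <- disk_cosine_coefficients(20, geom, lmax = 40)
  # asymptotic Bessel decay: high-order block much smaller than low-order
  expect_lt(max(abs(q$values[31:41, 31:41])),
            0.05 * max(abs(q$values[1:5, 1:5])))
  expect_true(all(is.finite(q$values)))
})

test_that("coefficient tables obey the similarity scaling", {
  g1 <- cleft_geometry(500, 500, 50, 20, 10)
  g2 <- cleft_geometry(1000, 1000, 50, 40, 20)
  for (lm in list(c(0, 0), c(1, 0), c(2, 3))) {
    c1 <- closed_form_disk_coefficient(lm[1], lm[2], 20, g1)
    c2 <- closed_form_disk_coefficient(lm[1], lm[2], 40, g2)
    # (Lx Ly / radius^2) c_lm invariant when k_lm * radius is held fixed
    expect_equal(500 * 500 / 20^2 * c1, 1000 * 1000 / 40^2 * c2,
                 tolerance = 1e-12)
  }
})

test_that("geometry and argument validation errors are raised", {
  geom <- nmj_geometry()
  expect_error(disk_cosine_coefficients(300, geom), "does not fit")
  expect_error(disk_cosine_coefficients(20, geom, lmax = -1), "lmax")
  expect_error(cleft_geometry(R = 300), "does not fit")
  expect_error(cleft_geometry(Lz = -1), "positive")
  expect_error(closed_form_disk_coefficient(-1, 0, 20, geom), ">= 0")
})
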