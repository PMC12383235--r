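test_that("worked conductance-to-diameter conversions match the published values", {
  m <- pore_model(l_nm = 5.4, rho_ohm_cm = 80)
  d <- hille_diameter(c(135, 320, 540), m)
  # printed values are 1.0, 1.4 and 2.0 nm
  expect_lt(abs(d[2] - 1.4), 0.1)
  expect_lt(abs(d[3] - 2.0), 0.1)
  expect_lt(abs(d[1] - 1.0), 0.1)
  # closed-form values to higher precision
  expect_equal(d, c(0.9174056, 1.4608580, 1.9529141), tolerance = 1e-6)
})

test_that("zero pore length reduces to the pure access-resistance limit d = rho*g", {
  m0 <- pore_model(l_nm = 0, rho_ohm_cm = 80)
  expect_identical(hille_diameter(320, m0), 80 * 320 * 1e-5)
  expect_equal(hille_conductance(0.256, m0), 320, tolerance = 1e-12)
})

test_that("diameter and conductance are exact algebraic inverses over the working box", {
  for (l in c(0, 2.7, 5.4, 20)) for (rho in c(10, 80, 200)) {
    m <- pore_model(l, rho)
    g <- c(10, 33, 135, 320, 540, 1000, 2000)
    expect_equal(hille_conductance(hille_diameter(g, m), m), g,
                 tolerance = 1e-9)
  }
})

test_that("closed-form root agrees with a numeric root-finder on the pore equation", {
  for (l in c(0.5, 5.4, 20)) for (rho in c(10, 80, 200)) {
    m <- pore_model(l, rho)
    for (g in c(10, 135, 320, 540, 2000)) {
      d_closed <- hille_diameter(g, m)
      # resistance balance in SI: 1/g = rho (4 l / (pi d^2) + 1 / d)
      fun <- function(d_nm) {
        1 / (g * 1e-12) -
          (rho * 1e-2) * (4 * l * 1e-9 / (pi * (d_nm * 1e-9)^2) +
                            1 / (d_nm * 1e-9))
      }
      d_num <- stats::uniroot(fun, c(1e-4, 1e3), tol = 1e-13)$root
      expect_equal(d_closed, d_num, tolerance = 1e-9)
    }
  }
})

test_that("diameter is monotone increasing in g, l and rho at fixed others", {
  # at fixed conductance, a longer or more resistive pore must be wider
  g <- seq(10, 2000, length.out = 40)
  expect_true(all(diff(hille_diameter(g, pore_model(5.4, 80))) > 0))
  ls <- seq(0, 20, length.out = 30)
  d_l <- vapply(ls, function(l) hille_diameter(320, pore_model(l, 80)),
                numeric(1))
  expect_true(all(diff(d_l) > 0))
  rhos <- seq(10, 200, length.out = 30)
  d_r <- vapply(rhos, function(r) hille_diameter(320, pore_model(5.4, r)),
                numeric(1))
  expect_true(all(diff(d_r) > 0))
  # and conductance falls as the pore lengthens at fixed diameter
  g_l <- vapply(ls, function(l) hille_conductance(1.4, pore_model(l, 80)),
                numeric(1))
  expect_true(all(diff(g_l) < 0))
})

test_that("working units (pS, nm, ohm cm) agree with an all-SI evaluation", {
  m <- pore_model(5.4, 80)
  for (g in c(15, 320, 1800)) {
    a_m <- (80 * 1e-2) * (g * 1e-12)            # rho*g in metres
    l_m <- 5.4e-9
    d_si <- a_m / 2 + sqrt(a_m^2 / 4 + 4 * a_m * l_m / pi)
    expect_equal(hille_diameter(g, m), d_si * 1e9, tolerance = 1e-12)
  }
})

test_that("non-positive inputs are rejected", {
  expect_error(hille_diameter(0), "positive")
  expect_error(hille_diameter(-5), "positive")
  expect_error(hille_conductance(0), "positive")
})
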