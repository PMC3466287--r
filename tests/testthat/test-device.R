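test_that("ionic strength and Debye length follow the electrolyte theory", {
  nacl <- data.frame(conc_mol_m3 = c(1, 1), z = c(1, -1))
  expect_equal(ionic_strength(nacl), 1)
  mgcl2 <- data.frame(conc_mol_m3 = c(1, 2), z = c(2, -1))
  expect_equal(ionic_strength(mgcl2), 3)
  expect_warning(I0 <- ionic_strength(data.frame(conc_mol_m3 = numeric(),
                                                 z = numeric())),
                 "undefined")
  expect_equal(I0, 0)

  # closed-form values with CODATA constants
  expect_equal(debye_length(1, eps_sol = 78, T_K = 298.15), 9.59,
               tolerance = 1e-3)
  expect_equal(debye_length(100, eps_sol = 78, T_K = 298.15), 0.959,
               tolerance = 1e-3)
  expect_equal(debye_length(nacl), debye_length(1))
  # scaling law: quadrupling I halves lambda_D
  expect_equal(debye_length(4) * 2, debye_length(1) * 1, tolerance = 1e-12)
  expect_error(debye_length(0), class = "nanofet_domain_error")
})

test_that("Thomas-Fermi length and carrier density invert each other", {
  lam <- tf_length(1.11e24, eps_NW = 12.0, m_star = 0.37)
  expect_equal(lam, 2.04, tolerance = 0.01)  # Table-default consistency

  # exact algebraic round trip
  set.seed(21)
  p <- 10^runif(20, 22, 27)
  expect_equal(carrier_density(tf_length(p), 12.0, 0.37), p,
               tolerance = 1e-9)

  # lambda_TF decreases with density, scales as p^(-1/6)
  expect_true(all(diff(tf_length(sort(p))) < 0))
  expect_equal(tf_length(1e24) / tf_length(64e24), 2, tolerance = 1e-9)

  expect_error(tf_length(-1), class = "nanofet_domain_error")
  expect_error(carrier_density(0), class = "nanofet_domain_error")
})

test_that("base conductance is the Drude wire value", {
  p <- device_params()
  g0 <- base_conductance(p)
  e <- physical_constants()$e
  expect_equal(g0, e * 1.11e24 * 1e-2 * pi * (10e-9)^2 / 2000e-9,
               tolerance = 1e-12)
  expect_equal(g0, 2.79e-7, tolerance = 2e-3)
  p2 <- device_params(L_nm = 4000)
  expect_equal(base_conductance(p2) * 2, g0)
  expect_gt(g0, 0)
})

test_that("screening factor is a bounded decreasing attenuation", {
  for (ld in c(0.5, 2, 10)) {
    p <- device_params(lambda_D_nm = ld)
    l <- seq(0, 30, by = 0.1)
    g <- screening_factor(l, p)
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(diff(g) < 0))
    expect_equal(screening_factor(0, p), 1)
    expect_lt(screening_factor(60 * ld, p), 1e-20)
  }
  # exponential-core decay bound
  p2 <- device_params(lambda_D_nm = 2)
  expect_lte(screening_factor(10, p2) / screening_factor(0, p2),
             exp(-5) + 0.01)
  expect_error(screening_factor(-1, device_params()),
               class = "nanofet_domain_error")
})

test_that("response factors reduce to the bare-wire closed form", {
  f <- poisson_factors(device_params())
  expect_gt(f$wire, 0)
  expect_gt(f$electrolyte, 0)
  expect_lt(f$electrolyte, 1)

  # with no oxide, the response at the wire surface must equal the
  # classic screening-model factor, written out independently here
  p <- device_params(t_ox_nm = 0, lambda_TF_nm = 1.7, lambda_D_nm = 3.1)
  x <- p$R_nm / p$lambda_TF_nm
  y <- p$R_nm / p$lambda_D_nm
  gamma0 <- 1 / (1 + (p$eps_sol * p$lambda_TF_nm) /
                   (p$eps_NW * p$lambda_D_nm) *
                   (besselI(x, 0) / besselI(x, 1)) *
                   (besselK(y, 1) / besselK(y, 0)))
  ff <- poisson_factors(p)
  expect_equal(screening_factor(0, p) * ff$wire * ff$electrolyte, gamma0,
               tolerance = 1e-12)
})

test_that("sensitivity is linear, signed, and dimensionally consistent", {
  params <- device_params()
  near <- function(q) {
    distance_profile(make_point_charges(
      data.frame(x_nm = 0, y_nm = 0, z_nm = 0, charge = q)),
      t_linker_nm = 1, t_ox_nm = 2)
  }
  zero <- nw_sensitivity(near(0), params)
  expect_equal(zero$sensitivity, 0)

  neg <- nw_sensitivity(near(-1), params)
  pos <- nw_sensitivity(near(+1), params)
  expect_gt(neg$sensitivity, 0)            # p-type accumulation
  expect_equal(pos$sensitivity, -neg$sensitivity)
  ntype <- nw_sensitivity(near(-1), device_params(doping = "n"))
  expect_equal(ntype$sensitivity, -neg$sensitivity)

  # conductances
  expect_equal(neg$dG_S, neg$sensitivity * neg$G0_S)
  expect_equal(sum(neg$sites$contribution), neg$sensitivity)

  # superposition: the union of two site sets responds like the sum
  set.seed(22)
  mk <- function(n) data.frame(x_nm = rnorm(n), y_nm = rnorm(n),
                               z_nm = runif(n, 0, 6),
                               charge = runif(n, -1, 1))
  a <- mk(5); b <- mk(7)
  zmin <- min(c(a$z_nm, b$z_nm))
  a$z_nm[which.min(a$z_nm)] <- zmin  # shared offset reference
  prof_u <- distance_profile(make_point_charges(rbind(a, b)), 1, 2)
  sep <- function(d) {
    pr <- make_point_charges(d)
    pr$dz_nm <- pr$z_nm - zmin
    pr$l_nm <- pr$dz_nm + 3
    class(pr) <- c("distance_profile", class(pr))
    nw_sensitivity(pr, params)$sensitivity
  }
  s_union <- nw_sensitivity(prof_u, params)$sensitivity
  expect_equal(s_union, sep(a) + sep(b), tolerance = 1e-12)

  # antisymmetric dipole at equal height cancels exactly
  dipole <- distance_profile(make_point_charges(
    data.frame(x_nm = c(-1, 1), y_nm = 0, z_nm = 0, charge = c(1, -1))), 1, 2)
  expect_identical(nw_sensitivity(dipole, params)$sensitivity, 0)

  # profile required
  expect_error(nw_sensitivity(make_point_charges(
    data.frame(x_nm = 0, y_nm = 0, z_nm = 0, charge = 1)), params),
    class = "nanofet_input_error")
})

test_that("screening trends: weaker electrolyte screening, larger signal", {
  prof <- distance_profile(make_point_charges(
    data.frame(x_nm = 0, y_nm = 0, z_nm = c(0, 1, 2.5),
               charge = c(-1, -0.5, -1))), 1, 2)
  lds <- c(0.5, 1, 2, 5, 10)
  s <- vapply(lds, function(ld) {
    nw_sensitivity(prof, device_params(lambda_D_nm = ld))$sensitivity
  }, 0)
  expect_true(all(diff(abs(s)) > 0))

  # raising every charge by a constant (thicker linker) weakens the signal
  tl <- c(0.5, 1, 2, 4, 8)
  s2 <- vapply(tl, function(t) {
    nw_sensitivity(prof, device_params(t_linker_nm = t))$sensitivity
  }, 0)
  expect_true(all(diff(abs(s2)) < 0))
})
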