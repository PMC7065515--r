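test_that("Fick flux is zero for a uniform profile", {
  pr <- porewater_profile(c(0, 10, 20, 30), rep(25, 4), 0.7, 0.01)
  expect_equal(fick_flux(pr)$value, 0)
})

test_that("Fick flux on an exactly linear profile matches phi*Ds*g", {
  phi <- 0.65; ds <- 0.012; g <- 0.107  # uM per m
  depths <- seq(0, 45, length.out = 12)
  pr <- porewater_profile(depths, 20 + g * depths, phi, ds)
  fl <- fick_flux(pr, basal_points = 4)
  expect_equal(fl$gradient, g, tolerance = 1e-12)
  # two-point hand slope over the basal window gives the same line
  expect_equal(fl$value, phi * ds * g, tolerance = 1e-12)
  expect_identical(fl$fit_points, 4)
})

test_that("a profile built to carry 0.010 mmol/m2/yr yields that flux", {
  phi <- 0.7; ds <- 0.015
  g <- 0.010 / (phi * ds)  # invert F = phi*Ds*g
  pr <- make_porewater_profile(seed = 7, n_points = 15, basal_gradient = g,
                               surface_conc = 21, noise_sd = 0,
                               porosity = phi, diffusivity = ds)
  expect_equal(fick_flux(pr)$value, 0.010, tolerance = 1e-12)
})

test_that("flux estimation input is validated", {
  pr <- porewater_profile(c(0, 10), c(1, 2), 0.5, 0.01)
  expect_error(fick_flux(pr, basal_points = 1), "at least 2")
  expect_error(fick_flux(pr, basal_points = 5), "exceeds")
  expect_error(porewater_profile(c(0, 0), c(1, 2), 0.5, 0.01),
               "strictly increasing")
  expect_error(porewater_profile(c(0, 1), c(1, 2), 1.2, 0.01))
})

test_that("no-reaction endpoint reproduces the hand unit conversion", {
  # I = 5e-6 mol/yr at Q = 0.01 m3/yr is 5e-4 mol/m3 = 0.5 uM
  m <- flow_path_model(path_length = 3900, flow_rate = 0.01,
                       start_concentration = 23.5,
                       end_concentration_observed = 28.2,
                       flux_start = 0.010, flux_end = 0.011,
                       effective_exchange_area = 5e-3 / 0.0105)
  # area chosen so mean flux (0.0105 mmol/m2/yr) x A = 5e-3 mmol = 5e-6 mol
  expect_equal(no_reaction_endpoint(m), 24.0, tolerance = 1e-9)
})

test_that("zero flux returns the start concentration exactly", {
  m <- flow_path_model(path_length = 3900, flow_rate = 0.05,
                       start_concentration = 23.5,
                       end_concentration_observed = 28.2,
                       flux_start = 0, flux_end = 0)
  expect_identical(no_reaction_endpoint(m), 23.5)
})

test_that("mass conservation holds for random models", {
  set.seed(11)
  for (i in 1:50) {
    m <- random_flow_path_model()
    i_mol <- mean(c(m$flux_start, m$flux_end)) * m$effective_exchange_area / 1000
    lhs <- m$flow_rate * (no_reaction_endpoint(m) - m$start_concentration) / 1000
    expect_equal(lhs, i_mol, tolerance = 1e-9)
  }
})

test_that("discretized along-path integration matches the closed form", {
  set.seed(12)
  for (i in 1:20) {
    m <- random_flow_path_model()
    expect_equal(segmented_endpoint(m, 100), no_reaction_endpoint(m),
                 tolerance = 1e-9)
  }
})

test_that("a conservative solute has zero reaction rate", {
  set.seed(13)
  for (i in 1:100) {
    m <- random_flow_path_model()
    m$end_concentration_observed <- no_reaction_endpoint(m)
    res <- reaction_rate(m)
    expect_equal(res$reaction_rate, 0, tolerance = 1e-9)
    expect_equal(res$excess_nitrate, 0, tolerance = 1e-9)
  }
})

test_that("reaction rate matches the closed form by hand and is linear", {
  q <- 0.05
  m <- flow_path_model(path_length = 3900, flow_rate = q,
                       start_concentration = 23.5,
                       end_concentration_observed = 28.2,
                       flux_start = 0.010, flux_end = 0.011,
                       effective_exchange_area = 0.476)
  i_mol <- 0.0105 * 0.476 / 1000
  hand <- ((28.2 - 23.5) / 1000 * q - i_mol) / (3900 * 100) * 1e6
  res <- reaction_rate(m)
  expect_equal(res$reaction_rate, hand, tolerance = 1e-12)
  expect_equal(res$o2_demand_rate, 2 * max(hand, 0))
  # doubling (end - start) at zero flux doubles R
  m0 <- flow_path_model(path_length = 3900, flow_rate = q,
                        start_concentration = 20,
                        end_concentration_observed = 24,
                        flux_start = 0, flux_end = 0)
  m2 <- m0; m2$end_concentration_observed <- 28
  expect_equal(reaction_rate(m2)$reaction_rate,
               2 * reaction_rate(m0)$reaction_rate)
})

test_that("results are identical when concentrations are given in mol/m3", {
  m_um <- flow_path_model(path_length = 3900, flow_rate = 0.05,
                          start_concentration = 23.5,
                          end_concentration_observed = 28.2,
                          flux_start = 0.010, flux_end = 0.011)
  m_si <- flow_path_model(path_length = 3900, flow_rate = 0.05,
                          start_concentration = 23.5e-3,
                          end_concentration_observed = 28.2e-3,
                          flux_start = 0.010, flux_end = 0.011,
                          conc_unit = "mol_m3")
  expect_equal(reaction_rate(m_si)$reaction_rate,
               reaction_rate(m_um)$reaction_rate)
  expect_equal(no_reaction_endpoint(m_si), no_reaction_endpoint(m_um))
})

test_that("rate results carry explicit units", {
  m <- random_flow_path_model()
  res <- reaction_rate(m)
  expect_match(res$units$reaction_rate, "umol")
  expect_match(res$units$no_reaction_endpoint, "umol L-1")
})

test_that("nitrification O2 fraction follows the 2:1 stoichiometry", {
  expect_equal(nitrification_o2_fraction(3, 100), 0.06)
  expect_equal(nitrification_o2_fraction(0, 100), 0)
  # invariant under common rescaling
  expect_equal(nitrification_o2_fraction(3, 100),
               nitrification_o2_fraction(30, 1000))
  expect_error(nitrification_o2_fraction(3, 0), "> 0")
  # accepts a rate_result too
  m <- flow_path_model(path_length = 100, flow_rate = 0.1,
                       start_concentration = 10,
                       end_concentration_observed = 20,
                       flux_start = 0, flux_end = 0)
  res <- reaction_rate(m)
  expect_equal(nitrification_o2_fraction(res, 100),
               res$o2_demand_rate / 100)
})

test_that("flow-rate sweep is monotone and matches direct evaluation", {
  m <- flow_path_model(path_length = 3900, flow_rate = 0.01,
                       start_concentration = 23.5,
                       end_concentration_observed = 28.2,
                       flux_start = 0.010, flux_end = 0.011,
                       effective_exchange_area = 0.476)
  sw <- sweep_flow_rate(m, c(0.01, 0.2), points = 25,
                        o2_consumption_rate = 500)
  expect_equal(nrow(sw), 25)
  # endpoint monotone non-increasing in Q_sw for positive fluxes
  expect_true(all(diff(sw$endpoint) <= 1e-12))
  # R at fixed observed end is monotone (linear) in Q_sw
  expect_true(all(diff(sw$reaction_rate) > 0) ||
              all(diff(sw$reaction_rate) < 0))
  # uncertainty bands bracket the central value
  expect_true(all(sw$endpoint_lo <= sw$endpoint & sw$endpoint <= sw$endpoint_hi))
  expect_true(all(sw$rate_lo <= sw$reaction_rate &
                  sw$reaction_rate <= sw$rate_hi))
  # single-point sweep equals direct evaluation
  sw1 <- sweep_flow_rate(m, c(0.05, 0.2), points = 1)
  m5 <- m; m5$flow_rate <- 0.05
  expect_equal(sw1$endpoint, no_reaction_endpoint(m5))
  expect_equal(sw1$reaction_rate, reaction_rate(m5)$reaction_rate)
})

test_that("the implied exchange area inverts the endpoint relation", {
  m <- flow_path_model(path_length = 3900, flow_rate = 0.01,
                       start_concentration = 23.5,
                       end_concentration_observed = 28.2,
                       flux_start = 0.010, flux_end = 0.011)
  a <- implied_exchange_area(m, 24.0, at_flow_rate = 0.01)
  m2 <- m; m2$effective_exchange_area <- a
  expect_equal(no_reaction_endpoint(m2), 24.0, tolerance = 1e-9)
  # sweeps report it so the geometry gap is visible
  sw <- sweep_flow_rate(m, c(0.01, 0.2), points = 5)
  expect_true(is.finite(attr(sw, "implied_exchange_area_m2")))
})

test_that("model construction is validated", {
  expect_error(flow_path_model(3900, 0, 23.5, 28.2, 0.01, 0.011), "flow_rate")
  expect_error(flow_path_model(-1, 0.01, 23.5, 28.2, 0.01, 0.011))
})
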