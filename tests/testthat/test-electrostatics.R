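test_that("binned charge density integrates to the total system charge", {
  cfg <- synth_config(seed = 31, duration_ns = 2, frame_interval_ps = 100,
                      n_ions_per_species = list(K = 7, CL = 3), n_waters = 10)
  sim <- gen_trajectory(cfg)
  cd <- bin_charge_density(sim$trajectory, n_bins = 64)
  dz <- diff(cd$z_edges)[1]
  total <- sum(cd$rho) * dz * cd$area
  expect_equal(total, sum(sim$trajectory$particles$charge), tolerance = 1e-9)

  # brute-force oracle on a single frame
  cd1 <- bin_charge_density(sim$trajectory, n_bins = 32, frames = 4)
  expect_equal(sum(cd1$rho) * diff(cd1$z_edges)[1] * cd1$area,
               sum(sim$trajectory$particles$charge), tolerance = 1e-9)
})

test_that("zero density gives an identically zero potential", {
  pp <- potential_from_density(gen_charge_density("zero", n_bins = 300))
  expect_true(all(pp$phi == 0))
})

test_that("capacitor plateau step matches sigma d / eps0 to < 0.5% at 1000 bins", {
  sigma <- 1e-4; d <- 60
  cd <- gen_charge_density("capacitor", n_bins = 1000, z_max = 160,
                           params = list(sigma = sigma, d = d, center = 80))
  pp <- potential_from_density(cd)
  step <- mean(pp$phi[pp$z < 45]) - mean(pp$phi[pp$z > 115])
  expect_lt(abs(step - capacitor_voltage_mv(sigma, d)) /
              capacitor_voltage_mv(sigma, d), 0.005)
})

test_that("double integration agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  cd <- gen_charge_density("gaussian_dipole", n_bins = 20000, z_max = 160,
                           params = list(amp = 1e-5, sd = 8, sep = 50))
  pp <- potential_from_density(cd)
  e_chg <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  rho_f <- splinefun(cd$z, cd$rho * e_chg / 1e-30)
  sol <- deSolve::lsoda(c(phi = 0, g = 0), times = c(cd$z[1], cd$z) * 1e-10,
                        func = function(t, y, p)
                          list(c(y["g"], -rho_f(t * 1e10) / eps0)),
                        rtol = 1e-12, atol = 1e-14)
  phi_ode <- sol[-1, "phi"] * 1000
  expect_lt(max(abs(pp$phi - phi_ode)) / max(abs(phi_ode)), 1e-6)
})

test_that("the integrator is linear (superposition)", {
  c1 <- gen_charge_density("gaussian_dipole", n_bins = 2000,
                           params = list(amp = 1e-5, sd = 6, sep = 40))
  c2 <- gen_charge_density("capacitor", n_bins = 2000,
                           params = list(sigma = 5e-5, d = 30, center = 60))
  mix <- c1; mix$rho <- 2 * c1$rho - 3 * c2$rho
  p1 <- potential_from_density(c1); p2 <- potential_from_density(c2)
  pm <- potential_from_density(mix)
  expect_equal(pm$phi, 2 * p1$phi - 3 * p2$phi, tolerance = 1e-9)
})

test_that("grid refinement changes the voltage by < 1% for smooth profiles", {
  dv_at <- function(nb) {
    c1 <- gen_charge_density("gaussian_dipole", n_bins = nb,
                             params = list(amp = 1e-5, sd = 6, sep = 30, center = 40))
    c2 <- gen_charge_density("gaussian_dipole", n_bins = nb,
                             params = list(amp = -1e-5, sd = 6, sep = 30, center = 120))
    cd <- c1; cd$rho <- c1$rho + c2$rho
    transmembrane_voltage(potential_from_density(cd), c(40, 120))[["upper"]]
  }
  v1 <- dv_at(500); v2 <- dv_at(1000)
  expect_lt(abs(v2 - v1) / abs(v2), 0.01)
})

test_that("transmembrane voltages are equal and opposite for the two membranes", {
  # symmetric zero-imbalance profile -> both zero
  dv0 <- transmembrane_voltage(
    potential_from_density(gen_charge_density("zero", n_bins = 400)), c(40, 120))
  expect_equal(unname(dv0), c(0, 0))

  # antisymmetric double capacitor -> |dV| = sigma d / eps0, opposite signs
  sigma <- 1e-4; d <- 20
  c1 <- gen_charge_density("capacitor", n_bins = 1000,
                           params = list(sigma = sigma, d = d, center = 40))
  c2 <- gen_charge_density("capacitor", n_bins = 1000,
                           params = list(sigma = -sigma, d = d, center = 120))
  cd <- c1; cd$rho <- c1$rho + c2$rho
  dv <- transmembrane_voltage(potential_from_density(cd), c(40, 120))
  expect_equal(dv[["upper"]], -dv[["lower"]])
  expect_equal(abs(dv[["upper"]]), capacitor_voltage_mv(sigma, d),
               tolerance = 1e-6)
})

test_that("non-uniform grids are rejected", {
  cd <- gen_charge_density("zero", n_bins = 100)
  cd$z[5] <- cd$z[5] + 0.1
  expect_error(potential_from_density(cd), "uniform")
})
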