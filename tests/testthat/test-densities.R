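test_that("a static ion puts all its occupancy mass in one bin", {
  geo <- upper_geometry()
  traj <- make_traj(list(hold(c(30, 30, 118), 50)), times = seq(0, 4900, by = 100))
  occ <- occupancy_histogram(traj, geo, species = "K")
  expect_equal(sum(occ$counts), 50)
  expect_equal(sum(occ$counts > 0), 1)
})

test_that("uniform positions fill z bins within multinomial error", {
  geo <- upper_geometry()
  set.seed(5)
  nfr <- 4000
  zs <- runif(nfr, 104, 132)               # uniform over cavity+SF+vestibule
  track <- cbind(30, 30, zs)
  traj <- make_traj(list(track), times = seq_len(nfr))
  occ <- occupancy_histogram(traj, geo, species = "K",
                             z_edges = seq(-16, 12, by = 2),
                             r_edges = c(0, 12))
  p <- 2 / 28                              # bin width / range
  expected <- nfr * p
  sdv <- sqrt(nfr * p * (1 - p))
  expect_true(all(abs(occ$counts - expected) < 4 * sdv))
  # mass conservation over the covering domain
  expect_equal(sum(occ$counts), occ$n_samples)
})

test_that("two planted SF residents give S3+S4 occupancy of about two ions", {
  cfg <- synth_config(seed = 11, duration_ns = 20, frame_interval_ps = 50,
                      n_ions_per_species = list(K = 2),
                      resident_ions = list(species = "K", sites = c("S3", "S4")))
  sim <- gen_trajectory(cfg)
  geo <- synth_geometry(cfg)
  so <- site_occupancy(sim$trajectory, geo, species = "K", sites = c("S3", "S4"))
  expect_equal(unname(so["total"]), 2, tolerance = 0.05)
})

test_that("Boltzmann inversion recovers a harmonic well", {
  set.seed(77)
  k <- 2                                    # kJ/mol/A^2
  Temp <- 300; kT <- 8.314462618e-3 * Temp
  sig <- sqrt(kT / k)
  z <- rnorm(1e5, 0, sig)
  breaks <- seq(-5 * sig, 5 * sig, length.out = 81)
  counts <- as.vector(table(cut(z, breaks)))
  w <- pmf_from_occupancy(counts, temperature = Temp)
  zc <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sel <- abs(zc) <= 2 * sig & !is.na(w)
  rmse <- sqrt(mean((w[sel] - 0.5 * k * zc[sel]^2)^2))
  expect_lt(rmse, 0.2)

  # doubling the sample leaves the estimate within sampling error
  z2 <- c(z, rnorm(1e5, 0, sig))
  w2 <- pmf_from_occupancy(as.vector(table(cut(z2, breaks))), temperature = Temp)
  expect_lt(max(abs(w2[sel] - w[sel])), 0.35)
})

test_that("PMF conventions: uniform histogram is flat, zero bins masked, reference at zero", {
  w <- pmf_from_occupancy(rep(100, 12))
  expect_true(all(w == 0))
  counts <- c(0, 5, 20, 10, 0)
  w2 <- pmf_from_occupancy(counts)
  expect_true(all(is.na(w2[counts == 0])))
  expect_equal(min(w2, na.rm = TRUE), 0)
  expect_error(pmf_from_occupancy(rep(0, 4)), "all-zero")
  # shift invariance: scaling all counts leaves w differences unchanged
  w3 <- pmf_from_occupancy(counts * 7)
  expect_equal(w3, w2)
})

test_that("hydration numbers count first-shell waters and shrink with the cutoff", {
  # six waters placed at 2.4 A from a potassium ion
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  center <- c(30, 30, 80)
  tracks <- c(list(hold(center, 3)),
              lapply(seq_len(6), function(i) hold(center + 2.4 * dirs[i, ], 3)))
  particles <- data.frame(id = 1:7, species = c("K", rep("WATER_O", 6)),
                          charge = c(1, rep(0, 6)))
  traj <- make_traj(tracks, times = c(0, 10, 20), particles = particles)
  expect_equal(hydration_number(traj, 1, frames = 2), 6L)
  expect_equal(hydration_number(traj, 1, frames = 2, cutoffs = c(K = 2.0)), 0L)
  # monotone: smaller cutoff never increases the count
  expect_lte(hydration_number(traj, 1, frames = 1, cutoffs = c(K = 2.5)),
             hydration_number(traj, 1, frames = 1, cutoffs = c(K = 3.5)))
})

test_that("shed hydration shells leave SF ions drier than bulk", {
  cfg <- synth_config(seed = 9, duration_ns = 20, frame_interval_ps = 50,
                      n_ions_per_species = list("NA" = 4),
                      n_override = list("NA" = list(inward = 2)),
                      hydration_n = 6, shed_in_sf = TRUE)
  sim <- gen_trajectory(cfg)
  cr <- sim$truth$crossings[1, ]
  t <- sim$trajectory$times
  f_bulk <- max(1, findInterval(cr$t_start_ps - 500, t))
  f_sf <- which(t >= (cr$t_enter_sf_ps + cr$t_exit_sf_ps) / 2)[1]
  h_bulk <- hydration_number(sim$trajectory, cr$ion_id, frames = f_bulk)
  h_sf <- hydration_number(sim$trajectory, cr$ion_id, frames = f_sf)
  expect_lt(h_sf, h_bulk)
})

test_that("coordination states count S_side protein oxygens by construction", {
  geo <- upper_geometry()
  # build a fixture: Na ion surrounded by D66 O, F69 O, S70 OG of subunit A
  site <- c(30 + 8.6, 30, 129.6)
  prot <- data.frame(
    subunit = c("A", "A", "A", "D"), resno = c(66L, 69L, 70L, 66L),
    atom = c("O", "O", "OG", "OD1"))
  offs <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, 0, 9))  # OD1 far
  tracks <- c(list(hold(site, 2)),
              lapply(1:4, function(i) hold(site + offs[i, ], 2)))
  particles <- data.frame(id = 1:5,
                          species = c("NA", rep("PROTEIN_ATOM", 4)),
                          charge = 0:0, subunit = c(NA, prot$subunit),
                          resno = c(NA, prot$resno), atom = c(NA, prot$atom))
  particles$charge <- c(1, 0, 0, 0, 0)
  traj <- make_traj(tracks, times = c(0, 10), particles = particles)
  cs <- coordination_state(traj, 1, 1, geo)
  expect_equal(cs$n_protein_O, 3L)
  expect_setequal(paste(cs$contributing_atoms$resno, cs$contributing_atoms$atom),
                  c("66 O", "69 O", "70 OG"))

  # alternative state: neighbouring-subunit D66 OD1 replaces S70 OG
  offs2 <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 9, 0), c(0, 2, 0))
  tracks2 <- c(list(hold(site, 2)),
               lapply(1:4, function(i) hold(site + offs2[i, ], 2)))
  traj2 <- make_traj(tracks2, times = c(0, 10), particles = particles)
  cs2 <- coordination_state(traj2, 1, 1, geo)
  expect_equal(cs2$n_protein_O, 3L)
  expect_setequal(paste(cs2$contributing_atoms$resno, cs2$contributing_atoms$atom),
                  c("66 O", "69 O", "66 OD1"))
})
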