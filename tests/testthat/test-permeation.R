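test_that("static ions produce no events", {
  geo <- upper_geometry()
  tracks <- list(hold(c(30, 30, 145), 20), hold(c(30, 30, 90), 20))
  traj <- make_traj(tracks, times = seq(0, 1900, by = 100))
  for (mode in c("full_crossing", "coupled_exchange")) {
    ev <- detect_events(traj, geo, mode = mode, species = "K")
    expect_equal(nrow(ev), 0)
  }
})

test_that("the coupled-exchange rule counts the scripted 3-frame example once", {
  geo <- upper_geometry()
  # ion X: extracellular -> SF; ion Y: SF -> cavity one frame later
  x <- rbind(c(30, 30, 140), c(30, 30, 120), c(30, 30, 120))
  y <- rbind(c(30, 30, 120), c(30, 30, 120), c(30, 30, 110))
  traj <- make_traj(list(x, y), times = c(0, 20, 40))
  ev <- detect_events(traj, geo, mode = "coupled_exchange", species = "K",
                      window_ps = 100)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "inward")
  expect_equal(ev$ion_id, 1L)
})

test_that("full-crossing detection recovers planted crossings exactly", {
  cfg <- recovery_config(seed = 42)
  sim <- gen_trajectory(cfg)
  geo <- synth_geometry(cfg)
  ev <- detect_events(sim$trajectory, geo, species = "K")
  truth <- sim$truth$crossings
  planted <- truth[truth$type == "crossing", ]

  expect_equal(nrow(ev), 20)
  expect_equal(attr(ev, "n_distractors"), 30)
  expect_equal(sum(ev$direction == "inward"), 12)
  expect_equal(sum(ev$direction == "outward"), 8)
  # event-by-event match (ion identity and SF entry time on the frame grid)
  key <- function(d, tcol) {
    d <- d[order(d[[tcol]]), ]
    paste(d$ion_id, d$direction)
  }
  expect_identical(key(as.data.frame(ev), "entry_frame_time"),
                   key(planted, "t_enter_sf_ps"))
  dt <- sort(ev$entry_frame_time) - sort(planted$t_enter_sf_ps)
  expect_true(all(dt >= 0 & dt <= cfg$frame_interval_ps))
})

test_that("counting is invariant to ion relabelling and time offsets", {
  cfg <- recovery_config(seed = 17)
  sim <- gen_trajectory(cfg)
  geo <- synth_geometry(cfg)
  ev <- detect_events(sim$trajectory, geo, species = "K")

  # permute particle order
  traj <- sim$trajectory
  perm <- sample(n_particles(traj))
  traj2 <- permeon_trajectory(traj$particles[perm, ],
                              traj$coords[perm, , , drop = FALSE],
                              traj$times, traj$box, wrap = FALSE)
  ev2 <- detect_events(traj2, geo, species = "K")
  expect_equal(nrow(ev2), nrow(ev))
  expect_identical(sort(paste(ev2$ion_id, ev2$direction)),
                   sort(paste(ev$ion_id, ev$direction)))

  # shift all frame times
  traj3 <- traj; traj3$times <- traj$times + 12345
  ev3 <- detect_events(traj3, geo, species = "K")
  expect_equal(ev3$entry_frame_time - 12345, ev$entry_frame_time)
})

test_that("pathway classification recovers planted side entries", {
  cfg <- recovery_config(seed = 42, side_entry_fraction = 0.3)
  sim <- gen_trajectory(cfg)
  geo <- synth_geometry(cfg)
  ev <- classify_pathway(detect_events(sim$trajectory, geo, species = "K"),
                         sim$trajectory, geo)
  truth <- sim$truth$crossings
  planted <- truth[truth$type == "crossing", ]
  planted <- planted[order(planted$t_enter_sf_ps), ]
  ev <- ev[order(ev$entry_frame_time), ]
  expect_identical(ev$pathway, planted$pathway)
})

test_that("coordination with S_side atoms flags side entries when the portal annulus misses them", {
  cfg <- recovery_config(seed = 8, side_entry_fraction = 1)
  sim <- gen_trajectory(cfg)
  gcfg <- cfg$geometry
  gcfg$axis_origin <- c(30, 30, 120)
  gcfg$side_portal_radius_min <- 0.5      # annulus 4.5-5 A: portal anchor at 8 A missed
  geo <- build_geometry(gcfg)
  ev <- detect_events(sim$trajectory, geo, species = "K")
  ev <- classify_pathway(ev, sim$trajectory, geo)
  expect_true(all(ev$pathway == "side"))
})

test_that("conductance arithmetic matches the published event counts", {
  # 18 inward events over 10 us at 460 mV print as 0.6 pS
  g <- conductance(18, 10, 460)
  expect_equal(round(g$conductance_pS, 1), 0.6)
  expect_equal(g$current_pA, 18 * 1.602176634e-19 / 1e-5 * 1e12)
  expect_equal(conductance(0, 10, 460)$conductance_pS, 0)
  expect_error(conductance(5, 0, 460), "total_time")
  expect_error(conductance(5, 10, 0), "voltage")
  # printed conductance ratios
  expect_equal(round(35 / 0.8), 44)
  expect_equal(7.2 / 0.8, 9)
})

test_that("conduction summaries aggregate per species and direction", {
  cfg <- recovery_config(seed = 42)
  sim <- gen_trajectory(cfg)
  geo <- synth_geometry(cfg)
  ev <- detect_events(sim$trajectory, geo, species = "K")
  cs <- conduction_summary(ev, total_time_us = 0.2, voltage_mv = 460)
  expect_equal(sum(cs$n), 20)
  expect_true(all(cs$conductance_pS >= 0))
  i <- cs$direction == "inward"
  expect_equal(cs$conductance_pS[i],
               conductance(cs$n[i], 0.2, 460)$conductance_pS)
})
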