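# Shared fixtures: geometries anchored at the synthetic upper channel and
# small hand-built trajectories.

upper_geometry <- function() build_geometry(default_geometry_config(c(30, 30, 120)))

# Trajectory from an explicit list of per-particle position matrices
# (n_frames x 3 each), all ions of one species unless a particles table is
# given.
make_traj <- function(tracks, times, species = "K", box = c(60, 60, 160),
                      particles = NULL) {
  np <- length(tracks)
  if (is.null(particles))
    particles <- data.frame(id = seq_len(np), species = species,
                            charge = species_charge(rep(species, np)))
  coords <- array(NA_real_, dim = c(np, 3, length(times)))
  for (i in seq_len(np)) coords[i, , ] <- t(tracks[[i]])
  permeon_trajectory(particles, coords, times, box)
}

# Repeat one xyz anchor over n frames.
hold <- function(xyz, n) matrix(xyz, nrow = n, ncol = 3, byrow = TRUE)

# Lean generator config used by several recovery tests.
recovery_config <- function(seed = 42, side_entry_fraction = 0.3) {
  synth_config(seed = seed, duration_ns = 200, frame_interval_ps = 25,
               n_ions_per_species = list(K = 30),
               n_override = list(K = list(inward = 12, outward = 8, partial = 30)),
               side_entry_fraction = side_entry_fraction)
}
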