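# Synthetic trajectory, scaffold and charge-density generators.
#
# The trajectory generator is a kinetic hopping model of the double-membrane
# ("computational electrophysiology") setup: two membranes at configurable z,
# a channel in the upper membrane, ions hopping among bulk / vestibule or side
# portal / SF / cavity anchor points with Gaussian positional jitter, waters
# forming rigid hydration shells, and carbonyl pseudo-atoms whose T62 C=O can
# be flipped on a planted schedule.  Everything planted (crossing times,
# pathways, flip intervals) is emitted in a ground-truth sidecar so the
# analyses can be tested for exact recovery.

#' Configuration for the synthetic trajectory generator
#'
#' Rates are per species in events per microsecond.  `n_override` can pin
#' exact event counts (a list per species with elements `inward`, `outward`,
#' `partial`), which keeps recovery tests deterministic; otherwise counts are
#' Poisson with mean rate x duration.  Completed crossings are followed, after
#' `recycle_delay_ps`, by a position swap back to the origin-side bulk,
#' mirroring the ion/water swaps that hold the compartment imbalance constant
#' in the real protocol, so per-side ion pools remain stationary.
#'
#' @param seed integer RNG seed.
#' @param duration_ns trajectory length (ns).
#' @param frame_interval_ps frame spacing (ps).
#' @param n_ions_per_species named list/vector, e.g. `list(K = 16)`.
#' @param n_waters free bulk water oxygens (beyond hydration shells).
#' @param crossing_rate_inward,crossing_rate_outward named lists of rates
#'   (events/us) for complete crossings.
#' @param partial_entry_rate named list of rates for distractor excursions
#'   that enter the SF and return to the same side.
#' @param side_entry_fraction probability that an extracellular-side transit
#'   uses a side portal instead of the axial vestibule path.
#' @param n_override optional exact counts, see Details.
#' @param hydration_n,hydration_radius waters per ion and shell radius (A).
#' @param shed_in_sf logical; shells stay behind while the ion is in the SF.
#' @param flip_schedule named list per subunit of two-column matrices
#'   `cbind(start_ns, end_ns)` of flipped intervals.
#' @param flip_widen radial widening (A) of a flipped subunit's T63/V64
#'   carbonyls, producing the asymmetric filter deformation.
#' @param jitter_sd Gaussian positional jitter around anchors (A).
#' @param compartment_imbalance extra permeant cations in compartment a
#'   (between the membrane midplanes) relative to b.
#' @param box,membrane_z box edge lengths and the two membrane midplane z (A).
#' @param entry_dwell_ps,exit_dwell_ps dwell at entry/exit anchors (ps).
#' @param sf_dwell_mean_ps,sf_dwell_min_ps,sf_dwell_max_ps exponential SF
#'   dwell-time parameters (ps).
#' @param recycle_delay_ps delay before the post-crossing position swap (ps).
#' @param resident_ions optional `list(species=, sites=)` pinning static ions
#'   at filter sites (e.g. `sites = c("S3","S4")`).
#' @param neutralize add enough CL counter-ions (split evenly between the
#'   compartments) to make the system charge-neutral, so the net charge
#'   difference between compartments is set by `compartment_imbalance` alone.
#' @param geometry geometry config (relative bounds), see
#'   [default_geometry_config()].
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, duration_ns = 100, frame_interval_ps = 50,
                         n_ions_per_species = list(K = 16), n_waters = 0,
                         crossing_rate_inward = list(), crossing_rate_outward = list(),
                         partial_entry_rate = list(), side_entry_fraction = 0,
                         n_override = NULL,
                         hydration_n = 0, hydration_radius = 2.6, shed_in_sf = TRUE,
                         flip_schedule = list(), flip_widen = 0.8,
                         jitter_sd = 0.3, compartment_imbalance = 2,
                         box = c(60, 60, 160), membrane_z = c(40, 120),
                         entry_dwell_ps = 300, sf_dwell_mean_ps = 500,
                         sf_dwell_min_ps = 150, sf_dwell_max_ps = 3000,
                         exit_dwell_ps = 300, recycle_delay_ps = 500,
                         resident_ions = NULL, neutralize = FALSE,
                         geometry = default_geometry_config()) {
  cfg <- as.list(environment())
  rates <- unlist(c(crossing_rate_inward, crossing_rate_outward, partial_entry_rate))
  if (length(rates) && any(rates < 0)) stop("config error: rates must be >= 0")
  if (side_entry_fraction < 0 || side_entry_fraction > 1)
    stop("config error: side_entry_fraction must be in [0, 1]")
  if (duration_ns <= 0) stop("config error: duration must be > 0")
  if (frame_interval_ps <= 0) stop("config error: frame_interval_ps must be > 0")
  if (length(membrane_z) != 2 || membrane_z[1] >= membrane_z[2])
    stop("config error: membrane_z must be two increasing z values")
  bad <- setdiff(names(n_ions_per_species), c("K", "NA", "RB", "CL"))
  if (length(bad)) stop("config error: unknown ion species ", paste(bad, collapse = ", "))
  structure(cfg, class = "synth_config")
}

# Anchor points in channel-relative coordinates (Angstrom).
.rel_anchors <- list(ext_idle_z = 25, int_idle_z = -30, vestibule = c(0, 0, 9),
                     sf = c(0, 0, 0), cavity = c(0, 0, -12),
                     portal_radius = 8, portal_z = 9)

.portal_anchor <- function(subunit) {
  phi <- .subunit_azimuth[[subunit]]
  c(.rel_anchors$portal_radius * cos(phi),
    .rel_anchors$portal_radius * sin(phi), .rel_anchors$portal_z)
}

# Draw event counts and times for one species/kind.
.plan_counts <- function(rate, dur_us, override) {
  if (!is.null(override)) return(as.integer(override))
  if (is.null(rate) || rate <= 0) return(0L)
  rpois(1, rate * dur_us)
}

#' Generate a synthetic permeation trajectory with planted ground truth
#'
#' @param config a [synth_config()].
#' @param frames if `FALSE`, only the event plan / ground truth is produced
#'   (cheap; used for rate calibration checks).
#' @return list of class `permeon_sim` with elements `trajectory` (a
#'   `permeon_trajectory`, or `NULL` when `frames = FALSE`), `truth`
#'   (`$crossings` and `$flips` data.frames, times in ps) and `config`.
#' @export
gen_trajectory <- function(config, frames = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  cfg <- config
  dur_ps <- cfg$duration_ns * 1000
  dur_us <- cfg$duration_ns / 1000
  origin_z <- cfg$membrane_z[2]                       # channel in upper membrane
  center_xy <- cfg$box[1:2] / 2
  horizon <- cfg$entry_dwell_ps + cfg$sf_dwell_max_ps + cfg$exit_dwell_ps +
    cfg$recycle_delay_ps + 200

  ## ---- event plan ---------------------------------------------------------
  species_set <- sort(unique(c(names(cfg$crossing_rate_inward),
                               names(cfg$crossing_rate_outward),
                               names(cfg$partial_entry_rate),
                               names(cfg$n_override))))
  plan <- list()
  for (sp in species_set) {
    ov <- cfg$n_override[[sp]]
    n_in  <- .plan_counts(cfg$crossing_rate_inward[[sp]],  dur_us, ov$inward)
    n_out <- .plan_counts(cfg$crossing_rate_outward[[sp]], dur_us, ov$outward)
    n_par <- .plan_counts(cfg$partial_entry_rate[[sp]],    dur_us, ov$partial)
    mk <- function(n, type, direction) {
      if (n == 0) return(NULL)
      data.frame(species = sp, type = type, direction = direction,
                 time = runif(n, 0, max(dur_ps - horizon, 1)),
                 stringsAsFactors = FALSE)
    }
    plan[[sp]] <- rbind(mk(n_in, "crossing", "inward"),
                        mk(n_out, "crossing", "outward"),
                        mk(n_par, "distractor", NA_character_))
  }
  plan <- do.call(rbind, plan)
  if (is.null(plan)) plan <- data.frame(species = character(), type = character(),
                                        direction = character(), time = numeric())
  if (nrow(plan)) {
    plan <- plan[order(plan$time), , drop = FALSE]
    plan$pathway <- ifelse(runif(nrow(plan)) < cfg$side_entry_fraction, "side", "axial")
    plan$subunit <- ifelse(plan$pathway == "side",
                           sample(SUBUNITS, nrow(plan), replace = TRUE), NA_character_)
    plan$start_side <- ifelse(plan$type == "distractor",
                              sample(c("ext", "int"), nrow(plan), replace = TRUE),
                              ifelse(plan$direction == "inward", "ext", "int"))
    plan$sf_dwell <- pmin(pmax(rexp(nrow(plan), 1 / cfg$sf_dwell_mean_ps),
                               max(cfg$sf_dwell_min_ps, 3 * cfg$frame_interval_ps)),
                          cfg$sf_dwell_max_ps)
  }

  ## ---- ion pools ----------------------------------------------------------
  ion_tab <- NULL
  next_id <- 1L
  for (sp in names(cfg$n_ions_per_species)) {
    n <- cfg$n_ions_per_species[[sp]]
    if (n <= 0) next
    imb <- if (sp %in% c("K", "NA", "RB")) cfg$compartment_imbalance else 0
    n_int <- min(n, max(0, round((n + imb) / 2)))
    ion_tab <- rbind(ion_tab, data.frame(
      id = seq.int(next_id, length.out = n), species = sp,
      side = rep(c("int", "ext"), c(n_int, n - n_int)), stringsAsFactors = FALSE))
    next_id <- next_id + n
  }
  if (is.null(ion_tab)) ion_tab <- data.frame(id = integer(), species = character(),
                                              side = character())
  if (isTRUE(cfg$neutralize)) {
    net <- if (nrow(ion_tab)) sum(species_charge(ion_tab$species)) else 0
    if (net > 0) {
      ion_tab <- rbind(ion_tab, data.frame(
        id = seq.int(next_id, length.out = net), species = "CL",
        side = rep(c("int", "ext"), length.out = net), stringsAsFactors = FALSE))
      next_id <- next_id + net
    }
  }

  idle_anchor <- function(side) {
    zrel <- if (side == "ext") .rel_anchors$ext_idle_z else .rel_anchors$int_idle_z
    c(center_xy + runif(2, -20, 20), origin_z + zrel)
  }
  entry_anchor <- function(pathway, subunit) {
    rel <- if (pathway == "side") .portal_anchor(subunit) else .rel_anchors$vestibule
    c(center_xy + rel[1:2], origin_z + rel[3])
  }
  axis_anchor <- function(rel) c(center_xy, origin_z + rel[3])

  segs <- vector("list", nrow(ion_tab))       # per-ion anchor segments
  names(segs) <- as.character(ion_tab$id)
  for (k in seq_len(nrow(ion_tab)))
    segs[[k]] <- data.frame(t = -Inf, tag = "idle",
                            x = NA, y = NA, z = NA)
  for (k in seq_len(nrow(ion_tab))) {
    a <- idle_anchor(ion_tab$side[k])
    segs[[k]][1, c("x", "y", "z")] <- a
  }
  free_at <- rep(0, nrow(ion_tab))

  add_seg <- function(k, t, tag, xyz) {
    segs[[k]] <<- rbind(segs[[k]],
                        data.frame(t = t, tag = tag, x = xyz[1], y = xyz[2], z = xyz[3]))
  }

  truth_rows <- list()
  if (nrow(plan)) for (ev in seq_len(nrow(plan))) {
    e <- plan[ev, ]
    cand <- which(ion_tab$species == e$species & ion_tab$side == e$start_side)
    if (!length(cand)) {
      warning("no ion available on side '", e$start_side, "' for species ",
              e$species, "; event dropped")
      next
    }
    k <- cand[order(free_at[cand], ion_tab$id[cand])][1]
    t0 <- max(e$time, free_at[k] + 10)
    ed <- cfg$entry_dwell_ps; xd <- cfg$exit_dwell_ps; sfd <- e$sf_dwell
    if (e$type == "crossing" && e$direction == "inward") {
      add_seg(k, t0, "entry", entry_anchor(e$pathway, e$subunit))
      add_seg(k, t0 + ed, "SF", axis_anchor(.rel_anchors$sf))
      add_seg(k, t0 + ed + sfd, "cavity", axis_anchor(.rel_anchors$cavity))
      t_end <- t0 + ed + sfd + xd
      add_seg(k, t_end, "idle", idle_anchor("int"))
      add_seg(k, t_end + cfg$recycle_delay_ps, "idle", idle_anchor("ext"))
      free_at[k] <- t_end + cfg$recycle_delay_ps + 100
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        type = "crossing", species = e$species, ion_id = ion_tab$id[k],
        direction = "inward", pathway = e$pathway, subunit = e$subunit,
        channel_copy = "upper", t_start_ps = t0, t_enter_sf_ps = t0 + ed,
        t_exit_sf_ps = t0 + ed + sfd, t_end_ps = t_end, stringsAsFactors = FALSE)
    } else if (e$type == "crossing") {                      # outward
      add_seg(k, t0, "cavity", axis_anchor(.rel_anchors$cavity))
      add_seg(k, t0 + ed, "SF", axis_anchor(.rel_anchors$sf))
      add_seg(k, t0 + ed + sfd, "entry", entry_anchor(e$pathway, e$subunit))
      t_end <- t0 + ed + sfd + xd
      add_seg(k, t_end, "idle", idle_anchor("ext"))
      add_seg(k, t_end + cfg$recycle_delay_ps, "idle", idle_anchor("int"))
      free_at[k] <- t_end + cfg$recycle_delay_ps + 100
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        type = "crossing", species = e$species, ion_id = ion_tab$id[k],
        direction = "outward", pathway = e$pathway, subunit = e$subunit,
        channel_copy = "upper", t_start_ps = t0, t_enter_sf_ps = t0 + ed,
        t_exit_sf_ps = t0 + ed + sfd, t_end_ps = t_end, stringsAsFactors = FALSE)
    } else {                                                # distractor
      first <- if (e$start_side == "ext") entry_anchor(e$pathway, e$subunit)
               else axis_anchor(.rel_anchors$cavity)
      add_seg(k, t0, "entry", first)
      add_seg(k, t0 + ed, "SF", axis_anchor(.rel_anchors$sf))
      add_seg(k, t0 + ed + sfd, "entry", first)
      t_end <- t0 + ed + sfd + xd
      add_seg(k, t_end, "idle", idle_anchor(e$start_side))
      free_at[k] <- t_end + 100
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        type = "distractor", species = e$species, ion_id = ion_tab$id[k],
        direction = NA_character_, pathway = e$pathway, subunit = e$subunit,
        channel_copy = "upper", t_start_ps = t0, t_enter_sf_ps = t0 + ed,
        t_exit_sf_ps = t0 + ed + sfd, t_end_ps = t_end, stringsAsFactors = FALSE)
    }
  }
  crossings <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(type = character(), species = character(), ion_id = integer(),
               direction = character(), pathway = character(), subunit = character(),
               channel_copy = character(), t_start_ps = numeric(),
               t_enter_sf_ps = numeric(), t_exit_sf_ps = numeric(),
               t_end_ps = numeric())

  flips <- do.call(rbind, lapply(names(cfg$flip_schedule), function(su) {
    iv <- cfg$flip_schedule[[su]]
    if (is.null(iv)) return(NULL)
    iv <- matrix(as.numeric(iv), ncol = 2)
    data.frame(subunit = su, start_ps = iv[, 1] * 1000, end_ps = iv[, 2] * 1000,
               stringsAsFactors = FALSE)
  }))
  if (is.null(flips)) flips <- data.frame(subunit = character(),
                                          start_ps = numeric(), end_ps = numeric())

  truth <- list(crossings = crossings, flips = flips)
  if (!frames)
    return(structure(list(trajectory = NULL, truth = truth, config = cfg),
                     class = "permeon_sim"))

  ## ---- frame emission -----------------------------------------------------
  times <- seq(0, dur_ps, by = cfg$frame_interval_ps)
  nf <- length(times)
  jit <- function(n) matrix(rnorm(n * 3, sd = cfg$jitter_sd), ncol = 3)
  emit_segs <- function(sg) {
    idx <- findInterval(times, sg$t)
    cbind(sg$x[idx], sg$y[idx], sg$z[idx])
  }

  rows <- list(); coords_list <- list()
  push <- function(row, pos) {
    rows[[length(rows) + 1]] <<- row
    coords_list[[length(coords_list) + 1]] <<- pos
  }

  # 1. pool ions
  for (k in seq_len(nrow(ion_tab))) {
    pos <- emit_segs(segs[[k]]) + jit(nf)
    push(data.frame(id = ion_tab$id[k], species = ion_tab$species[k],
                    charge = species_charge(ion_tab$species[k]),
                    subunit = NA, resno = NA, atom = NA), pos)
  }
  next_id <- if (nrow(ion_tab)) max(ion_tab$id) + 1L else 1L

  # 2. resident filter-site ions
  if (!is.null(cfg$resident_ions)) {
    for (site in cfg$resident_ions$sites) {
      zrel <- cfg$geometry$site_planes[[site]]
      if (is.null(zrel)) stop("config error: unknown site ", site)
      anchor <- c(center_xy, origin_z + zrel)
      pos <- matrix(anchor, nrow = nf, ncol = 3, byrow = TRUE) + jit(nf)
      push(data.frame(id = next_id, species = cfg$resident_ions$species,
                      charge = species_charge(cfg$resident_ions$species),
                      subunit = NA, resno = NA, atom = NA), pos)
      next_id <- next_id + 1L
    }
  }

  # 3. hydration-shell waters (follow their ion except, optionally, in the SF)
  if (cfg$hydration_n > 0) for (k in seq_len(nrow(ion_tab))) {
    sg <- segs[[k]]
    if (cfg$shed_in_sf) {
      sf_rows <- which(sg$tag == "SF")
      for (r in sf_rows) sg[r, c("x", "y", "z")] <- sg[r - 1, c("x", "y", "z")]
    }
    base <- emit_segs(sg)
    for (w in seq_len(cfg$hydration_n)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1, 2.2, cfg$hydration_radius)
      pos <- sweep(base, 2, u, "+") + jit(nf)
      push(data.frame(id = next_id, species = "WATER_O", charge = 0,
                      subunit = NA, resno = NA, atom = NA), pos)
      next_id <- next_id + 1L
    }
  }

  # 4. free bulk waters (outside the membrane slabs)
  if (cfg$n_waters > 0) {
    half <- 15
    zones <- rbind(c(0, cfg$membrane_z[1] - half),
                   c(cfg$membrane_z[1] + half, cfg$membrane_z[2] - half),
                   c(cfg$membrane_z[2] + half, cfg$box[3]))
    wz <- apply(zones, 1, diff); wz <- wz / sum(wz)
    for (w in seq_len(cfg$n_waters)) {
      zone <- sample.int(3, 1, prob = wz)
      anchor <- c(runif(2, 0, cfg$box[1:2]), runif(1, zones[zone, 1], zones[zone, 2]))
      pos <- matrix(anchor, nrow = nf, ncol = 3, byrow = TRUE) + jit(nf)
      push(data.frame(id = next_id, species = "WATER_O", charge = 0,
                      subunit = NA, resno = NA, atom = NA), pos)
      next_id <- next_id + 1L
    }
  }

  # 5. filter carbonyl pseudo-atoms (C and O of T62/T63/V64/G65 per subunit)
  #    and the S_side coordinating oxygens.
  flip_state <- function(su) {
    st <- rep(FALSE, nf)
    iv <- flips[flips$subunit == su, , drop = FALSE]
    for (r in seq_len(nrow(iv)))
      st <- st | (times >= iv$start_ps[r] & times < iv$end_ps[r])
    st
  }
  planes <- c("62" = -4.5, "63" = -2, "64" = 1, "65" = 3.5)
  resnames <- c("62" = "THR", "63" = "THR", "64" = "VAL", "65" = "GLY")
  rC <- 4.6
  for (su in SUBUNITS) {
    phi <- .subunit_azimuth[[su]]
    er <- c(cos(phi), sin(phi))
    flipped <- flip_state(su)
    for (res in names(planes)) {
      widen <- if (res %in% c("63", "64")) cfg$flip_widen * flipped else 0
      radius_C <- rC + widen
      radius_O <- if (res == "62") ifelse(flipped, rC + 1.23, rC - 1.23)
                  else rC - 1.23 + widen
      zabs <- origin_z + planes[[res]]
      posC <- cbind(center_xy[1] + radius_C * er[1], center_xy[2] + radius_C * er[2],
                    rep(zabs, nf)) + jit(nf)
      posO <- cbind(center_xy[1] + radius_O * er[1], center_xy[2] + radius_O * er[2],
                    rep(zabs, nf)) + jit(nf)
      for (at in c("C", "O")) {
        push(data.frame(id = next_id, species = "PROTEIN_ATOM", charge = 0,
                        subunit = su, resno = as.integer(res), atom = at),
             if (at == "C") posC else posO)
        next_id <- next_id + 1L
      }
    }
    sside <- data.frame(
      resno = c(66L, 69L, 70L, 66L), atom = c("O", "O", "OG", "OD1"),
      u = c(8.0, 8.0, 10.6, 6.2), v = c(1.8, -1.8, 0, -5.2),
      z = c(10.6, 8.6, 9.6, 10.0))
    et <- c(-sin(phi), cos(phi))
    for (r in seq_len(nrow(sside))) {
      anchor <- c(center_xy + sside$u[r] * er + sside$v[r] * et,
                  origin_z + sside$z[r])
      pos <- matrix(anchor, nrow = nf, ncol = 3, byrow = TRUE) + jit(nf)
      push(data.frame(id = next_id, species = "PROTEIN_ATOM", charge = 0,
                      subunit = su, resno = sside$resno[r], atom = sside$atom[r]),
           pos)
      next_id <- next_id + 1L
    }
  }

  particles <- do.call(rbind, rows)
  coords <- array(NA_real_, dim = c(nrow(particles), 3, nf))
  for (i in seq_along(coords_list)) coords[i, , ] <- t(coords_list[[i]])
  traj <- permeon_trajectory(particles, coords, times, cfg$box)
  structure(list(trajectory = traj, truth = truth, config = cfg),
            class = "permeon_sim")
}

#' @export
print.permeon_sim <- function(x, ...) {
  cat("<permeon_sim> seed", x$config$seed, "\n")
  if (!is.null(x$trajectory)) print(x$trajectory)
  cr <- x$truth$crossings
  cat(sprintf("  planted: %d crossings (%d inward, %d outward), %d distractors\n",
              sum(cr$type == "crossing"),
              sum(cr$direction == "inward", na.rm = TRUE),
              sum(cr$direction == "outward", na.rm = TRUE),
              sum(cr$type == "distractor")))
  invisible(x)
}

#' Geometry of the synthetic channel copy
#'
#' Convenience wrapper returning the validated absolute-coordinate geometry of
#' the channel in the upper (or lower) membrane of a [synth_config()] system.
#'
#' @param config a `synth_config`.
#' @param copy `"upper"` or `"lower"`.
#' @return a `channel_geometry`.
#' @export
synth_geometry <- function(config, copy = c("upper", "lower")) {
  copy <- match.arg(copy)
  gcfg <- config$geometry
  oz <- if (copy == "upper") config$membrane_z[2] else config$membrane_z[1]
  gcfg$axis_origin <- c(config$box[1:2] / 2, oz)
  build_geometry(gcfg)
}
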