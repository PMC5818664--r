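# Ion occupancy, potential of mean force by Boltzmann inversion, hydration
# numbers and S_side coordination states.

#' Ion occupancy histogram over channel-frame coordinates
#'
#' Bins the axial (z, relative to the SF centre) and radial coordinates of
#' every selected ion in every frame into a 2D (z, r) histogram.  Half-open
#' bins `[lo, hi)`; samples outside the grid are not counted.
#'
#' @param trajectory a `permeon_trajectory`.
#' @param geometry a `channel_geometry`.
#' @param species ion species to histogram.
#' @param z_edges,r_edges bin edges (A) in channel-frame coordinates.
#' @return object of class `pmf_grid`: list with `z_edges`, `r_edges`,
#'   `counts` (nz x nr matrix), `n_samples` (ions x frames presented) and
#'   `n_binned`.
#' @export
occupancy_histogram <- function(trajectory, geometry, species = c("K", "NA", "RB"),
                                z_edges = seq(-20, 16, by = 0.5),
                                r_edges = seq(0, 12, by = 0.5)) {
  p <- trajectory$particles
  ids <- p$id[p$species %in% species]
  nz <- length(z_edges) - 1; nr <- length(r_edges) - 1
  counts <- matrix(0L, nz, nr)
  n_samples <- 0L
  for (id in ids) {
    cc <- channel_coords(particle_track(trajectory, id), geometry,
                         box = trajectory$box)
    n_samples <- n_samples + nrow(cc)
    iz <- findInterval(cc$s, z_edges)
    ir <- findInterval(cc$r, r_edges)
    ok <- iz >= 1 & iz <= nz & ir >= 1 & ir <= nr &
      cc$s < z_edges[nz + 1] & cc$r < r_edges[nr + 1]
    if (any(ok)) {
      tab <- table(factor(iz[ok], levels = 1:nz), factor(ir[ok], levels = 1:nr))
      counts <- counts + unclass(tab)
    }
  }
  structure(list(z_edges = z_edges, r_edges = r_edges, counts = counts,
                 n_samples = n_samples, n_binned = sum(counts)),
            class = "pmf_grid")
}

#' Mean per-site ion occupancy
#'
#' Integrates the occupancy over an axial window centred on each named filter
#' site plane (within the SF radius) and divides by the number of frames,
#' giving the average number of ions resident at the site(s).
#'
#' @param trajectory a `permeon_trajectory`.
#' @param geometry a `channel_geometry`.
#' @param species ion species to count.
#' @param sites site-plane labels, e.g. `c("S3", "S4")`.
#' @param half_width half-width of each site window (A).
#' @return named numeric vector of mean occupancies, plus a `"total"` entry
#'   for the union of the windows.
#' @export
site_occupancy <- function(trajectory, geometry, species = c("K", "NA", "RB"),
                           sites = c("S3", "S4"), half_width = 1.75) {
  p <- trajectory$particles
  ids <- p$id[p$species %in% species]
  nf <- n_frames(trajectory)
  per_site <- setNames(numeric(length(sites)), sites)
  in_any <- 0
  for (id in ids) {
    cc <- channel_coords(particle_track(trajectory, id), geometry,
                         box = trajectory$box)
    inside_r <- cc$r <= geometry$sf_radius
    any_site <- rep(FALSE, nf)
    for (s in sites) {
      zc <- geometry$site_planes[[s]]
      if (is.null(zc)) stop("unknown site plane: ", s)
      hit <- inside_r & abs(cc$s - zc) <= half_width
      per_site[s] <- per_site[s] + sum(hit)
      any_site <- any_site | hit
    }
    in_any <- in_any + sum(any_site)
  }
  c(per_site / nf, total = in_any / nf)
}

#' Potential of mean force by Boltzmann inversion
#'
#' `w = -kB T ln(p / p_ref)` with `p` the normalised occupancy and `p_ref`
#' the maximum-density bin, so the reference bin has `w = 0` and all reported
#' free energies (barriers) are positive.  Zero-count bins are masked
#' (`NA`), never imputed.
#'
#' @param counts a `pmf_grid` from [occupancy_histogram()], or a bare numeric
#'   vector/matrix of counts.
#' @param temperature temperature in K (default 300, the simulation value).
#' @return for a `pmf_grid` input, the grid with elements `w` (kJ/mol) and
#'   `temperature` added; for bare counts, an object of the same shape.
#' @export
pmf_from_occupancy <- function(counts, temperature = 300) {
  grid <- NULL
  if (inherits(counts, "pmf_grid")) { grid <- counts; counts <- grid$counts }
  if (all(counts == 0)) stop("all-zero histogram: no occupancy to invert")
  if (any(counts < 0)) stop("negative counts")
  p <- counts / sum(counts)
  w <- -.kB_kJmol * temperature * log(p / max(p))
  w[counts == 0] <- NA_real_
  if (!is.null(grid)) {
    grid$w <- w
    grid$temperature <- temperature
    grid
  } else w
}

#' Hydration number of an ion
#'
#' Number of water oxygens within the species' first-shell cutoff of the ion.
#' Default cutoffs are standard first RDF minima: Na-O 3.1 A, K-O 3.5 A.
#'
#' @param trajectory a `permeon_trajectory`.
#' @param ion_id particle id of the ion.
#' @param frames frame indices (default: all frames).
#' @param cutoffs named cutoff vector in A per species.
#' @return integer vector of hydration numbers, one per requested frame.
#' @export
hydration_number <- function(trajectory, ion_id, frames = NULL,
                             cutoffs = c("NA" = 3.1, K = 3.5, RB = 3.6)) {
  p <- trajectory$particles
  i <- match(ion_id, p$id)
  if (is.na(i)) stop("unknown ion id: ", ion_id)
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  cutoff <- cutoffs[[p$species[i]]] %||% 3.5
  widx <- which(p$species == "WATER_O")
  vapply(frames, function(f) {
    if (!length(widx)) return(0L)
    ion <- trajectory$coords[i, , f]
    wz <- matrix(trajectory$coords[widx, , f], ncol = 3)
    sum(rowSums(sweep(wz, 2, ion)^2) <= cutoff^2)
  }, integer(1))
}

#' S_side coordination state of an ion
#'
#' Counts the protein oxygens of the S_side coordinating sets (D66/F69
#' backbone carbonyls, S70 or neighbouring-subunit D66 side-chain oxygen)
#' and the water oxygens within the cutoff of the ion at one frame.
#' Coordination states are distinguished by the `(n_protein_O, n_water_O)`
#' signature.
#'
#' @param trajectory a `permeon_trajectory`.
#' @param ion_id ion particle id.
#' @param frame frame index.
#' @param geometry a `channel_geometry` (supplies `s_side_atoms`).
#' @param cutoffs named ion-oxygen cutoffs (A).
#' @return list with `frame_time`, `ion_id`, `n_protein_O`, `n_water_O` and
#'   `contributing_atoms` (data.frame subunit/resno/atom).
#' @export
coordination_state <- function(trajectory, ion_id, frame, geometry,
                               cutoffs = c("NA" = 3.2, K = 3.6, RB = 3.8)) {
  p <- trajectory$particles
  i <- match(ion_id, p$id)
  if (is.na(i)) stop("unknown ion id: ", ion_id)
  cutoff <- cutoffs[[p$species[i]]] %||% 3.5
  ion <- trajectory$coords[i, , frame]
  sel_all <- unique(do.call(rbind, geometry$s_side_atoms))
  pid <- paste(p$subunit, p$resno, p$atom)
  idx <- which(p$species == "PROTEIN_ATOM" &
               pid %in% paste(sel_all$subunit, sel_all$resno, sel_all$atom))
  contrib <- NULL
  n_prot <- 0L
  if (length(idx)) {
    pz <- matrix(trajectory$coords[idx, , frame], ncol = 3)
    hit <- rowSums(sweep(pz, 2, ion)^2) <= cutoff^2
    n_prot <- sum(hit)
    contrib <- p[idx[hit], c("subunit", "resno", "atom")]
  }
  n_wat <- hydration_number(trajectory, ion_id, frames = frame,
                            cutoffs = setNames(cutoff, p$species[i]))
  list(frame_time = trajectory$times[frame], ion_id = ion_id,
       n_protein_O = n_prot, n_water_O = as.integer(n_wat),
       contributing_atoms = contrib)
}
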