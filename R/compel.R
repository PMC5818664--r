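# Two-compartment bookkeeping for the computational-electrophysiology setup:
# compartment assignment, per-species ion-count imbalance, and the
# deterministic ion/water position-swap algorithm that restores a target
# imbalance.

#' Assign particles to compartments a / b
#'
#' Compartment a is the open axial slab strictly between the two membrane
#' midplanes; b is the (periodic) complement.  A particle exactly at a
#' midplane coordinate belongs to b.
#'
#' @param z numeric vector of z coordinates, or a `permeon_frame`.
#' @param midplanes two distinct membrane midplane z values.
#' @return character vector of `"a"` / `"b"`.
#' @export
assign_compartments <- function(z, midplanes) {
  if (inherits(z, "permeon_frame")) z <- z$xyz[, 3]
  if (length(midplanes) != 2 || midplanes[1] == midplanes[2])
    stop("midplanes must be two distinct z values")
  m <- sort(midplanes)
  ifelse(z > m[1] & z < m[2], "a", "b")
}

#' Per-frame compartment ion counts and imbalance
#'
#' @param trajectory a `permeon_trajectory`.
#' @param midplanes two membrane midplane z values.
#' @param species species to count (default: all ion species present).
#' @param frames optional frame indices.
#' @return data.frame with one row per frame and species: `time_ps`,
#'   `species`, `n_a`, `n_b`, `delta_n` (a minus b), plus the frame's net
#'   charge difference `delta_q`.
#' @export
compartment_counts <- function(trajectory, midplanes, species = NULL,
                               frames = NULL) {
  p <- trajectory$particles
  if (is.null(species)) species <- intersect(ION_SPECIES, unique(p$species))
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  ion_idx <- which(p$species %in% species)
  out <- list()
  for (i in frames) {
    z <- trajectory$coords[, 3, i]
    comp <- assign_compartments(z, midplanes)
    dq <- sum(p$charge[comp == "a"]) - sum(p$charge[comp == "b"])
    for (sp in species) {
      sel <- ion_idx[p$species[ion_idx] == sp]
      na <- sum(comp[sel] == "a"); nb <- sum(comp[sel] == "b")
      out[[length(out) + 1]] <- data.frame(
        time_ps = trajectory$times[i], species = sp, n_a = na, n_b = nb,
        delta_n = na - nb, delta_q = dq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Axial distance to a compartment centre under periodic wrap.
.wrap_dist <- function(z, center, L) {
  d <- abs(z - center) %% L
  pmin(d, L - d)
}

#' Swap instructions restoring a target compartment imbalance
#'
#' Computes the minimal set of ion/water position exchanges that brings
#' `delta_n = n_a - n_b` for `species` to `target_delta_n`.  Each swap
#' exchanges the positions of one ion in the surplus compartment and one
#' water in the deficit compartment and therefore changes `delta_n` by 2, so
#' `ceiling(|current - target| / 2)` swaps are returned (an odd difference
#' can only reach the adjacent parity-consistent value).  Candidates are
#' chosen deterministically: the surplus-compartment ion closest to its bulk
#' centre and the deficit-compartment water closest to its bulk centre, ties
#' broken by lowest particle id.
#'
#' @param frame a `permeon_frame` (see [get_frame()]).
#' @param target_delta_n desired `n_a - n_b` (default 2, the standard
#'   two-ion imbalance).
#' @param species permeant species to control.
#' @param midplanes two membrane midplane z values.
#' @return data.frame with columns `ion_id`, `water_id` (possibly 0 rows).
#' @export
maintain_imbalance <- function(frame, target_delta_n = 2, species = "K",
                               midplanes) {
  stopifnot(inherits(frame, "permeon_frame"))
  p <- frame$particles
  z <- frame$xyz[, 3]
  L <- frame$box[3]
  comp <- assign_compartments(z, midplanes)
  m <- sort(midplanes)
  center_a <- mean(m)
  center_b <- (m[2] + (m[1] + L)) / 2 %% L
  ions <- which(p$species == species)
  cur <- sum(comp[ions] == "a") - sum(comp[ions] == "b")
  diff <- target_delta_n - cur
  n_swaps <- ceiling(abs(diff) / 2)
  if (n_swaps == 0)
    return(data.frame(ion_id = integer(), water_id = integer()))

  surplus <- if (diff > 0) "b" else "a"      # compartment that must give up ions
  deficit <- if (diff > 0) "a" else "b"
  center <- c(a = center_a, b = center_b)
  ion_cand <- ions[comp[ions] == surplus]
  wat <- which(p$species == "WATER_O")
  wat_cand <- wat[comp[wat] == deficit]
  if (length(ion_cand) < n_swaps)
    stop("not enough ", species, " ions in compartment ", surplus,
         " (need ", n_swaps, ", have ", length(ion_cand), ")")
  if (length(wat_cand) < n_swaps)
    stop("not enough waters in compartment ", deficit,
         " (need ", n_swaps, ", have ", length(wat_cand), ")")
  ion_ord <- ion_cand[order(.wrap_dist(z[ion_cand], center[[surplus]], L),
                            p$id[ion_cand])]
  wat_ord <- wat_cand[order(.wrap_dist(z[wat_cand], center[[deficit]], L),
                            p$id[wat_cand])]
  data.frame(ion_id = p$id[ion_ord[seq_len(n_swaps)]],
             water_id = p$id[wat_ord[seq_len(n_swaps)]])
}

#' Apply swap instructions to a frame
#'
#' Exchanges the positions of each listed ion/water pair; particle identities
#' and counts are untouched.
#'
#' @param frame a `permeon_frame`.
#' @param swaps data.frame from [maintain_imbalance()].
#' @return the modified `permeon_frame`.
#' @export
apply_swaps <- function(frame, swaps) {
  for (r in seq_len(nrow(swaps))) {
    i <- match(swaps$ion_id[r], frame$particles$id)
    j <- match(swaps$water_id[r], frame$particles$id)
    tmp <- frame$xyz[i, ]
    frame$xyz[i, ] <- frame$xyz[j, ]
    frame$xyz[j, ] <- tmp
  }
  frame
}
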