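# Selectivity-filter conformer diagnostics: per-subunit carbonyl-flip
# classification, opposing-carbonyl distances d1/d2, hydrogen-bond detection
# and amide-proton contact maps.

.carbonyl_idx <- function(particles, subunit, resno) {
  list(C = which(particles$species == "PROTEIN_ATOM" & particles$subunit == subunit &
                   particles$resno == resno & particles$atom == "C"),
       O = which(particles$species == "PROTEIN_ATOM" & particles$subunit == subunit &
                   particles$resno == resno & particles$atom == "O"))
}

#' Classify the carbonyl-flip state of one subunit
#'
#' Measures the angle between the C=O vector of the chosen residue and the
#' crystal reference direction (by default the inward radial direction from
#' the carbonyl carbon toward the pore axis).  Labels: `crystal` below 60
#' degrees, `flipped_T62` above 120 degrees, `other` in between.
#'
#' @param trajectory a `permeon_trajectory` carrying carbonyl pseudo-atoms.
#' @param subunit subunit label (A-D).
#' @param resno residue number carrying the flip (default 62).
#' @param geometry a `channel_geometry` (defines the pore axis for the
#'   default reference).
#' @param reference_direction optional explicit reference 3-vector(s); a
#'   single vector or an n_frames x 3 matrix.
#' @param frames frame indices (default: all).
#' @return data.frame with `frame`, `time_ps`, `angle_deg`, `label`.
#' @export
classify_flip <- function(trajectory, subunit, resno = 62, geometry = NULL,
                          reference_direction = NULL, frames = NULL) {
  p <- trajectory$particles
  idx <- .carbonyl_idx(p, subunit, resno)
  if (!length(idx$C) || !length(idx$O))
    stop("no carbonyl C/O pseudo-atoms for subunit ", subunit, " residue ", resno)
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  Cp <- matrix(trajectory$coords[idx$C[1], , frames], ncol = 3, byrow = TRUE)
  Op <- matrix(trajectory$coords[idx$O[1], , frames], ncol = 3, byrow = TRUE)
  co <- Op - Cp
  if (is.null(reference_direction)) {
    if (is.null(geometry)) stop("supply either geometry or reference_direction")
    ax <- geometry$axis; orig <- geometry$axis_origin
    rel <- sweep(Cp, 2, orig)
    s <- as.vector(rel %*% ax)
    perp <- rel - outer(s, ax)
    ref <- -perp / sqrt(rowSums(perp^2))     # inward radial (crystal direction)
  } else {
    ref <- if (is.null(dim(reference_direction)))
      matrix(reference_direction, nrow = length(frames), ncol = 3, byrow = TRUE)
    else reference_direction
    ref <- ref / sqrt(rowSums(ref^2))
  }
  cosang <- rowSums(co * ref) / sqrt(rowSums(co^2))
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang) * 180 / pi
  label <- ifelse(ang < 60, "crystal", ifelse(ang > 120, "flipped_T62", "other"))
  data.frame(frame = frames, time_ps = trajectory$times[frames],
             angle_deg = ang, label = label, stringsAsFactors = FALSE)
}

#' Per-subunit conformer timeline with temporal hysteresis
#'
#' Applies [classify_flip()] to every subunit and optionally smooths flicker:
#' runs of a label shorter than `hysteresis_frames` that are flanked by a
#' common label are absorbed into it.
#'
#' @inheritParams classify_flip
#' @param hysteresis_frames minimum run length kept as its own state
#'   (default 5 frames; isolated jitter-induced mislabels are absorbed).
#' @return data.frame (frames x subunits wide): `frame`, `time_ps`, then one
#'   label column per subunit; class `conformer_timeline`.
#' @export
conformer_timeline <- function(trajectory, resno = 62, geometry = NULL,
                               hysteresis_frames = 5) {
  subs <- sort(unique(stats::na.omit(trajectory$particles$subunit)))
  out <- data.frame(frame = seq_len(n_frames(trajectory)),
                    time_ps = trajectory$times)
  for (su in subs) {
    lab <- classify_flip(trajectory, su, resno = resno, geometry = geometry)$label
    if (hysteresis_frames > 1) {
      r <- rle(lab)
      n <- length(r$lengths)
      if (n >= 3) for (k in 2:(n - 1)) {
        if (r$lengths[k] < hysteresis_frames &&
            identical(r$values[k - 1], r$values[k + 1]))
          r$values[k] <- r$values[k + 1]
      }
      lab <- inverse.rle(r)
    }
    out[[su]] <- lab
  }
  structure(out, class = c("conformer_timeline", "data.frame"))
}

#' Opposing-carbonyl distances d1 (T63) and d2 (V64)
#'
#' Euclidean distances between the designated carbonyl oxygens of paired
#' subunits across the pore, per frame.  The default pairing follows the
#' opposing-subunit convention `(A,B)` and `(C,D)`; the diagonal pairing can
#' be supplied instead.
#'
#' @param trajectory a `permeon_trajectory` with carbonyl pseudo-atoms.
#' @param pairing list of two character pairs, e.g.
#'   `list(c("A","B"), c("C","D"))`.
#' @param frames frame indices (default: all).
#' @return data.frame with `frame`, `time_ps`, then `d1_<pair>` and
#'   `d2_<pair>` columns (A).
#' @export
opposing_distance_timeline <- function(trajectory,
                                       pairing = list(c("A", "B"), c("C", "D")),
                                       frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  p <- trajectory$particles
  out <- data.frame(frame = frames, time_ps = trajectory$times[frames])
  for (pr in pairing) {
    for (res in c(63, 64)) {
      i1 <- .carbonyl_idx(p, pr[1], res)$O
      i2 <- .carbonyl_idx(p, pr[2], res)$O
      if (!length(i1) || !length(i2))
        stop("missing carbonyl O for residue ", res, " in pairing ",
             paste(pr, collapse = "-"))
      a <- matrix(trajectory$coords[i1[1], , frames], ncol = 3, byrow = TRUE)
      b <- matrix(trajectory$coords[i2[1], , frames], ncol = 3, byrow = TRUE)
      d <- sqrt(rowSums((a - b)^2))
      nm <- paste0(if (res == 63) "d1_" else "d2_", paste(pr, collapse = ""))
      out[[nm]] <- d
    }
  }
  out
}

#' Opposing-carbonyl distances of a static structure
#'
#' @param structure an `sf_structure` (e.g. from [gen_sf_scaffold()]).
#' @param pairing list of two subunit pairs.
#' @return data.frame with columns `pair`, `d1`, `d2` (A).
#' @export
opposing_distances <- function(structure,
                               pairing = list(c("A", "B"), c("C", "D"))) {
  getO <- function(ch, res) {
    r <- structure[structure$chain == ch & structure$resno == res &
                     structure$atom == "O", c("x", "y", "z")]
    if (nrow(r) == 0) stop("missing carbonyl O: chain ", ch, " residue ", res)
    as.numeric(r[1, ])
  }
  do.call(rbind, lapply(pairing, function(pr) {
    data.frame(pair = paste(pr, collapse = ""),
               d1 = sqrt(sum((getO(pr[1], 63) - getO(pr[2], 63))^2)),
               d2 = sqrt(sum((getO(pr[1], 64) - getO(pr[2], 64))^2)))
  }))
}

#' Detect backbone hydrogen bonds in a structure
#'
#' Backbone amide donors (N-H) against backbone carbonyl acceptors (C=O),
#' using the geometric criteria H...O <= `dist_cutoff` and N-H...O angle >=
#' `angle_min` degrees.
#'
#' @param structure an `sf_structure` with amide H atoms (see
#'   [reconstruct_amide_h()] if absent).
#' @param dist_cutoff H-to-acceptor distance cutoff (A).
#' @param angle_min minimum donor angle (degrees).
#' @return data.frame with donor/acceptor chain + residue, `h_to_acceptor`
#'   (A) and `angle` (degrees).
#' @export
detect_hbonds <- function(structure, dist_cutoff = 2.5, angle_min = 150) {
  don <- structure[structure$atom == "H", ]
  dn  <- structure[structure$atom == "N", ]
  acc <- structure[structure$atom == "O", ]
  out <- list()
  for (i in seq_len(nrow(don))) {
    H <- as.numeric(don[i, c("x", "y", "z")])
    Nrow <- dn[dn$chain == don$chain[i] & dn$resno == don$resno[i], ]
    if (nrow(Nrow) == 0) next
    N <- as.numeric(Nrow[1, c("x", "y", "z")])
    for (j in seq_len(nrow(acc))) {
      if (acc$chain[j] == don$chain[i] && acc$resno[j] == don$resno[i]) next
      O <- as.numeric(acc[j, c("x", "y", "z")])
      d <- sqrt(sum((O - H)^2))
      if (d > dist_cutoff) next
      v1 <- N - H; v2 <- O - H
      ang <- acos(pmin(pmax(sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang < angle_min) next
      out[[length(out) + 1]] <- data.frame(
        donor_chain = don$chain[i], donor_resno = don$resno[i],
        acceptor_chain = acc$chain[j], acceptor_resno = acc$resno[j],
        h_to_acceptor = d, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      acceptor_chain = character(), acceptor_resno = integer(),
                      h_to_acceptor = numeric(), angle = numeric()))
  do.call(rbind, out)
}

#' Amide-proton contact map
#'
#' All same-chain residue pairs whose amide protons are closer than `cutoff`
#' (strict inequality), the geometric analogue of an NHHN cross-peak whose
#' intensity falls off beyond about 4 A.
#'
#' @param structure an `sf_structure` with amide H atoms.
#' @param cutoff H-H distance cutoff (A).
#' @return data.frame with `chain`, `resno_i`, `resno_j` (i < j), `dist`.
#' @export
amide_contact_map <- function(structure, cutoff = 4.0) {
  hs <- structure[structure$atom == "H", ]
  out <- list()
  for (ch in unique(hs$chain)) {
    sub <- hs[hs$chain == ch, ]
    sub <- sub[order(sub$resno), ]
    n <- nrow(sub)
    if (n < 2) next
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((as.numeric(sub[i, c("x", "y", "z")]) -
                       as.numeric(sub[j, c("x", "y", "z")]))^2))
      if (d < cutoff)
        out[[length(out) + 1]] <- data.frame(
          chain = ch, resno_i = sub$resno[i], resno_j = sub$resno[j],
          dist = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), resno_i = integer(),
                      resno_j = integer(), dist = numeric()))
  do.call(rbind, out)
}
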