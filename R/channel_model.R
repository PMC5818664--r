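# Channel coordinate system, regions and filter-site geometry.
#
# Conventions: lengths in Angstrom, times in ps, +axis (default +z) points
# extracellular.  All axial intervals are half-open [lo, hi).

#' Default S_side coordinating-atom selectors
#'
#' One entry per subunit.  The off-axis S_side binding site at the filter's
#' side entry is coordinated by the backbone carbonyl oxygens of D66 and F69
#' plus a side-chain oxygen from either S70 of the same subunit or D66 of the
#' neighbouring subunit.
#'
#' @return named list (subunits A-D) of data.frames with columns
#'   `subunit`, `resno`, `atom`.
#' @export
default_s_side_atoms <- function() {
  out <- lapply(SUBUNITS, function(su) {
    data.frame(
      subunit = c(su, su, su, .neighbor_subunit[[su]]),
      resno   = c(66L, 69L, 70L, 66L),
      atom    = c("O", "O", "OG", "OD1"),
      stringsAsFactors = FALSE
    )
  })
  names(out) <- SUBUNITS
  out
}

#' Default channel-geometry configuration
#'
#' Axial region bounds are relative to the selectivity-filter (SF) centre at
#' the axis origin.  Site planes: B34 is the T63 carbonyl-oxygen plane, B23
#' the V64 plane (B34 closer to the cavity); S3/S4 are the adjacent cage
#' positions.  The channel literature gives no numeric extents for these
#' regions, so all values here are engineering defaults and fully overridable.
#'
#' @param axis_origin 3-vector, absolute position of the SF centre (Angstrom).
#' @return a plain list suitable for [build_geometry()].
#' @export
default_geometry_config <- function(axis_origin = c(0, 0, 0)) {
  list(
    axis = c(0, 0, 1),
    axis_origin = axis_origin,
    region_bounds = list(
      intracellular_bulk = c(-55, -18),
      cavity             = c(-18, -6),
      sf                 = c(-6, 6),
      vestibule          = c(6, 12),
      extracellular_bulk = c(12, 40)
    ),
    sf_radius = 4.5,
    side_portal_radius_min = 5.5,
    site_planes = list(S4 = -3.5, B34 = -2, S3 = -0.5, B23 = 1, S2 = 2.5, S1 = 4),
    s_side_atoms = default_s_side_atoms()
  )
}

.region_bound_names <- c("intracellular_bulk", "cavity", "sf", "vestibule",
                         "extracellular_bulk")

#' Build and validate a channel geometry
#'
#' Validates a geometry configuration (see [default_geometry_config()] for the
#' key names) and returns a `channel_geometry` object.  Checks: unit-normalises
#' the axis; region intervals must be ordered, contiguous and non-overlapping;
#' radii positive; the B34 site plane must lie below B23 (closer to the
#' cavity).
#'
#' @param config named list with elements `axis`, `axis_origin`,
#'   `region_bounds`, `sf_radius`, `side_portal_radius_min`, `site_planes`,
#'   and optionally `s_side_atoms`.
#' @return object of class `channel_geometry`.
#' @export
build_geometry <- function(config = default_geometry_config()) {
  stopifnot(is.list(config))
  axis <- as.numeric(config$axis)
  if (length(axis) != 3 || !all(is.finite(axis)) || sum(axis^2) == 0)
    stop("geometry config error: 'axis' must be a finite non-zero 3-vector")
  axis <- axis / sqrt(sum(axis^2))
  origin <- as.numeric(config$axis_origin)
  if (length(origin) != 3 || !all(is.finite(origin)))
    stop("geometry config error: 'axis_origin' must be a finite 3-vector")

  rb <- config$region_bounds
  if (!identical(names(rb), .region_bound_names))
    stop("geometry config error: region_bounds must be exactly, in order: ",
         paste(.region_bound_names, collapse = ", "))
  bounds <- t(vapply(rb, function(b) {
    b <- as.numeric(b)
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("geometry config error: each region bound must be c(lo, hi) with lo < hi")
    b
  }, numeric(2)))
  for (i in seq_len(nrow(bounds) - 1)) {
    if (abs(bounds[i, 2] - bounds[i + 1, 1]) > 1e-9)
      stop("geometry config error: region intervals must be contiguous (",
           .region_bound_names[i], " ends at ", bounds[i, 2], " but ",
           .region_bound_names[i + 1], " starts at ", bounds[i + 1, 1], ")")
  }

  sf_radius <- as.numeric(config$sf_radius)
  portal <- as.numeric(config$side_portal_radius_min)
  if (!is.finite(sf_radius) || sf_radius <= 0)
    stop("geometry config error: sf_radius must be > 0")
  if (!is.finite(portal) || portal < 0)
    stop("geometry config error: side_portal_radius_min must be >= 0")

  sp <- lapply(config$site_planes, as.numeric)
  need <- c("S4", "B34", "S3", "B23", "S2", "S1")
  if (!all(need %in% names(sp)))
    stop("geometry config error: site_planes must name ", paste(need, collapse = ", "))
  if (!(sp$B34 < sp$B23))
    stop("geometry config error: site plane B34 must lie below B23 (closer to the cavity)")

  structure(list(
    axis = axis, axis_origin = origin,
    region_bounds = rb_to_matrix(rb),
    sf_radius = sf_radius, side_portal_radius_min = portal,
    site_planes = sp,
    s_side_atoms = if (is.null(config$s_side_atoms)) default_s_side_atoms()
                   else config$s_side_atoms
  ), class = "channel_geometry")
}

rb_to_matrix <- function(rb) {
  m <- t(vapply(rb, as.numeric, numeric(2)))
  colnames(m) <- c("lo", "hi")
  m
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("<channel_geometry>\n")
  cat("  axis:", paste(signif(x$axis, 3), collapse = " "),
      " origin:", paste(signif(x$axis_origin, 4), collapse = " "), "\n")
  b <- x$region_bounds
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-20s [%g, %g)\n", rownames(b)[i], b[i, 1], b[i, 2]))
  cat(sprintf("  sf_radius %g A, side portal annulus (%g, %g] A\n",
              x$sf_radius, x$sf_radius, x$sf_radius + x$side_portal_radius_min))
  invisible(x)
}

#' Axial and radial channel-frame coordinates of positions
#'
#' Projects absolute positions onto the channel axis, optionally wrapping the
#' axial displacement into `[-L/2, L/2)` for a periodic box (wrap is along the
#' axis with period equal to the box extent projected onto it).
#'
#' @param positions numeric 3-vector or n x 3 matrix (Angstrom).
#' @param geometry a `channel_geometry`.
#' @param box optional 3-vector of box edge lengths for periodic wrapping.
#' @return data.frame with columns `s` (axial, Angstrom, relative to the
#'   origin) and `r` (radial distance from the axis).
#' @export
channel_coords <- function(positions, geometry, box = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  if (ncol(positions) != 3) stop("positions must be a 3-vector or an n x 3 matrix")
  if (!all(is.finite(positions))) stop("input error: non-finite position")
  rel <- sweep(positions, 2, geometry$axis_origin)
  s <- as.vector(rel %*% geometry$axis)
  if (!is.null(box)) {
    L <- sum(abs(geometry$axis * box))
    s <- ((s + L / 2) %% L) - L / 2
  }
  perp <- rel - outer(s, geometry$axis)
  r <- sqrt(rowSums(perp^2))
  data.frame(s = s, r = r)
}

#' Assign channel regions to positions
#'
#' Maps each position to exactly one region label.  Axial intervals are
#' half-open `[lo, hi)`.  Within the SF axial span, radial distance
#' `<= sf_radius` gives `SF`; within the vestibule span it gives `VESTIBULE`.
#' Over both spans, the annulus `(sf_radius, sf_radius +
#' side_portal_radius_min]` is labelled `SIDE_PORTAL`.  Cavity positions
#' further than the portal annulus from the axis, and anything else inside the
#' channel's axial extent that fits no region, are `MEMBRANE_OTHER`.
#'
#' @inheritParams channel_coords
#' @return factor with levels [REGION_LEVELS], one label per position.
#' @export
assign_region <- function(positions, geometry, box = NULL) {
  cc <- channel_coords(positions, geometry, box = box)
  s <- cc$s; r <- cc$r
  b <- geometry$region_bounds
  lab <- rep("MEMBRANE_OTHER", length(s))
  inside <- function(region) s >= b[region, "lo"] & s < b[region, "hi"]
  r_portal_max <- geometry$sf_radius + geometry$side_portal_radius_min

  lab[inside("intracellular_bulk")] <- "INTRACELLULAR_BULK"
  lab[inside("extracellular_bulk")] <- "EXTRACELLULAR_BULK"
  cav <- inside("cavity")
  lab[cav & r <= r_portal_max] <- "CAVITY"
  in_sf <- inside("sf")
  lab[in_sf & r <= geometry$sf_radius] <- "SF"
  in_ves <- inside("vestibule")
  lab[in_ves & r <= geometry$sf_radius] <- "VESTIBULE"
  portal <- (in_sf | in_ves) & r > geometry$sf_radius & r <= r_portal_max
  lab[portal] <- "SIDE_PORTAL"
  factor(lab, levels = REGION_LEVELS)
}

#' Per-frame region labels for selected particles of a trajectory
#'
#' @param trajectory a `permeon_trajectory`.
#' @param geometry a `channel_geometry`.
#' @param ids particle ids to label (default: all ions).
#' @param wrap logical, apply periodic axial wrapping using the trajectory box.
#' @return integer matrix (frames x particles) of indices into
#'   [REGION_LEVELS]; particle ids as column names.
#' @export
region_timeline <- function(trajectory, geometry, ids = NULL, wrap = TRUE) {
  p <- trajectory$particles
  if (is.null(ids)) ids <- p$id[p$species %in% c("K", "NA", "RB", "CL")]
  idx <- match(ids, p$id)
  if (anyNA(idx)) stop("unknown particle id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  nf <- length(trajectory$times)
  out <- matrix(NA_integer_, nrow = nf, ncol = length(ids),
                dimnames = list(NULL, as.character(ids)))
  box <- if (wrap) trajectory$box else NULL
  for (j in seq_along(idx)) {
    xyz <- t(trajectory$coords[idx[j], , ])        # frames x 3
    out[, j] <- as.integer(assign_region(xyz, geometry, box = box))
  }
  out
}
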