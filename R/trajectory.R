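# Trajectory container: typed particles + a (particles x 3 x frames) array.

#' Construct a trajectory object
#'
#' The in-memory contract shared by all analyses: a particle table, a frame
#' time vector (ps), orthorhombic box edge lengths (Angstrom) and a dense
#' coordinate array.  Coordinates are expected to be wrapped into `[0, box)`
#' per axis; [gen_trajectory()] and [read_trajectory()] do this at ingest.
#'
#' @param particles data.frame with columns `id` (unique integer), `species`
#'   (see [SPECIES_LEVELS]), `charge`, and optional `subunit`, `resno`,
#'   `atom` (NA where not applicable).
#' @param coords numeric array of dim `c(nrow(particles), 3, n_frames)`.
#' @param times numeric vector of frame times in ps.
#' @param box numeric 3-vector of box edge lengths in Angstrom.
#' @param wrap wrap coordinates into `[0, box)` (default TRUE).
#' @return object of class `permeon_trajectory`.
#' @export
permeon_trajectory <- function(particles, coords, times, box, wrap = TRUE) {
  req <- c("id", "species", "charge")
  if (!all(req %in% names(particles)))
    stop("particles must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(particles$id)) stop("particle ids must be unique")
  if (!all(particles$species %in% SPECIES_LEVELS))
    stop("unknown species in particle table")
  for (col in c("subunit", "resno", "atom"))
    if (is.null(particles[[col]])) particles[[col]] <- NA
  if (length(dim(coords)) != 3 ||
      dim(coords)[1] != nrow(particles) || dim(coords)[2] != 3 ||
      dim(coords)[3] != length(times))
    stop("coords must be an array of dim c(n_particles, 3, n_frames)")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths")
  if (wrap) for (k in 1:3) coords[, k, ] <- coords[, k, ] %% box[k]
  structure(list(particles = particles, coords = coords,
                 times = as.numeric(times), box = box),
            class = "permeon_trajectory")
}

#' @export
print.permeon_trajectory <- function(x, ...) {
  tab <- table(x$particles$species)
  cat(sprintf("<permeon_trajectory> %d particles, %d frames, box %s A\n",
              nrow(x$particles), length(x$times),
              paste(signif(x$box, 4), collapse = " x ")))
  cat("  time range:", signif(min(x$times), 6), "-", signif(max(x$times), 6), "ps\n")
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames / particles
#' @param trajectory a `permeon_trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$times)

#' @rdname n_frames
#' @export
n_particles <- function(trajectory) nrow(trajectory$particles)

#' Extract one frame
#'
#' @param trajectory a `permeon_trajectory`.
#' @param i frame index (1-based).
#' @return list with `time` (ps), `box`, `particles` and an n x 3 `xyz`
#'   matrix; class `permeon_frame`.
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(length(i) == 1, i >= 1, i <= n_frames(trajectory))
  xyz <- trajectory$coords[, , i, drop = FALSE]
  dim(xyz) <- dim(xyz)[1:2]
  structure(list(time = trajectory$times[i], box = trajectory$box,
                 particles = trajectory$particles, xyz = xyz),
            class = "permeon_frame")
}

#' Positions of one particle across frames
#'
#' @param trajectory a `permeon_trajectory`.
#' @param id particle id.
#' @return n_frames x 3 matrix.
#' @export
particle_track <- function(trajectory, id) {
  idx <- match(id, trajectory$particles$id)
  if (is.na(idx)) stop("unknown particle id: ", id)
  out <- t(trajectory$coords[idx, , ])
  if (n_frames(trajectory) == 1) dim(out) <- c(1, 3)
  out
}
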