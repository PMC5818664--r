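# Plain-text columnar trajectory format (the contract format), geometry
# configuration files, and tabular export helpers.
#
# Layout of the columnar format:
#   # permeon trajectory v1
#   # box <Lx> <Ly> <Lz>
#   # n_frames <F> n_particles <P>
#   #P <id> <species> <charge> <subunit|.> <resno|.> <atom|.>   (P lines)
#   frame,time_ps,id,species,x,y,z                               (header row)
#   <one row per particle per frame>
# Missing metadata is written as "."; numbers use full (%.17g) precision so a
# write/read cycle is lossless.

#' Write a trajectory in the documented columnar text format
#'
#' @param trajectory a `permeon_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  p <- trajectory$particles
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  header <- c(
    "# permeon trajectory v1",
    paste("# box", paste(sprintf("%.17g", trajectory$box), collapse = " ")),
    sprintf("# n_frames %d n_particles %d", n_frames(trajectory), n_particles(trajectory)),
    sprintf("#P %d %s %.17g %s %s %s", p$id, p$species, p$charge,
            dot(p$subunit), dot(p$resno), dot(p$atom))
  )
  nf <- n_frames(trajectory); np <- n_particles(trajectory)
  dt <- data.table::data.table(
    frame   = rep(seq_len(nf), each = np),
    time_ps = sprintf("%.17g", rep(trajectory$times, each = np)),
    id      = rep(p$id, nf),
    species = rep(p$species, nf),
    x = sprintf("%.17g", as.vector(trajectory$coords[, 1, ])),
    y = sprintf("%.17g", as.vector(trajectory$coords[, 2, ])),
    z = sprintf("%.17g", as.vector(trajectory$coords[, 3, ]))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(dt), collapse = ","), con)
  writeLines(do.call(paste, c(as.list(dt), sep = ",")), con)
  invisible(path)
}

#' Read a trajectory from the columnar text format
#'
#' Inverse of [write_trajectory()]; malformed headers or rows raise a parse
#' error naming the offending line.
#'
#' @param path input file path.
#' @return a `permeon_trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error: empty trajectory file: ", path)
  if (!identical(lines[1], "# permeon trajectory v1"))
    stop("parse error at line 1: expected '# permeon trajectory v1'")
  box <- suppressWarnings(as.numeric(strsplit(lines[2], "\\s+")[[1]][3:5]))
  if (length(box) != 3 || anyNA(box))
    stop("parse error at line 2: expected '# box Lx Ly Lz'")
  m <- regmatches(lines[3], regexec("^# n_frames (\\d+) n_particles (\\d+)$", lines[3]))[[1]]
  if (length(m) != 3) stop("parse error at line 3: expected '# n_frames F n_particles P'")
  nf <- as.integer(m[2]); np <- as.integer(m[3])

  pl <- 3 + seq_len(np)
  if (length(lines) < max(pl) || !all(startsWith(lines[pl], "#P ")))
    stop("parse error: expected ", np, " '#P' particle lines after line 3")
  undot <- function(x) { x[x == "."] <- NA_character_; x }
  ptab <- do.call(rbind, lapply(seq_along(pl), function(k) {
    f <- strsplit(sub("^#P ", "", lines[pl[k]]), "\\s+")[[1]]
    if (length(f) != 6) stop("parse error at line ", pl[k], ": malformed particle line")
    f
  }))
  particles <- data.frame(
    id = as.integer(ptab[, 1]), species = ptab[, 2],
    charge = as.numeric(ptab[, 3]), subunit = undot(ptab[, 4]),
    resno = suppressWarnings(as.integer(undot(ptab[, 5]))),
    atom = undot(ptab[, 6]), stringsAsFactors = FALSE
  )
  if (!all(particles$species %in% SPECIES_LEVELS))
    stop("parse error: unknown species in particle table")

  body_start <- max(pl) + 1
  dt <- data.table::fread(text = lines[body_start:length(lines)],
                          sep = ",", header = TRUE, na.strings = NULL,
                          colClasses = list(character = "species"))
  need <- c("frame", "time_ps", "id", "species", "x", "y", "z")
  if (!identical(names(dt), need))
    stop("parse error at line ", body_start, ": expected header ",
         paste(need, collapse = ","))
  if (nrow(dt) != nf * np)
    stop("parse error: expected ", nf * np, " data rows, found ", nrow(dt))
  ord <- order(dt$frame, match(dt$id, particles$id))
  dt <- as.data.frame(dt)[ord, ]
  coords <- array(NA_real_, dim = c(np, 3, nf))
  coords[, 1, ] <- dt$x; coords[, 2, ] <- dt$y; coords[, 3, ] <- dt$z
  times <- dt$time_ps[seq(1, nrow(dt), by = np)]
  permeon_trajectory(particles, coords, times, box, wrap = FALSE)
}

#' Read a geometry configuration file (YAML or JSON)
#'
#' Keys follow [default_geometry_config()]; missing keys fall back to the
#' defaults.  The result is validated by [build_geometry()].
#'
#' @param path path to a YAML (or JSON, a YAML subset) config file.
#' @return a `channel_geometry`.
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_geometry_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$region_bounds))
    base$region_bounds <- lapply(cfg$region_bounds, as.numeric)
  build_geometry(base)
}

#' Write the planted ground truth of a synthetic run as tabular text
#'
#' Two comma-separated files: `<stem>_crossings.csv` (one row per planted
#' crossing or distractor excursion) and `<stem>_flips.csv` (per-subunit
#' flipped intervals in ps).
#'
#' @param truth the `$truth` element of a [gen_trajectory()] result.
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_truth <- function(truth, stem) {
  paths <- c(paste0(stem, "_crossings.csv"), paste0(stem, "_flips.csv"))
  data.table::fwrite(truth$crossings, paths[1])
  data.table::fwrite(truth$flips, paths[2])
  invisible(paths)
}
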