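# End-to-end pipeline: simulate or ingest a trajectory, then run compartment
# bookkeeping, voltage, event detection, pathway classification, conductance,
# occupancy/PMF, hydration/coordination and the conformer timeline, writing a
# machine-readable JSON summary plus tabular outputs.

#' Default pipeline configuration
#'
#' @param seed RNG seed, recorded in all outputs.
#' @param outdir output directory.
#' @return nested list of pipeline parameters; override any element before
#'   passing it to [run_pipeline()].
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("permeon_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    input_trajectory = NULL,       # path to a columnar file; NULL -> simulate
    synth = list(duration_ns = 200, frame_interval_ps = 100,
                 n_ions_per_species = list(K = 16), n_waters = 20,
                 crossing_rate_inward = list(K = 40),
                 crossing_rate_outward = list(K = 20),
                 partial_entry_rate = list(K = 20),
                 side_entry_fraction = 0.2, hydration_n = 2,
                 neutralize = TRUE,
                 flip_schedule = list(A = rbind(c(50, 150)))),
    species = NULL,                # default: species with events configured
    mode = "full_crossing",
    hysteresis_ps = 100,
    voltage_bins = 80, voltage_stride = 5,
    pmf_bins = list(z = seq(-20, 16, by = 1), r = seq(0, 12, by = 1)),
    temperature = 300,
    log = TRUE
  )
}

.log <- function(cfg, ...) if (isTRUE(cfg$log)) message("[permeon] ", ...)

#' Run the full analysis pipeline
#'
#' Executes, in order: ingest (or synthesis) -> compartment counts and
#' membrane voltage -> event detection -> pathway classification ->
#' conductance -> occupancy/PMF -> hydration/coordination -> conformer
#' timeline.  Writes `summary.json` (with the seed and a config hash) and
#' comma-separated tables into `config$outdir`.  Re-running with identical
#' config and seed reproduces the outputs byte for byte.
#'
#' @param config list from [default_run_config()] (possibly modified).
#' @return the summary list, invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "ingest"
  result <- tryCatch({
    sargs <- cfg$synth
    sargs$seed <- cfg$seed
    scfg <- do.call(synth_config, sargs)
    if (!is.null(cfg$input_trajectory)) {
      .log(cfg, "reading trajectory from ", cfg$input_trajectory)
      traj <- read_trajectory(cfg$input_trajectory)
      truth <- NULL
    } else {
      .log(cfg, "simulating trajectory (seed ", cfg$seed, ")")
      sim <- gen_trajectory(scfg)
      traj <- sim$trajectory
      truth <- sim$truth
    }
    geo <- synth_geometry(scfg, "upper")
    membranes <- scfg$membrane_z
    species <- cfg$species %||% unique(c(names(scfg$crossing_rate_inward),
                                         names(scfg$crossing_rate_outward)))
    if (!length(species)) species <- intersect(ION_SPECIES,
                                               unique(traj$particles$species))

    stage <- "compartments/voltage"
    .log(cfg, "compartment counts and membrane voltage")
    comp <- compartment_counts(traj, membranes, species = species,
                               frames = seq(1, n_frames(traj),
                                            by = cfg$voltage_stride))
    volt <- voltage_timeline(traj, membranes, n_bins = cfg$voltage_bins,
                             stride = cfg$voltage_stride)

    stage <- "events"
    .log(cfg, "event detection (", cfg$mode, ")")
    ev <- detect_events(traj, geo, mode = cfg$mode, species = species,
                        hysteresis_ps = cfg$hysteresis_ps)
    stage <- "pathways"
    if (cfg$mode == "full_crossing" && nrow(ev))
      ev <- classify_pathway(ev, traj, geo)
    stage <- "conductance"
    total_us <- diff(range(traj$times)) * 1e-6
    vref <- unname(volt$mean["upper"])
    cond <- if (nrow(ev) && is.finite(vref) && vref != 0)
      conduction_summary(ev, total_us, vref) else NULL

    stage <- "occupancy/pmf"
    .log(cfg, "occupancy histogram and PMF")
    occ <- occupancy_histogram(traj, geo, species = species,
                               z_edges = cfg$pmf_bins$z, r_edges = cfg$pmf_bins$r)
    pmf <- if (occ$n_binned > 0) pmf_from_occupancy(occ, cfg$temperature) else NULL
    sites <- site_occupancy(traj, geo, species = species)

    stage <- "hydration/coordination"
    ion_ids <- traj$particles$id[traj$particles$species %in% species]
    hyd <- if (length(ion_ids)) {
      mid <- ion_ids[1]
      mean(hydration_number(traj, mid,
                            frames = seq(1, n_frames(traj),
                                         by = cfg$voltage_stride)))
    } else NA_real_

    stage <- "conformers"
    .log(cfg, "conformer timeline")
    tl <- conformer_timeline(traj, geometry = geo)
    subs <- setdiff(names(tl), c("frame", "time_ps"))
    flip_frac <- vapply(subs, function(su) mean(tl[[su]] == "flipped_T62"),
                        numeric(1))

    stage <- "write"
    .log(cfg, "writing outputs to ", cfg$outdir)
    data.table::fwrite(as.data.frame(ev), file.path(cfg$outdir, "events.csv"))
    data.table::fwrite(comp, file.path(cfg$outdir, "compartments.csv"))
    data.table::fwrite(volt$per_frame, file.path(cfg$outdir, "voltage.csv"))
    data.table::fwrite(as.data.frame(tl), file.path(cfg$outdir, "conformers.csv"))
    if (!is.null(pmf)) {
      zc <- (pmf$z_edges[-1] + pmf$z_edges[-length(pmf$z_edges)]) / 2
      rc <- (pmf$r_edges[-1] + pmf$r_edges[-length(pmf$r_edges)]) / 2
      long <- data.frame(z = rep(zc, times = length(rc)),
                         r = rep(rc, each = length(zc)),
                         counts = as.vector(pmf$counts),
                         w_kJ_mol = as.vector(pmf$w))
      data.table::fwrite(long, file.path(cfg$outdir, "pmf.csv"))
    }
    if (!is.null(truth)) write_truth(truth, file.path(cfg$outdir, "truth"))

    pathway_tab <- if (nrow(ev)) table(factor(ev$pathway, levels = c("axial", "side")))
                   else table(factor(character(), levels = c("axial", "side")))
    summary <- list(
      seed = cfg$seed,
      config_hash = rlang::hash(cfg[setdiff(names(cfg), c("outdir", "log"))]),
      n_frames = n_frames(traj), n_particles = n_particles(traj),
      total_time_us = total_us,
      voltage_mV = list(mean = as.list(volt$mean), sd = as.list(volt$sd)),
      events = list(
        n_total = nrow(ev),
        n_inward = sum(ev$direction == "inward"),
        n_outward = sum(ev$direction == "outward"),
        n_distractors = attr(ev, "n_distractors"),
        pathway = as.list(pathway_tab),
        side_fraction = if (nrow(ev)) unname(pathway_tab["side"] / nrow(ev)) else NA
      ),
      conductance = if (!is.null(cond)) lapply(seq_len(nrow(cond)), function(i)
        as.list(cond[i, ])) else list(),
      site_occupancy = as.list(sites),
      mean_hydration_first_ion = hyd,
      flipped_fraction = as.list(flip_frac)
    )
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    summary
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
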