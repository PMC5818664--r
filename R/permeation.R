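# Permeation-event detection, axial/side pathway classification, and
# conversion of event counts to currents and conductances.
#
# Two counting modes: "full_crossing" follows each ion's region sequence from
# one bulk, through the SF, to the opposite bulk (distractor excursions that
# return to the same side are never events); "coupled_exchange" implements the
# literal coupled rule (an ion enters the SF from one side while another ion
# leaves it to the other side within a time window).

# Region tokens: 1 = extracellular side bulk, 2 = intracellular side
# (cavity or bulk), 3 = SF, 0 = transit (vestibule/side portal), -1 = other.
.region_token <- function(region_idx) {
  map <- c(INTRACELLULAR_BULK = 2, CAVITY = 2, SF = 3, VESTIBULE = 0,
           EXTRACELLULAR_BULK = 1, SIDE_PORTAL = 0, MEMBRANE_OTHER = -1)
  unname(map[REGION_LEVELS][region_idx])
}

.empty_events <- function() {
  data.frame(ion_id = integer(), species = character(), direction = character(),
             pathway = character(), entry_frame_time = numeric(),
             exit_frame_time = numeric(), entry_region_sequence = character(),
             transit_sequence = character(), transit_start = numeric(),
             transit_end = numeric(), channel_copy = character(),
             stringsAsFactors = FALSE)
}

# Merge brief departures from the SF (shorter than the hysteresis dwell and
# flanked by SF visits) back into the SF.
.apply_hysteresis <- function(tok, times, hysteresis_ps) {
  r <- rle(tok)
  if (length(r$lengths) < 3) return(tok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  dur <- times[ends] - times[starts]
  for (k in 2:(length(r$lengths) - 1)) {
    if (r$values[k] != 3 && r$values[k - 1] == 3 && r$values[k + 1] == 3 &&
        dur[k] < hysteresis_ps)
      r$values[k] <- 3
  }
  inverse.rle(r)
}

.detect_full_crossing <- function(tok, times, regions, hysteresis_ps) {
  tok <- .apply_hysteresis(tok, times, hysteresis_ps)
  r <- rle(tok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  v <- r$values
  events <- list()
  n_distract <- 0L
  last_bulk <- NA_integer_      # side the ion last resided in (1 ext, 2 int)
  pending <- FALSE              # TRUE once the ion has entered the SF
  left_bulk_at <- NA_integer_   # first frame index after leaving that bulk
  sf_first <- NA_integer_; sf_last <- NA_integer_
  for (k in seq_along(v)) {
    if (v[k] %in% c(1, 2)) {
      if (pending) {
        if (v[k] != last_bulk) {
          events[[length(events) + 1]] <- list(
            direction = if (last_bulk == 1) "inward" else "outward",
            entry_time = times[sf_first], exit_time = times[starts[k]],
            pre_idx = c(left_bulk_at, sf_first),
            post_idx = c(sf_last, starts[k]))
        } else n_distract <- n_distract + 1L
        pending <- FALSE
      }
      last_bulk <- v[k]
      left_bulk_at <- NA_integer_
    } else if (v[k] == 3) {
      if (!pending && !is.na(last_bulk)) {
        pending <- TRUE
        if (is.na(left_bulk_at)) left_bulk_at <- starts[k]
        sf_first <- starts[k]
      }
      if (pending) sf_last <- ends[k]
    } else {
      if (is.na(left_bulk_at) && !is.na(last_bulk)) left_bulk_at <- starts[k]
    }
  }
  list(events = events, n_distractors = n_distract)
}

#' Detect permeation events
#'
#' @param trajectory a `permeon_trajectory`.
#' @param geometry a `channel_geometry`, or a named list of them (e.g.
#'   `list(upper =, lower =)`) to attribute events to channel copies.
#' @param mode `"full_crossing"` (default) or `"coupled_exchange"`.
#' @param species ion species to follow.
#' @param hysteresis_ps departures from the SF shorter than this are treated
#'   as SF residence (full_crossing mode).
#' @param window_ps pairing window of the coupled rule (coupled_exchange).
#' @return data.frame of class `permeon_events`, one row per event, with the
#'   number of same-side distractor excursions as attribute `n_distractors`.
#' @export
detect_events <- function(trajectory, geometry, mode = c("full_crossing",
                                                         "coupled_exchange"),
                          species = c("K", "NA", "RB"), hysteresis_ps = 100,
                          window_ps = 200) {
  mode <- match.arg(mode)
  if (inherits(geometry, "channel_geometry")) geometry <- list(upper = geometry)
  p <- trajectory$particles
  ids <- p$id[p$species %in% species]
  out <- .empty_events()
  n_distract <- 0L
  if (length(ids) == 0 || n_frames(trajectory) == 0)
    return(structure(out, class = c("permeon_events", "data.frame"),
                     n_distractors = 0L))
  times <- trajectory$times
  for (copy in names(geometry)) {
    geo <- geometry[[copy]]
    rt <- region_timeline(trajectory, geo, ids = ids)
    if (mode == "full_crossing") {
      for (j in seq_along(ids)) {
        tok <- .region_token(rt[, j])
        res <- .detect_full_crossing(tok, times, rt[, j], hysteresis_ps)
        n_distract <- n_distract + res$n_distractors
        for (e in res$events) {
          pre_regions <- REGION_LEVELS[rt[e$pre_idx[1]:e$pre_idx[2], j]]
          post_regions <- REGION_LEVELS[rt[e$post_idx[1]:e$post_idx[2], j]]
          transit <- if (e$direction == "inward") pre_regions else post_regions
          tr_win <- if (e$direction == "inward")
            times[e$pre_idx] else times[e$post_idx]
          sp <- p$species[match(ids[j], p$id)]
          out <- rbind(out, data.frame(
            ion_id = ids[j], species = sp, direction = e$direction,
            pathway = NA_character_, entry_frame_time = e$entry_time,
            exit_frame_time = e$exit_time,
            entry_region_sequence = paste(rle(pre_regions)$values, collapse = "|"),
            transit_sequence = paste(rle(transit)$values, collapse = "|"),
            transit_start = tr_win[1], transit_end = tr_win[2],
            channel_copy = copy, stringsAsFactors = FALSE))
        }
      }
    } else {
      out <- rbind(out, .detect_coupled(rt, ids, p, times, copy, window_ps))
    }
  }
  out <- out[order(out$entry_frame_time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("permeon_events", "data.frame"),
            n_distractors = n_distract)
}

.detect_coupled <- function(rt, ids, particles, times, copy, window_ps) {
  nf <- nrow(rt)
  if (nf < 2) return(.empty_events())
  entries <- list(); exits <- list()
  side_of <- function(token) if (token %in% c(1, 0)) "ext" else if (token == 2) "int" else NA
  for (j in seq_along(ids)) {
    tok <- .region_token(rt[, j])
    for (t in 1:(nf - 1)) {
      if (tok[t] != 3 && tok[t + 1] == 3) {
        s <- side_of(tok[t])
        if (!is.na(s)) entries[[length(entries) + 1]] <-
            list(time = times[t + 1], side = s, ion = j)
      } else if (tok[t] == 3 && tok[t + 1] != 3) {
        s <- side_of(tok[t + 1])
        if (!is.na(s)) exits[[length(exits) + 1]] <-
            list(time = times[t + 1], side = s, ion = j)
      }
    }
  }
  out <- .empty_events()
  if (!length(entries) || !length(exits)) return(out)
  ex_used <- rep(FALSE, length(exits))
  ex_time <- vapply(exits, `[[`, numeric(1), "time")
  ex_side <- vapply(exits, `[[`, character(1), "side")
  ord <- order(vapply(entries, `[[`, numeric(1), "time"))
  for (en in entries[ord]) {
    want <- if (en$side == "ext") "int" else "ext"
    cand <- which(!ex_used & ex_side == want & abs(ex_time - en$time) <= window_ps)
    if (!length(cand)) next
    pick <- cand[which.min(abs(ex_time[cand] - en$time))]
    ex_used[pick] <- TRUE
    sp <- particles$species[match(ids[en$ion], particles$id)]
    out <- rbind(out, data.frame(
      ion_id = ids[en$ion], species = sp,
      direction = if (en$side == "ext") "inward" else "outward",
      pathway = NA_character_, entry_frame_time = en$time,
      exit_frame_time = ex_time[pick], entry_region_sequence = NA_character_,
      transit_sequence = NA_character_, transit_start = NA_real_,
      transit_end = NA_real_, channel_copy = copy, stringsAsFactors = FALSE))
  }
  out
}

#' Classify the conduction pathway of detected events
#'
#' An event is a side entry if, during the extracellular-side transit window
#' (before SF entry for inward events, after SF exit for outward ones), the
#' ion either carries the `SIDE_PORTAL` region label or lies within the
#' species' coordination cutoff of any S_side coordinating-atom set; otherwise
#' the pathway is axial (through the vestibule along the pore axis).
#'
#' @param events a `permeon_events` data.frame (full_crossing mode).
#' @param trajectory the trajectory the events came from.
#' @param geometry the corresponding `channel_geometry` (or named list).
#' @param cutoffs named ion-oxygen coordination cutoffs in A.
#' @return `events` with the `pathway` column filled.
#' @export
classify_pathway <- function(events, trajectory, geometry,
                             cutoffs = c("NA" = 3.2, K = 3.6, RB = 3.8)) {
  if (inherits(geometry, "channel_geometry")) geometry <- list(upper = geometry)
  p <- trajectory$particles
  for (r in seq_len(nrow(events))) {
    seqs <- events$transit_sequence[r]
    if (!is.na(seqs) && grepl("SIDE_PORTAL", seqs, fixed = TRUE)) {
      events$pathway[r] <- "side"
      next
    }
    geo <- geometry[[events$channel_copy[r]]]
    if (is.na(events$transit_start[r])) stop("event ", r, " has no transit window; ",
                                             "classify full_crossing events")
    win <- which(trajectory$times >= events$transit_start[r] &
                 trajectory$times <= events$transit_end[r])
    if (!length(win)) stop("event frames missing from trajectory")
    track <- particle_track(trajectory, events$ion_id[r])[win, , drop = FALSE]
    cutoff <- cutoffs[[events$species[r]]] %||% 3.5
    near <- FALSE
    for (su in names(geo$s_side_atoms)) {
      sel <- geo$s_side_atoms[[su]]
      idx <- which(p$species == "PROTEIN_ATOM" &
                   paste(p$subunit, p$resno, p$atom) %in%
                     paste(sel$subunit, sel$resno, sel$atom))
      if (!length(idx)) next
      for (i in idx) {
        apos <- matrix(trajectory$coords[i, , win], ncol = 3, byrow = TRUE)
        d2 <- rowSums((track - apos)^2)
        if (any(d2 <= cutoff^2)) { near <- TRUE; break }
      }
      if (near) break
    }
    events$pathway[r] <- if (near) "side" else "axial"
  }
  events
}

#' Conductance and current from an event count
#'
#' `G = N e / (t |V|)` and `I = N e / t`, the standard conversion of a
#' permeation count over simulated time at a transmembrane voltage.
#'
#' @param n_events number of permeation events.
#' @param total_time_us simulated time in microseconds.
#' @param voltage_mv transmembrane voltage in mV (sign ignored for G).
#' @return list with `conductance_pS` and `current_pA`.
#' @export
conductance <- function(n_events, total_time_us, voltage_mv) {
  if (total_time_us <= 0) stop("total_time_us must be > 0")
  if (voltage_mv == 0) stop("voltage must be non-zero")
  charge_C <- n_events * .e_charge
  t_s <- total_time_us * 1e-6
  current_A <- charge_C / t_s
  list(conductance_pS = current_A / (abs(voltage_mv) * 1e-3) * 1e12,
       current_pA = current_A * 1e12)
}

#' Summarise events as a conduction table
#'
#' @param events a `permeon_events` data.frame.
#' @param total_time_us simulated time (us).
#' @param voltage_mv transmembrane voltage (mV).
#' @return data.frame with per-species, per-direction counts, current and
#'   conductance.
#' @export
conduction_summary <- function(events, total_time_us, voltage_mv) {
  if (nrow(events) == 0)
    return(data.frame(species = character(), direction = character(),
                      n = integer(), current_pA = numeric(),
                      conductance_pS = numeric()))
  agg <- stats::aggregate(list(n = events$ion_id),
                   by = list(species = events$species,
                             direction = events$direction), FUN = length)
  g <- t(vapply(agg$n, function(n) {
    cc <- conductance(n, total_time_us, voltage_mv)
    c(cc$current_pA, cc$conductance_pS)
  }, numeric(2)))
  agg$current_pA <- g[, 1]
  agg$conductance_pS <- g[, 2]
  agg
}
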