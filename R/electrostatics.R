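# Membrane potential from the charge density by double integration of the
# Poisson equation, d^2(phi)/dz^2 = -rho/eps0, with vacuum permittivity and
# phi = dphi/dz = 0 at a declared reference (the g_potential convention).
# Units: z in Angstrom, rho in e/A^3, phi in mV.

#' Bin the charge density of a trajectory along z
#'
#' Time-averaged over the requested frames; the sum of rho times slab volume
#' equals the mean total system charge.
#'
#' @param trajectory a `permeon_trajectory`.
#' @param n_bins number of uniform z bins across the box.
#' @param frames optional frame indices (default: all).
#' @return object of class `charge_density`: list with `z_edges`, `z` (bin
#'   centres), `rho` (e/A^3), `area` (box cross-section, A^2) and `box`.
#' @export
bin_charge_density <- function(trajectory, n_bins = 100, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  Lz <- trajectory$box[3]
  edges <- seq(0, Lz, length.out = n_bins + 1)
  dz <- edges[2] - edges[1]
  area <- trajectory$box[1] * trajectory$box[2]
  q <- trajectory$particles$charge
  acc <- numeric(n_bins)
  for (i in frames) {
    z <- trajectory$coords[, 3, i] %% Lz
    bin <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L), n_bins)
    acc <- acc + as.vector(tapply(q, factor(bin, levels = seq_len(n_bins)), sum,
                                  default = 0))
  }
  rho <- acc / length(frames) / (dz * area)
  structure(list(z_edges = edges, z = (edges[-1] + edges[-length(edges)]) / 2,
                 rho = rho, area = area, box = trajectory$box),
            class = "charge_density")
}

#' Analytic charge-density profiles for testing the Poisson integrator
#'
#' `zero`: identically zero.  `capacitor`: two opposite delta-like sheets of
#' surface density `sigma` (e/A^2) at separation `d`, the lower plate
#' positive.  `gaussian_dipole`: an antisymmetric pair of Gaussians (integral
#' zero), `params = list(amp, sd, sep)`.
#'
#' @param profile one of `"zero"`, `"capacitor"`, `"gaussian_dipole"`.
#' @param n_bins number of bins.
#' @param z_max grid extent (profile on `[0, z_max]`, Angstrom).
#' @param params named list of profile parameters.
#' @return a `charge_density` with unit cross-sectional area.
#' @export
gen_charge_density <- function(profile = c("zero", "capacitor", "gaussian_dipole"),
                               n_bins = 1000, z_max = 160, params = list()) {
  profile <- match.arg(profile)
  edges <- seq(0, z_max, length.out = n_bins + 1)
  z <- (edges[-1] + edges[-length(edges)]) / 2
  dz <- edges[2] - edges[1]
  rho <- numeric(n_bins)
  if (profile == "capacitor") {
    sigma <- params$sigma %||% 1e-3
    d <- params$d %||% (z_max / 3)
    center <- params$center %||% (z_max / 2)
    lo <- which.min(abs(z - (center - d / 2)))
    hi <- which.min(abs(z - (center + d / 2)))
    rho[lo] <- sigma / dz
    rho[hi] <- -sigma / dz
  } else if (profile == "gaussian_dipole") {
    amp <- params$amp %||% 1e-4
    sdv <- params$sd %||% 8
    sep <- params$sep %||% (z_max / 3)
    center <- params$center %||% (z_max / 2)
    rho <- amp * (exp(-(z - (center - sep / 2))^2 / (2 * sdv^2)) -
                  exp(-(z - (center + sep / 2))^2 / (2 * sdv^2)))
  }
  structure(list(z_edges = edges, z = z, rho = rho, area = 1,
                 box = c(1, 1, z_max)), class = "charge_density")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Electrostatic potential profile by double integration
#'
#' Solves `d2(phi)/dz2 = -rho/eps0` on the uniform grid of a
#' [bin_charge_density()] / [gen_charge_density()] profile by cumulative
#' (trapezoidal) double integration, imposing `phi = 0` and `dphi/dz = 0` at
#' the reference coordinate.
#'
#' @param density a `charge_density`.
#' @param reference_z axial reference (default: the first bin centre, i.e.
#'   the box edge).
#' @return object of class `potential_profile`: list with `z`, `phi` (mV),
#'   `rho`, `z_edges`, `reference_z`.
#' @export
potential_from_density <- function(density, reference_z = NULL) {
  z <- density$z
  dz <- diff(z)
  if (any(abs(dz - dz[1]) > 1e-9 * abs(dz[1])))
    stop("potential_from_density requires a uniform grid")
  if (is.null(reference_z)) reference_z <- z[1]
  # SI: rho e/A^3 -> C/m^3; z A -> m
  rho_si <- density$rho * .e_charge / 1e-30
  z_si <- z * 1e-10
  I1 <- as.vector(pracma::cumtrapz(z_si, rho_si))          # int rho dz
  I2 <- as.vector(pracma::cumtrapz(z_si, z_si * rho_si))   # int z rho dz
  phi0 <- -(z_si * I1 - I2) / .eps0                        # phi with phi(z1)=phi'(z1)=0
  iref <- which.min(abs(z - reference_z))
  slope_ref <- -I1[iref] / .eps0
  phi <- phi0 - phi0[iref] - slope_ref * (z_si - z_si[iref])
  structure(list(z = z, phi = phi * 1000, rho = density$rho,
                 z_edges = density$z_edges, reference_z = z[iref]),
            class = "potential_profile")
}

#' Closed-form voltage step of a parallel-plate capacitor
#'
#' @param sigma sheet charge density (e/A^2).
#' @param d plate separation (A).
#' @return plateau potential difference in mV.
#' @export
capacitor_voltage_mv <- function(sigma, d) {
  (sigma * .e_charge / 1e-20) * (d * 1e-10) / .eps0 * 1000
}

# Mean of phi over the central `frac` part of the axial window [lo, hi],
# wrapping around the box length L when lo > hi.
.plateau_mean <- function(pp, lo, hi, L, frac = 0.5) {
  if (hi < lo) hi <- hi + L
  len <- hi - lo
  wlo <- lo + (1 - frac) / 2 * len
  whi <- hi - (1 - frac) / 2 * len
  zw <- pp$z
  sel <- (zw >= wlo & zw <= whi) | (zw + L >= wlo & zw + L <= whi)
  if (!any(sel)) stop("empty plateau window [", wlo, ", ", whi, "]")
  mean(pp$phi[sel])
}

#' Per-membrane transmembrane voltages from a potential profile
#'
#' The two membrane midplanes split the box into compartment a (between them)
#' and the periodically wrapped compartment b.  Each membrane's voltage is the
#' plateau mean of phi on its extracellular-facing side (+z) minus the
#' intracellular-facing side, using the central `window_frac` of each bulk
#' compartment; for an antisymmetric double-membrane setup the two values have
#' opposite signs.
#'
#' @param potential a `potential_profile`.
#' @param membranes two membrane midplane z values (A), increasing.
#' @param window_frac central fraction of each compartment used as plateau.
#' @return named numeric vector `c(lower = , upper = )` in mV.
#' @export
transmembrane_voltage <- function(potential, membranes, window_frac = 0.5) {
  stopifnot(length(membranes) == 2, membranes[1] < membranes[2])
  L <- max(potential$z_edges)
  m1 <- membranes[1]; m2 <- membranes[2]
  phi_a <- .plateau_mean(potential, m1, m2, L, window_frac)
  phi_b <- .plateau_mean(potential, m2, m1, L, window_frac)   # wraps
  c(lower = phi_a - phi_b, upper = phi_b - phi_a)
}

#' Frame-resolved transmembrane voltage of a trajectory
#'
#' Bins the charge density per frame (or per block of frames), integrates the
#' Poisson equation and extracts both membrane voltages, reporting the
#' frame-wise spread.
#'
#' @param trajectory a `permeon_trajectory`.
#' @param membranes two membrane midplane z values (A).
#' @param n_bins z bins for the charge density.
#' @param stride use every `stride`-th frame.
#' @param window_frac plateau fraction, see [transmembrane_voltage()].
#' @return list with `per_frame` (data.frame time_ps, dv_lower, dv_upper),
#'   `mean` and `sd` (named vectors, mV).
#' @export
voltage_timeline <- function(trajectory, membranes, n_bins = 100, stride = 1,
                             window_frac = 0.5) {
  frames <- seq(1, n_frames(trajectory), by = stride)
  res <- vapply(frames, function(i) {
    cd <- bin_charge_density(trajectory, n_bins = n_bins, frames = i)
    transmembrane_voltage(potential_from_density(cd), membranes, window_frac)
  }, numeric(2))
  per_frame <- data.frame(time_ps = trajectory$times[frames],
                          dv_lower = res["lower", ], dv_upper = res["upper", ])
  list(per_frame = per_frame,
       mean = c(lower = mean(per_frame$dv_lower), upper = mean(per_frame$dv_upper)),
       sd = c(lower = sd(per_frame$dv_lower), upper = sd(per_frame$dv_upper)))
}
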