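---
title: "Analysing ion permeation in double-membrane channel simulations with permeon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing ion permeation in double-membrane channel simulations with permeon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeon)
```

## The problem

Non-selective cation channels such as NaK conduct Na⁺ and K⁺ with comparable
efficiency even though their selectivity filter (SF) resembles that of highly
K⁺-selective channels.  In a *computational electrophysiology* setup, a
simulation box holds two stacked membranes, each carrying one channel copy,
and a small, maintained ion-count imbalance between the two aqueous
compartments sustains transmembrane voltages of opposite sign across the two
membranes.  Ions then permeate spontaneously, and the analysis questions are:

* how many complete permeation events occurred, in which direction, and
  through which channel copy;
* which *pathway* each ion took — the canonical axial route through the
  vestibule, or an off-axis **side entry** past the S_side binding site
  (two backbone carbonyls from D66 and F69 plus a side-chain oxygen from S70
  of the same or D66 of the neighbouring subunit);
* what voltage the imbalance actually produced;
* where ions reside (occupancy, free-energy surfaces), how hydrated they
  are, and which SF conformer — crystal or T62-carbonyl-flipped — each
  subunit occupies.

permeon implements this analysis chain as composable functions over a plain
trajectory container, plus a kinetic synthetic-trajectory generator that
replaces microsecond-scale atomistic MD for development and testing.

## Coordinate system and regions

All analyses share a channel-centric cylindrical frame
(`channel_coords()`): the axial coordinate `s` is measured along the membrane
normal from the SF centre (+s is extracellular), the radial coordinate `r`
from the pore axis.  Lengths are in Å, times in ps.

`assign_region()` partitions space into
`INTRACELLULAR_BULK | CAVITY | SF | VESTIBULE | EXTRACELLULAR_BULK |
SIDE_PORTAL | MEMBRANE_OTHER`.  Axial intervals are half-open `[lo, hi)`, so
a point exactly on the SF/vestibule boundary is VESTIBULE — one fixed
convention rather than a tolerance.  Within the SF *and* vestibule axial
spans, the radial annulus `(sf_radius, sf_radius + side_portal_radius_min]`
maps to SIDE_PORTAL; we treat the portals as spanning both levels because
side-entering ions approach the upper SF from vestibule height.  The default
radii (4.5 Å pore, portals out to 10 Å) and all axial extents are
engineering choices — the source structures do not define "vestibule" or
"cavity" numerically — and every value is overridable through
`build_geometry()` / a YAML config (`inst/extdata/geometry_default.yaml`).

Site planes: the B34 plane is the centroid height of the four T63 backbone
carbonyl oxygens and B23 that of the V64 carbonyls, with S3/S4 the adjacent
cage midpoints.  Whether "B23/B34" denote in-plane positions or between-plane
cages is not decidable from the literature prose; we adopt the carbonyl-plane
convention and record it here rather than asserting it as the original
intent.

## The synthetic trajectory generator

`gen_trajectory()` emits a two-membrane box (default 60 × 60 × 160 Å,
membrane midplanes at z = 40 and 120 Å, channel in the upper membrane) in
which ions hop among region anchor points:

* complete crossings arrive as a Poisson process with configurable
  per-species inward/outward rates (events·µs⁻¹); a pinned-count override
  exists for exact-recovery tests;
* each crossing traverses bulk → vestibule *or* side portal (Bernoulli with
  `side_entry_fraction`) → SF → opposite side;
* distractor excursions enter the SF and return to the same side, at their
  own rate — these must never be counted as events;
* SF dwell times are exponential (mean 0.5 ns by default, clamped to at
  least three frames).  No dwell-time distributions are reported for the real
  system; these are placeholders chosen so that "short-lived" SF residence is
  resolvable at the default 50 ps frame interval, not estimates;
* every ion carries a rigid hydration shell (`hydration_n` waters at
  2.2–2.6 Å) which optionally stays behind while the ion is in the SF;
* carbonyl pseudo-atoms (C and O of T62/T63/V64/G65 per subunit) are
  emitted, with the T62 C=O rotated ~180° about the backbone direction
  during scheduled flip intervals, and the S_side oxygens placed at the four
  portals;
* a flipped subunit's T63/V64 carbonyls widen radially by `flip_widen`
  (default 0.8 Å).  The flip-induced asymmetric deformation of the lower SF
  is qualitative in the source material; 0.8 Å is our choice, large enough to
  separate the opposing-distance distributions from the 0.3 Å positional
  jitter;
* Gaussian jitter (sd 0.3 Å) is added to every coordinate so that the
  classification code is exercised against noise;
* after a completed crossing the ion is swapped back to its origin-side bulk
  (a position teleport after 500 ps).  This mirrors the ion/water
  position-swap algorithm that holds the compartment imbalance constant in
  the real protocol and keeps the per-side ion pools stationary, so
  one-directional runs do not deplete a compartment.

Everything planted — crossing times, directions, pathways, flip intervals —
is returned as a ground-truth sidecar (`$truth`) and can be written as
tabular text (`write_truth()`), which is what the recovery tests compare
against.

What the generator does **not** emulate: energetics and force fields, water
dynamics beyond rigid shells, realistic dwell-time statistics, membrane
dielectrics, or correlated multi-ion knock-on motion.  Passing tests on
synthetic data therefore demonstrate that the *analysis* is correct given its
region semantics, not that the kinetic model reproduces MD.

## Event counting

Two bookkeeping rules are provided because the field's verbal counting rule
("an ion moved from the cavity to the SF and another ion left the SF") and
the single-file crossings visible in trajectory movies imply slightly
different ledgers:

* `full_crossing` (default): an event is an ion whose region sequence runs
  from one bulk, through the SF, to the opposite side (the cavity already
  counts as the intracellular side).  Departures from the SF shorter than the
  hysteresis dwell (default 100 ps, configurable; boundary flicker is
  expected at finite jitter) are treated as continued SF residence.
  Same-side excursions are tallied separately and never counted.
* `coupled_exchange`: the literal coupled rule — an SF entry from one side is
  paired with the nearest unconsumed SF exit to the other side within
  `window_ps` (default 200 ps).  The original rule does not state its
  temporal window, so the window is an explicit parameter; each
  entry/exit transition is consumed at most once, greedily in time order.

`conductance()` converts counts to current and conductance,
`G = N·e / (t·|V|)`; with the published inputs (18 inward events, 10 µs,
460 mV) it reproduces the printed 0.6 pS.

## Pathway classification

`classify_pathway()` inspects the extracellular-side transit window — the
frames between leaving bulk and entering the SF for inward events, and
between leaving the SF and reaching bulk for outward events (side entries
operate in both directions).  The event is a side entry if the ion carries
the SIDE_PORTAL label anywhere in that window, or lies within the ion–oxygen
coordination cutoff (defaults: Na⁺ 3.2 Å, K⁺ 3.6 Å — typical first-shell
distances; not reported by the source) of any S_side atom set.  The
coordination route matters when the portal annulus is configured narrowly;
the geometric route suffices otherwise.

## Membrane potential

`potential_from_density()` solves the Poisson equation
`d²φ/dz² = −ρ/ε₀` by cumulative trapezoidal double integration of the binned
charge density, with vacuum permittivity (no dielectric profile — this is
the plain double-integration prescription of the standard tooling) and
`φ = dφ/dz = 0` at an explicit reference (default: the box edge).  For
delta-like charge sheets the trapezoidal smearing is symmetric about the
sheet's bin, so plateau differences are exact to machine precision; for
smooth profiles the method converges quadratically and agrees with an
independent two-pass ODE solve to better than 10⁻⁶ relative at 2 × 10⁴ bins.

`transmembrane_voltage()` reports, per membrane, the plateau mean of φ on
the extracellular-facing (+z) side minus the intracellular-facing side,
using the central 50 % of each bulk compartment (avoiding interfacial
oscillations; fraction configurable).  A single charged capacitor in a
periodic box necessarily mixes its two plateaus across the boundary, so the
physically meaningful test case is the antisymmetric double-capacitor
profile, which recovers ±σd/ε₀ exactly with opposite signs for the two
membranes.

## Occupancy, PMF, hydration

`occupancy_histogram()` bins (s, r) samples of selected species;
`pmf_from_occupancy()` applies Boltzmann inversion
`w = −k_B T ln(p/p_ref)` at 300 K (the simulation temperature) with the
maximum-density bin as reference, so reported barriers are positive.
Zero-count bins are masked, never imputed.  On 10⁵ samples from a harmonic
well the inversion recovers `½kz²` with RMSE well below 0.2 kJ·mol⁻¹ over
|z| ≤ 2σ.

`hydration_number()` counts water oxygens within first-shell cutoffs
(Na⁺–O 3.1 Å, K⁺–O 3.5 Å, standard first RDF minima), and
`coordination_state()` resolves the S_side coordination signature
`(n_protein_O, n_water_O)` with its contributing atoms.

## Conformer diagnostics

`classify_flip()` measures the angle between the instantaneous C=O vector
and the crystal reference direction (inward radial).  Labels: crystal
< 60°, flipped > 120°, `other` between — the flip itself is ~180°, but no
classification boundary is defined in the literature, so the 60/120 bands
are ours.  `conformer_timeline()` applies temporal hysteresis (default: runs
shorter than 5 frames flanked by a common label are absorbed), which
suppresses the occasional jitter-induced `other` frame.

`opposing_distance_timeline()` measures d1 (opposing T63 carbonyl O–O) and
d2 (V64) for the `(A,B)`/`(C,D)` pairing by default; whether those labels
denote adjacent or diagonal subunits in the original figures is not
deducible, so the pairing is a parameter, and in the generator A/B and C/D
are constructed opposing.  Distances are measured between carbonyl oxygens
(not Cα), since the deformation of interest is of the carbonyl-lined pore.

`detect_hbonds()` uses the geometric criteria H···O ≤ 2.5 Å and N–H···O
angle ≥ 150°, restricted to backbone amide donors and backbone carbonyl
acceptors, which keeps the crystal-vs-flipped comparison an exact set
difference: {T63NH→T60CO, V64NH→V59CO} versus {V64NH→T62CO}.
`amide_contact_map()` lists same-chain amide-proton pairs under a cutoff
(default 4 Å, the distance scale beyond which NHHN-type cross-peaks
vanish); the idealised scaffolds (`gen_sf_scaffold()`) are built so the
crystal form has every vicinal ⁶¹LTTVG⁶⁵ contact under 4 Å while the flipped
form places T62H–T63H at exactly 4.5 Å.  The scaffolds are constraint-driven
synthetic constructs, not crystallographic coordinates; in particular the
flipped T62 carbonyl is repositioned to realise the rearranged hydrogen-bond
network rather than rotated about a physical backbone.

## Compartment bookkeeping

`assign_compartments()` puts the open slab strictly between the membrane
midplanes in compartment a and everything else (including the midplane
coordinates themselves) in b.  `maintain_imbalance()` returns the minimal
deterministic swap list — surplus-compartment ion closest to its bulk
centre, deficit-compartment water closest to its bulk centre, ties by lowest
id — that restores a target Δn; each swap changes Δn by 2, so an odd
difference lands on the adjacent parity-consistent value.  The original
maintenance algorithm's candidate-selection rule is not described in the
source material; the rule above is a documented, deterministic substitute.
Applying the returned swaps and re-running yields an empty list
(idempotence), and swaps never create or destroy particles.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: recovery
trajectories of 200 ns–2 µs at 25–50 ps frame spacing with ~30 ions
(10⁴–10⁵ frame×particle samples), 10⁵-sample PMF inversions, 10³–2×10⁴-bin
Poisson grids, and 100-state swap audits.  These sizes were chosen so each
statistical check has comfortable power (e.g. 200 classified events put 3
binomial SE at ±0.097 around a planted side fraction of 0.70) while a full
run of everything stays within a few minutes.  Event counts at the scale of
the real µs simulations (tens of events per 10 µs) are deliberately not
reproduced by simulation — that would require atomistic MD — so conductance
arithmetic is checked against the printed event counts and voltages
directly.

## Known limitations

* The generator's kinetics are schematic; rate constants, dwell times and
  the flip-deformation magnitude are placeholders, so only *recovery* of
  planted structure is meaningful, not absolute rates.
* The Poisson integrator has no dielectric profile and no Ewald-style
  periodic corrections; voltages from raw ion distributions in vacuum are
  larger than those of a solvated membrane system.
* The coupled_exchange window and the full_crossing hysteresis interact
  with the frame interval; both must exceed one frame and stay below the
  shortest genuine dwell to guarantee exact recovery.
* Hydrogen-bond analysis ignores side-chain acceptors by design; structures
  lacking amide protons must pass through `reconstruct_amide_h()` first.
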