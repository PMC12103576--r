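#' Simulation configuration for dual-channel membrane binding fields
#'
#' Bundles every parameter of the stochastic two-species membrane simulator:
#' field geometry, movie length and frame interval, per-channel surface
#' densities, free/bound diffusion coefficients, reversible-binding rate
#' parameters, confinement-zone geometry, and the measurement model
#' (localization noise, inter-channel registration residual, detection
#' dropout). Defaults emulate fast two-color TIRF movies of receptor and
#' co-receptor molecules at near-physiological densities: 400 frames at
#' 33 ms/frame on a 10 x 10 um field with ~0.42 and ~0.59 molecules/um2 in
#' the two channels and ~20 nm localization/registration error.
#'
#' @param field_width_um,field_height_um field size in um (periodic domain).
#' @param n_frames number of frames in the movie.
#' @param dt_s frame interval in seconds.
#' @param density_a_per_um2,density_b_per_um2 surface density of each
#'   channel, molecules/um2. Realized molecule counts are Poisson draws.
#' @param d_free_um2_s diffusion coefficient of unbound molecules, um2/s.
#' @param d_bound_um2_s diffusion coefficient of bound pairs, um2/s.
#' @param kon_hazard per-frame binding probability applied to each free A-B
#'   pair closer than `reaction_radius_um`. Calibrate against a target
#'   association rate constant with [calibrate_binding_hazard()].
#' @param koff_per_s dissociation rate constant, 1/s. A bound pair separates
#'   each frame with probability `1 - exp(-koff_per_s * dt_s)`.
#' @param reaction_radius_um capture radius for binding, um.
#' @param contact_radius_um on binding, a pair further apart than this is
#'   pulled to this separation (molecular contact), so bound pairs stay
#'   detectable inside the colocalization search radius even when the
#'   capture radius is large. Default: `min(reaction_radius_um, 0.05)`.
#' @param confinement_zone_radius_um radius of static circular confinement
#'   zones, um.
#' @param confinement_area_fraction fraction of the field area covered by
#'   confinement zones (zones may overlap; the fraction sets the zone count).
#' @param d_confined_factor multiplier in (0, 1] applied to the diffusion
#'   coefficient inside a confinement zone.
#' @param zone_escape_prob probability that a step crossing a zone boundary
#'   from inside is allowed to leave; otherwise it is reflected back into
#'   the zone.
#' @param zone_entry_prob probability that a step crossing a zone boundary
#'   from outside is allowed to enter; otherwise the step is rejected.
#'   Default `zone_escape_prob * sqrt(d_confined_factor)`: because step
#'   lengths differ across the boundary (slow diffusion inside), flux
#'   balance requires `p_entry * sigma_out = p_escape * sigma_in`; this
#'   choice keeps the steady-state molecule density spatially uniform
#'   (no pile-up inside zones), which the density bookkeeping of the
#'   kinetics normalization assumes.
#' @param release_radius_um if set, a dissociating pair is separated to this
#'   distance (random direction) instead of staying at contact. Placing it
#'   just outside `reaction_radius_um` suppresses instant rebinding, which
#'   the dwell-time deconvolution model does not represent (it would merge
#'   consecutive binding events into one long apparent event). NULL (default)
#'   leaves the pair at its contact separation.
#' @param bind_in_zones_only if TRUE, binding only occurs when the A molecule
#'   is inside a confinement zone (used to emulate interactions nucleating in
#'   confined membrane domains).
#' @param loc_sigma_um localization noise s.d. per axis, um.
#' @param registration_residual_um s.d. of the fixed per-field channel-B
#'   offset emulating imperfect inter-channel registration, um.
#' @param dropout_prob per-localization missed-detection probability.
#' @param split_gap_frames a detected track is emitted as separate segments
#'   wherever more than this many consecutive frames are missing.
#' @param seed integer seed making the field reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_field()], [calibrate_binding_hazard()]
#' @export
sim_config <- function(field_width_um = 10, field_height_um = 10,
                       n_frames = 400L, dt_s = 0.033,
                       density_a_per_um2 = 0.42, density_b_per_um2 = 0.59,
                       d_free_um2_s = 0.1, d_bound_um2_s = 0.05,
                       kon_hazard = 0, koff_per_s = 1,
                       reaction_radius_um = 0.05,
                       contact_radius_um = NULL,
                       confinement_zone_radius_um = 0.1,
                       confinement_area_fraction = 0.1,
                       d_confined_factor = 0.1,
                       zone_escape_prob = 0.1,
                       zone_entry_prob = NULL,
                       release_radius_um = NULL,
                       bind_in_zones_only = FALSE,
                       loc_sigma_um = 0.02,
                       registration_residual_um = 0.02,
                       dropout_prob = 0.05,
                       split_gap_frames = 1L,
                       seed = 1L) {
  cfg <- list(
    field_width_um = field_width_um, field_height_um = field_height_um,
    n_frames = as.integer(n_frames), dt_s = dt_s,
    density_a_per_um2 = density_a_per_um2,
    density_b_per_um2 = density_b_per_um2,
    d_free_um2_s = d_free_um2_s, d_bound_um2_s = d_bound_um2_s,
    kon_hazard = kon_hazard, koff_per_s = koff_per_s,
    reaction_radius_um = reaction_radius_um,
    contact_radius_um = contact_radius_um %||% min(reaction_radius_um, 0.05),
    confinement_zone_radius_um = confinement_zone_radius_um,
    confinement_area_fraction = confinement_area_fraction,
    d_confined_factor = d_confined_factor,
    zone_escape_prob = zone_escape_prob,
    zone_entry_prob = zone_entry_prob %||%
      (zone_escape_prob * sqrt(d_confined_factor)),
    release_radius_um = release_radius_um,
    bind_in_zones_only = isTRUE(bind_in_zones_only),
    loc_sigma_um = loc_sigma_um,
    registration_residual_um = registration_residual_um,
    dropout_prob = dropout_prob,
    split_gap_frames = as.integer(split_gap_frames),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_scalar_num(cfg$field_width_um, "field_width_um", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$field_height_um, "field_height_um", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$n_frames, "n_frames", 2)
  assert_scalar_num(cfg$dt_s, "dt_s", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$density_a_per_um2, "density_a_per_um2", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$density_b_per_um2, "density_b_per_um2", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$d_free_um2_s, "d_free_um2_s", 0)
  assert_scalar_num(cfg$d_bound_um2_s, "d_bound_um2_s", 0)
  assert_scalar_num(cfg$kon_hazard, "kon_hazard", 0, 1)
  assert_scalar_num(cfg$koff_per_s, "koff_per_s", 0)
  assert_scalar_num(cfg$reaction_radius_um, "reaction_radius_um", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$contact_radius_um, "contact_radius_um", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$confinement_zone_radius_um, "confinement_zone_radius_um", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$confinement_area_fraction, "confinement_area_fraction", 0, 1)
  assert_scalar_num(cfg$d_confined_factor, "d_confined_factor", 0, 1, strict_lower = TRUE)
  assert_scalar_num(cfg$zone_escape_prob, "zone_escape_prob", 0, 1)
  assert_scalar_num(cfg$zone_entry_prob, "zone_entry_prob", 0, 1)
  if (!is.null(cfg$release_radius_um)) {
    assert_scalar_num(cfg$release_radius_um, "release_radius_um", 0,
                      strict_lower = TRUE)
  }
  assert_scalar_num(cfg$loc_sigma_um, "loc_sigma_um", 0)
  assert_scalar_num(cfg$registration_residual_um, "registration_residual_um", 0)
  assert_scalar_num(cfg$dropout_prob, "dropout_prob", 0, 1)
  assert_scalar_num(cfg$split_gap_frames, "split_gap_frames", 0)
  area <- cfg$field_width_um * cfg$field_height_um
  if (cfg$density_a_per_um2 * area < 1 || cfg$density_b_per_um2 * area < 1) {
    stop("expected molecule count (density x area) must be >= 1 in both channels",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  field: %g x %g um, %d frames @ %g s\n",
              x$field_width_um, x$field_height_um, x$n_frames, x$dt_s))
  cat(sprintf("  densities A/B: %g / %g um^-2; D free/bound: %g / %g um^2/s\n",
              x$density_a_per_um2, x$density_b_per_um2,
              x$d_free_um2_s, x$d_bound_um2_s))
  cat(sprintf("  binding: hazard %g/frame within %g um; koff %g /s\n",
              x$kon_hazard, x$reaction_radius_um, x$koff_per_s))
  cat(sprintf("  confinement: zones r=%g um, area fraction %g, D factor %g\n",
              x$confinement_zone_radius_um, x$confinement_area_fraction,
              x$d_confined_factor))
  cat(sprintf("  measurement: loc sigma %g um, reg residual %g um, dropout %g\n",
              x$loc_sigma_um, x$registration_residual_um, x$dropout_prob))
  invisible(x)
}
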