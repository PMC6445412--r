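# Synthetic generators for the three input classes: environment
# dioptric-defocus maps, peripheral-refraction meridian scan sets, and
# on-eye over-refraction scan sets for multifocal contact lenses.

SCENE_ARCHETYPES <- c("office", "corridor", "living_room")
LENS_DESIGNS <- c("near_centre", "distance_centre")
PROFILE_CLASSES <- c("NPS", "RPM", "RPH", "TPS")
SCAN_ELEVATIONS <- c(-20, -10, 0, 10, 20)
SCAN_AZIMUTHS <- seq(-40, 40, by = 1)

#' Specify a synthetic indoor scene
#'
#' A scene is a dioptric-defocus map of the visual field: at each field angle
#' the mismatch `1/gaze_distance - 1/object_distance` in dioptres between the
#' accommodative (gaze) plane and the object there. Archetype presets emulate
#' the qualitative structure of indoor activities: `"office"` is near work
#' (gaze 0.5 m) with a desk plane in the inferior field against a farther
#' room; `"corridor"` is a far, low-variance field (gaze 3 m); and
#' `"living_room"` mixes near and far patches around a 2 m gaze.
#'
#' @param archetype `"office"`, `"corridor"` or `"living_room"`.
#' @param gaze_distance Distance of the gaze/accommodation plane in metres.
#' @param background_distance Object distance outside all patches, metres.
#' @param object_patches List of patches, each a list with elements `x`, `y`
#'   (patch centre, degrees, within +-20), `radius` (degrees) and
#'   `distance` (metres). Later patches overwrite earlier ones.
#' @param smoothness Gaussian smoothing scale in degrees (0 disables).
#' @param noise_sd SD of i.i.d. Gaussian pixel noise in dioptres.
#' @param seed Integer seed; `make_scene()` is deterministic given the spec.
#' @return A `scene_spec` list.
#' @export
#' @examples
#' sc <- make_scene(scene_spec("office", seed = 1))
scene_spec <- function(archetype,
                       gaze_distance = NULL,
                       background_distance = NULL,
                       object_patches = NULL,
                       smoothness = 1.5,
                       noise_sd = 0.1,
                       seed = 1L) {
  archetype <- arg_match(archetype, SCENE_ARCHETYPES)
  preset <- switch(archetype,
    office = list(
      gaze = 0.5, background = 3,
      patches = list(
        list(x = 0, y = -12, radius = 9, distance = 0.55),  # desk / document
        list(x = -12, y = 6, radius = 6, distance = 4),     # far wall corner
        list(x = 10, y = 2, radius = 5, distance = 2)       # side shelf
      )
    ),
    corridor = list(
      gaze = 3, background = 3.5,
      patches = list(
        list(x = 0, y = -14, radius = 10, distance = 1.8),  # floor ahead
        list(x = 14, y = 0, radius = 5, distance = 2.5)     # near wall
      )
    ),
    living_room = list(
      gaze = 2, background = 4,
      patches = list(
        list(x = -8, y = -10, radius = 7, distance = 1),    # coffee table
        list(x = 8, y = 4, radius = 6, distance = 2.5),     # tv / shelf
        list(x = -12, y = 10, radius = 5, distance = 5)     # window
      )
    )
  )
  spec <- list(
    archetype = archetype,
    gaze_distance = gaze_distance %||% preset$gaze,
    background_distance = background_distance %||% preset$background,
    object_patches = object_patches %||% preset$patches,
    smoothness = smoothness,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (spec$gaze_distance <= 0 || spec$background_distance <= 0) {
    abort("Gaze and background distances must be positive (metres).")
  }
  for (p in spec$object_patches) {
    if (p$distance <= 0) abort("Patch distances must be positive (metres).")
    if (abs(p$x) > MAP_EXTENT || abs(p$y) > MAP_EXTENT) {
      abort("Patch centres must lie within +-20 degrees.")
    }
  }
  structure(spec, class = "scene_spec")
}

# Truncated-Gaussian separable smoothing operator (rows renormalised so a
# constant field stays exactly constant).
smoothing_operator <- function(sigma_px) {
  idx <- seq_len(MAP_N)
  B <- exp(-outer(idx, idx, "-")^2 / (2 * sigma_px^2))
  B[abs(outer(idx, idx, "-")) > ceiling(4 * sigma_px)] <- 0
  B / rowSums(B)
}

#' Generate an environment dioptric-defocus map
#'
#' Rasterises the scene's object distances onto the 400 x 400 visual-field
#' grid, converts to dioptric defocus relative to the gaze plane, smooths at
#' the spec's spatial scale and adds Gaussian pixel noise.
#'
#' @param spec A [scene_spec()].
#' @return A `field_map` in the `VISUAL_FIELD` frame, semantics
#'   `"ENV_DEFOCUS"`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ctr <- pixel_centres()
  x <- matrix(ctr, MAP_N, MAP_N, byrow = TRUE)
  y <- matrix(rev(ctr), MAP_N, MAP_N)
  dist <- matrix(spec$background_distance, MAP_N, MAP_N)
  for (p in spec$object_patches) {
    inside <- (x - p$x)^2 + (y - p$y)^2 <= p$radius^2
    dist[inside] <- p$distance
  }
  defocus <- 1 / spec$gaze_distance - 1 / dist
  if (spec$smoothness > 0) {
    B <- smoothing_operator(spec$smoothness / MAP_PITCH)
    defocus <- B %*% defocus %*% t(B)
  }
  if (spec$noise_sd > 0) {
    defocus <- defocus + with_seed(
      spec$seed, matrix(rnorm(MAP_N * MAP_N, sd = spec$noise_sd), MAP_N)
    )
  }
  field_map(defocus, frame = "VISUAL_FIELD", semantics = "ENV_DEFOCUS")
}

#' Specify a synthetic peripheral-refraction shell
#'
#' The noiseless spherical-equivalent surface is
#' `M(azimuth, elevation) = central_M + symmetric_curvature * azimuth^2 +
#' skew(azimuth) + elevation_curvature * elevation^2`, where the skew term is
#' a smooth half-cosine ramp over the outer 20 degrees of the skewed side,
#' reaching `skew_amplitude` at 40 degrees. Repeated scans add i.i.d.
#' Gaussian noise per point. Azimuths follow the scan-table convention:
#' visual-field angle, nasal visual field positive.
#'
#' @param target_class `"NPS"`, `"RPM"`, `"RPH"` or `"TPS"` — the profile the
#'   parameters are meant to produce. Inconsistent parameter/side
#'   combinations (e.g. NPS with a temporal skew) are rejected.
#' @param central_M Central spherical equivalent, dioptres.
#' @param symmetric_curvature Quadratic relative-periphery term, D/deg^2
#'   (negative for relative peripheral myopia, positive for hyperopia).
#' @param skew_amplitude One-sided edge shift in dioptres (>= 0).
#' @param skew_side `"nasal"`, `"temporal"` or `"none"`.
#' @param elevation_curvature Quadratic term along elevation, D/deg^2.
#' @param scan_noise_sd Per-scan Gaussian noise SD in dioptres. Default 0.26,
#'   the pooled between-scan SD the filtering stage is expected to leave.
#' @param n_scans Repeated scans per fixation (default 4).
#' @param seed Integer seed.
#' @return A `shell_spec` list.
#' @export
shell_spec <- function(target_class,
                       central_M = -3,
                       symmetric_curvature = 0,
                       skew_amplitude = 0,
                       skew_side = c("none", "nasal", "temporal"),
                       elevation_curvature = 0,
                       scan_noise_sd = 0.26,
                       n_scans = 4L,
                       seed = 1L) {
  target_class <- arg_match(target_class, PROFILE_CLASSES)
  skew_side <- arg_match(skew_side)
  if (skew_amplitude < 0) abort("`skew_amplitude` must be >= 0.")
  if (n_scans < 2) abort("`n_scans` must be at least 2.")
  if (scan_noise_sd < 0) abort("`scan_noise_sd` must be >= 0.")
  ok <- switch(target_class,
    NPS = skew_side == "nasal" && skew_amplitude > 0,
    TPS = skew_side == "temporal" && skew_amplitude > 0,
    RPM = skew_side == "none" && symmetric_curvature < 0,
    RPH = skew_side == "none" && symmetric_curvature > 0
  )
  if (!ok) {
    abort(sprintf(
      "Parameters are inconsistent with target class %s (skew_side %s).",
      target_class, skew_side
    ))
  }
  structure(
    list(
      target_class = target_class, central_M = central_M,
      symmetric_curvature = symmetric_curvature,
      skew_amplitude = skew_amplitude, skew_side = skew_side,
      elevation_curvature = elevation_curvature,
      scan_noise_sd = scan_noise_sd, n_scans = as.integer(n_scans),
      seed = as.integer(seed)
    ),
    class = "shell_spec"
  )
}

#' Shell spec with a given peripheral amplitude for a target class
#'
#' Convenience constructor: `amplitude` is the relative-periphery magnitude
#' at 40 degrees. For the skewed classes it becomes `skew_amplitude`; for
#' RPM/RPH it sets `symmetric_curvature = +-amplitude / 1600`.
#'
#' @param target_class Profile class label.
#' @param amplitude Peripheral amplitude at 40 degrees, dioptres (> 0).
#' @param ... Passed to [shell_spec()].
#' @return A `shell_spec`.
#' @export
shell_spec_for_class <- function(target_class, amplitude, ...) {
  target_class <- arg_match(target_class, PROFILE_CLASSES)
  stopifnot(amplitude > 0)
  switch(target_class,
    NPS = shell_spec("NPS", skew_amplitude = amplitude, skew_side = "nasal",
                     ...),
    TPS = shell_spec("TPS", skew_amplitude = amplitude,
                     skew_side = "temporal", ...),
    RPM = shell_spec("RPM", symmetric_curvature = -amplitude / 1600, ...),
    RPH = shell_spec("RPH", symmetric_curvature = amplitude / 1600, ...)
  )
}

# Half-cosine one-sided edge ramp: 0 inside +-20 deg, amplitude at |az| = 40.
skew_term <- function(azimuth, amplitude, side) {
  if (side == "none" || amplitude == 0) return(rep(0, length(azimuth)))
  s <- if (side == "nasal") azimuth else -azimuth
  ramp <- ifelse(s > 20, (1 - cos(pi * (s - 20) / 20)) / 2, 0)
  amplitude * ramp
}

shell_mean_surface <- function(spec, azimuth, elevation) {
  spec$central_M +
    spec$symmetric_curvature * azimuth^2 +
    skew_term(azimuth, spec$skew_amplitude, spec$skew_side) +
    spec$elevation_curvature * elevation^2
}

#' Generate a naked-eye meridian scan set
#'
#' Emulates repeated peripheral wavefront scans along the five horizontal
#' meridians (elevations 0, +-10, +-20 degrees; 81 azimuths from -40 to +40).
#'
#' @param spec A [shell_spec()].
#' @return A tibble with columns `condition` (`"NAKED"`), `elevation_deg`,
#'   `azimuth_deg`, `scan_index`, `M_diopters` — one row per scan per point.
#' @export
#' @examples
#' scans <- make_shell(shell_spec_for_class("NPS", 1.5, seed = 7))
#' dplyr::count(scans, elevation_deg)
make_shell <- function(spec) {
  stopifnot(inherits(spec, "shell_spec"))
  grid <- expand_grid(
    elevation_deg = SCAN_ELEVATIONS,
    azimuth_deg = SCAN_AZIMUTHS,
    scan_index = seq_len(spec$n_scans)
  )
  mu <- shell_mean_surface(spec, grid$azimuth_deg, grid$elevation_deg)
  noise <- if (spec$scan_noise_sd > 0) {
    with_seed(spec$seed, rnorm(nrow(grid), sd = spec$scan_noise_sd))
  } else {
    0
  }
  tibble(
    condition = "NAKED",
    elevation_deg = grid$elevation_deg,
    azimuth_deg = grid$azimuth_deg,
    scan_index = grid$scan_index,
    M_diopters = mu + noise
  )
}

#' Specify a multifocal contact-lens design
#'
#' Radial power profiles with a Gaussian transition between the centre and
#' the add zone: a near-centre lens is
#' `centre_power + add_power * exp(-r^2 / transition_radius^2)` and a
#' distance-centre lens
#' `centre_power + add_power * (1 - exp(-r^2 / transition_radius^2))`, with
#' `r` the field angle from the (possibly decentred) lens axis. An optional
#' azimuthal tilt `asymmetry_amplitude * azimuth / 40` emulates the
#' nasal-temporal asymmetry seen in on-eye profiles.
#'
#' @param design `"near_centre"` or `"distance_centre"`.
#' @param centre_power Power at the lens centre, dioptres (default -0.25).
#' @param add_power Add power in dioptres; defaults to 2.25 for near-centre
#'   and 2.50 for distance-centre designs. Must be >= 0.
#' @param transition_radius Radial scale of the centre/add transition,
#'   degrees.
#' @param decentration Numeric `(dx, dy)` offset of the lens axis, degrees.
#' @param asymmetry_amplitude Tilt reaching this many dioptres at +-40
#'   degrees azimuth (signed; 0 = rotationally symmetric design).
#' @param scan_noise_sd Extra per-scan over-refraction noise SD, dioptres
#'   (default 0: on-eye scans reuse the naked-eye scan noise).
#' @param seed Integer seed for the extra noise.
#' @return A `lens_spec` list.
#' @export
lens_spec <- function(design,
                      centre_power = -0.25,
                      add_power = NULL,
                      transition_radius = 15,
                      decentration = c(0, 0),
                      asymmetry_amplitude = 0,
                      scan_noise_sd = 0,
                      seed = 1L) {
  design <- arg_match(design, LENS_DESIGNS)
  add_power <- add_power %||%
    switch(design, near_centre = 2.25, distance_centre = 2.50)
  if (add_power < 0) abort("`add_power` must be >= 0.")
  if (transition_radius <= 0) abort("`transition_radius` must be > 0.")
  if (length(decentration) != 2L) {
    abort("`decentration` must be a length-2 (dx, dy) vector in degrees.")
  }
  structure(
    list(
      design = design, centre_power = centre_power, add_power = add_power,
      transition_radius = transition_radius,
      decentration = as.numeric(decentration),
      asymmetry_amplitude = asymmetry_amplitude,
      scan_noise_sd = scan_noise_sd, seed = as.integer(seed)
    ),
    class = "lens_spec"
  )
}

#' Analytic lens power at field angles
#'
#' Evaluates the design's noiseless power profile (including decentration and
#' asymmetry tilt) at scan coordinates. This is the quantity over-refraction
#' subtraction recovers.
#'
#' @param spec A [lens_spec()].
#' @param azimuth,elevation Field angles in degrees (vectorised).
#' @return Dioptres, same length as the inputs.
#' @export
lens_power_profile <- function(spec, azimuth, elevation) {
  stopifnot(inherits(spec, "lens_spec"))
  r2 <- (azimuth - spec$decentration[1])^2 +
    (elevation - spec$decentration[2])^2
  g <- exp(-r2 / spec$transition_radius^2)
  radial <- switch(spec$design,
    near_centre = spec$centre_power + spec$add_power * g,
    distance_centre = spec$centre_power + spec$add_power * (1 - g)
  )
  radial + spec$asymmetry_amplitude * azimuth / 40
}

#' Generate on-eye over-refraction scans for a lens design
#'
#' Each naked-eye scan value gains the lens's analytic power at that point,
#' plus optional extra measurement noise. Subtracting the averaged naked-eye
#' set from the averaged on-eye set therefore recovers the lens profile
#' exactly when `scan_noise_sd = 0`.
#'
#' @param spec A [lens_spec()].
#' @param naked A naked-eye scan tibble from [make_shell()].
#' @return A scan tibble with `condition` `"ON_LENS_NEAR_CENTRE"` or
#'   `"ON_LENS_DISTANCE_CENTRE"`.
#' @export
make_lens_scans <- function(spec, naked) {
  stopifnot(inherits(spec, "lens_spec"))
  check_scan_table(naked)
  lens <- lens_power_profile(spec, naked$azimuth_deg, naked$elevation_deg)
  noise <- if (spec$scan_noise_sd > 0) {
    with_seed(spec$seed, rnorm(nrow(naked), sd = spec$scan_noise_sd))
  } else {
    0
  }
  out <- naked
  out$condition <- paste0("ON_LENS_", toupper(spec$design))
  out$M_diopters <- naked$M_diopters + lens + noise
  out
}

check_scan_table <- function(x, call = rlang::caller_env()) {
  needed <- c("condition", "elevation_deg", "azimuth_deg", "scan_index",
              "M_diopters")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    abort(
      sprintf("Scan table must have columns: %s.",
              paste(needed, collapse = ", ")),
      call = call
    )
  }
  invisible(x)
}
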