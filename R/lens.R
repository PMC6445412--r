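# Lens power profiles from over-refraction subtraction, theoretical
# symmetric designs, and lens power maps.

#' Lens power profile by over-refraction subtraction
#'
#' Subtracts the averaged naked-eye refraction from the averaged on-eye
#' refraction, point by point on the meridian grid, yielding the lens's
#' effective in-situ power profile. A point missing in either input stays
#' missing in the profile.
#'
#' @param on_eye Averaged meridian tibble measured with the lens on
#'   (condition `"ON_LENS_*"`).
#' @param naked Averaged meridian tibble of the naked eye, same grid.
#' @param design `"near_centre"` or `"distance_centre"`; inferred from the
#'   on-eye condition label when `NULL`.
#' @return A `lens_profile` object: the per-point `power_D` differences on
#'   the meridian grid plus the design label.
#' @export
#' @examples
#' naked <- average_scans(make_shell(shell_spec_for_class("NPS", 1, seed = 4,
#'                                                        scan_noise_sd = 0)))
#' on <- average_scans(make_lens_scans(lens_spec("near_centre"),
#'                                     make_shell(shell_spec_for_class(
#'                                       "NPS", 1, seed = 4,
#'                                       scan_noise_sd = 0))))
#' prof <- over_refraction(on, naked)
over_refraction <- function(on_eye, naked, design = NULL) {
  check_averaged_table(on_eye)
  check_averaged_table(naked)
  if (is.null(design)) {
    cond <- unique(on_eye$condition)
    design <- switch(cond[[1]],
      ON_LENS_NEAR_CENTRE = "near_centre",
      ON_LENS_DISTANCE_CENTRE = "distance_centre",
      abort("Cannot infer `design` from the on-eye condition label.")
    )
  }
  design <- arg_match(design, LENS_DESIGNS)
  a <- on_eye |>
    select("elevation_deg", "azimuth_deg", on_M = "mean_M",
           on_missing = "missing")
  b <- naked |>
    select("elevation_deg", "azimuth_deg", naked_M = "mean_M",
           naked_missing = "missing")
  if (nrow(a) != nrow(b)) abort("On-eye and naked grids do not match.")
  joined <- inner_join(a, b, by = c("elevation_deg", "azimuth_deg"))
  if (nrow(joined) != nrow(a)) {
    abort("On-eye and naked grids do not match.")
  }
  diffs <- joined |>
    mutate(
      missing = .data$on_missing | .data$naked_missing,
      power_D = if_else(.data$missing, NA_real_,
                        .data$on_M - .data$naked_M)
    ) |>
    select("elevation_deg", "azimuth_deg", "power_D", "missing") |>
    arrange(.data$elevation_deg, .data$azimuth_deg)
  new_lens_profile(design, diffs, symmetric = FALSE)
}

new_lens_profile <- function(design, differences, symmetric) {
  structure(
    list(design = design, differences = differences, symmetric = symmetric),
    class = "lens_profile"
  )
}

#' @export
print.lens_profile <- function(x, ...) {
  cat(sprintf(
    "<lens_profile> %s%s: %d grid points (%d missing)\n",
    x$design, if (x$symmetric) " (symmetrized)" else "",
    nrow(x$differences), sum(x$differences$missing)
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.lens_profile <- function(x, ...) x$differences

#' Theoretical symmetric lens profile
#'
#' Mirror-averages each meridian about azimuth zero:
#' `s(theta) = (f(theta) + f(-theta)) / 2`. This preserves each meridian's
#' mean, is idempotent, and yields an exactly left-right-symmetric profile —
#' the theoretical counterpart of an asymmetric measured profile. Elevation
#' is not symmetrized. Missingness propagates from either mirror point.
#'
#' @param profile A `lens_profile` on an azimuth grid symmetric about 0.
#' @return A `lens_profile` flagged `symmetric = TRUE`.
#' @export
symmetrize <- function(profile) {
  stopifnot(inherits(profile, "lens_profile"))
  d <- profile$differences
  mirrored <- d |>
    mutate(azimuth_deg = -.data$azimuth_deg) |>
    select("elevation_deg", "azimuth_deg", mirror_D = "power_D",
           mirror_missing = "missing")
  joined <- inner_join(d, mirrored, by = c("elevation_deg", "azimuth_deg"))
  if (nrow(joined) != nrow(d)) {
    abort("Azimuth grid must be symmetric about 0 to symmetrize.")
  }
  out <- joined |>
    mutate(
      missing = .data$missing | .data$mirror_missing,
      power_D = if_else(.data$missing, NA_real_,
                        (.data$power_D + .data$mirror_D) / 2)
    ) |>
    select("elevation_deg", "azimuth_deg", "power_D", "missing") |>
    arrange(.data$elevation_deg, .data$azimuth_deg)
  new_lens_profile(profile$design, out, symmetric = TRUE)
}

#' Lens power map from a lens profile
#'
#' Interpolates the per-meridian power differences into a 400 x 400 retinal
#' lens power map with the same tensor-spline contract as [fit_surface()].
#'
#' @param profile A `lens_profile`.
#' @return A `field_map` with semantics `"LENS_POWER"`, RETINAL frame.
#' @export
lens_power_map <- function(profile) {
  stopifnot(inherits(profile, "lens_profile"))
  averaged <- profile$differences |>
    mutate(
      condition = paste0("LENS_", toupper(profile$design)),
      mean_M = .data$power_D
    )
  fit_surface(averaged, semantics = "LENS_POWER")
}
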