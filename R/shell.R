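# Filtering and averaging of repeated meridian scans, peripheral-refraction
# profile classification, and interpolation of the 40 x 40 degree field map.

#' Shell processing parameters
#'
#' @param sd_threshold Acceptance threshold on the between-scan standard
#'   deviation at each angle, dioptres (default 1). Points whose repeated
#'   scans spread more than this are flagged missing.
#' @param tau Classification threshold in dioptres (default 0.25, one
#'   clinical refraction step): how much more positive an edge-zone mean must
#'   be than a reference zone to count as skew/relative hyperopia.
#' @param central_zone Half-width of the central comparison zone, degrees
#'   (default 10: a 20-degree central area).
#' @param edge_zone Inner and outer azimuth bounds of the edge zones,
#'   degrees (default `c(20, 40)`: the outer 20 degrees on each side).
#' @return A `shell_params` list.
#' @export
shell_params <- function(sd_threshold = 1, tau = 0.25,
                         central_zone = 10, edge_zone = c(20, 40)) {
  if (sd_threshold <= 0) abort("`sd_threshold` must be > 0.")
  if (tau <= 0) abort("`tau` must be > 0.")
  if (central_zone <= 0 || central_zone > max(SCAN_AZIMUTHS)) {
    abort("`central_zone` must lie within the scan range.")
  }
  if (length(edge_zone) != 2L || edge_zone[1] >= edge_zone[2] ||
      edge_zone[2] > max(SCAN_AZIMUTHS)) {
    abort("`edge_zone` must be increasing bounds within the scan range.")
  }
  structure(
    list(sd_threshold = sd_threshold, tau = tau,
         central_zone = central_zone, edge_zone = edge_zone),
    class = "shell_params"
  )
}

#' Average repeated scans and filter unreliable points
#'
#' Per (condition, elevation, azimuth) point: the mean and sample SD over the
#' repeated spherical-equivalent values. Points whose SD exceeds
#' `params$sd_threshold` are flagged `missing` (their mean is set to `NA`,
#' never silently zero). A meridian in which more than half of the points are
#' missing raises a quality error.
#'
#' @param scans Scan tibble (see [make_shell()]); every point needs at least
#'   two repeats.
#' @param params [shell_params()].
#' @return A tibble with columns `condition`, `elevation_deg`, `azimuth_deg`,
#'   `mean_M`, `sd_M`, `n_used`, `missing`.
#' @export
#' @examples
#' avg <- average_scans(make_shell(shell_spec_for_class("RPM", 1, seed = 2)))
average_scans <- function(scans, params = shell_params()) {
  check_scan_table(scans)
  stopifnot(inherits(params, "shell_params"))
  avg <- scans |>
    group_by(.data$condition, .data$elevation_deg, .data$azimuth_deg) |>
    summarise(
      mean_M = mean(.data$M_diopters),
      sd_M = sd(.data$M_diopters),
      n_used = n(),
      .groups = "drop"
    ) |>
    mutate(
      missing = .data$sd_M > params$sd_threshold,
      mean_M = if_else(.data$missing, NA_real_, .data$mean_M)
    ) |>
    arrange(.data$condition, .data$elevation_deg, .data$azimuth_deg)
  if (any(avg$n_used < 2L)) {
    abort("Every scan point needs at least 2 repeats to estimate its SD.")
  }
  bad <- avg |>
    group_by(.data$condition, .data$elevation_deg) |>
    summarise(frac = mean(.data$missing), .groups = "drop") |>
    filter(.data$frac > 0.5)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Meridian quality error: > 50%% of points missing at elevation(s) %s.",
      paste(unique(bad$elevation_deg), collapse = ", ")
    ))
  }
  avg
}

check_averaged_table <- function(x, call = rlang::caller_env()) {
  needed <- c("condition", "elevation_deg", "azimuth_deg", "mean_M",
              "missing")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    abort(
      sprintf("Averaged meridian table must have columns: %s.",
              paste(needed, collapse = ", ")),
      call = call
    )
  }
  invisible(x)
}

#' Classify the peripheral-refraction profile from the equatorial meridian
#'
#' Compares zone means of the averaged equator (elevation 0): `N` over the
#' nasal edge zone, `T` over the temporal edge zone and `C` over the central
#' zone (azimuths in the scan convention, nasal visual field positive).
#' With threshold `tau`, the label is the first match of:
#' RPH if `N - C >= tau` and `T - C >= tau`; RPM if `C - N >= tau` and
#' `C - T >= tau`; NPS if `N - C >= tau` and `N - T >= tau`; TPS if
#' `T - C >= tau` and `T - N >= tau`; otherwise INDETERMINATE.
#'
#' @param averaged Averaged meridian tibble from [average_scans()].
#' @param params [shell_params()].
#' @return A `profile_class` object with the label and the three zone means.
#' @export
classify_profile <- function(averaged, params = shell_params()) {
  check_averaged_table(averaged)
  stopifnot(inherits(params, "shell_params"))
  eq <- averaged |>
    filter(.data$elevation_deg == 0, !.data$missing)
  if (nrow(eq) == 0L) abort("No usable equatorial (elevation 0) points.")
  zone_mean <- function(lo, hi) {
    v <- eq$mean_M[eq$azimuth_deg >= lo & eq$azimuth_deg <= hi]
    if (length(v) == 0L) {
      abort(sprintf(
        "Zone [%g, %g] deg is empty after removing unreliable points.",
        lo, hi
      ))
    }
    mean(v)
  }
  N <- zone_mean(params$edge_zone[1], params$edge_zone[2])
  T_ <- zone_mean(-params$edge_zone[2], -params$edge_zone[1])
  C <- zone_mean(-params$central_zone, params$central_zone)
  tau <- params$tau
  label <- if (N - C >= tau && T_ - C >= tau) {
    "RPH"
  } else if (C - N >= tau && C - T_ >= tau) {
    "RPM"
  } else if (N - C >= tau && N - T_ >= tau) {
    "NPS"
  } else if (T_ - C >= tau && T_ - N >= tau) {
    "TPS"
  } else {
    "INDETERMINATE"
  }
  structure(
    list(label = label, nasal_edge_mean = N, temporal_edge_mean = T_,
         central_mean = C, tau = tau),
    class = "profile_class"
  )
}

#' @export
print.profile_class <- function(x, ...) {
  cat(sprintf(
    "<profile_class> %s (tau = %.2f D)\n  zone means [D]: nasal %.3f, central %.3f, temporal %.3f\n",
    x$label, x$tau, x$nasal_edge_mean, x$central_mean, x$temporal_edge_mean
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.profile_class <- function(x, ...) {
  tibble(
    label = x$label, nasal_edge_mean = x$nasal_edge_mean,
    temporal_edge_mean = x$temporal_edge_mean, central_mean = x$central_mean,
    tau = x$tau
  )
}

# Crop one condition's averaged set to the central +-20 deg span, fill
# missing points by linear interpolation along each meridian (never across
# meridians), and return a node grid in retinal coordinates.
shell_nodes <- function(averaged) {
  check_averaged_table(averaged)
  if (n_distinct(averaged$condition) != 1L) {
    abort("Surface fitting expects a single condition at a time.")
  }
  elevs <- sort(unique(averaged$elevation_deg))
  if (!identical(elevs, as.numeric(SCAN_ELEVATIONS))) {
    abort("Expected the five meridians at elevations -20, -10, 0, 10, 20.")
  }
  central <- averaged |>
    filter(abs(.data$azimuth_deg) <= MAP_EXTENT) |>
    arrange(.data$elevation_deg, .data$azimuth_deg)
  filled <- central |>
    group_by(.data$elevation_deg) |>
    group_modify(function(df, key) {
      ok <- !df$missing
      if (!any(ok)) {
        abort(sprintf(
          "Entire meridian at elevation %g is missing in the central span.",
          key$elevation_deg[[1]]
        ))
      }
      if (sum(ok) == 1L) {
        df$mean_M <- df$mean_M[ok]
      } else if (!all(ok)) {
        df$mean_M <- approx(
          x = df$azimuth_deg[ok], y = df$mean_M[ok],
          xout = df$azimuth_deg, rule = 2
        )$y
      }
      df
    }) |>
    ungroup()
  # Scan convention -> retinal frame of a right eye: nasal visual field
  # projects to temporal retina (and superior field to inferior retina).
  list(
    x_nodes = -filled$azimuth_deg[filled$elevation_deg == 0],
    y_by_meridian = -elevs,
    values = lapply(elevs, function(e) {
      filled$mean_M[filled$elevation_deg == e]
    })
  )
}

#' Interpolating surface through the five-meridian node grid
#'
#' Returns a vectorised function `f(x, y)` (retinal degrees) built as a
#' tensor-product cubic-spline interpolant: a cubic spline along each
#' meridian's azimuth nodes, then a cubic spline through the five meridian
#' values at each requested `x`. The interpolant reproduces every
#' (non-missing) node value exactly.
#'
#' @param averaged Averaged meridian tibble for a single condition.
#' @return A function of vectors `x`, `y` returning dioptres.
#' @export
shell_interpolant <- function(averaged) {
  nodes <- shell_nodes(averaged)
  # nodes$values[[i]] is ordered by increasing azimuth; with x = -azimuth
  # that is decreasing x, so reverse each meridian onto an increasing x grid.
  xn <- rev(nodes$x_nodes)
  vals <- lapply(nodes$values, rev)
  yo <- order(nodes$y_by_meridian)
  yn <- nodes$y_by_meridian[yo]
  vals <- vals[yo]
  function(x, y) {
    stopifnot(length(x) == length(y))
    ux <- sort(unique(x))
    per_meridian <- vapply(
      vals, function(v) spline(xn, v, xout = ux, method = "fmm")$y,
      numeric(length(ux))
    )
    per_meridian <- matrix(per_meridian, nrow = length(ux))
    out <- numeric(length(x))
    for (i in seq_along(ux)) {
      sel <- x == ux[i]
      out[sel] <- spline(yn, per_meridian[i, ], xout = y[sel],
                         method = "fmm")$y
    }
    out
  }
}

#' Fit the 40 x 40 degree field map from averaged meridians
#'
#' Samples the [shell_interpolant()] surface at the 400 x 400 half-offset
#' pixel centres. The scan-table azimuth/elevation convention (visual field,
#' nasal and superior positive) is converted to the retinal frame of a right
#' eye, so the output map is RETINAL.
#'
#' @param averaged Averaged meridian tibble for a single condition.
#' @param semantics Semantics of the resulting map (default
#'   `"EYE_REFRACTION"`; lens profiles use `"LENS_POWER"`).
#' @return A `field_map` in the `RETINAL` frame.
#' @export
#' @examples
#' avg <- average_scans(make_shell(shell_spec_for_class("RPH", 1, seed = 3)))
#' m <- fit_surface(avg)
#' dim(m$values)
fit_surface <- function(averaged, semantics = "EYE_REFRACTION") {
  f <- shell_interpolant(averaged)
  ctr <- pixel_centres()
  xg <- rep(ctr, each = MAP_N)
  yg <- rep(rev(ctr), times = MAP_N)
  vals <- matrix(f(xg, yg), nrow = MAP_N)
  field_map(vals, frame = "RETINAL", semantics = semantics)
}
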