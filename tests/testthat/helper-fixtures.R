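# Small builders shared across test files.

# Kruskal-Wallis from a list of group vectors.
kw_from_groups <- function(groups) {
  df <- data.frame(
    v = unlist(groups),
    g = rep(paste0("g", seq_along(groups)), lengths(groups))
  )
  retdefocus::kruskal_wallis(df, v, g)
}

# Scan table with one scripted set of repeats at a chosen point and a quiet
# constant background elsewhere.
scans_with_point <- function(repeats, elevation = 0, azimuth = 0,
                             background = -3) {
  grid <- tidyr::expand_grid(
    condition = "NAKED",
    elevation_deg = c(-20, -10, 0, 10, 20),
    azimuth_deg = seq(-40, 40, by = 1),
    scan_index = seq_along(repeats)
  )
  grid$M_diopters <- background
  at <- grid$elevation_deg == elevation & grid$azimuth_deg == azimuth
  grid$M_diopters[at] <- repeats[grid$scan_index[at]]
  grid
}

# Noiseless shell scans whose averaged equator has prescribed zone means:
# central value c0, nasal edge value nv, temporal edge value tv (flat zones,
# linear blends between them).
scans_with_zone_means <- function(c0, nv, tv, n_scans = 4) {
  az <- seq(-40, 40, by = 1)
  profile <- function(th) {
    if (th >= 20) {
      c0 + (nv - c0) * 1
    } else if (th <= -20) {
      c0 + (tv - c0) * 1
    } else {
      c0
    }
  }
  vals <- vapply(az, profile, numeric(1))
  grid <- tidyr::expand_grid(
    condition = "NAKED",
    elevation_deg = c(-20, -10, 0, 10, 20),
    azimuth_deg = az,
    scan_index = seq_len(n_scans)
  )
  grid$M_diopters <- vals[match(grid$azimuth_deg, az)]
  grid
}

# A field_map with constant value.
constant_map <- function(value, frame = "RETINAL",
                         semantics = "COMBINED_DEFOCUS") {
  field_map(matrix(value, 400, 400), frame = frame, semantics = semantics)
}

# Averaged-meridian tibble built directly from a function mu(azimuth,
# elevation), bypassing scan noise entirely.
averaged_from_function <- function(mu, condition = "NAKED") {
  grid <- tidyr::expand_grid(
    condition = condition,
    elevation_deg = c(-20, -10, 0, 10, 20),
    azimuth_deg = seq(-40, 40, by = 1)
  )
  tibble::tibble(
    condition = grid$condition,
    elevation_deg = grid$elevation_deg,
    azimuth_deg = grid$azimuth_deg,
    mean_M = mu(grid$azimuth_deg, grid$elevation_deg),
    sd_M = 0,
    n_used = 4L,
    missing = FALSE
  )
}
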