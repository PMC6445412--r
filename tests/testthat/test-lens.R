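make_noiseless_pair <- function(lens = lens_spec("near_centre"),
                                shell = shell_spec_for_class(
                                  "NPS", 1, scan_noise_sd = 0
                                )) {
  naked_scans <- make_shell(shell)
  on_scans <- make_lens_scans(lens, naked_scans)
  list(
    naked = average_scans(naked_scans),
    on_eye = average_scans(on_scans),
    lens = lens
  )
}

test_that("over-refraction subtraction recovers the nominal add", {
  # naked -3.25, on-eye -1.00 -> +2.25 D (the nominal high add)
  naked <- averaged_from_function(function(az, el) rep(-3.25, length(az)))
  on_eye <- averaged_from_function(function(az, el) rep(-1.00, length(az)),
                                   condition = "ON_LENS_NEAR_CENTRE")
  prof <- over_refraction(on_eye, naked)
  expect_true(all(prof$differences$power_D == 2.25))
  expect_equal(prof$design, "near_centre")
  expect_false(prof$symmetric)

  # on-eye identical to naked -> all-zero profile
  zero <- over_refraction(
    averaged_from_function(function(az, el) rep(-3, length(az)),
                           condition = "ON_LENS_DISTANCE_CENTRE"),
    averaged_from_function(function(az, el) rep(-3, length(az)))
  )
  expect_true(all(zero$differences$power_D == 0))
})

test_that("missingness propagates and mismatched grids are rejected", {
  naked <- averaged_from_function(function(az, el) rep(-3, length(az)))
  on_eye <- averaged_from_function(function(az, el) rep(-1, length(az)),
                                   condition = "ON_LENS_NEAR_CENTRE")
  naked$missing[5] <- TRUE
  naked$mean_M[5] <- NA
  on_eye$missing[10] <- TRUE
  on_eye$mean_M[10] <- NA
  prof <- over_refraction(on_eye, naked)
  expect_true(prof$differences$missing[5])
  expect_true(prof$differences$missing[10])
  expect_true(is.na(prof$differences$power_D[5]))
  expect_equal(sum(prof$differences$missing), 2L)

  expect_error(over_refraction(on_eye[-1, ], naked), "do not match")
})

test_that("noiseless over-refraction recovers the analytic lens profile", {
  for (design in c("near_centre", "distance_centre")) {
    lens <- lens_spec(design, decentration = c(2, -1),
                      asymmetry_amplitude = 0.5)
    pair <- make_noiseless_pair(lens = lens)
    prof <- over_refraction(pair$on_eye, pair$naked)
    d <- prof$differences
    expected <- lens_power_profile(lens, d$azimuth_deg, d$elevation_deg)
    expect_lt(max(abs(d$power_D - expected)), 1e-9)
  }
})

test_that("symmetrize mirror-averages, is idempotent, preserves means", {
  # toy meridian [0, 1, 2] at azimuths [-10, 0, 10] -> [1, 1, 1]
  naked <- averaged_from_function(function(az, el) rep(0, length(az)))
  on_eye <- averaged_from_function(function(az, el) az / 10,
                                   condition = "ON_LENS_NEAR_CENTRE")
  prof <- over_refraction(on_eye, naked)
  sym <- symmetrize(prof)
  d <- sym$differences
  expect_true(all(abs(d$power_D) < 1e-12))
  expect_true(sym$symmetric)

  lens <- lens_spec("near_centre", decentration = c(3, 1),
                    asymmetry_amplitude = 1)
  pair <- make_noiseless_pair(lens = lens)
  prof2 <- over_refraction(pair$on_eye, pair$naked)
  sym2 <- symmetrize(prof2)
  # exact mirror symmetry
  wide <- sym2$differences
  mirror <- dplyr::left_join(
    wide, dplyr::mutate(wide, azimuth_deg = -azimuth_deg),
    by = c("elevation_deg", "azimuth_deg")
  )
  expect_equal(mirror$power_D.x, mirror$power_D.y)
  # idempotence
  expect_equal(symmetrize(sym2)$differences$power_D,
               sym2$differences$power_D)
  # per-meridian means preserved
  mean_by_meridian <- function(p) {
    p$differences |>
      dplyr::group_by(elevation_deg) |>
      dplyr::summarise(m = mean(power_D), .groups = "drop") |>
      dplyr::pull(m)
  }
  expect_equal(mean_by_meridian(sym2), mean_by_meridian(prof2))
  # an already-symmetric profile is unchanged
  pair_sym <- make_noiseless_pair(lens = lens_spec("near_centre"))
  prof_sym <- over_refraction(pair_sym$on_eye, pair_sym$naked)
  expect_equal(symmetrize(prof_sym)$differences$power_D,
               prof_sym$differences$power_D)
})

test_that("lens power maps honour the fit_surface contract", {
  naked <- averaged_from_function(function(az, el) rep(0, length(az)))
  # all-zero profile -> blank-equivalent map
  zero_prof <- over_refraction(
    averaged_from_function(function(az, el) rep(0, length(az)),
                           condition = "ON_LENS_NEAR_CENTRE"),
    naked
  )
  zmap <- lens_power_map(zero_prof)
  expect_equal(zmap$values, blank_map()$values)
  expect_equal(zmap$semantics, "LENS_POWER")

  # constant +2.25 profile -> constant +2.25 map
  cmap <- lens_power_map(over_refraction(
    averaged_from_function(function(az, el) rep(2.25, length(az)),
                           condition = "ON_LENS_NEAR_CENTRE"),
    naked
  ))
  expect_equal(max(abs(cmap$values - 2.25)), 0, tolerance = 1e-9)

  # noiseless synthetic near-centre profile: map matches the analytic
  # profile at the meridian nodes
  lens <- lens_spec("near_centre")
  pair <- make_noiseless_pair(lens = lens)
  prof <- over_refraction(pair$on_eye, pair$naked)
  f <- shell_interpolant(
    dplyr::mutate(prof$differences, condition = "LENS", mean_M = power_D)
  )
  nodes <- dplyr::filter(prof$differences, abs(azimuth_deg) <= 20)
  got <- f(-nodes$azimuth_deg, -nodes$elevation_deg)
  expected <- lens_power_profile(lens, nodes$azimuth_deg,
                                 nodes$elevation_deg)
  expect_lt(max(abs(got - expected)), 1e-6)
})

test_that("lens_power_map is linear in the node values", {
  naked <- averaged_from_function(function(az, el) rep(0, length(az)))
  mk <- function(fun) {
    over_refraction(
      averaged_from_function(fun, condition = "ON_LENS_NEAR_CENTRE"), naked
    )
  }
  p1 <- mk(function(az, el) 0.02 * az + 0.5)
  p2 <- mk(function(az, el) -0.001 * az^2 + 0.01 * el)
  psum <- mk(function(az, el) 0.02 * az + 0.5 - 0.001 * az^2 + 0.01 * el)
  m1 <- lens_power_map(p1)
  m2 <- lens_power_map(p2)
  msum <- lens_power_map(psum)
  expect_lt(max(abs(msum$values - (m1$values + m2$values))), 1e-9)
})
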