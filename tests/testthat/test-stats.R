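test_that("Kruskal-Wallis H matches hand computation and handles ties", {
  # mean ranks 2, 5, 8 -> H = 12/(9*10) * 3 * (9 + 0 + 9) = 7.2
  kw <- kw_from_groups(list(1:3, 4:6, 7:9))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(unname(kw$mean_ranks), c(2, 5, 8))
  expect_equal(kw$p.value, stats::pchisq(7.2, 2, lower.tail = FALSE))

  # identical groups: H = 0, p = 1 even though every value is tied
  kw0 <- kw_from_groups(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)

  # permuting group order leaves H unchanged
  kw_a <- kw_from_groups(list(c(1, 5, 3), c(2, 2, 8), c(9, 4)))
  kw_b <- kw_from_groups(list(c(9, 4), c(1, 5, 3), c(2, 2, 8)))
  expect_equal(kw_a$statistic, kw_b$statistic)

  expect_error(kw_from_groups(list(1:3)), "two groups")
  df_empty <- data.frame(v = 1:3, g = factor(c("a", "a", "b"),
                                             levels = c("a", "b", "c")))
  expect_error(kruskal_wallis(df_empty, v, g), "at least one value")

  # broom-style accessors
  expect_equal(glance(kw)$statistic, 7.2)
  expect_equal(tidy(kw)$mean_rank, c(2, 5, 8))
})

test_that("Mann-Whitney U handles exact, tied and degenerate cases", {
  # a = {1,2}, b = {3,4}: U = 0, exact two-sided p = 2/6
  m <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(m$U, 0)
  expect_equal(m$p.value, 1 / 3)
  expect_equal(m$method, "exact")

  # identical multisets: U = n^2/2, p = 1 (mid-ranks force the tie branch)
  a <- c(1, 2, 3, 4)
  m2 <- mann_whitney_u(a, a)
  expect_equal(m2$U, length(a)^2 / 2)
  expect_equal(m2$p.value, 1)

  # duality: swapping samples maps U to n_a * n_b - U, same p
  set.seed(10)
  x <- rnorm(6)
  y <- rnorm(9)
  m_xy <- mann_whitney_u(x, y)
  m_yx <- mann_whitney_u(y, x)
  expect_equal(m_xy$U, 6 * 9 - m_yx$U)
  expect_equal(m_xy$p.value, m_yx$p.value)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact MWU p-values equal full enumeration on small samples", {
  set.seed(11)
  for (i in 1:20) {
    na <- sample(2:5, 1)
    nb <- sample(2:6, 1)
    x <- sample(seq_len(100), na) / 7
    y <- (sample(seq_len(100), nb) + 0.5) / 7 # half-offset: never ties x
    # mix the ranges so orderings vary
    if (i %% 2 == 0) y <- y - 5
    m <- mann_whitney_u(x, y)
    expect_equal(m$U, oracle_mwu_u(x, y))
    expect_equal(m$p.value, oracle_mwu_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("KW and MWU statistics match brute force on 500 random cases", {
  set.seed(12)
  for (i in 1:250) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) {
      round(rnorm(sample(2:12, 1)) * 4) / 4 # induces ties
    })
    expect_equal(kw_from_groups(groups)$statistic, oracle_kw_h(groups),
                 tolerance = 1e-10)
  }
  for (i in 1:250) {
    x <- round(rnorm(sample(2:12, 1)) * 4) / 4
    y <- round(rnorm(sample(2:12, 1)) * 4) / 4
    expect_equal(mann_whitney_u(x, y)$U, oracle_mwu_u(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg step-up matches its definition", {
  res <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$reject))
  expect_equal(res$critical_p, 0.05)

  res1 <- benjamini_hochberg(rep(1, 5), q = 0.05)
  expect_true(all(!res1$reject))
  expect_equal(res1$critical_p, 0)

  set.seed(13)
  for (i in 1:200) {
    m <- sample(1:30, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    got <- benjamini_hochberg(p, q)
    want <- oracle_bh(p, q)
    expect_identical(got$reject, want$reject)
    expect_equal(got$critical_p, want$critical_p)
  }

  # order invariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.03)
  perm <- c(3, 1, 5, 2, 4)
  a <- benjamini_hochberg(p, 0.05)
  b <- benjamini_hochberg(p[perm], 0.05)
  expect_identical(a$reject[perm], b$reject)
  expect_equal(a$critical_p, b$critical_p)

  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("post-hoc pairwise comparisons control obvious cases", {
  # three well-separated groups: all pairs significant
  kw <- kw_from_groups(list(1:15, 101:115, 201:215))
  ph <- posthoc_pairwise(kw, alpha = 0.05)
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$significant))
  expect_gt(attr(ph, "critical_p"), 0)
  expect_lt(attr(ph, "critical_p"), 0.05)

  # two identical groups among three: that pair not significant
  kw2 <- kw_from_groups(list(1:15, 1:15, 201:215))
  ph2 <- posthoc_pairwise(kw2)
  same_pair <- ph2[ph2$group_a == "g1" & ph2$group_b == "g2", ]
  expect_false(same_pair$significant)
  expect_equal(same_pair$statistic, 0)

  expect_error(posthoc_pairwise(kw, alpha = 1.2), "alpha")
})

test_that("Holm flags equal brute-force Holm on the raw Dunn p-values", {
  set.seed(14)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    shift <- runif(k, 0, 2)
    groups <- lapply(shift, function(s) rnorm(sample(5:15, 1), mean = s))
    kw <- kw_from_groups(groups)
    ph <- posthoc_pairwise(kw, alpha = 0.05, method = "holm")
    expect_identical(ph$significant, oracle_holm_reject(ph$raw_p, 0.05))
  }
})

test_that("shifting one group up moves its rank z monotonically", {
  set.seed(15)
  base <- list(rnorm(30), rnorm(30), rnorm(30))
  # z for the (g1, g2) and (g1, g3) pairs, signed as mean_rank(g1) - other
  zs <- vapply(c(0, 0.5, 1, 2, 4), function(delta) {
    g <- base
    g[[1]] <- g[[1]] + delta
    ph <- posthoc_pairwise(kw_from_groups(g))
    mean(ph$statistic[ph$group_a == "g1"])
  }, numeric(1))
  expect_true(all(diff(zs) >= 0))
})

test_that("region analysis flags shifted conditions and spares identical ones", {
  masks <- make_region_masks()
  set.seed(16)
  noise <- matrix(rnorm(160000, sd = 0.3), 400)
  env <- field_map(noise, "RETINAL", "ENV_DEFOCUS")
  eye <- constant_map(-0.5, semantics = "EYE_POWER")
  shifted <- constant_map(2.25, semantics = "LENS_POWER")

  conds <- build_all_conditions(
    scenes = list(office = env),
    eye_maps = list(NPS = eye),
    lens_maps = list(near_centre = shifted)
  )
  regions <- extract_condition_regions(conds, masks)

  # constant +2.25 D shift in every pixel: all regions significant
  res <- region_condition_analysis(regions, "optic")
  expect_equal(nrow(res), 16L) # one pair per region
  expect_true(all(res$significant))
  expect_equal(nrow(nonsignificance_summary(res)), 0L)

  # identical condition maps: nothing significant anywhere
  conds2 <- conds
  conds2$map[[2]] <- conds2$map[[1]]
  regions2 <- extract_condition_regions(conds2, masks)
  res2 <- region_condition_analysis(regions2, "optic")
  expect_true(all(!res2$significant))
  expect_equal(nrow(nonsignificance_summary(res2)), 16L)

  # bookkeeping: rows = 16 regions x pairs tested
  conds3 <- build_all_conditions(
    scenes = list(office = env),
    eye_maps = list(NPS = eye),
    lens_maps = list(near_centre = shifted,
                     distance_centre = constant_map(
                       -0.25, semantics = "LENS_POWER"
                     ))
  )
  res3 <- region_condition_analysis(
    extract_condition_regions(conds3, masks), "optic"
  )
  expect_equal(nrow(res3), 16L * 3L)

  expect_error(region_condition_analysis(regions, "scene"), "two levels")
})

test_that("per-meridian scan comparison applies BH within each meridian", {
  # two lens conditions differing only beyond 20 degrees azimuth
  naked <- make_shell(shell_spec_for_class("NPS", 1, scan_noise_sd = 0.1,
                                           seed = 21))
  a <- make_lens_scans(lens_spec("near_centre", scan_noise_sd = 0.2,
                                 seed = 22), naked)
  b_spec <- lens_spec("near_centre", asymmetry_amplitude = 3,
                      scan_noise_sd = 0.2, seed = 23)
  b <- make_lens_scans(b_spec, naked)
  cmp <- compare_scan_profiles(a, b, q = 0.05)
  expect_equal(nrow(cmp), 5 * 81)
  # one critical value per meridian
  per_meridian <- cmp |>
    dplyr::group_by(elevation_deg) |>
    dplyr::summarise(k = dplyr::n_distinct(critical_p), .groups = "drop")
  expect_true(all(per_meridian$k == 1L))
  # strong asymmetry: edge points differ far more often than centre points
  edge_rate <- mean(cmp$significant[abs(cmp$azimuth_deg) > 30])
  centre_rate <- mean(cmp$significant[abs(cmp$azimuth_deg) <= 3])
  expect_gt(edge_rate, centre_rate)
})
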