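# Nonparametric comparison machinery: Kruskal-Wallis with rank-based
# familywise-error post-hoc comparisons, Mann-Whitney U, Benjamini-Hochberg
# step-up FDR, and the region x condition analysis over combined maps.

#' Kruskal-Wallis rank test over groups in a data frame
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square upper-tail p-value
#' (df = k - 1), plus the per-group mean ranks and tie term needed by the
#' rank-based post-hoc comparisons. If every value is identical across all
#' groups, H is defined as 0 with p = 1.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the values and the group
#'   labels; every group must be non-empty and there must be at least two
#'   groups.
#' @return A `kw_test` object; see [tidy()] and [glance()] methods.
#' @export
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                  g = rep(c("a", "b", "c"), each = 3))
#' glance(kruskal_wallis(df, v, g))
kruskal_wallis <- function(data, value, group) {
  stopifnot(is.data.frame(data))
  x <- rlang::eval_tidy(enquo(value), data)
  g <- rlang::eval_tidy(enquo(group), data)
  if (anyNA(x) || anyNA(g)) abort("Values and groups must not contain NA.")
  g <- if (is.factor(g)) g else factor(g) # keep declared (possibly empty) levels
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  n_i <- table(g)
  if (any(n_i == 0L)) abort("Every group must contain at least one value.")
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  mean_ranks <- tapply(r, g, mean)
  if (length(unique(x)) == 1L) {
    H <- 0
    p <- 1
  } else {
    kt <- kruskal.test(x, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(
    list(
      statistic = H, df = nlevels(g) - 1L, p.value = p,
      mean_ranks = setNames(as.numeric(mean_ranks), levels(g)),
      n = setNames(as.integer(n_i), levels(g)),
      N = N, tie_term = tie_term
    ),
    class = "kw_test"
  )
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (%d groups, N = %d)\n",
    x$statistic, x$df, x$p.value, length(x$n), x$N
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.kw_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    n_groups = length(x$n), n_total = x$N
  )
}

#' @exportS3Method generics::tidy
tidy.kw_test <- function(x, ...) {
  tibble(group = names(x$n), n = unname(x$n),
         mean_rank = unname(x$mean_ranks))
}

#' Mann-Whitney U test
#'
#' U from mid-rank sums. Two-sided p-value by exact enumeration of the null
#' rank distribution when `min(n_a, n_b) <= 8` and there are no ties, and by
#' the normal approximation with tie-corrected variance otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return An `mwu_test` list with `U` (statistic for sample `a`),
#'   `p.value`, `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p.value
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both samples must be non-empty.")
  }
  if (anyNA(a) || anyNA(b)) abort("Samples must not contain NA.")
  na <- length(a)
  nb <- length(b)
  N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (!has_ties && min(na, nb) <= 8L) {
    lower <- min(U, na * nb - U)
    p <- min(1, 2 * pwilcox(lower, na, nb))
    method <- "exact"
  } else {
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - na * nb / 2) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal_tie_corrected"
  }
  structure(
    list(U = U, p.value = p, method = method, n_a = na, n_b = nb),
    class = "mwu_test"
  )
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n_a, x$n_b, x$p.value, x$method))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mwu_test <- function(x, ...) {
  tibble(U = x$U, p.value = x$p.value, method = x$method,
         n_a = x$n_a, n_b = x$n_b)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard step-up: with sorted p-values `p(1) <= ... <= p(m)`, find the
#' largest `i` with `p(i) <= (i/m) q` and reject hypotheses `1..i`. The
#' effective critical p-value `(i/m) q` (0 when nothing is rejected) is
#' returned alongside the rejection flags, in the input order.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q Target false-discovery rate (default 0.05).
#' @return List with `reject` (logical, input order), `critical_p`,
#'   `n_rejected`.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) abort("`pvals` must be non-empty.")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) / m * q)
  if (length(ok) == 0L) {
    list(reject = rep(FALSE, m), critical_p = 0, n_rejected = 0L)
  } else {
    k <- max(ok)
    crit <- k / m * q
    list(reject = pvals <= ps[k], critical_p = crit, n_rejected = k)
  }
}

#' Pairwise post-hoc comparisons after Kruskal-Wallis
#'
#' Dunn-type z statistics on mean-rank differences with the pooled
#' tie-corrected variance, under one of three familywise controls:
#' `"tukey_ranks"` (default; the studentized-range criterion applied to the
#' rank z statistics, the convention of common multiple-comparison routines),
#' `"holm"`, or `"bh"` (Benjamini-Hochberg, an FDR control). The table also
#' carries the effective corrected critical raw p-value: the largest raw p
#' that would still be declared significant.
#'
#' @param kw A [kruskal_wallis()] result.
#' @param alpha Familywise significance level in (0, 1).
#' @param method `"tukey_ranks"`, `"holm"` or `"bh"`.
#' @return A `pairwise_table` tibble with one row per unordered group pair:
#'   `group_a`, `group_b`, `mean_rank_diff`, `statistic` (z), `raw_p`,
#'   `adj_p`, `significant`; attributes `method`, `alpha`, `critical_p`.
#' @export
posthoc_pairwise <- function(kw, alpha = 0.05,
                             method = c("tukey_ranks", "holm", "bh")) {
  stopifnot(inherits(kw, "kw_test"))
  method <- arg_match(method)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  k <- length(kw$n)
  N <- kw$N
  pooled_var <- N * (N + 1) / 12 - kw$tie_term / (12 * (N - 1))
  pairs <- utils::combn(names(kw$n), 2L)
  diff <- kw$mean_ranks[pairs[1, ]] - kw$mean_ranks[pairs[2, ]]
  se <- sqrt(pooled_var * (1 / kw$n[pairs[1, ]] + 1 / kw$n[pairs[2, ]]))
  z <- ifelse(se > 0, diff / se, 0)
  raw_p <- 2 * pnorm(-abs(z))
  if (method == "tukey_ranks") {
    q_stat <- abs(z) * sqrt(2)
    adj_p <- ptukey(q_stat, nmeans = k, df = Inf, lower.tail = FALSE)
    critical_p <- 2 * pnorm(-qtukey(1 - alpha, nmeans = k, df = Inf) /
                              sqrt(2))
    significant <- adj_p <= alpha
  } else {
    adj_p <- p.adjust(raw_p, method = if (method == "holm") "holm" else "BH")
    significant <- adj_p <= alpha
    critical_p <- if (any(significant)) max(raw_p[significant]) else 0
  }
  out <- tibble(
    group_a = pairs[1, ], group_b = pairs[2, ],
    mean_rank_diff = unname(diff), statistic = unname(z),
    raw_p = unname(raw_p), adj_p = unname(adj_p),
    significant = unname(significant)
  )
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  attr(out, "critical_p") <- unname(critical_p)
  class(out) <- c("pairwise_table", class(out))
  out
}

#' Region-by-region comparison of combined condition maps
#'
#' For every ring-by-quadrant region and every combination of the two
#' held-fixed factors, runs a Kruskal-Wallis test across the levels of the
#' varying factor on the pooled pixel values, followed by
#' [posthoc_pairwise()] familywise-corrected pairwise comparisons.
#'
#' @param regions Tidy region table from [extract_condition_regions()]:
#'   columns `scene`, `optic`, `profile`, `ring`, `quadrant`, `value`.
#' @param factor_name The factor whose levels are compared: `"scene"`,
#'   `"optic"` or `"profile"`.
#' @param alpha Familywise level (default 0.05).
#' @param method Post-hoc method, see [posthoc_pairwise()].
#' @return A `region_analysis` tibble: one row per region, stratum and group
#'   pair, with the KW p-value, the pairwise statistics and significance
#'   flags; attributes `factor`, `alpha`, `method`.
#' @export
region_condition_analysis <- function(regions,
                                      factor_name = c("optic", "scene",
                                                      "profile"),
                                      alpha = 0.05,
                                      method = c("tukey_ranks", "holm",
                                                 "bh")) {
  factor_name <- arg_match(factor_name)
  method <- arg_match(method)
  needed <- c("ring", "quadrant", "value", factor_name)
  if (!is.data.frame(regions) || !all(needed %in% names(regions))) {
    abort(sprintf("`regions` must contain columns: %s.",
                  paste(needed, collapse = ", ")))
  }
  strata <- intersect(c("scene", "optic", "profile"), names(regions))
  strata <- setdiff(strata, factor_name)
  n_levels <- n_distinct(regions[[factor_name]])
  if (n_levels < 2L) {
    abort(sprintf("`%s` must have at least two levels.", factor_name))
  }
  out <- regions |>
    group_by(across(all_of(c("ring", "quadrant", strata)))) |>
    group_modify(function(df, key) {
      counts <- table(df[[factor_name]])
      counts <- counts[counts > 0]
      if (length(counts) != n_levels) {
        abort("A region/condition cell has no pixels.")
      }
      kw <- kruskal_wallis(df, .data$value, .data[[factor_name]])
      ph <- posthoc_pairwise(kw, alpha = alpha, method = method)
      ph$kw_p <- kw$p.value
      ph$critical_p <- attr(ph, "critical_p")
      as_tibble(ph)
    }) |>
    ungroup()
  attr(out, "factor") <- factor_name
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("region_analysis", class(out))
  out
}

#' Non-significant comparisons per region
#'
#' Filters a [region_condition_analysis()] table down to the pairs that were
#' NOT significant after the familywise correction — the exceptions the
#' region-wise analysis reports (absence of a region means every comparison
#' there was significant).
#'
#' @param analysis A `region_analysis` tibble.
#' @return Tibble of the non-significant rows, with a `pair` label column.
#' @export
nonsignificance_summary <- function(analysis) {
  if (!inherits(analysis, "region_analysis")) {
    abort("`analysis` must come from region_condition_analysis().")
  }
  analysis |>
    as_tibble() |>
    filter(!.data$significant) |>
    mutate(pair = paste(.data$group_a, .data$group_b, sep = " vs ")) |>
    arrange(.data$ring, .data$quadrant)
}

#' Plot non-significant region contrasts
#'
#' Ring-by-quadrant grid marking, for each stratum, the group pairs that were
#' not significantly different; blank cells were significant everywhere.
#'
#' @param object A `region_analysis` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.region_analysis <- function(object, ...) {
  ns <- nonsignificance_summary(object)
  base <- expand_grid(
    ring = factor(RING_LEVELS, levels = RING_LEVELS),
    quadrant = factor(QUADRANT_LEVELS, levels = QUADRANT_LEVELS)
  )
  p <- ggplot(base, aes(x = .data$ring, y = .data$quadrant)) +
    geom_tile(fill = "grey95", colour = "grey70")
  if (nrow(ns) > 0L) {
    p <- p + geom_point(
      data = ns,
      aes(x = .data$ring, y = .data$quadrant, colour = .data$pair),
      position = position_dodge(width = 0.6), size = 2
    )
  }
  p +
    labs(
      x = "eccentricity ring [deg]", y = "quadrant",
      colour = paste(attr(object, "factor"), "pair"),
      title = sprintf(
        "Non-significant %s contrasts (alpha = %g, %s)",
        attr(object, "factor"), attr(object, "alpha"), attr(object, "method")
      )
    ) +
    theme_minimal()
}

#' Point-wise comparison of two scan profiles with per-meridian FDR control
#'
#' At every (elevation, azimuth) point, a Mann-Whitney U test between the two
#' conditions' repeated scans; within each meridian, Benjamini-Hochberg
#' defines the critical p-value at FDR level `q`.
#'
#' @param a,b Scan tibbles on the same grid (e.g. two lens conditions'
#'   over-refraction scans, or naked vs on-lens).
#' @param q FDR level per meridian (default 0.05).
#' @return Tibble with `elevation_deg`, `azimuth_deg`, `U`, `p`,
#'   `critical_p` (per meridian) and `significant`.
#' @export
compare_scan_profiles <- function(a, b, q = 0.05) {
  check_scan_table(a)
  check_scan_table(b)
  nest_scans <- function(x, col) {
    x |>
      group_by(.data$elevation_deg, .data$azimuth_deg) |>
      summarise("{col}" := list(.data$M_diopters), .groups = "drop")
  }
  joined <- inner_join(
    nest_scans(a, "scans_a"), nest_scans(b, "scans_b"),
    by = c("elevation_deg", "azimuth_deg")
  )
  if (nrow(joined) != n_distinct(a[, c("elevation_deg", "azimuth_deg")])) {
    abort("The two scan tables must share the same meridian grid.")
  }
  tests <- joined |>
    mutate(
      test = map2(.data$scans_a, .data$scans_b, mann_whitney_u),
      U = map_dbl(.data$test, "U"),
      p = map_dbl(.data$test, "p.value")
    ) |>
    select("elevation_deg", "azimuth_deg", "U", "p")
  tests |>
    group_by(.data$elevation_deg) |>
    group_modify(function(df, key) {
      bh <- benjamini_hochberg(df$p, q = q)
      df$critical_p <- bh$critical_p
      df$significant <- bh$reject
      df
    }) |>
    ungroup() |>
    arrange(.data$elevation_deg, .data$azimuth_deg)
}
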