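# Combined condition maps (scene x optic x profile) and ring/quadrant
# segmentation of the 20-degree analysis disc.

SCENE_LEVELS <- c("office", "corridor", "living_room")
OPTIC_LEVELS <- c("naked", "near_centre", "distance_centre")
RING_LEVELS <- c("R0_5", "R5_10", "R10_15", "R15_20")
QUADRANT_LEVELS <- c("SUPERIOR", "INFERIOR", "NASAL", "TEMPORAL")

#' Combine environment, eye and lens maps into one retinal defocus map
#'
#' Element-wise sum of the three retinal-frame maps. The environment map must
#' already be flipped to retinal coordinates; pass [blank_map()] as `lens`
#' for the naked-eye condition.
#'
#' @param env Environment defocus `field_map`, RETINAL frame.
#' @param eye Eye power `field_map`, RETINAL frame.
#' @param lens Lens power `field_map` or [blank_map()] (default).
#' @return A `field_map` with semantics `"COMBINED_DEFOCUS"`.
#' @export
combine_condition <- function(env, eye, lens = blank_map()) {
  stopifnot(is_field_map(env), is_field_map(eye), is_field_map(lens))
  if (env$frame == "VISUAL_FIELD") {
    abort(paste(
      "Environment map is still in the VISUAL_FIELD frame;",
      "apply flip_to_retinal() first."
    ))
  }
  add_maps(env, eye, lens, semantics = "COMBINED_DEFOCUS")
}

#' Build the full set of combined condition maps
#'
#' Crosses every scene with every optic (naked eye plus the lens designs) and
#' every peripheral-refraction profile class: with 3 scenes, 3 optics and 4
#' profiles this yields the full set of 36 combined maps from 10 distinct
#' baseline inputs.
#'
#' @param scenes Named list of retinal-frame environment `field_map`s.
#' @param eye_maps Named list of eye power `field_map`s, one per profile
#'   class (names are the class labels).
#' @param lens_maps Named list of lens power `field_map`s, one per lens
#'   design; the `"naked"` optic is added automatically with [blank_map()].
#' @return A `condition_set` tibble with columns `scene`, `optic`, `profile`
#'   and a `map` list-column of combined `field_map`s.
#' @export
build_all_conditions <- function(scenes, eye_maps, lens_maps) {
  check_named_maps <- function(x, what) {
    if (!is.list(x) || is.null(names(x)) || any(names(x) == "") ||
        anyDuplicated(names(x)) > 0L) {
      abort(sprintf("`%s` must be a uniquely named list of field_maps.", what))
    }
    if (!all(vapply(x, is_field_map, logical(1)))) {
      abort(sprintf("`%s` must contain only field_map objects.", what))
    }
  }
  check_named_maps(scenes, "scenes")
  check_named_maps(eye_maps, "eye_maps")
  if (length(lens_maps) > 0L) check_named_maps(lens_maps, "lens_maps")
  if ("naked" %in% names(lens_maps)) {
    abort("Do not supply a 'naked' lens map; the blank map is added for you.")
  }
  optics <- c(list(naked = blank_map()), lens_maps)
  grid <- expand_grid(
    scene = names(scenes), optic = names(optics), profile = names(eye_maps)
  )
  maps <- pmap(grid, function(scene, optic, profile) {
    combine_condition(scenes[[scene]], eye_maps[[profile]], optics[[optic]])
  })
  out <- grid
  out$map <- maps
  structure(out, class = c("condition_set", class(out)))
}

#' Ring-by-quadrant region masks of the analysis disc
#'
#' Segments the 400 x 400 grid into four 5-degree eccentricity rings
#' (`(0,5]`, `(5,10]`, `(10,15]`, `(15,20]` at pixel centres) crossed with
#' four quadrant sectors bounded by the +-45-degree diagonals and centred on
#' the superior, inferior, nasal and temporal half-axes of the retina.
#' Sector bounds are half-open angular intervals (each sector includes its
#' clockwise diagonal boundary), so every diagonal pixel belongs to exactly
#' one sector and the four quadrant counts in each ring are identical by the
#' grid's 4-fold rotational symmetry. Pixels beyond 20 degrees eccentricity
#' (the matrix corners) are excluded from all statistics.
#'
#' @return A `region_mask_set`: a list with `region_id` (400 x 400 integer
#'   matrix, 0 = excluded) and `keys` (tibble of `region_id`, `ring`,
#'   `quadrant`, `n_pixels`).
#' @export
#' @examples
#' masks <- make_region_masks()
#' region_pixel_counts(masks)
make_region_masks <- function() {
  ctr <- pixel_centres()
  x <- matrix(ctr, MAP_N, MAP_N, byrow = TRUE)
  y <- matrix(rev(ctr), MAP_N, MAP_N)
  d <- sqrt(x^2 + y^2)
  ring <- findInterval(d, c(0, 5, 10, 15, 20), left.open = TRUE) # (lo, hi]
  ring[d > MAP_EXTENT] <- 0L
  ang <- atan2(y, x) * 180 / pi
  quad <- integer(length(ang))
  quad[ang > -45 & ang <= 45] <- 3L   # NASAL  (+x)
  quad[ang > 45 & ang <= 135] <- 1L   # SUPERIOR (+y)
  quad[ang > -135 & ang <= -45] <- 2L # INFERIOR (-y)
  quad[quad == 0L] <- 4L              # TEMPORAL (-x)
  keys <- expand_grid(
    ring = factor(RING_LEVELS, levels = RING_LEVELS),
    quadrant = factor(QUADRANT_LEVELS, levels = QUADRANT_LEVELS)
  )
  keys$region_id <- seq_len(nrow(keys))
  region_id <- matrix(0L, MAP_N, MAP_N)
  inside <- ring > 0L
  region_id[inside] <- (ring[inside] - 1L) * 4L +
    matrix(quad, MAP_N)[inside]
  counts <- tabulate(region_id[region_id > 0L], nbins = nrow(keys))
  keys$n_pixels <- counts
  structure(
    list(region_id = region_id, keys = keys[, c("region_id", "ring",
                                                "quadrant", "n_pixels")]),
    class = "region_mask_set"
  )
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat(sprintf(
    "<region_mask_set> %d regions, %d analysed pixels, %d excluded\n",
    nrow(x$keys), sum(x$keys$n_pixels), sum(x$region_id == 0L)
  ))
  invisible(x)
}

#' Pixel counts per ring-by-quadrant region
#'
#' @param masks A [make_region_masks()] result.
#' @return Tibble with `ring`, `quadrant`, `n_pixels`.
#' @export
region_pixel_counts <- function(masks) {
  stopifnot(inherits(masks, "region_mask_set"))
  masks$keys |> select("ring", "quadrant", "n_pixels")
}

#' Extract per-region pixel values from a retinal map
#'
#' @param map A RETINAL-frame `field_map`.
#' @param masks A [make_region_masks()] result.
#' @return A long tibble with `ring`, `quadrant` and one `value` row per
#'   pixel inside the 20-degree disc.
#' @export
extract_regions <- function(map, masks = make_region_masks()) {
  stopifnot(is_field_map(map), inherits(masks, "region_mask_set"))
  if (map$frame != "RETINAL") {
    abort("Region extraction expects a RETINAL-frame map.")
  }
  id <- as.vector(masks$region_id)
  keep <- id > 0L
  tibble(region_id = id[keep], value = as.vector(map$values)[keep]) |>
    inner_join(masks$keys, by = "region_id") |>
    select("ring", "quadrant", "value")
}

#' Tidy region table for a whole condition set
#'
#' Unnests every combined map of a [build_all_conditions()] result into a
#' long table of per-region pixel values, the input to
#' [region_condition_analysis()].
#'
#' @param conditions A `condition_set` tibble.
#' @param masks A [make_region_masks()] result.
#' @return Tibble with `scene`, `optic`, `profile`, `ring`, `quadrant`,
#'   `value`.
#' @export
extract_condition_regions <- function(conditions,
                                      masks = make_region_masks()) {
  if (!is.data.frame(conditions) ||
      !all(c("scene", "optic", "profile", "map") %in% names(conditions))) {
    abort("`conditions` must be a condition_set tibble (see build_all_conditions).")
  }
  conditions |>
    mutate(regions = map(.data$map, extract_regions, masks = masks)) |>
    select("scene", "optic", "profile", "regions") |>
    unnest("regions")
}
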