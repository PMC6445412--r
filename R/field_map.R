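# Dioptric field maps: 400 x 400 matrices over the central +-20 degrees,
# sampled every 0.1 degrees at half-offset pixel centres.

MAP_N <- 400L
MAP_PITCH <- 0.1
MAP_EXTENT <- 20

FIELD_FRAMES <- c("VISUAL_FIELD", "RETINAL")
FIELD_SEMANTICS <- c(
  "ENV_DEFOCUS", "EYE_REFRACTION", "EYE_POWER", "LENS_POWER",
  "COMBINED_DEFOCUS", "BLANK"
)
SIGN_CONVENTION <- "positive = relatively myopic defocus (focal plane in front of the retina)"

#' Pixel-centre coordinates of the 400-sample field grid
#'
#' Pixel centres sit at half-offsets: column `c` (1-based) is at
#' `(c - 200.5) * 0.1` degrees, so coordinates run from -19.95 to +19.95 and
#' no pixel lies exactly on an axis. In the RETINAL frame of a right eye,
#' +x is nasal retina and +y superior retina.
#'
#' @return Numeric vector of 400 coordinates in degrees, increasing.
#' @export
#' @examples
#' range(pixel_centres())
pixel_centres <- function() {
  (seq_len(MAP_N) - (MAP_N + 1) / 2) * MAP_PITCH
}

#' Construct a dioptric field map
#'
#' A `field_map` wraps a 400 x 400 numeric matrix of dioptre values over the
#' central 40 x 40 degrees of field, plus its coordinate frame and semantics.
#' Row 1 is the top of the field (+y); column 1 is the left (-x).
#'
#' @param values 400 x 400 numeric matrix, all entries finite, in dioptres.
#' @param frame `"VISUAL_FIELD"` or `"RETINAL"`.
#' @param semantics What the values mean: one of `"ENV_DEFOCUS"`,
#'   `"EYE_REFRACTION"`, `"EYE_POWER"`, `"LENS_POWER"`,
#'   `"COMBINED_DEFOCUS"`, `"BLANK"`.
#' @param eye Only `"OD"` (right eye) is modelled.
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, frame, semantics, eye = "OD") {
  frame <- arg_match(frame, FIELD_FRAMES)
  semantics <- arg_match(semantics, FIELD_SEMANTICS)
  eye <- arg_match(eye, "OD")
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (!all(dim(values) == c(MAP_N, MAP_N))) {
    abort(sprintf(
      "`values` must be %d x %d (got %d x %d).",
      MAP_N, MAP_N, nrow(values), ncol(values)
    ))
  }
  if (!all(is.finite(values))) {
    abort("`values` must contain only finite dioptre values.")
  }
  structure(
    list(
      values = unname(values), frame = frame, semantics = semantics,
      eye = eye, pixel_pitch = MAP_PITCH, extent = MAP_EXTENT
    ),
    class = "field_map"
  )
}

is_field_map <- function(x) inherits(x, "field_map")

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(
    "<field_map> %d x %d @ %.1f deg/px, frame %s, semantics %s, eye %s\n",
    nrow(x$values), ncol(x$values), x$pixel_pitch, x$frame, x$semantics, x$eye
  ))
  cat(sprintf(
    "  values [D]: min %.3f, median %.3f, max %.3f\n",
    min(x$values), stats::median(x$values), max(x$values)
  ))
  cat(" ", SIGN_CONVENTION, "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.field_map <- function(x, ...) {
  ctr <- pixel_centres()
  vals <- as.vector(x$values)
  tibble(
    x = rep(ctr, each = MAP_N),
    y = rep(rev(ctr), times = MAP_N),
    value = vals
  )
}

#' Blank (all-zero) retinal map
#'
#' Stands in for the lens power map of the naked-eye condition, so the same
#' three-term sum builds every combined map.
#'
#' @return A `field_map` of zeros, RETINAL frame, semantics `"BLANK"`.
#' @export
#' @examples
#' sum(blank_map()$values)
blank_map <- function() {
  field_map(matrix(0, MAP_N, MAP_N), frame = "RETINAL", semantics = "BLANK")
}

# Raw up-down + left-right flip; an involution on any matrix.
flip_matrix <- function(m) {
  m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
}

#' Flip a visual-field map into retinal coordinates
#'
#' The retinal image is inverted and reversed relative to the visual field,
#' so scene maps recorded in visual-field coordinates are flipped upside down
#' and left-right before they can be stacked with retinal-frame maps.
#'
#' @param map A `field_map` in the `VISUAL_FIELD` frame.
#' @return The flipped `field_map` in the `RETINAL` frame.
#' @export
flip_to_retinal <- function(map) {
  stopifnot(is_field_map(map))
  if (map$frame != "VISUAL_FIELD") {
    abort("`map` is already in the RETINAL frame; refusing to double-flip.")
  }
  out <- map
  out$values <- flip_matrix(map$values)
  out$frame <- "RETINAL"
  out
}

#' Sum field maps element-wise
#'
#' Stacks maps that share frame, pitch and extent. Used to merge an
#' environment defocus map, an eye power map and a lens power map into one
#' combined retinal defocus map.
#'
#' @param ... `field_map` objects, or a single list of them.
#' @param semantics Semantics of the sum (default `"COMBINED_DEFOCUS"`).
#' @return A `field_map` with the element-wise sum.
#' @export
add_maps <- function(..., semantics = "COMBINED_DEFOCUS") {
  maps <- list(...)
  if (length(maps) == 1L && !is_field_map(maps[[1L]])) maps <- maps[[1L]]
  if (length(maps) < 1L || !all(vapply(maps, is_field_map, logical(1)))) {
    abort("`add_maps()` expects one or more field_map objects.")
  }
  frames <- vapply(maps, function(m) m$frame, character(1))
  if (length(unique(frames)) != 1L) {
    abort("All maps must share the same coordinate frame.")
  }
  vals <- Reduce(`+`, lapply(maps, function(m) m$values))
  field_map(vals, frame = frames[[1L]], semantics = semantics)
}

#' Negate a refraction map into a power map
#'
#' A peripheral-refraction map states the correction the eye needs; negating
#' it expresses the eye's relative power contribution to retinal defocus.
#'
#' @param map A `field_map` in dioptres.
#' @return A `field_map` with every value negated and semantics `"EYE_POWER"`.
#' @export
invert_to_power <- function(map) {
  stopifnot(is_field_map(map))
  out <- map
  out$values <- -map$values
  out$semantics <- "EYE_POWER"
  out
}

#' Write / read a field map as matrix CSV plus JSON sidecar
#'
#' `write_field_map()` stores the 400 x 400 values as a headerless CSV matrix
#' and the metadata (frame, semantics, eye, pixel pitch, extent, sign
#' convention) in a `.json` sidecar next to it. `read_field_map()` reverses
#' the operation and validates dimensions, finiteness and metadata.
#'
#' @param map A `field_map`.
#' @param path Path of the CSV file; the sidecar replaces the extension with
#'   `.json`.
#' @return `write_field_map()` returns `path` invisibly; `read_field_map()`
#'   returns a `field_map`.
#' @export
write_field_map <- function(map, path) {
  stopifnot(is_field_map(map))
  write.table(
    format(map$values, digits = 17, trim = TRUE, scientific = TRUE),
    file = path, sep = ",", row.names = FALSE, col.names = FALSE,
    quote = FALSE
  )
  meta <- list(
    frame = map$frame, semantics = map$semantics, eye = map$eye,
    pixel_pitch = map$pixel_pitch, extent = map$extent,
    sign_convention = SIGN_CONVENTION
  )
  write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(file_path_sans_ext(path), ".json")

#' @rdname write_field_map
#' @export
read_field_map <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) abort(sprintf("Metadata sidecar not found: %s", sp))
  meta <- read_json(sp, simplifyVector = TRUE)
  required <- c("frame", "semantics", "eye", "pixel_pitch", "extent")
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys) > 0L) {
    abort(sprintf(
      "Metadata sidecar is missing required keys: %s",
      paste(missing_keys, collapse = ", ")
    ))
  }
  raw <- scan(path, what = double(), sep = ",", quiet = TRUE)
  if (length(raw) != MAP_N * MAP_N) {
    abort(sprintf(
      "Map CSV must hold %d values (%d x %d); got %d.",
      MAP_N * MAP_N, MAP_N, MAP_N, length(raw)
    ))
  }
  vals <- matrix(raw, nrow = MAP_N, byrow = TRUE)
  n_col <- length(scan(path, what = double(), sep = ",", nlines = 1,
                       quiet = TRUE))
  if (n_col != MAP_N) {
    abort(sprintf("Map CSV must have %d columns; got %d.", MAP_N, n_col))
  }
  field_map(vals, frame = meta$frame, semantics = meta$semantics,
            eye = meta$eye)
}

#' Plot a field map
#'
#' Raster plot in field coordinates with a diverging dioptre scale centred at
#' zero. Positive values are relatively myopic defocus.
#'
#' @param object A `field_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.field_map <- function(object, ...) {
  df <- as_tibble(object)
  xlab_ <- if (object$frame == "RETINAL") "x [deg, + = nasal retina]" else
    "x [deg, visual field]"
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(name = "D", low = "#313695", mid = "white",
                         high = "#a50026", midpoint = 0) +
    coord_equal() +
    labs(
      x = xlab_, y = "y [deg]",
      title = sprintf("%s (%s frame)", object$semantics, object$frame)
    ) +
    theme_minimal()
}
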