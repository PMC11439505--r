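#' Rescale a series into the arccos domain
#'
#' Min–max affine rescaling onto a subinterval of \[-1, 1\], the domain
#' required by the polar-angle encoding (`arccos`). The default range is
#' the full symmetric interval \[-1, 1\]; the field encoding (see [gaf()])
#' uses \[0, 1\], which keeps the resulting Gramian entries monotone in the
#' raw values. A constant series has no range and maps to the midpoint of
#' `range` by convention (0 for the symmetric default), giving a
#' well-defined degenerate field rather than a division by zero.
#'
#' @param x Numeric series.
#' @param range Length-2 target interval, a subinterval of \[-1, 1\].
#' @return Numeric vector with values in `range`.
#' @export
rescale_to_unit <- function(x, range = c(-1, 1)) {
  if (!is.numeric(x) || length(x) == 0L) abort("`x` must be a nonempty numeric series.")
  if (length(range) != 2L || range[1] >= range[2] || range[1] < -1 || range[2] > 1) {
    abort("`range` must be an increasing subinterval of [-1, 1].")
  }
  rng <- base::range(x)
  if (rng[1] == rng[2]) return(rep(mean(range), length(x)))
  range[1] + (range[2] - range[1]) * (x - rng[1]) / (rng[2] - rng[1])
}

#' Polar encoding of a unit-interval series
#'
#' Maps a series with values in \[-1, 1\] to polar coordinates: angles
#' `theta_i = arccos(x_i)` in \[0, pi\] and radii `r_i = i / T` for the
#' 1-based timestamp `i` of a series of length `T`. Values within `1e-9` of
#' the unit interval are clamped; values farther outside raise an error
#' naming the offending index.
#'
#' @param x Numeric series with `|x_i| <= 1` (within tolerance).
#' @return A list of class `polar_series` with `theta`, `r`, `t_len` and the
#'   (clamped) `x`.
#' @export
to_polar <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) abort("`x` must be a nonempty numeric series.")
  tol <- 1e-9
  bad <- which(abs(x) > 1 + tol)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Values outside [-1, 1] at index(es) %s; rescale the series first.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  x <- pmin(1, pmax(-1, x))
  t_len <- length(x)
  structure(
    list(theta = acos(x), r = seq_len(t_len) / t_len, t_len = t_len, x = x),
    class = "polar_series"
  )
}

#' Gramian angular field matrix
#'
#' Builds the (summation-form) Gramian angular field of a polar-encoded
#' series: `G[i, j] = cos(theta_i + theta_j)`. The matrix is symmetric with
#' entries in \[-1, 1\] and diagonal `2 x_i^2 - 1`; it captures the pairwise
#' angular superposition of the series values, rendering temporal structure
#' as image texture.
#'
#' @param polar A `polar_series` from [to_polar()], or a numeric series
#'   already scaled to \[-1, 1\].
#' @return A `T x T` matrix of class `gaf_matrix`.
#' @export
gaf_matrix <- function(polar) {
  if (is.numeric(polar)) polar <- to_polar(polar)
  if (!inherits(polar, "polar_series")) {
    abort("`polar` must be a `polar_series` or a numeric series in [-1, 1].")
  }
  g <- cos(outer(polar$theta, polar$theta, `+`))
  class(g) <- c("gaf_matrix", class(g))
  g
}

#' Gramian angular field of a raw daily play-time series
#'
#' Convenience composition: min–max rescaling, polar encoding, then the
#' Gramian angular field matrix. Because the rescaling absorbs any affine
#' transform of the raw series, the resulting field is invariant to the
#' scale and offset of the input.
#'
#' The default `"monotone"` encoding rescales onto \[0, 1\] (angles in
#' \[0, pi/2\]), making every field entry increase monotonically with the
#' two days' play times: pairs of no-play days sit at the low end of
#' \[-1, 1\] and pairs of long-play days at the high end, so rendered
#' images read directly as light = no play, dark = long play. The
#' `"symmetric"` encoding uses the full \[-1, 1\] interval, in which both
#' extremes of the raw scale map to +1 and the field encodes deviation
#' structure rather than level.
#'
#' @param series Numeric daily play-time series.
#' @param encoding `"monotone"` (default) or `"symmetric"`.
#' @return A `gaf_matrix`.
#' @examples
#' g <- gaf(c(45, 50, 0, 0, 48, 52, 0))
#' dim(g)
#' @export
gaf <- function(series, encoding = c("monotone", "symmetric")) {
  encoding <- match.arg(encoding)
  range <- if (encoding == "monotone") c(0, 1) else c(-1, 1)
  gaf_matrix(to_polar(rescale_to_unit(series, range = range)))
}

# Deterministic colormaps for rendering. "ylgnbu" (default) maps low field
# values to light yellow and high values to dark blue, so days without play
# read as light regions.
gaf_palette <- function(colormap_name, n = 256L) {
  if (!is.character(colormap_name) || length(colormap_name) != 1L) {
    abort("`colormap_name` must be a single string.")
  }
  pal <- switch(colormap_name,
    ylgnbu = grDevices::hcl.colors(n, "YlGnBu", rev = TRUE),
    gray = ,
    grey = grDevices::gray.colors(n, start = 0.95, end = 0.05),
    viridis = grDevices::hcl.colors(n, "viridis"),
    abort(sprintf(
      "Unknown colormap %s; available: \"ylgnbu\", \"gray\", \"viridis\".",
      deparse(colormap_name)
    ))
  )
  # orient light -> dark so that -1 renders light
  rgb1 <- grDevices::col2rgb(pal[1])
  rgbn <- grDevices::col2rgb(pal[n])
  lum <- function(v) sum(c(0.299, 0.587, 0.114) * v)
  if (lum(rgb1) < lum(rgbn)) pal <- rev(pal)
  pal
}

#' Render a Gramian angular field as a color image
#'
#' Deterministically maps field values from \[-1, 1\] onto a colormap. Under
#' the default yellow-to-blue map, low values (days without play) render
#' light and high values (long play days) render dark, so consistent
#' players produce predominantly dark images and non-players predominantly
#' light ones.
#'
#' @param g A `gaf_matrix` (or any numeric matrix with values in \[-1, 1\]).
#' @param colormap_name One of `"ylgnbu"` (default), `"gray"`, `"viridis"`.
#' @return A `gaf_image`: a `T x T x 3` array of RGB values in \[0, 1\].
#' @export
render_gaf_image <- function(g, colormap_name = "ylgnbu") {
  if (!is.matrix(g)) abort("`g` must be a matrix.")
  pal <- gaf_palette(colormap_name)
  idx <- pmin(256L, pmax(1L, 1L + floor((g + 1) / 2 * 256)))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(NA_real_, dim = c(nrow(g), ncol(g), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, ], nrow(g), ncol(g))
  structure(img, class = "gaf_image", colormap_name = colormap_name)
}

#' Write a Gramian angular field image to a PNG file
#'
#' @param img A `gaf_image` from [render_gaf_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaf_png <- function(img, path) {
  if (!inherits(img, "gaf_image")) abort("`img` must be a `gaf_image`.")
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' Gramian angular fields for every participant in a cohort
#'
#' Extracts each participant's daily play-time series and computes its
#' Gramian angular field. By default the full structured-phase series is
#' used (the span the clustering operates on); `span = "train"` restricts to
#' the first `train_days` days so that clustering sees no test-period data.
#'
#' @param cohort A play-log tibble covering one or more participants.
#' @param span `"full"` (default) or `"train"`.
#' @param train_days Days in the training portion (used when
#'   `span = "train"`).
#' @param encoding Rescaling passed to [gaf()]. The `"symmetric"` default
#'   here differs from [gaf()]'s display default: for grouping participants
#'   the full-interval field carries more pattern texture (both play and
#'   no-play stretches produce high-contrast structure), which suits the
#'   linear feature extractor; use `"monotone"` when the fields are meant
#'   to be looked at.
#' @return A named list of `gaf_matrix` objects, one per participant.
#' @export
cohort_gafs <- function(cohort, span = c("full", "train"), train_days = 30,
                        encoding = "symmetric") {
  assert_play_log(cohort)
  span <- match.arg(span)
  if (span == "train") cohort <- filter(cohort, .data$day_index <= train_days)
  series <- cohort |>
    arrange(.data$participant_id, .data$day_index) |>
    group_by(.data$participant_id) |>
    summarise(series = list(.data$duration), .groups = "drop")
  lens <- lengths(series$series)
  if (length(unique(lens)) != 1L) {
    abort("All participants must share the same number of days for GAF clustering.")
  }
  out <- map(series$series, gaf, encoding = encoding)
  names(out) <- series$participant_id
  out
}

#' @rdname render_gaf_image
#' @param object A `gaf_matrix`.
#' @param ... Unused.
#' @export
autoplot.gaf_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(
    i = seq_len(nrow(object)), j = seq_len(ncol(object))
  )
  df$value <- object[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colors = gaf_palette("ylgnbu", 64), limits = c(-1, 1), name = "G"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "day j", y = "day i") +
    ggplot2::theme_minimal()
}
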