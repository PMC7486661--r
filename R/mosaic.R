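#' Hexagonal-equivalent spacing of a point mosaic
#'
#' Converts the density of a planar point set into the spacing of the ideal
#' hexagonal lattice with the same density, via `rho = 2 / (sqrt(3) * d^2)`.
#' This is the standard way to summarise retinal ganglion cell (RGC) mosaics
#' by a single representative nearest-neighbour scale.
#'
#' @param positions A two-column matrix or data frame of x/y positions (um).
#' @param region_area Area of the region the points were sampled from (um^2).
#' @return Spacing `d` in um.
#' @examples
#' pts <- cbind(runif(1000, 0, 1000), runif(1000, 0, 1000))
#' estimate_spacing(pts, 1e6)
#' @export
estimate_spacing <- function(positions, region_area) {
  positions <- as_xy(positions)
  if (nrow(positions) == 0L) stop("empty mosaic", call. = FALSE)
  if (nrow(positions) < 2L) stop("need >= 2 points to estimate spacing", call. = FALSE)
  stopifnot(region_area > 0)
  rho <- nrow(positions) / region_area
  sqrt(2 / (sqrt(3) * rho))
}

# coerce tibbles / matrices to a plain 2-col matrix of finite coordinates
as_xy <- function(positions) {
  if (is.data.frame(positions)) positions <- cbind(positions$x, positions$y)
  positions <- as.matrix(positions)
  if (length(positions) == 0L) return(matrix(numeric(0), ncol = 2))
  storage.mode(positions) <- "double"
  if (ncol(positions) != 2L) stop("positions must have two columns (x, y)", call. = FALSE)
  if (!all(is.finite(positions))) stop("non-finite coordinates", call. = FALSE)
  positions
}

#' Nodes of a hexagonal lattice inside a disc
#'
#' @param spacing Nearest-neighbour distance of the lattice (um).
#' @param center Disc center, length-2 numeric (um).
#' @param radius Disc radius (um).
#' @return A tibble with columns `x`, `y`. One node always coincides with
#'   `center`, so the returned set is never empty.
#' @export
synthesize_hex_lattice <- function(spacing, center = c(0, 0), radius) {
  stopifnot(length(center) == 2, is.finite(radius), radius > 0)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive", call. = FALSE)
  row_h <- spacing * sqrt(3) / 2
  jmax <- ceiling(radius / row_h) + 1L
  imax <- ceiling(radius / spacing) + 1L
  j <- seq(-jmax, jmax)
  grid <- tidyr::expand_grid(i = seq(-imax, imax), j = j)
  x <- center[1] + grid$i * spacing + (grid$j %% 2) * spacing / 2
  y <- center[2] + grid$j * row_h
  keep <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
  tibble::tibble(x = x[keep], y = y[keep])
}

#' Synthetic jittered ON/OFF RGC mosaic
#'
#' Generates independent hexagonal ON and OFF lattices over a square field,
#' each with a random phase offset and per-node jitter, emulating the
#' semi-regular mosaics of recorded RGC populations. The OFF mosaic is
#' typically denser than the ON mosaic in higher mammals (ratio 1.3 here).
#' The default densities put the ON lattice at the wave automaton's
#' marginal-propagation regime (slow, ragged Stage III fronts) and the
#' default extent yields roughly 300 cortical dipole sites; the jitter gives
#' mosaics with regularity comparable to measured ones.
#'
#' @param density_on,density_off Target cell densities (um^-2).
#' @param jitter_fraction Jitter magnitude as a fraction of the lattice
#'   spacing, in `[0, 0.5]`; each node is displaced uniformly within a disc of
#'   radius `jitter_fraction * spacing`.
#' @param extent Side of the square field (um), centered on the origin.
#' @param seed Integer seed; the mosaic is reproducible bit-exactly.
#' @return An `rgc_mosaic`: a tibble with columns `x`, `y`, `polarity`
#'   (`"on"`/`"off"`), carrying attributes `d_on`, `d_off` (hexagonal
#'   equivalent spacings, computed from the bounding-box density) and
#'   `source`.
#' @examples
#' m <- generate_synthetic_mosaic(seed = 1)
#' mosaic_spacings(m)
#' @export
generate_synthetic_mosaic <- function(density_on = 9.64e-5,
                                      density_off = 1.253e-4,
                                      jitter_fraction = 0.45,
                                      extent = 670,
                                      seed = 1L) {
  stopifnot(density_on > 0, density_off > 0,
            jitter_fraction >= 0, jitter_fraction <= 0.5, extent > 0)
  set.seed(seed)
  one_layer <- function(density) {
    spacing <- sqrt(2 / (sqrt(3) * density))
    # lattice covering the square, random phase within one unit cell
    lat <- synthesize_hex_lattice(spacing, center = c(0, 0),
                                  radius = extent / sqrt(2) + 2 * spacing)
    phase <- stats::runif(2, 0, spacing)
    x <- lat$x + phase[1]
    y <- lat$y + phase[2]
    if (jitter_fraction > 0) {
      ang <- stats::runif(length(x), 0, 2 * pi)
      rad <- jitter_fraction * spacing * sqrt(stats::runif(length(x)))
      x <- x + rad * cos(ang)
      y <- y + rad * sin(ang)
    }
    keep <- abs(x) <= extent / 2 & abs(y) <= extent / 2
    tibble::tibble(x = x[keep], y = y[keep])
  }
  on <- one_layer(density_on)
  off <- one_layer(density_off)
  new_rgc_mosaic(on, off,
                 source = sprintf("synthetic(rho_on=%.3g, rho_off=%.3g, seed=%d)",
                                  density_on, density_off, as.integer(seed)))
}

#' Construct an `rgc_mosaic` from ON and OFF point sets
#'
#' Spacings `d_on`/`d_off` are derived from the density of each polarity over
#' the axis-aligned bounding box of the full mosaic.
#'
#' @param on,off Tibbles/matrices of positions (um).
#' @param source Free-text provenance tag.
#' @export
new_rgc_mosaic <- function(on, off, source = "unknown") {
  on <- as_xy(on); off <- as_xy(off)
  if (nrow(on) < 2L || nrow(off) < 2L) stop("empty mosaic", call. = FALSE)
  all <- rbind(on, off)
  area <- diff(range(all[, 1])) * diff(range(all[, 2]))
  m <- tibble::tibble(
    x = c(on[, 1], off[, 1]),
    y = c(on[, 2], off[, 2]),
    polarity = rep(c("on", "off"), c(nrow(on), nrow(off)))
  )
  structure(m,
            class = c("rgc_mosaic", class(tibble::tibble())),
            d_on = estimate_spacing(on, area),
            d_off = estimate_spacing(off, area),
            source = source)
}

#' @export
print.rgc_mosaic <- function(x, ...) {
  sp <- mosaic_spacings(x)
  cat(sprintf("<rgc_mosaic> %d ON + %d OFF cells, d_on = %.1f um, d_off = %.1f um\n",
              sum(x$polarity == "on"), sum(x$polarity == "off"), sp["d_on"], sp["d_off"]))
  cat(sprintf("  source: %s\n", attr(x, "source") %||% "unknown"))
  NextMethod()
}

#' Spacings stored on a mosaic
#' @param mosaic An `rgc_mosaic` or `extended_mosaic`.
#' @return Named numeric vector with `d_on` and `d_off` (um).
#' @export
mosaic_spacings <- function(mosaic) {
  c(d_on = attr(mosaic, "d_on"), d_off = attr(mosaic, "d_off"))
}

mosaic_positions <- function(mosaic, polarity) {
  as_xy(mosaic[mosaic$polarity == polarity, c("x", "y")])
}

#' Extend a data mosaic with padding lattices and an amacrine-cell lattice
#'
#' Pads the ON and OFF mosaics with hexagonal lattices of matching spacing out
#' to a circular boundary (so that waves can travel long distances without
#' edge artifacts), and overlays a hexagonal amacrine cell (AC) lattice whose
#' density equals the summed ON + OFF density. Padding nodes closer than one
#' spacing to a same-polarity data cell are dropped to avoid doublets at the
#' seam. Padding and AC cells participate in wave propagation only; analyses
#' are restricted to `is_data` cells.
#'
#' @param mosaic An `rgc_mosaic`.
#' @param boundary_radius Disc radius around the data centroid (um).
#' @return An `extended_mosaic` tibble with columns `x`, `y`, `type`
#'   (`"on"`, `"off"`, `"ac"`) and `is_data`.
#' @export
extend_mosaic <- function(mosaic, boundary_radius = 3000) {
  sp <- mosaic_spacings(mosaic)
  on <- mosaic_positions(mosaic, "on")
  off <- mosaic_positions(mosaic, "off")
  center <- colMeans(rbind(on, off))
  r_data <- sqrt(max(rowSums(sweep(rbind(on, off), 2, center)^2)))
  if (boundary_radius <= r_data)
    stop("boundary smaller than data extent", call. = FALSE)

  pad_layer <- function(data_pos, spacing) {
    lat <- as_xy(synthesize_hex_lattice(spacing, center = center, radius = boundary_radius))
    keep <- min_dist_to(lat, data_pos) > spacing
    lat[keep, , drop = FALSE]
  }
  pad_on <- pad_layer(on, sp["d_on"])
  pad_off <- pad_layer(off, sp["d_off"])
  rho_ac <- 2 / (sqrt(3) * sp["d_on"]^2) + 2 / (sqrt(3) * sp["d_off"]^2)
  d_ac <- sqrt(2 / (sqrt(3) * rho_ac))
  ac <- as_xy(synthesize_hex_lattice(d_ac, center = center, radius = boundary_radius))

  m <- tibble::tibble(
    x = c(on[, 1], pad_on[, 1], off[, 1], pad_off[, 1], ac[, 1]),
    y = c(on[, 2], pad_on[, 2], off[, 2], pad_off[, 2], ac[, 2]),
    type = rep(c("on", "off", "ac"),
               c(nrow(on) + nrow(pad_on), nrow(off) + nrow(pad_off), nrow(ac))),
    is_data = c(rep(TRUE, nrow(on)), rep(FALSE, nrow(pad_on)),
                rep(TRUE, nrow(off)), rep(FALSE, nrow(pad_off)),
                rep(FALSE, nrow(ac)))
  )
  structure(m,
            class = c("extended_mosaic", class(tibble::tibble())),
            d_on = unname(sp["d_on"]), d_off = unname(sp["d_off"]), d_ac = d_ac,
            boundary_radius = boundary_radius, center = center,
            source = attr(mosaic, "source"))
}

#' @export
print.extended_mosaic <- function(x, ...) {
  cat(sprintf("<extended_mosaic> %d ON (%d data), %d OFF (%d data), %d AC; boundary %.0f um\n",
              sum(x$type == "on"), sum(x$type == "on" & x$is_data),
              sum(x$type == "off"), sum(x$type == "off" & x$is_data),
              sum(x$type == "ac"), attr(x, "boundary_radius")))
  NextMethod()
}

# minimum distance from each row of a to the point set b (used at the seam)
min_dist_to <- function(a, b) {
  if (nrow(a) == 0L) return(numeric(0))
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
  }, numeric(1))
}

#' Read / write RGC mosaics as CSV
#'
#' The on-disk dialect is comma-separated with a header `x,y,polarity`;
#' polarity labels are matched case-insensitively against `"on"`/`"off"`.
#'
#' @param path File path.
#' @return `read_mosaic()` returns an `rgc_mosaic`.
#' @export
read_mosaic <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("x", "y", "polarity")) {
    if (!col %in% names(raw)) stop(sprintf("missing column '%s'", col), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop(sprintf("non-numeric coordinate at line %d", bad[1] + 1L), call. = FALSE)
  pol <- tolower(raw$polarity)
  badp <- which(!pol %in% c("on", "off"))
  if (length(badp))
    stop(sprintf("unknown polarity label '%s' at line %d", raw$polarity[badp[1]], badp[1] + 1L),
         call. = FALSE)
  new_rgc_mosaic(cbind(x[pol == "on"], y[pol == "on"]),
                 cbind(x[pol == "off"], y[pol == "off"]),
                 source = path)
}

#' @rdname read_mosaic
#' @param mosaic An `rgc_mosaic`.
#' @export
write_mosaic <- function(mosaic, path) {
  readr::write_csv(tibble::tibble(x = mosaic$x, y = mosaic$y, polarity = mosaic$polarity),
                   path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
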