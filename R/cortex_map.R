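#' Preferred orientation from an ON/OFF dipole
#'
#' The preferred orientation of a site is perpendicular to its ON->OFF dipole
#' axis (an ON/OFF pair responds best to an edge orthogonal to the axis):
#' `theta = (atan2(off - on) + 90) mod 180` in degrees. Swapping ON and OFF
#' leaves the orientation unchanged.
#'
#' @param on_com,off_com ON and OFF centers of mass; length-2 vectors or
#'   two-column matrices (um).
#' @return Orientation(s) in degrees, `[0, 180)`.
#' @export
site_orientation <- function(on_com, off_com) {
  if (is.null(dim(on_com))) on_com <- matrix(on_com, ncol = 2)
  if (is.null(dim(off_com))) off_com <- matrix(off_com, ncol = 2)
  d <- off_com - on_com
  if (any(rowSums(d^2) == 0)) stop("coincident ON/OFF centers of mass", call. = FALSE)
  (atan2(d[, 2], d[, 1]) * 180 / pi + 90) %% 180
}

map_grid <- function(xy, pixel_size, pad = 0) {
  xs <- seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad, by = pixel_size)
  ys <- seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad, by = pixel_size)
  list(xs = xs, ys = ys)
}

new_rw_map <- function(values, defined, xs, ys, pixel_size, sigma, kind) {
  structure(list(values = values, defined = defined, xs = xs, ys = ys,
                 pixel_size = pixel_size, sigma = sigma, kind = kind),
            class = "rw_map")
}

#' @export
print.rw_map <- function(x, ...) {
  cat(sprintf("<rw_map:%s> %d x %d px (%.3g um/px), %.0f%% defined\n",
              x$kind, length(x$xs), length(x$ys), x$pixel_size,
              100 * mean(x$defined)))
  invisible(x)
}

#' Render a smoothed cortical orientation map
#'
#' Orientation preferences are vector-averaged on the doubled angle: each
#' pixel takes `theta = arg( sum_k G(|x - x_k|; sigma) exp(2i theta_k) ) / 2`,
#' which is the only smoothing that respects the circular topology of
#' orientation. Pixels farther than `3 sigma` from every site (or with
#' near-zero kernel mass) are flagged undefined.
#'
#' @param sites Tibble with columns `x`, `y`, `theta` (degrees), e.g.
#'   [place_cortical_sites()] output, optionally with re-estimated `theta`.
#' @param sigma_img Gaussian filter width (um): 36 for cat-like, 56 for
#'   monkey-like maps.
#' @param pixel_size Pixel size (um); defaults to `sigma_img / 3`.
#' @param grid Optional grid (list with `xs`, `ys`) to render on.
#' @return An `rw_map` with `values` = orientation in degrees `[0, 180)` and
#'   a `defined` mask; matrices are `length(xs) x length(ys)`.
#' @export
render_orientation_map <- function(sites, sigma_img, pixel_size = sigma_img / 3,
                                   grid = NULL) {
  xy <- cbind(sites$x, sites$y)
  if (is.null(grid)) grid <- map_grid(xy, pixel_size)
  px <- as.matrix(expand.grid(x = grid$xs, y = grid$ys))
  G <- gauss_kernel_matrix(px, xy, sigma_img)
  z <- G %*% exp(2i * sites$theta * pi / 180)
  mass <- rowSums(G)
  d2min <- apply((outer(px[, 1], xy[, 1], "-")^2 + outer(px[, 2], xy[, 2], "-")^2), 1, min)
  defined <- mass >= 1e-6 & d2min <= (3 * sigma_img)^2
  theta <- (Arg(z) / 2 * 180 / pi) %% 180
  dim(theta) <- dim(defined) <- c(length(grid$xs), length(grid$ys))
  theta[!defined] <- NA_real_
  new_rw_map(theta, defined, grid$xs, grid$ys, pixel_size, sigma_img, "orientation")
}

nearest_pixel <- function(map, point) {
  c(which.min(abs(map$xs - point[1])), which.min(abs(map$ys - point[2])))
}

#' Orientation similarity map
#'
#' `OPsim(x) = cos(2 (theta(x) - theta(s)))` relative to the orientation at
#' the reference point: 1 for identical orientation, -1 for orthogonal.
#'
#' @param map An orientation `rw_map`.
#' @param reference_point Length-2 numeric (um); mapped to the nearest pixel,
#'   which must be defined.
#' @return An `rw_map` of kind `"similarity"` with values in `[-1, 1]`.
#' @export
orientation_similarity <- function(map, reference_point) {
  ij <- nearest_pixel(map, reference_point)
  if (!map$defined[ij[1], ij[2]]) stop("reference pixel undefined", call. = FALSE)
  sim <- cos(2 * (map$values - map$values[ij[1], ij[2]]) * pi / 180)
  new_rw_map(sim, map$defined, map$xs, map$ys, map$pixel_size, map$sigma, "similarity")
}

#' Estimate the spatial period of the orientation map
#'
#' Renders the map at several filter sizes, takes the 2D power spectrum of
#' `exp(2i theta)`, and records the radially-averaged peak spatial frequency
#' per filter size. The period is `1 / f` averaged over the longest run of
#' consecutive filter sizes whose peak frequencies agree within
#' `plateau_tol` (at least `min_run` sizes).
#'
#' @param sites Tibble with `x`, `y`, `theta`.
#' @param filter_sizes Gaussian filter widths to scan (um).
#' @param pixel_size Shared rendering pixel size (um); default
#'   `min(filter_sizes) / 3`.
#' @param plateau_tol Relative agreement defining the plateau (0.05).
#' @param min_run Minimum plateau length (3).
#' @return Period in um.
#' @export
estimate_map_period <- function(sites, filter_sizes, pixel_size = NULL,
                                plateau_tol = 0.05, min_run = 3L) {
  stopifnot(length(filter_sizes) >= 2)
  filter_sizes <- sort(filter_sizes)
  pixel_size <- pixel_size %||% (min(filter_sizes) / 3)
  xy <- cbind(sites$x, sites$y)
  # a (nearly) constant orientation field has no spatial structure: its only
  # spectral content would come from the window shape
  resultant <- Mod(mean(exp(2i * sites$theta * pi / 180)))
  if (resultant > 0.99)
    stop("orientation map is (nearly) constant; period undefined", call. = FALSE)
  grid <- map_grid(xy, pixel_size)
  peak_freq <- vapply(filter_sizes, function(s) {
    m <- render_orientation_map(sites, s, pixel_size, grid = grid)
    z <- exp(2i * m$values * pi / 180)
    z[!m$defined] <- 0
    P <- Mod(stats::fft(z))^2
    nx <- nrow(P); ny <- ncol(P)
    fx <- c(seq(0, floor(nx / 2)), seq(-(ceiling(nx / 2) - 1), -1)) / (nx * pixel_size)
    fy <- c(seq(0, floor(ny / 2)), seq(-(ceiling(ny / 2) - 1), -1)) / (ny * pixel_size)
    fr <- sqrt(outer(fx^2, fy^2, "+"))
    # radial average, excluding the DC bin
    df <- 1 / (max(nx, ny) * pixel_size)
    bins <- matrix(pmax(1L, as.integer(round(fr / df))), nx, ny)
    bins[1, 1] <- 0L
    pw <- tapply(as.vector(P), as.vector(bins), mean)
    pw <- pw[names(pw) != "0"]
    as.numeric(names(pw)[which.max(pw)]) * df
  }, numeric(1))
  if (any(peak_freq <= 0)) stop("map has no non-DC spectral peak", call. = FALSE)
  # longest run of consecutive sizes agreeing within plateau_tol
  ok <- abs(diff(peak_freq)) / pmax(peak_freq[-length(peak_freq)], 1e-12) <= plateau_tol
  runs <- rle(ok)
  if (!any(runs$values & runs$lengths >= (min_run - 1L)))
    stop("no stable plateau", call. = FALSE)
  best <- which.max(ifelse(runs$values, runs$lengths, 0L))
  start <- if (best > 1) sum(runs$lengths[seq_len(best - 1)]) + 1L else 1L
  idx <- seq(start, start + runs$lengths[best])
  1 / mean(peak_freq[idx])
}
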