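#' Random driving stimulus for spontaneous activity
#'
#' The drive to each site is `I_local * G_local + I_background * G_background`:
#' a dominant 2D Gaussian bump (width `sigma_local`, peak 1) centered on a
#' uniformly chosen site, plus per-site `U(0, 1)` noise smoothed with a
#' Gaussian of width `sigma_background` and max-normalized to 1.
#'
#' @param sites Tibble with `x`, `y` (cortical site positions, um).
#' @param i_local,sigma_local Local stimulus amplitude (10) and width (20 um).
#' @param i_background,sigma_background Background amplitude (0.01) and
#'   smoothing width (30 um).
#' @param seed Integer seed.
#' @return A `stimulus_field` list with per-site `drive`, the components, and
#'   the local center.
#' @export
make_stimulus <- function(sites, i_local = 10, sigma_local = 20,
                          i_background = 0.01, sigma_background = 30,
                          seed = 1L) {
  stopifnot(nrow(sites) >= 1)
  set.seed(seed)
  xy <- cbind(sites$x, sites$y)
  center <- xy[sample.int(nrow(xy), 1L), ]
  g_local <- exp(-((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2) /
                   (2 * sigma_local^2))
  u <- stats::runif(nrow(xy))
  K <- gauss_kernel_matrix(xy, xy, sigma_background)
  g_bg <- as.vector(K %*% u) / rowSums(K)
  g_bg <- g_bg / max(g_bg)
  structure(list(drive = i_local * g_local + i_background * g_bg,
                 g_local = g_local, g_background = g_bg,
                 local_center = center, seed = as.integer(seed)),
            class = "stimulus_field")
}

#' Recurrent amplification of a stimulus by the horizontal network
#'
#' With feedforward input silenced, iterates the linear recurrence
#' \code{r <- W' r + I_stim} from zero activity until the norm has grown by
#' `growth_factor` relative to its value at iteration 10 (the network
#' "diverges" along its dominant connectivity mode), or until `max_iter`.
#' The final pattern is scaled to unit maximum; the overall scale is
#' immaterial because activity images are z-scored downstream.
#'
#' @param hn_final A [finalize_incoming()]-normalized `lhc_network`.
#' @param stimulus A `stimulus_field` (or a numeric per-site drive vector).
#' @param growth_factor Divergence criterion (1e6).
#' @param max_iter Iteration cap (500).
#' @return Per-site activity pattern with unit maximum; attribute
#'   `"diverged"` reports whether the growth criterion was met.
#' @export
run_recurrent <- function(hn_final, stimulus, growth_factor = 1e6,
                          max_iter = 500L) {
  drive <- if (inherits(stimulus, "stimulus_field")) stimulus$drive else as.numeric(stimulus)
  Wt <- t(hn_final$W)
  r <- numeric(length(drive))
  ref <- NA_real_
  diverged <- FALSE
  for (k in seq_len(max_iter)) {
    r <- as.vector(Wt %*% r) + drive
    nrm <- sqrt(sum(r^2))
    if (k == 10L) ref <- nrm
    if (k > 10L && is.finite(ref) && ref > 0 && nrm >= growth_factor * ref) {
      diverged <- TRUE
      break
    }
    if (!is.finite(nrm)) break  # guard against overflow past divergence
  }
  structure(r / max(r), diverged = diverged)
}

#' Render a z-scored activity image
#'
#' Kernel-weighted (normalized-convolution) interpolation of per-site
#' activity onto a pixel grid with a Gaussian of width `sigma_img`, followed
#' by z-scoring over defined pixels (mean 0, SD 1).
#'
#' @param pattern Per-site activity values.
#' @param sites Tibble with `x`, `y`.
#' @param sigma_img Filter width (um).
#' @param pixel_size Pixel size (um); default `sigma_img / 3`.
#' @param grid Optional shared grid (list `xs`, `ys`).
#' @return An `rw_map` of kind `"activity"`.
#' @export
render_activity <- function(pattern, sites, sigma_img, pixel_size = sigma_img / 3,
                            grid = NULL) {
  xy <- cbind(sites$x, sites$y)
  if (is.null(grid)) grid <- map_grid(xy, pixel_size)
  px <- as.matrix(expand.grid(x = grid$xs, y = grid$ys))
  G <- gauss_kernel_matrix(px, xy, sigma_img)
  mass <- rowSums(G)
  d2min <- apply((outer(px[, 1], xy[, 1], "-")^2 + outer(px[, 2], xy[, 2], "-")^2), 1, min)
  defined <- mass >= 1e-6 & d2min <= (3 * sigma_img)^2
  vals <- as.vector(G %*% pattern) / mass
  if (sum(defined) < 2L) stop("fewer than two defined pixels", call. = FALSE)
  mu <- mean(vals[defined]); sdv <- stats::sd(vals[defined])
  if (sdv < 1e-12 * max(abs(mu), 1))
    stop("constant activity image (zero SD)", call. = FALSE)
  vals <- (vals - mu) / sdv
  vals[!defined] <- NA_real_
  dim(vals) <- dim(defined) <- c(length(grid$xs), length(grid$ys))
  new_rw_map(vals, defined, grid$xs, grid$ys, pixel_size, sigma_img, "activity")
}

#' Simulate a set of spontaneous activity images
#'
#' Repeats stimulus generation, recurrent amplification and rendering
#' `n_images` times on a common grid.
#'
#' @param hn_final A finalized `lhc_network`.
#' @param sites Site tibble (`x`, `y`).
#' @param n_images Number of images (200).
#' @param sigma_img Rendering filter width (um).
#' @param seed Integer seed (one sub-seed per image).
#' @param ... Passed to [make_stimulus()].
#' @return An `activity_set`: list of `rw_map`s plus the shared grid.
#' @export
simulate_spontaneous_set <- function(hn_final, sites, n_images = 200,
                                     sigma_img, seed = 1L, ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  xy <- cbind(sites$x, sites$y)
  grid <- map_grid(xy, sigma_img / 3)
  images <- lapply(seeds, function(s) {
    stim <- make_stimulus(sites, seed = s, ...)
    pat <- run_recurrent(hn_final, stim)
    render_activity(pat, sites, sigma_img, grid = grid)
  })
  structure(list(images = images, grid = grid, sigma_img = sigma_img,
                 seed = as.integer(seed)),
            class = "activity_set")
}

#' @export
print.activity_set <- function(x, ...) {
  cat(sprintf("<activity_set> %d z-scored images on %d x %d px\n",
              length(x$images), length(x$grid$xs), length(x$grid$ys)))
  invisible(x)
}

#' Seed-pixel correlation map of spontaneous activity
#'
#' Pearson correlation, across the image set, between activity at the
#' reference pixel and activity at every other pixel.
#'
#' @param activity_set An `activity_set` (needs >= 3 images).
#' @param reference_point Length-2 numeric (um); nearest defined pixel used.
#' @return An `rw_map` of kind `"correlation"` in `[-1, 1]`; zero-variance
#'   pixels are masked (NA), not errors.
#' @export
correlation_map <- function(activity_set, reference_point) {
  imgs <- activity_set$images
  stopifnot(length(imgs) >= 3)
  m1 <- imgs[[1]]
  ij <- nearest_pixel(m1, reference_point)
  if (!m1$defined[ij[1], ij[2]]) stop("reference pixel undefined", call. = FALSE)
  X <- vapply(imgs, function(m) as.vector(m$values), numeric(length(m1$values)))
  ref <- X[(ij[2] - 1L) * length(m1$xs) + ij[1], ]
  Xc <- X - rowMeans(X)
  refc <- ref - mean(ref)
  sx <- sqrt(rowSums(Xc^2))
  denom <- sx * sqrt(sum(refc^2))
  r <- as.vector(Xc %*% refc) / denom
  r[denom == 0] <- NA_real_
  r[!m1$defined] <- NA_real_
  dim(r) <- dim(m1$defined)
  new_rw_map(r, m1$defined & is.finite(r), m1$xs, m1$ys, m1$pixel_size,
             m1$sigma, "correlation")
}
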