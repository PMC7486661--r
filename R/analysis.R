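#' Cuzick's nonparametric test for trend across ordered groups
#'
#' Wilcoxon-type rank test: with integer group scores `l_g` and pooled
#' midranks `r_i`, the statistic is `T = sum l_{g_i} r_i`, standardized by
#' its exact permutation mean and variance (with tie correction) to a normal
#' `z`; the p value is two-sided. Negative `z` means values decrease along
#' the group ordering.
#'
#' @param values Numeric outcomes (e.g. connection weights).
#' @param groups Ordered group membership (integer codes or ordered factor).
#' @return An `rw_trend` with `z`, `p`, and per-group summaries.
#' @export
cuzick_test <- function(values, groups) {
  g <- as.integer(if (is.factor(groups)) unclass(groups) else groups)
  keep <- is.finite(values) & !is.na(g)
  values <- values[keep]; g <- g[keep]
  if (length(unique(g)) < 2L) stop("need >= 2 nonempty groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  l <- g  # integer scores 1..k
  T_obs <- sum(l * r)
  # exchangeable midrank moments
  var_r <- (n^2 - 1) / 12
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  var_r <- var_r - tie_sum / (12 * n)
  cov_r <- -(n + 1) / 12 + tie_sum / (12 * n * (n - 1))
  e_T <- sum(l) * (n + 1) / 2
  v_T <- var_r * sum(l^2) + cov_r * (sum(l)^2 - sum(l^2))
  z <- if (v_T <= 0) 0 else (T_obs - e_T) / sqrt(v_T)
  p <- if (v_T <= 0) 1 else 2 * stats::pnorm(-abs(z))
  grp <- tibble::tibble(group = sort(unique(g))) |>
    dplyr::mutate(n = as.integer(table(factor(g, levels = .data$group))),
                  mean = as.numeric(tapply(values, factor(g, levels = .data$group), mean)))
  new_rw_trend(z, p, "cuzick", grp)
}

new_rw_trend <- function(z, p, method, groups) {
  structure(list(z = z, p = p, method = method, groups = groups),
            class = "rw_trend")
}

#' @export
print.rw_trend <- function(x, ...) {
  cat(sprintf("<rw_trend:%s> z = %.3f, p = %.3g (%d groups, n = %d)\n",
              x$method, x$z, x$p, nrow(x$groups), sum(x$groups$n)))
  invisible(x)
}

#' @export
tidy.rw_trend <- function(x, ...) x$groups

#' @export
glance.rw_trend <- function(x, ...) {
  tibble::tibble(method = x$method, z = x$z, p.value = x$p,
                 n = sum(x$groups$n), n_groups = nrow(x$groups))
}

#' Trend of connection weights across orientation-difference bins
#'
#' Bins the orientation difference of connected pairs into `n_bins` bins of
#' `bin_width` degrees over `[0, 90]` and applies [cuzick_test()] to the
#' weights. Connections shorter than `min_length` (um) are excluded (local
#' connections trivially link co-tuned sites); pass `min_length = NULL` to
#' retain all connections, as appropriate when no map period is estimable.
#'
#' @param values Per-connection weights.
#' @param delta_theta Per-connection orientation differences (degrees,
#'   `[0, 90]`).
#' @param lengths Optional per-connection lengths (um).
#' @param min_length Optional exclusion threshold (um).
#' @param n_bins,bin_width Binning of `[0, 90]` (6 x 15 degrees).
#' @return An `rw_trend`.
#' @export
cuzick_trend <- function(values, delta_theta, lengths = NULL, min_length = NULL,
                         n_bins = 6L, bin_width = 15) {
  if (!is.null(min_length) && !is.null(lengths)) {
    keep <- lengths >= min_length
    values <- values[keep]; delta_theta <- delta_theta[keep]
  }
  bins <- pmin(floor(delta_theta / bin_width), n_bins - 1L) + 1L
  cuzick_test(values, bins)
}

#' Cochran-Armitage test for trend in proportions
#'
#' Tests a linear trend in the proportion of "coupled" pairs across ordered
#' orientation-difference groups (default three groups of 30 degrees), using
#' the standard score-based z statistic; p is two-sided. Negative `z` means
#' coupling probability decreases with orientation difference.
#'
#' @param coupled Logical per pair.
#' @param delta_theta Per-pair orientation difference (degrees).
#' @param breaks Group boundaries (default `c(0, 30, 60, 90)`).
#' @param scores Ordered group scores (default `1:3`).
#' @return An `rw_trend`.
#' @export
cochran_armitage_trend <- function(coupled, delta_theta,
                                   breaks = c(0, 30, 60, 90),
                                   scores = seq_len(length(breaks) - 1L)) {
  g <- cut(pmin(delta_theta, max(breaks) - 1e-9), breaks = breaks,
           include.lowest = TRUE, right = FALSE, labels = FALSE)
  if (anyNA(g)) stop("delta_theta outside the group breaks", call. = FALSE)
  n_g <- tabulate(g, nbins = length(scores))
  if (any(n_g == 0L)) stop("a group has zero pairs", call. = FALSE)
  x_g <- vapply(seq_along(scores), function(k) sum(coupled[g == k]), numeric(1))
  N <- sum(n_g); pbar <- sum(x_g) / N
  num <- sum(scores * (x_g - n_g * pbar))
  v <- pbar * (1 - pbar) * (sum(scores^2 * n_g) - sum(scores * n_g)^2 / N)
  z <- if (v <= 0) 0 else num / sqrt(v)
  p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs(z))
  grp <- tibble::tibble(group = seq_along(scores), n = as.integer(n_g),
                        mean = x_g / n_g)
  new_rw_trend(z, p, "cochran_armitage", grp)
}

#' Orientation difference between two preferred orientations
#' @param a,b Orientations in degrees.
#' @return Difference in `[0, 90]` degrees.
#' @export
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Pairwise connection table of a horizontal network
#'
#' Long tibble of all directed off-diagonal connections with weight,
#' orientation difference, and Euclidean length, ready for the trend tests.
#'
#' @param hn An `lhc_network`.
#' @param thetas Per-site preferred orientations (degrees), e.g.
#'   [site_orientations()].
#' @param sites Site tibble with `x`, `y`.
#' @export
connection_table <- function(hn, thetas, sites) {
  n <- nrow(hn$W)
  from <- rep(seq_len(n), n); to <- rep(seq_len(n), each = n)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  tibble::tibble(
    from = from, to = to, weight = hn$W[cbind(from, to)],
    delta_theta = orientation_diff(thetas[from], thetas[to]),
    length = sqrt((sites$x[from] - sites$x[to])^2 + (sites$y[from] - sites$y[to])^2)
  )
}

#' Hopkins statistic (log-ratio form) in a circular window
#'
#' Compares nearest-neighbour distances of a random 10% member subset (`w`)
#' against distances from an equal number of uniform random probe locations
#' in the window (`x`): `H = ln(sum x^2 / sum w^2)`. `H` is approximately 0
#' under complete spatial randomness and positive for clustered points.
#'
#' @param points Two-column matrix of points inside the window.
#' @param center,radius Window disc.
#' @param member_frac Subset fraction (0.1).
#' @return `H` (numeric scalar).
#' @export
hopkins_stat <- function(points, center, radius, member_frac = 0.1) {
  points <- as_xy(points)
  n <- nrow(points)
  if (n < 2L) stop("too few points", call. = FALSE)
  m <- max(1L, round(member_frac * n))
  sub <- sample.int(n, m)
  w <- vapply(sub, function(i) {
    sqrt(min((points[-i, 1] - points[i, 1])^2 + (points[-i, 2] - points[i, 2])^2))
  }, numeric(1))
  ang <- stats::runif(m, 0, 2 * pi)
  rad <- radius * sqrt(stats::runif(m))
  px <- center[1] + rad * cos(ang); py <- center[2] + rad * sin(ang)
  x <- vapply(seq_len(m), function(i) {
    sqrt(min((points[, 1] - px[i])^2 + (points[, 2] - py[i])^2))
  }, numeric(1))
  log(sum(x^2) / sum(w^2))
}

#' Sliding-window Hopkins statistics over a point set
#'
#' Window centers form a square grid of the given stride over the point
#' bounding box; windows containing at least `min_points` points contribute
#' an H value.
#'
#' @param points Two-column matrix.
#' @param window_radius Disc radius (um).
#' @param stride Grid stride (um).
#' @param min_points Minimum points per window (10).
#' @return Tibble with window centers, point counts and `H`.
#' @export
sliding_hopkins <- function(points, window_radius, stride, min_points = 10L) {
  points <- as_xy(points)
  cx <- seq(min(points[, 1]), max(points[, 1]), by = stride)
  cy <- seq(min(points[, 2]), max(points[, 2]), by = stride)
  out <- list()
  for (x0 in cx) for (y0 in cy) {
    inwin <- (points[, 1] - x0)^2 + (points[, 2] - y0)^2 <= window_radius^2
    if (sum(inwin) < min_points) next
    H <- hopkins_stat(points[inwin, , drop = FALSE], c(x0, y0), window_radius)
    out[[length(out) + 1L]] <- tibble::tibble(x = x0, y = y0, n = sum(inwin), H = H)
  }
  if (!length(out)) return(tibble::tibble(x = numeric(0), y = numeric(0),
                                          n = integer(0), H = numeric(0)))
  dplyr::bind_rows(out)
}

#' Clustering index (CI) of a presynaptic cell's connection field
#'
#' Takes the top 20% strongest postsynaptic cortical locations of the given
#' presynaptic site, excludes the disc of radius `2 d_off` around its soma
#' (only remote, long-range clustering is of interest), and slides a circular
#' window of radius `2 d_off` (stride `d_off`) over the remaining locations;
#' the CI is the median windowed Hopkins H.
#'
#' @param hn An `lhc_network`.
#' @param sites Site tibble (`x`, `y`).
#' @param presyn Presynaptic site index.
#' @param d_off OFF mosaic spacing (um), the model's spatial yardstick.
#' @param top_frac Fraction of strongest connections retained (0.2).
#' @param min_points Minimum remote points required (25).
#' @return CI (numeric scalar).
#' @export
clustering_index <- function(hn, sites, presyn, d_off, top_frac = 0.2,
                             min_points = 25L) {
  w <- hn$W[presyn, ]
  w[presyn] <- -Inf
  n_top <- ceiling(top_frac * (length(w) - 1L))
  top <- order(w, decreasing = TRUE)[seq_len(n_top)]
  px <- sites$x[top]; py <- sites$y[top]
  far <- (px - sites$x[presyn])^2 + (py - sites$y[presyn])^2 > (2 * d_off)^2
  if (sum(far) < min_points) stop("too few points outside the exclusion disc", call. = FALSE)
  hs <- sliding_hopkins(cbind(px[far], py[far]), 2 * d_off, d_off)
  if (!nrow(hs)) stop("no window held enough points", call. = FALSE)
  stats::median(hs$H)
}

#' Population clustering indices
#'
#' CI values for `n_cells` randomly selected presynaptic sites (sites whose
#' connection fields are too sparse for a CI are skipped and resampled).
#'
#' @inheritParams clustering_index
#' @param n_cells Number of presynaptic cells (50).
#' @param seed Integer seed (cell selection, Hopkins subsampling).
#' @return Tibble with `presyn` and `ci`.
#' @export
clustering_indices <- function(hn, sites, d_off, n_cells = 50L, seed = 1L,
                               top_frac = 0.2) {
  set.seed(seed)
  cand <- sample.int(nrow(sites))
  out <- list()
  for (p in cand) {
    ci <- tryCatch(clustering_index(hn, sites, p, d_off, top_frac),
                   error = function(e) NULL)
    if (!is.null(ci)) out[[length(out) + 1L]] <- tibble::tibble(presyn = p, ci = ci)
    if (length(out) >= n_cells) break
  }
  if (length(out) < n_cells)
    warning(sprintf("only %d of %d cells yielded a CI", length(out), n_cells))
  dplyr::bind_rows(out)
}

#' Pairwise similarity of horizontal networks
#'
#' Pearson correlation between the flattened off-diagonal weight matrices of
#' every unordered pair of networks (20 networks give 190 pairs).
#'
#' @param networks List of `lhc_network`s of identical shape.
#' @return Tibble with `i`, `j`, `r`.
#' @export
network_similarity <- function(networks) {
  stopifnot(length(networks) >= 2)
  n <- nrow(networks[[1]]$W)
  vecs <- lapply(networks, function(h) {
    if (nrow(h$W) != n) stop("network shape mismatch", call. = FALSE)
    h$W[row(h$W) != col(h$W)]
  })
  pairs <- utils::combn(length(networks), 2)
  tibble::tibble(
    i = pairs[1, ], j = pairs[2, ],
    r = vapply(seq_len(ncol(pairs)), function(k) {
      stats::cor(vecs[[pairs[1, k]]], vecs[[pairs[2, k]]])
    }, numeric(1))
  )
}

rotate_map_values <- function(map, angle) {
  nx <- length(map$xs); ny <- length(map$ys)
  cx <- mean(range(map$xs)); cy <- mean(range(map$ys))
  gx <- rep(map$xs, ny) - cx
  gy <- rep(map$ys, each = nx) - cy
  sx <- cx + cos(-angle) * gx - sin(-angle) * gy
  sy <- cy + sin(-angle) * gx + cos(-angle) * gy
  ix <- round((sx - map$xs[1]) / map$pixel_size) + 1L
  iy <- round((sy - map$ys[1]) / map$pixel_size) + 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  vals <- rep(NA_real_, nx * ny)
  vals[ok] <- map$values[cbind(ix[ok], iy[ok])]
  dim(vals) <- c(nx, ny)
  vals
}

#' Match an activity correlation map against the orientation similarity map
#'
#' Pearson r between the two maps over jointly defined pixels, with a
#' rotation control: the correlation map is rotated about the grid center by
#' `n_rotations` random angles and r recomputed on each overlap region
#' (rotations leaving under 50% overlap are redrawn; angles within
#' `min_angle` of the identity are excluded so every control actually
#' displaces the map). The p value is a paired t test of the data r against
#' the control r values.
#'
#' @param corr_map,similarity_map `rw_map`s on the same grid.
#' @param n_rotations Number of rotation controls (100).
#' @param seed Integer seed.
#' @param min_angle Smallest control rotation (radians; default 15 degrees).
#' @return List with `r`, `p`, `controls` and `n_exceed` (controls >= data r).
#' @export
map_match <- function(corr_map, similarity_map, n_rotations = 100L, seed = 1L,
                      min_angle = pi / 12) {
  if (!identical(dim(corr_map$values), dim(similarity_map$values)))
    stop("maps on different grids", call. = FALSE)
  both <- corr_map$defined & similarity_map$defined &
    is.finite(corr_map$values) & is.finite(similarity_map$values)
  r_data <- stats::cor(corr_map$values[both], similarity_map$values[both])
  set.seed(seed)
  controls <- numeric(n_rotations)
  n_base <- sum(both)
  for (k in seq_len(n_rotations)) {
    for (try in 1:100) {
      rot <- rotate_map_values(corr_map,
                               stats::runif(1, min_angle, 2 * pi - min_angle))
      ok <- both & is.finite(rot)
      if (sum(ok) >= 0.5 * n_base) break
    }
    controls[k] <- stats::cor(rot[ok], similarity_map$values[ok])
  }
  p <- stats::t.test(r_data - controls)$p.value
  list(r = r_data, p = p, controls = controls, n_exceed = sum(controls >= r_data))
}

#' Presynaptic-to-postsynaptic retina-V1 activity correlation
#'
#' For each cortical site, its most strongly connected ON and OFF RGCs are
#' selected from the trained feedforward weights; for each wave, the Pearson
#' correlation between the site's response trace and each selected RGC's
#' activation is measured within `window_steps` of the site's peak response
#' time. Sites that stay below `active_threshold` in a wave are skipped.
#'
#' @param ff Trained `ff_network`.
#' @param dataset A `wave_dataset` (Stage II or III).
#' @param hn Optional `lhc_network` adding recurrent horizontal input.
#' @param n_waves Number of waves sampled (100).
#' @param window_steps Half-window around the peak, in steps (10 = 1 s).
#' @param active_threshold Minimum peak response for a (site, wave) sample.
#' @param seed Integer seed for wave sampling.
#' @return Tibble with `wave`, `site`, `polarity`, `r`.
#' @export
retina_v1_correlation <- function(ff, dataset, hn = NULL, n_waves = 100L,
                                  window_steps = 10L, active_threshold = 0.1,
                                  seed = 1L) {
  set.seed(seed)
  recs <- dataset$recordings
  idx <- if (length(recs) > n_waves) sample(seq_along(recs), n_waves) else seq_along(recs)
  W_on <- ff$W[seq_len(ff$n_on), , drop = FALSE]
  W_off <- ff$W[ff$n_on + seq_len(ff$n_off), , drop = FALSE]
  best_on <- apply(W_on, 2, which.max)
  best_off <- apply(W_off, 2, which.max)
  out <- list()
  for (w in idx) {
    rec <- recs[[w]]
    drive <- crossprod(ff$W, dataset_activation(rec))
    R <- if (is.null(hn)) v1_sigmoid(drive, ff$theta_v1, ff$delta_v1) else
      recurrent_response_cpp(drive, hn$W, ff$theta_v1, ff$delta_v1)
    T_n <- ncol(R)
    tmax <- max.col(R, ties.method = "first")
    peaks <- R[cbind(seq_len(nrow(R)), tmax)]
    for (k in which(peaks >= active_threshold)) {
      win <- max(1L, tmax[k] - window_steps):min(T_n, tmax[k] + window_steps)
      resp <- R[k, win]
      if (stats::sd(resp) == 0) next
      for (pol in c("on", "off")) {
        tr <- if (pol == "on") rec$A_on[best_on[k], win] else rec$A_off[best_off[k], win]
        if (stats::sd(tr) == 0) next
        out[[length(out) + 1L]] <- tibble::tibble(wave = w, site = k,
                                                  polarity = pol,
                                                  r = stats::cor(resp, tr))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Wave-frequency modulation experiment
#'
#' Increasing the wave occurrence frequency by a factor `gamma_f` puts
#' `gamma_f` times as many waves inside the learning-threshold averaging
#' window, so the horizontal network is trained with
#' `tau = gamma_f * tau0`. For each `gamma_f` and repeat, training runs with
#' periodic checkpoints; the development time is the number of waves until
#' the 6-bin orientation trend first reaches Cuzick `z < z_crit` at two
#' consecutive checkpoints. Differences across `gamma_f` are tested by
#' one-way ANOVA.
#'
#' @param ff Trained `ff_network`.
#' @param dataset A `wave_dataset`.
#' @param gamma_f Frequency factors in `[1, 2]`.
#' @param repeats Repeats per factor (5).
#' @param tau0 Unmodulated averaging window (10 learning steps).
#' @param eps Learning rate.
#' @param max_epochs Training budget in epochs.
#' @param checkpoint_every Checkpoint interval in waves.
#' @param z_crit Development criterion on the Cuzick z (-3).
#' @param thetas Per-site preferred orientations.
#' @param sites Site tibble.
#' @param min_length Optional length exclusion for the trend (um).
#' @param seed Integer seed.
#' @return List with per-run tibble `runs` (censored runs report the budget)
#'   and `p` from `stats::aov` on uncensored development times.
#' @export
frequency_experiment <- function(ff, dataset, gamma_f = c(1, 1.5, 2),
                                 repeats = 5L, tau0 = 10, eps = 2e-7,
                                 max_epochs = 30L, checkpoint_every = NULL,
                                 z_crit = -3, thetas = NULL, sites = NULL,
                                 min_length = NULL, seed = 1L,
                                 precision = "double") {
  stopifnot(all(gamma_f >= 1), all(gamma_f <= 2))
  thetas <- thetas %||% site_orientations(ff)
  sites <- sites %||% ff$sites
  drives <- ff_drives(ff, dataset)
  n_waves <- length(drives)
  checkpoint_every <- checkpoint_every %||% n_waves
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(gamma_f) * repeats),
                      nrow = repeats)
  trend_z <- function(hn, ...) {
    ct <- connection_table(hn, thetas, sites)
    ct <- dplyr::filter(ct, .data$weight > 0)
    glance(cuzick_trend(ct$weight, ct$delta_theta, ct$length, min_length))$z
  }
  runs <- list()
  for (gi in seq_along(gamma_f)) {
    for (rep_i in seq_len(repeats)) {
      s <- run_seeds[rep_i, gi]
      hn <- init_horizontal(ncol(ff$W), seed = s)
      hn <- train_horizontal(hn, ff, dataset, epochs = max_epochs, eps = eps,
                             tau = gamma_f[gi] * tau0, seed = s + 1L,
                             drives = drives, precision = precision,
                             checkpoint_every = checkpoint_every,
                             checkpoint_fn = trend_z,
                             stop_fn = function(cps) {
                               zs <- vapply(cps, function(c) c$value, numeric(1))
                               k <- length(zs)
                               k >= 2 && zs[k] < z_crit && zs[k - 1] < z_crit
                             })
      zs <- vapply(hn$checkpoints, function(c) c$value, numeric(1))
      nw <- vapply(hn$checkpoints, function(c) c$n_waves, numeric(1))
      hit <- which(zs < z_crit & dplyr::lead(zs, default = Inf) < z_crit)
      censored <- length(hit) == 0L
      dev_w <- if (censored) max(nw) else nw[hit[1]]
      g_now <- gamma_f[gi]
      runs[[length(runs) + 1L]] <- tibble::tibble(
        gamma_f = g_now, rep = rep_i, dev_waves = dev_w,
        # physical development time in units of the baseline inter-wave
        # interval: waves arrive gamma_f times faster under modulation
        dev_time = dev_w / g_now,
        censored = censored)
    }
  }
  runs <- dplyr::bind_rows(runs)
  fit <- stats::aov(dev_time ~ factor(gamma_f), data = runs)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(runs = runs, p = p)
}

#' Direction-biased wave training experiment
#'
#' For each of 12 wave axes `theta` (multiples of 30 degrees), a fresh
#' horizontal network is trained on waves propagating within
#' `theta +/- 15` degrees; the training length matches the unbiased
#' protocol (the biased pool is recycled so the network sees the standard
#' number of wave presentations). The mean developed weight is compared
#' between site pairs whose shared preferred orientation lies within 15
#' degrees of `theta` ("parallel") and of `theta + 90` ("orthogonal"). A
#' control network per axis is trained identically on an unbiased random
#' pool of matched size. Parallel and orthogonal means are compared across
#' the 12 axes by two-sample t tests.
#'
#' @param ff Trained `ff_network`.
#' @param dataset A direction-balanced `wave_dataset`.
#' @param epochs,eps,tau Training parameters of the unbiased protocol.
#' @param thetas Per-site preferred orientations.
#' @param seed Integer seed.
#' @param presentations Total wave presentations per network; defaults to
#'   `epochs * n_waves` to match the unbiased protocol.
#' @param precision Passed to [train_horizontal()].
#' @return List with per-axis tibble `angles` and `p_biased`, `p_control`.
#' @export
biased_wave_experiment <- function(ff, dataset, epochs = 30L, eps = 2e-7,
                                   tau = 10, thetas = NULL, seed = 1L,
                                   presentations = NULL,
                                   precision = "double") {
  thetas <- thetas %||% site_orientations(ff)
  drives <- ff_drives(ff, dataset)
  angles <- vapply(dataset$recordings, function(r) r$direction_angle, numeric(1))
  presentations <- presentations %||% (epochs * length(drives))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 24L)
  axis <- seq(0, 330, by = 30)
  n_sites <- ncol(ff$W)
  # a moving activity front is an oriented edge: the neurons it drives best
  # are those whose preferred orientation matches the front line, i.e. the
  # propagation axis + 90 degrees
  pair_means <- function(W, th_axis) {
    near <- function(t0) orientation_diff(thetas, t0 %% 180) <= 15
    par_set <- which(near(th_axis + 90)); orth_set <- which(near(th_axis))
    pm <- function(set) {
      if (length(set) < 2L) return(NA_real_)
      M <- W[set, set]
      mean(M[row(M) != col(M)])
    }
    c(parallel = pm(par_set), orthogonal = pm(orth_set))
  }
  out <- list()
  for (a in seq_along(axis)) {
    dang <- abs((angles - axis[a] + 180) %% 360 - 180)
    sel <- which(dang <= 15)
    if (!length(sel)) next
    ctrl_sel <- sample(seq_along(drives), length(sel))
    eff_epochs <- max(1L, as.integer(round(presentations / length(sel))))
    hn_b <- train_horizontal(init_horizontal(n_sites, seeds[a]), ff, dataset,
                             epochs = eff_epochs, eps = eps, tau = tau,
                             seed = seeds[a] + 1L, drives = drives[sel],
                             precision = precision)
    hn_c <- train_horizontal(init_horizontal(n_sites, seeds[12L + a]), ff, dataset,
                             epochs = eff_epochs, eps = eps, tau = tau,
                             seed = seeds[12L + a] + 1L, drives = drives[ctrl_sel],
                             precision = precision)
    mb <- pair_means(hn_b$W, axis[a]); mc <- pair_means(hn_c$W, axis[a])
    out[[length(out) + 1L]] <- tibble::tibble(
      theta = axis[a], n_waves = length(sel),
      biased_parallel = mb["parallel"], biased_orthogonal = mb["orthogonal"],
      control_parallel = mc["parallel"], control_orthogonal = mc["orthogonal"])
  }
  angles_tbl <- dplyr::bind_rows(out)
  tt <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2) return(NA_real_)
    stats::t.test(a[ok], b[ok])$p.value
  }
  list(angles = angles_tbl,
       p_biased = tt(angles_tbl$biased_parallel, angles_tbl$biased_orthogonal),
       p_control = tt(angles_tbl$control_parallel, angles_tbl$control_orthogonal))
}
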