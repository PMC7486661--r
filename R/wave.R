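#' Parameters of the retinal wave cellular automaton
#'
#' Defaults are the model's standard operating point: 100 ms time step,
#' 400 um ON dendritic radius, 40 um AC dendritic radius, bursting threshold
#' 14, AC threshold 0.5, OFF inhibition threshold -0.2, 1 s active duration,
#' input-strength SD 0.2, 80% waiting fraction and 400 um ignition radius.
#'
#' @param dt Time step (s).
#' @param r_on,r_ac Dendritic interaction radii (um) for ON->ON / ON->AC and
#'   AC->OFF coupling.
#' @param theta_on,theta_ac,theta_off Activation thresholds (input units).
#'   Comparisons are strict: a cell activates only when input *exceeds* its
#'   threshold; an OFF cell is inhibited while input is *below* `theta_off`
#'   and rebounds to active once input returns to `>= theta_off`.
#' @param t_active Burst duration of ON/OFF cells (s); must be an integer
#'   multiple of `dt`.
#' @param delta_c SD of the per-cell input strength `eta ~ N(1, delta_c)`.
#' @param sigma_wave Gaussian smoothing width for postprocessing (um); when
#'   `NULL`, `0.85 * d_off` of the mosaic is used.
#' @param waiting_fraction Fraction of ON cells assigned the waiting state at
#'   initialization (the rest start inactive and leave "holes" in the wave).
#' @param r_init Ignition radius (um).
#' @param stage `"III"` (ON/OFF-asynchronous, amacrine-mediated) or `"II"`
#'   (synchronous: AC silenced, ON drives OFF directly with threshold
#'   `theta_on`).
#' @param max_steps Step cap per wave.
#' @return A `wave_params` list.
#' @export
wave_params <- function(dt = 0.1, r_on = 400, r_ac = 40,
                        theta_on = 14, theta_ac = 0.5, theta_off = -0.2,
                        t_active = 1, delta_c = 0.2, sigma_wave = NULL,
                        waiting_fraction = 0.8, r_init = 400,
                        stage = c("III", "II"), max_steps = 600) {
  stage <- match.arg(stage)
  stopifnot(dt > 0, waiting_fraction > 0, waiting_fraction <= 1)
  t_steps <- t_active / dt
  if (abs(t_steps - round(t_steps)) > 1e-9)
    stop("t_active must be an integer multiple of dt", call. = FALSE)
  structure(list(dt = dt, r_on = r_on, r_ac = r_ac, theta_on = theta_on,
                 theta_ac = theta_ac, theta_off = theta_off,
                 t_active = t_active, t_steps = as.integer(round(t_steps)),
                 delta_c = delta_c, sigma_wave = sigma_wave,
                 waiting_fraction = waiting_fraction, r_init = r_init,
                 stage = stage, max_steps = as.integer(max_steps)),
            class = "wave_params")
}

ext_layer <- function(ext, type) as_xy(ext[ext$type == type, c("x", "y")])

ext_data_idx <- function(ext, type) which(ext$is_data[ext$type == type])

#' Precompute the coupling lists of an extended mosaic
#'
#' ON-ON and ON-AC pairs within `r_on`, AC-OFF pairs within `r_ac`, and (for
#' the Stage II variant) ON-OFF pairs within `r_on`. Computing these once and
#' passing them to [simulate_wave()] amortises the neighbour search across a
#' wave dataset.
#'
#' @param ext An `extended_mosaic`.
#' @param params A [wave_params()] list.
#' @export
wave_couplings <- function(ext, params = wave_params()) {
  on <- ext_layer(ext, "on"); off <- ext_layer(ext, "off"); ac <- ext_layer(ext, "ac")
  list(
    on_on = radius_pairs(on, on, params$r_on, exclude_self = TRUE),
    on_ac = radius_pairs(on, ac, params$r_on),
    ac_off = radius_pairs(ac, off, params$r_ac),
    on_off = if (params$stage == "II") radius_pairs(on, off, params$r_on) else
      replicate(nrow(on), integer(0), simplify = FALSE)
  )
}

#' Simulate one retinal wave
#'
#' Runs the discrete-state cellular automaton until no cell is active (or
#' `max_steps` is reached), starting from an ignition disc of radius
#' `r_init` around `init_center`.
#'
#' @param ext An `extended_mosaic`.
#' @param params A [wave_params()] list.
#' @param init_center Ignition center (um), inside the mosaic boundary.
#' @param seed Integer seed (waiting-state assignment, input strengths).
#' @param couplings Optional precomputed [wave_couplings()].
#' @param record_states Keep the full per-step state of every cell (memory
#'   heavy; intended for small mosaics).
#' @return A `cell_state_history`: per-step lists of active ON/OFF cell
#'   indices (within each layer of the extended mosaic), plus bookkeeping.
#' @export
simulate_wave <- function(ext, params = wave_params(), init_center, seed,
                          couplings = NULL, record_states = FALSE) {
  center <- attr(ext, "center")
  if (sqrt(sum((init_center - center)^2)) > attr(ext, "boundary_radius"))
    stop("init_center outside boundary", call. = FALSE)
  if (is.null(couplings)) couplings <- wave_couplings(ext, params)
  on <- ext_layer(ext, "on")
  set.seed(seed)
  res <- ca_simulate_cpp(on, couplings$on_on, couplings$on_ac, couplings$ac_off,
                         couplings$on_off,
                         n_ac = sum(ext$type == "ac"), n_off = sum(ext$type == "off"),
                         theta_on = params$theta_on, theta_ac = params$theta_ac,
                         theta_off = params$theta_off, delta_c = params$delta_c,
                         waiting_fraction = params$waiting_fraction,
                         r_init = params$r_init, init_center = as.numeric(init_center),
                         t_steps = params$t_steps, max_steps = params$max_steps,
                         stage = if (params$stage == "II") 2L else 3L,
                         record_states = record_states)
  res$init_center <- as.numeric(init_center)
  res$seed <- as.integer(seed)
  res$stage <- params$stage
  class(res) <- "cell_state_history"
  res
}

#' @export
print.cell_state_history <- function(x, ...) {
  cat(sprintf("<cell_state_history> stage %s, %d steps%s\n", x$stage, x$n_steps,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Smooth and normalize a wave history into a recording
#'
#' For every time step, the activation of each *data* cell is the sum of
#' Gaussian kernels (width `sigma_wave`, default `0.85 * d_off`) centered on
#' the active data cells of the same layer; each layer is then max-normalized
#' per step (steps with an empty layer stay zero). Steps during which neither
#' data layer carries activity (the wave is outside the data window) are
#' trimmed from both ends.
#'
#' @param history A `cell_state_history` from [simulate_wave()].
#' @param ext The `extended_mosaic` the wave ran on.
#' @param params The [wave_params()] used.
#' @return A `wave_recording` with activation matrices `A_on`
#'   (`n_data_on x T`) and `A_off`, data-cell positions, and (after
#'   [classify_direction()]) a direction bin.
#' @export
postprocess_wave <- function(history, ext, params = wave_params()) {
  d_off <- attr(ext, "d_off")
  sigma <- params$sigma_wave %||% (0.85 * d_off)
  idx_on <- ext_data_idx(ext, "on"); idx_off <- ext_data_idx(ext, "off")
  pos_on <- ext_layer(ext, "on")[idx_on, , drop = FALSE]
  pos_off <- ext_layer(ext, "off")[idx_off, , drop = FALSE]
  G_on <- gauss_kernel_matrix(pos_on, pos_on, sigma)
  G_off <- gauss_kernel_matrix(pos_off, pos_off, sigma)

  smooth_layer <- function(active, idx, G) {
    n <- nrow(G)
    A <- matrix(0, n, length(active))
    for (s in seq_along(active)) {
      act <- match(intersect(active[[s]], idx), idx)
      if (length(act))
        A[, s] <- rowSums(G[, act, drop = FALSE])
    }
    A
  }
  A_on <- smooth_layer(history$on_active, idx_on, G_on)
  A_off <- smooth_layer(history$off_active, idx_off, G_off)

  live <- which(colSums(A_on) + colSums(A_off) > 0)
  if (length(live)) {
    keep <- seq(min(live), max(live))
    A_on <- A_on[, keep, drop = FALSE]
    A_off <- A_off[, keep, drop = FALSE]
    t_offset <- min(live) - 1L
  } else {
    A_on <- A_on[, integer(0), drop = FALSE]
    A_off <- A_off[, integer(0), drop = FALSE]
    t_offset <- 0L
  }
  norm_cols <- function(A) {
    mx <- apply(A, 2, max)
    nz <- mx > 0
    A[, nz] <- sweep(A[, nz, drop = FALSE], 2, mx[nz], "/")
    A
  }
  structure(list(A_on = norm_cols(A_on), A_off = norm_cols(A_off),
                 pos_on = pos_on, pos_off = pos_off,
                 direction_bin = NA_integer_, direction_angle = NA_real_,
                 init_center = history$init_center, seed = history$seed,
                 stage = history$stage, truncated = isTRUE(history$truncated),
                 t_offset = t_offset, sigma_wave = sigma),
            class = "wave_recording")
}

gauss_kernel_matrix <- function(a, b, sigma) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  exp(-d2 / (2 * sigma^2))
}

#' @export
print.wave_recording <- function(x, ...) {
  cat(sprintf("<wave_recording> stage %s, %d ON x %d OFF data cells, %d steps, bin %s\n",
              x$stage, nrow(x$A_on), nrow(x$A_off), ncol(x$A_on),
              ifelse(is.na(x$direction_bin), "?", x$direction_bin)))
  invisible(x)
}

#' Classify the propagation direction of a recording
#'
#' The direction is the angle of the displacement of the ON-activity centroid
#' from the first to the last step with nonzero ON activity, binned into 12
#' sectors of 30 degrees centered on 0, 30, ..., 330 degrees (bin 0 = +x,
#' bin 3 = +y).
#'
#' @param recording A `wave_recording`.
#' @return The recording with `direction_bin` (0..11) and `direction_angle`
#'   (degrees) filled in.
#' @export
classify_direction <- function(recording) {
  on_mass <- colSums(recording$A_on)
  live <- which(on_mass > 0)
  if (length(live) < 2L) stop("no net propagation", call. = FALSE)
  centroid <- function(s) {
    w <- recording$A_on[, s]
    colSums(recording$pos_on * w) / sum(w)
  }
  disp <- centroid(max(live)) - centroid(min(live))
  if (sqrt(sum(disp^2)) < 1) stop("no net propagation", call. = FALSE)
  ang <- atan2(disp[2], disp[1]) * 180 / pi
  recording$direction_angle <- ang %% 360
  recording$direction_bin <- as.integer(round(recording$direction_angle / 30)) %% 12L
  recording
}

#' Assemble a direction-balanced wave dataset
#'
#' Simulates waves ignited at `0.9 * boundary_radius` from the mosaic center
#' at uniformly random angles until each of the 12 direction bins holds
#' `n_waves / 12` recordings. Waves that never reach the data window, show no
#' net propagation, or hit the step cap are discarded (they still count
#' against the attempt budget).
#'
#' @param ext An `extended_mosaic`.
#' @param params A [wave_params()] list.
#' @param n_waves Total dataset size; must be a multiple of 12.
#' @param seed Integer seed controlling per-wave seeds and ignition angles.
#' @param max_attempts Simulation budget before giving up.
#' @return A `wave_dataset`: the list of balanced recordings plus mosaic
#'   metadata (`d_off`, data-cell positions).
#' @export
assemble_wave_dataset <- function(ext, params = wave_params(), n_waves, seed,
                                  max_attempts = 40L * n_waves) {
  if (n_waves %% 12 != 0) stop("n_waves must be a multiple of 12", call. = FALSE)
  per_bin <- n_waves / 12
  set.seed(seed)
  wave_seeds <- sample.int(.Machine$integer.max - 1L, max_attempts)
  angles <- stats::runif(max_attempts, 0, 2 * pi)
  center <- attr(ext, "center")
  r_ignite <- 0.9 * attr(ext, "boundary_radius")
  couplings <- wave_couplings(ext, params)

  bins <- vector("list", 12)
  filled <- integer(12)
  attempt <- 0L
  while (any(filled < per_bin)) {
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop(sprintf("direction bins could not be filled within %d simulations (counts: %s)",
                   max_attempts, paste(filled, collapse = ",")), call. = FALSE)
    ic <- center + r_ignite * c(cos(angles[attempt]), sin(angles[attempt]))
    hist <- simulate_wave(ext, params, ic, wave_seeds[attempt], couplings)
    if (isTRUE(hist$truncated)) next
    rec <- postprocess_wave(hist, ext, params)
    if (ncol(rec$A_on) < 2L) next
    rec <- tryCatch(classify_direction(rec), error = function(e) NULL)
    if (is.null(rec)) next
    b <- rec$direction_bin + 1L
    if (filled[b] >= per_bin) next
    bins[[b]] <- c(bins[[b]], list(rec))
    filled[b] <- filled[b] + 1L
  }
  recordings <- unlist(bins, recursive = FALSE)
  structure(list(recordings = recordings, stage = params$stage,
                 d_off = attr(ext, "d_off"),
                 pos_on = recordings[[1]]$pos_on, pos_off = recordings[[1]]$pos_off,
                 params = params, seed = as.integer(seed), control = FALSE),
            class = "wave_dataset")
}

#' @export
print.wave_dataset <- function(x, ...) {
  cat(sprintf("<wave_dataset> %d stage-%s waves%s, %d ON + %d OFF data cells\n",
              length(x$recordings), x$stage,
              if (isTRUE(x$control)) " (permuted control)" else "",
              nrow(x$pos_on), nrow(x$pos_off)))
  invisible(x)
}

#' Permuted-activity control dataset
#'
#' For every recording and every time step, activation values are shuffled
#' across cell indices (independently per layer and step). Per-step, per-layer
#' sums and maxima are preserved exactly while spatial wave structure is
#' destroyed.
#'
#' @param dataset A `wave_dataset`.
#' @param seed Integer seed.
#' @export
permute_activity <- function(dataset, seed) {
  set.seed(seed)
  shuffle <- function(A) {
    for (s in seq_len(ncol(A))) A[, s] <- A[sample.int(nrow(A)), s]
    A
  }
  dataset$recordings <- lapply(dataset$recordings, function(rec) {
    rec$A_on <- shuffle(rec$A_on)
    rec$A_off <- shuffle(rec$A_off)
    rec
  })
  dataset$control <- TRUE
  dataset
}

#' @export
tidy.wave_recording <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(layer = "on",
                   cell = rep(seq_len(nrow(x$A_on)), ncol(x$A_on)),
                   step = rep(seq_len(ncol(x$A_on)), each = nrow(x$A_on)),
                   activation = as.vector(x$A_on)),
    tibble::tibble(layer = "off",
                   cell = rep(seq_len(nrow(x$A_off)), ncol(x$A_off)),
                   step = rep(seq_len(ncol(x$A_off)), each = nrow(x$A_off)),
                   activation = as.vector(x$A_off))
  )
}

#' @export
tidy.wave_dataset <- function(x, ...) {
  purrr::map_dfr(seq_along(x$recordings), function(i) {
    r <- x$recordings[[i]]
    tibble::tibble(wave = i, direction_bin = r$direction_bin,
                   direction_angle = r$direction_angle,
                   n_steps = ncol(r$A_on), seed = r$seed)
  })
}
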