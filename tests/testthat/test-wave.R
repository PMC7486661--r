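test_that("cellular-automaton state machine is sound", {
  h <- tiny_history()
  p <- tiny_params()
  ext <- tiny_ext()
  n_on <- sum(ext$type == "on")
  n_off <- sum(ext$type == "off")

  # every ON/OFF active episode lasts exactly T_active/dt = 10 steps, and
  # inactive is absorbing (single contiguous episode per cell)
  check_episodes <- function(active_lists, n_cells) {
    steps_active <- integer(n_cells)
    first <- rep(NA_integer_, n_cells)
    last <- rep(NA_integer_, n_cells)
    for (s in seq_along(active_lists)) {
      idx <- active_lists[[s]]
      steps_active[idx] <- steps_active[idx] + 1L
      first[idx][is.na(first[idx])] <- s
      last[idx] <- s
    }
    fired <- !is.na(first)
    # contiguity: active count equals span -> one episode, no re-activation
    expect_true(all(last[fired] - first[fired] + 1L == steps_active[fired]))
    expect_true(all(steps_active[fired] == p$t_steps))
    fired
  }
  fired_on <- check_episodes(h$on_active, n_on)
  fired_off <- check_episodes(h$off_active, n_off)
  expect_gt(sum(fired_on), 0.2 * n_on)
  expect_gt(sum(fired_off), 0.2 * n_off)

  # 80/20 waiting split is exact
  expect_equal(h$n_waiting_on, round(0.8 * n_on))
})

test_that("waves are deterministic given seed and ignition is monotone in R_init", {
  ext <- tiny_ext()
  p <- tiny_params()
  ic <- attr(ext, "center") + c(900, 0)
  h1 <- simulate_wave(ext, p, ic, seed = 123)
  h2 <- simulate_wave(ext, p, ic, seed = 123)
  expect_identical(h1$on_active, h2$on_active)
  expect_identical(h1$off_active, h2$off_active)

  n_ign <- vapply(c(200, 400, 800), function(r) {
    pp <- wave_params(r_init = r)
    simulate_wave(ext, pp, ic, seed = 55)$n_ignited
  }, numeric(1))
  expect_true(all(diff(n_ign) >= 0))

  expect_error(simulate_wave(ext, p, attr(ext, "center") + c(5000, 0), seed = 1),
               "outside boundary")
})

test_that("stage III is ON/OFF asynchronous and stage II synchronous", {
  ext <- tiny_ext()
  ic <- attr(ext, "center") + c(0.9 * 1200, 0)
  onset <- function(lists, n) {
    o <- rep(NA_integer_, n)
    for (s in seq_along(lists)) {
      idx <- lists[[s]]
      o[idx][is.na(o[idx])] <- s
    }
    o
  }
  lag_for <- function(stage) {
    p <- wave_params(stage = stage)
    h <- simulate_wave(ext, p, ic, seed = 42, couplings = wave_couplings(ext, p))
    pon <- ext[ext$type == "on", c("x", "y")]
    poff <- ext[ext$type == "off", c("x", "y")]
    o_on <- onset(h$on_active, nrow(pon))
    o_off <- onset(h$off_active, nrow(poff))
    lags <- vapply(which(!is.na(o_off)), function(j) {
      i <- which.min((pon$x - poff$x[j])^2 + (pon$y - poff$y[j])^2)
      if (is.na(o_on[i])) NA_real_ else o_off[j] - o_on[i]
    }, numeric(1))
    stats::median(lags, na.rm = TRUE)
  }
  expect_gt(lag_for("III"), 0)
  expect_lte(lag_for("II"), 1)
})

test_that("postprocessing smooths, max-normalizes per layer and step, and trims", {
  rec <- tiny_recording()
  mx_on <- apply(rec$A_on, 2, max)
  mx_off <- apply(rec$A_off, 2, max)
  # any step with activity in a layer has max exactly 1; empty layers all zero
  expect_true(all(mx_on[mx_on > 0] == 1))
  expect_true(all(mx_off[mx_off > 0] == 1))
  expect_true(all(rec$A_on >= 0 & rec$A_on <= 1))
  # trimmed: first and last steps carry some activity
  expect_gt(mx_on[1] + mx_off[1], 0)
  expect_gt(mx_on[ncol(rec$A_on)] + mx_off[ncol(rec$A_off)], 0)
})

test_that("a single active cell normalizes to exactly 1", {
  # hand-built history: one data ON cell active for one step
  ext <- tiny_ext()
  idx_on <- which(ext$is_data[ext$type == "on"])
  h <- list(on_active = list(idx_on[1]), off_active = list(integer(0)),
            n_steps = 1L, truncated = FALSE, init_center = c(0, 0), seed = 1L,
            stage = "III")
  class(h) <- "cell_state_history"
  rec <- postprocess_wave(h, ext, tiny_params())
  expect_equal(max(rec$A_on), 1)
  expect_equal(rec$A_on[1, 1], 1)
  expect_true(all(rec$A_off == 0))
})

test_that("direction classification follows the 30-degree bin convention", {
  # synthetic recording: a blob of ON activity drifting in a known direction
  drift_recording <- function(angle_deg) {
    pos <- as.matrix(expand.grid(x = seq(-200, 200, by = 40),
                                 y = seq(-200, 200, by = 40)))
    ang <- angle_deg * pi / 180
    steps <- 8
    A <- sapply(seq_len(steps), function(s) {
      c0 <- (s - 4.5) * 40 * c(cos(ang), sin(ang))
      exp(-((pos[, 1] - c0[1])^2 + (pos[, 2] - c0[2])^2) / (2 * 60^2))
    })
    structure(list(A_on = A / max(A), A_off = A * 0, pos_on = pos, pos_off = pos,
                   direction_bin = NA, direction_angle = NA,
                   init_center = c(0, 0), seed = 1L, stage = "III",
                   truncated = FALSE, t_offset = 0L, sigma_wave = 60),
              class = "wave_recording")
  }
  expect_equal(classify_direction(drift_recording(0))$direction_bin, 0L)
  expect_equal(classify_direction(drift_recording(90))$direction_bin, 3L)
  # rotational equivariance: +90 degrees shifts the bin by 3 (mod 12)
  for (a in c(12, 57, 200, 301)) {
    b1 <- classify_direction(drift_recording(a))$direction_bin
    b2 <- classify_direction(drift_recording(a + 90))$direction_bin
    expect_equal(b2, (b1 + 3L) %% 12L)
  }
  # stationary blob errors
  still <- drift_recording(0)
  still$A_on <- still$A_on[, c(1, 1, 1)]
  expect_error(classify_direction(still), "no net propagation")
})

test_that("assembled datasets are direction-balanced", {
  ds <- tiny_dataset()
  bins <- vapply(ds$recordings, function(r) r$direction_bin, integer(1))
  expect_equal(unname(table(factor(bins, levels = 0:11))), rep(2L, 12),
               ignore_attr = TRUE)
  expect_length(ds$recordings, 24)
})

test_that("permuted control preserves per-step per-layer sums and maxima exactly", {
  ds <- tiny_dataset()
  perm <- permute_activity(ds, seed = 31)
  for (k in c(1, 7, 20)) {
    expect_identical(colSums(perm$recordings[[k]]$A_on), colSums(ds$recordings[[k]]$A_on))
    expect_identical(apply(perm$recordings[[k]]$A_off, 2, max),
                     apply(ds$recordings[[k]]$A_off, 2, max))
  }
  # permuting twice with an independent seed still preserves sums
  perm2 <- permute_activity(perm, seed = 77)
  expect_identical(colSums(perm2$recordings[[3]]$A_on), colSums(ds$recordings[[3]]$A_on))

  # spatial structure is destroyed: lag-d_off Moran-style autocorrelation drops
  rec <- ds$recordings[[1]]
  s_mid <- which.max(colSums(rec$A_on))
  moran <- function(vals) {
    d <- as.matrix(dist(rec$pos_on))
    wgt <- d > 0 & d < 1.5 * ds$d_off
    v <- vals - mean(vals)
    sum(wgt * outer(v, v)) / (sum(wgt) * stats::var(v))
  }
  m_orig <- moran(rec$A_on[, s_mid])
  m_perm <- moran(perm$recordings[[1]]$A_on[, s_mid])
  expect_gt(m_orig, 0.3)
  expect_lt(abs(m_perm), 0.2)
})
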