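test_that("cortical sites sit at qualifying dipole midpoints", {
  m <- new_rgc_mosaic(
    on = rbind(c(0, 0), c(1000, 1000)),
    off = rbind(c(60, 0), c(2000, -2000))
  )
  # force a known spacing for the rule: use the real tiny mosaic for the scan
  sites <- place_cortical_sites(tiny_mosaic())
  mos <- tiny_mosaic()
  d_off <- mosaic_spacings(mos)["d_off"]
  on <- as.matrix(mos[mos$polarity == "on", c("x", "y")])
  off <- as.matrix(mos[mos$polarity == "off", c("x", "y")])
  # brute-force all-pairs oracle
  cnt <- 0L
  for (i in seq_len(nrow(on))) for (j in seq_len(nrow(off))) {
    if (sqrt(sum((on[i, ] - off[j, ])^2)) < 1.5 * d_off) cnt <- cnt + 1L
  }
  expect_equal(nrow(sites), cnt)
  # midpoints
  expect_equal(sites$x, (on[sites$parent_on, 1] + off[sites$parent_off, 1]) / 2)

  # single qualifying pair / no pair
  m1 <- new_rgc_mosaic(rbind(c(0, 0), c(5000, 5000)), rbind(c(30, 0), c(-5000, -5000)))
  s1 <- place_cortical_sites(m1)
  expect_true(any(abs(s1$x - 15) < 1e-9 & abs(s1$y) < 1e-9))
})

test_that("feedforward initialization is exponential in distance", {
  ff <- tiny_ff()
  m <- tiny_mosaic()
  on <- as.matrix(m[m$polarity == "on", c("x", "y")])
  k <- 3
  d <- sqrt((on[, 1] - ff$sites$x[k])^2 + (on[, 2] - ff$sites$y[k])^2)
  expect_equal(ff$W[seq_len(ff$n_on), k], 0.05 * exp(-d / 18), tolerance = 1e-12)
  # weight at zero distance would be w_init; at d_ff it is w_init / e
  expect_equal(0.05 * exp(-18 / 18), 0.05 / exp(1))
  # monotone decay
  ord <- order(d)
  expect_true(all(diff(ff$W[seq_len(ff$n_on), k][ord]) <= 1e-15))
})

test_that("sigmoid response matches its closed form and is monotone", {
  ff <- tiny_ff()
  n_rgc <- nrow(ff$W)
  # u = theta -> 0.5 exactly: feed activation that lands on the midpoint
  act <- numeric(n_rgc)
  r0 <- compute_response(ff, act)
  expect_equal(unname(r0), rep(1 / (1 + exp(0.5 / 0.15)), ncol(ff$W)), tolerance = 1e-12)
  r_mid <- compute_response(ff, act, extra_input = 0.5)
  expect_equal(unname(r_mid), rep(0.5, ncol(ff$W)), tolerance = 1e-12)
  # strictly increasing in input
  us <- seq(0, 1, by = 0.1)
  rs <- vapply(us, function(u) compute_response(ff, act, extra_input = u)[1], numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("feedforward covariance training matches a straight-line oracle bit-exactly", {
  # toy: 2 RGCs (1 ON, 1 OFF), 1 site, 3 hand-set "waves"
  ff <- tiny_ff()
  ff$W <- matrix(c(0.03, 0.02), nrow = 2)
  ff$n_on <- 1L; ff$n_off <- 1L
  waves <- list(
    rbind(c(0.2, 0.9, 0.1), c(0.8, 0.3, 0.0)),
    rbind(c(1.0, 0.5, 0.2), c(0.1, 0.9, 0.4)),
    rbind(c(0.0, 0.3, 0.6), c(0.5, 0.5, 0.5))
  )
  ds <- list(recordings = lapply(waves, function(w)
    list(A_on = w[1, , drop = FALSE], A_off = w[2, , drop = FALSE])))

  eps <- 0.005; tau <- 15
  # independent oracle: plain loop over the decided update rule
  oracle <- function(W, epochs, seed) {
    set.seed(seed)
    Rbar <- NULL
    sig <- function(u) 1 / (1 + exp(-(u - 0.5) / 0.15))
    for (e in seq_len(epochs)) {
      for (w in sample(3)) {
        A <- waves[[w]]
        R <- sig(drop(crossprod(W, A)))
        tstar <- which.max(R)  # which.max returns the earliest max
        peak <- R[tstar]
        if (is.null(Rbar)) Rbar <- peak
        W <- W + eps * A[, tstar] * (peak - Rbar)
        W[W < 0] <- 0; W[W > 0.14] <- 0.14
        Rbar <- (1 - 1 / tau) * Rbar + peak / tau
      }
    }
    W
  }
  trained <- train_feedforward(ff, ds, epochs = 4, eps = eps, tau = tau, seed = 77)
  expect_identical(trained$W, oracle(matrix(c(0.03, 0.02), 2), 4, 77))
})

test_that("trained feedforward weights respect the resource limit everywhere", {
  ds <- tiny_dataset()
  ff <- train_feedforward(tiny_ff(), ds, epochs = 3, seed = 5)
  expect_true(all(ff$W >= 0))
  expect_true(all(ff$W <= 0.14 + 1e-15))
  # constant peak responses are a fixed point: Rbar converges, updates vanish
  ds_const <- list(recordings = list(list(A_on = matrix(0.5, 2, 3),
                                          A_off = matrix(0.5, 2, 3))))
  ff2 <- tiny_ff(); ff2$W <- matrix(0.01, 4, 2); ff2$n_on <- 2L; ff2$n_off <- 2L
  t1 <- train_feedforward(ff2, ds_const, epochs = 1, seed = 1)
  t2 <- train_feedforward(ff2, ds_const, epochs = 50, seed = 1)
  expect_equal(t1$W, t2$W, tolerance = 1e-12)
})

test_that("site orientation estimates fall back to parent geometry when degenerate", {
  ff <- tiny_ff()
  expect_identical(site_orientations(ff), ff$sites$theta)  # untrained -> parents
  ff$trained <- TRUE
  th_w <- site_orientations(ff)  # weight-weighted, init weights ~ dipole geometry
  expect_true(all(th_w >= 0 & th_w < 180))
  ff$W[] <- 0
  expect_identical(site_orientations(ff, "weights"), ff$sites$theta)
})
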