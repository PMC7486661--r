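test_that("Cuzick z agrees with a Monte-Carlo permutation null", {
  set.seed(11)
  g <- rep(1:6, each = 10)
  x <- rnorm(60) - 0.3 * g   # moderate decreasing trend
  res <- cuzick_test(x, g)
  expect_lt(res$z, 0)

  # permutation oracle for the same statistic
  r <- rank(x)
  T_obs <- sum(g * r)
  n_mc <- 2e4
  T_mc <- vapply(seq_len(n_mc), function(i) sum(g * sample(r)), numeric(1))
  p_mc <- mean(abs(T_mc - mean(T_mc)) >= abs(T_obs - mean(T_mc)))
  mc_err <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(res$p - p_mc), 2 * mc_err + 0.01)
  # and the z itself against permutation moments
  z_mc <- (T_obs - mean(T_mc)) / sd(T_mc)
  expect_equal(res$z, z_mc, tolerance = 0.05)
})

test_that("Cuzick test is rank-based and degenerates gracefully", {
  g <- rep(1:3, each = 5)
  x <- c(rnorm(15))
  r1 <- cuzick_test(x, g)
  r2 <- cuzick_test(x + 100, g)        # shift invariance
  expect_equal(r1$z, r2$z)
  r3 <- cuzick_test(exp(x), g)         # monotone-transform invariance
  expect_equal(r1$z, r3$z)
  # all values equal: no trend detectable
  r4 <- cuzick_test(rep(1, 15), g)
  expect_equal(r4$z, 0)
  expect_equal(r4$p, 1)
  expect_error(cuzick_test(x, rep(1, 15)), "2 nonempty groups")
})

test_that("cuzick_trend bins into six 15-degree groups and honors exclusion", {
  set.seed(2)
  dth <- runif(300, 0, 90)
  w <- 1 - dth / 100 + rnorm(300, 0, 0.05)
  len <- runif(300, 0, 500)
  tr <- cuzick_trend(w, dth)
  expect_equal(nrow(tr$groups), 6)
  expect_lt(tr$z, -3)
  tr2 <- cuzick_trend(w, dth, lengths = len, min_length = 250)
  expect_equal(sum(tr2$groups$n), sum(len >= 250))
})

test_that("Cochran-Armitage matches exact enumeration on a small table", {
  # 3 groups of n = 8; exact conditional null by multivariate hypergeometric
  n_g <- c(8, 8, 8); x_g <- c(7, 4, 2)
  coupled <- unlist(mapply(function(n, x) c(rep(TRUE, x), rep(FALSE, n - x)),
                           n_g, x_g, SIMPLIFY = FALSE))
  dth <- rep(c(10, 40, 70), times = n_g)
  res <- cochran_armitage_trend(coupled, dth)
  expect_lt(res$z, 0)

  z_of <- function(x1, x2, x3) {
    xg <- c(x1, x2, x3); N <- 24; pbar <- sum(xg) / N; s <- 1:3
    num <- sum(s * (xg - 8 * pbar))
    v <- pbar * (1 - pbar) * (sum(s^2 * 8) - sum(s * 8)^2 / N)
    num / sqrt(v)
  }
  k <- sum(x_g)
  tab <- expand.grid(x1 = 0:8, x2 = 0:8)
  tab$x3 <- k - tab$x1 - tab$x2
  tab <- tab[tab$x3 >= 0 & tab$x3 <= 8, ]
  pr <- choose(8, tab$x1) * choose(8, tab$x2) * choose(8, tab$x3) / choose(24, k)
  zs <- mapply(z_of, tab$x1, tab$x2, tab$x3)
  p_exact <- sum(pr[abs(zs) >= abs(res$z) - 1e-12])
  expect_lt(abs(res$p - p_exact), 0.03)

  # antisymmetry under reversing group order
  res_rev <- cochran_armitage_trend(coupled, 90 - dth)
  expect_equal(res_rev$z, -res$z, tolerance = 1e-12)
  # equal proportions -> z = 0
  expect_equal(cochran_armitage_trend(rep(c(TRUE, FALSE), 30),
                                      rep(c(10, 40, 70), 20))$z, 0)
  expect_error(cochran_armitage_trend(coupled[1:16], dth[1:16]), "zero pairs")
})

test_that("Hopkins statistic is calibrated on CSR and detects planted clumps", {
  set.seed(20)
  # complete spatial randomness: mean H over repeated windows ~ 0
  H <- replicate(100, {
    n <- 60
    ang <- runif(n, 0, 2 * pi); rad <- 300 * sqrt(runif(n))
    pts <- cbind(rad * cos(ang), rad * sin(ang))
    hopkins_stat(pts, c(0, 0), 300)
  })
  expect_lt(abs(mean(H)), 0.15)

  # one tight clump: probe distances dominate member NN distances -> H >> 0
  set.seed(21)
  clump <- cbind(rnorm(60, 250, 4), rnorm(60, 0, 4))
  H_clump <- replicate(50, hopkins_stat(clump, c(250, 0), 300))
  expect_gt(mean(H_clump), 1)
})

test_that("clustering_index takes the median windowed H of remote top connections", {
  set.seed(5)
  n <- 500
  sites <- tibble::tibble(x = runif(n, 0, 600), y = runif(n, 0, 600))
  d_off <- 70
  # presynaptic cell 1 with strongest weights forming two remote clumps
  W <- matrix(runif(n * n, 0, 1e-5), n, n); diag(W) <- 0
  c1 <- c(450, 450); c2 <- c(120, 480)
  near1 <- which((sites$x - c1[1])^2 + (sites$y - c1[2])^2 < 80^2)
  near2 <- which((sites$x - c2[1])^2 + (sites$y - c2[2])^2 < 80^2)
  W[1, c(near1, near2)] <- 1e-4
  hn <- structure(list(W = W, w_limit = 5e-4, trained = TRUE), class = "lhc_network")
  set.seed(9)
  ci_clumped <- clustering_index(hn, sites, 1, d_off)
  # same weights but shuffled over postsynaptic sites: no spatial clumping
  set.seed(9)
  W2 <- W; W2[1, -1] <- sample(W[1, -1])
  hn2 <- structure(list(W = W2, w_limit = 5e-4, trained = TRUE), class = "lhc_network")
  ci_flat <- clustering_index(hn2, sites, 1, d_off)
  expect_gt(ci_clumped, ci_flat)
  expect_gt(ci_clumped, 0.5)

  set.seed(31)
  cis <- clustering_indices(hn, sites, d_off, n_cells = 10, seed = 3)
  expect_equal(nrow(cis), 10)
  expect_true(all(is.finite(cis$ci)))
})

test_that("network similarity enumerates unordered pairs of flattened weights", {
  set.seed(8)
  nets <- lapply(1:20, function(k) init_horizontal(40, seed = k))
  sim <- network_similarity(nets)
  expect_equal(nrow(sim), 190)
  # independent random networks: mean r ~ 0
  expect_lt(abs(mean(sim$r)), 3 * sd(sim$r) / sqrt(190) + 0.01)
  # identical networks: r = 1
  expect_equal(network_similarity(list(nets[[1]], nets[[1]]))$r, 1)
  bad <- init_horizontal(10, seed = 1)
  expect_error(network_similarity(list(nets[[1]], bad)), "shape mismatch")
})

test_that("map_match gives r = 1 on identity and beats all rotation controls on a planted pair", {
  set.seed(12)
  sites <- tibble::tibble(x = runif(150, 0, 400), y = runif(150, 0, 400),
                          theta = (180 * ((runif(150, 0, 400)) / 150)) %% 180)
  # structured map: stripes
  sites$theta <- (180 * sites$x / 150) %% 180
  om <- render_orientation_map(sites, 30)
  sim_map <- orientation_similarity(om, c(200, 200))
  mm <- map_match(sim_map, sim_map, n_rotations = 40, seed = 4)
  expect_equal(mm$r, 1)
  expect_equal(mm$n_exceed, 0)
  expect_true(all(mm$controls < 1))
  expect_lt(mm$p, 1e-6)
})

test_that("correlation_map matches a textbook two-pass Pearson on a toy image set", {
  set.seed(14)
  sites <- tibble::tibble(x = runif(40, 0, 200), y = runif(40, 0, 200))
  hn <- init_horizontal(40, seed = 2)
  hn$trained <- TRUE
  hnf <- finalize_incoming(hn)
  acts <- simulate_spontaneous_set(hnf, sites, n_images = 5, sigma_img = 30, seed = 6)
  cm <- correlation_map(acts, c(100, 100))
  X <- vapply(acts$images, function(m) as.vector(m$values), numeric(length(cm$values)))
  ij <- c(which.min(abs(cm$xs - 100)), which.min(abs(cm$ys - 100)))
  ref <- X[(ij[2] - 1) * length(cm$xs) + ij[1], ]
  for (px in which(cm$defined)[c(3, 17, 40)]) {
    expect_equal(cm$values[px], cor(X[px, ], ref), tolerance = 1e-12)
  }
  expect_equal(cm$values[ij[1], ij[2]], 1, tolerance = 1e-12)
})
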