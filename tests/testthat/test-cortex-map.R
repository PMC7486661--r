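test_that("site_orientation follows the perpendicular-to-dipole convention", {
  expect_equal(site_orientation(c(0, 0), c(1, 0)), 90)
  expect_equal(site_orientation(c(1, 0), c(0, 0)), 90)  # ON/OFF swap: same axis
  expect_equal(site_orientation(c(0, 0), c(1, 1)), 135)
  expect_error(site_orientation(c(1, 1), c(1, 1)), "coincident")
  # vectorized + range contract
  set.seed(1)
  a <- matrix(rnorm(40), ncol = 2); b <- matrix(rnorm(40), ncol = 2)
  th <- site_orientation(a, b)
  expect_true(all(th >= 0 & th < 180))
})

test_that("orientation map smoothing is circular and equivariant", {
  set.seed(3)
  sites <- tibble::tibble(x = runif(80, 0, 300), y = runif(80, 0, 300),
                          theta = runif(80, 0, 180))
  # constant field stays constant
  const <- dplyr::mutate(sites, theta = 30)
  m <- render_orientation_map(const, sigma_img = 36)
  expect_true(all(abs(m$values[m$defined] - 30) < 1e-6))

  # two antipodal orientations at equal distance: vector sum ~ 0, pixel undefined-safe
  two <- tibble::tibble(x = c(-50, 50), y = c(0, 0), theta = c(0, 90))
  m2 <- render_orientation_map(two, sigma_img = 36, pixel_size = 10)
  mid <- c(which.min(abs(m2$xs - 0)), which.min(abs(m2$ys - 0)))
  z <- sum(exp(2i * two$theta * pi / 180) *
             exp(-((two$x)^2 + (two$y)^2) / (2 * 36^2)))
  expect_lt(Mod(z), 1e-6)

  # rotating sites and orientations by 10 degrees rotates the map
  rot <- 10 * pi / 180
  sites_r <- dplyr::mutate(sites,
    x2 = cos(rot) * .data$x - sin(rot) * .data$y,
    y2 = sin(rot) * .data$x + cos(rot) * .data$y,
    theta = (.data$theta + 10) %% 180, x = .data$x2, y = .data$y2)
  m1 <- render_orientation_map(sites, 36, pixel_size = 12)
  mr <- render_orientation_map(sites_r, 36, pixel_size = 12)
  # compare at matched rotated probe points
  probes <- cbind(runif(25, 80, 220), runif(25, 80, 220))
  v1 <- vapply(seq_len(nrow(probes)), function(k) {
    ij <- c(which.min(abs(m1$xs - probes[k, 1])), which.min(abs(m1$ys - probes[k, 2])))
    m1$values[ij[1], ij[2]]
  }, numeric(1))
  pr <- probes %*% t(matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2))
  v2 <- vapply(seq_len(nrow(pr)), function(k) {
    ij <- c(which.min(abs(mr$xs - pr[k, 1])), which.min(abs(mr$ys - pr[k, 2])))
    mr$values[ij[1], ij[2]]
  }, numeric(1))
  dd <- abs(v2 - (v1 + 10)) %% 180
  expect_lt(median(pmin(dd, 180 - dd), na.rm = TRUE), 6)
})

test_that("orientation similarity is the doubled-angle cosine", {
  set.seed(4)
  sites <- tibble::tibble(x = runif(60, 0, 200), y = runif(60, 0, 200),
                          theta = runif(60, 0, 180))
  m <- render_orientation_map(sites, 30)
  s <- orientation_similarity(m, c(100, 100))
  ij <- c(which.min(abs(m$xs - 100)), which.min(abs(m$ys - 100)))
  expect_equal(s$values[ij[1], ij[2]], 1)
  expect_true(all(s$values[s$defined] >= -1 - 1e-12 & s$values[s$defined] <= 1 + 1e-12))
  # antipode and quadrature
  th0 <- m$values[ij[1], ij[2]]
  k <- which(abs(orientation_diff(m$values, th0) - 90) < 2 & m$defined)
  if (length(k)) expect_true(all(s$values[k] < -0.99))
  k45 <- which(abs(orientation_diff(m$values, th0) - 45) < 1 & m$defined)
  if (length(k45)) expect_true(all(abs(s$values[k45]) < 0.06))
})

test_that("map period recovery finds planted stripes and flags degenerate maps", {
  lam <- 150
  grid <- expand.grid(x = seq(0, 600, by = 15), y = seq(0, 600, by = 15))
  sites <- tibble::tibble(x = grid$x, y = grid$y,
                          theta = (180 * grid$x / lam) %% 180)
  per <- estimate_map_period(sites, filter_sizes = c(18, 24, 30, 36, 42),
                             pixel_size = 10)
  expect_equal(per, lam, tolerance = 0.1)
  # invariant to appending one outlier filter size
  per2 <- estimate_map_period(sites, filter_sizes = c(18, 24, 30, 36, 42, 300),
                              pixel_size = 10)
  expect_equal(per2, per, tolerance = 0.02)
  # spatially constant map: no non-DC structure -> error
  flat <- dplyr::mutate(sites, theta = 77)
  expect_error(estimate_map_period(flat, filter_sizes = c(18, 24, 30, 36)),
               "constant")
  # rotation invariance of the period estimate (up to pixel-window effects)
  rot <- 35 * pi / 180
  sites_r <- tibble::tibble(
    x = cos(rot) * sites$x - sin(rot) * sites$y,
    y = sin(rot) * sites$x + cos(rot) * sites$y,
    theta = (sites$theta + 35) %% 180)
  per_r <- estimate_map_period(sites_r, filter_sizes = c(18, 24, 30, 36, 42),
                               pixel_size = 10)
  expect_equal(per_r, lam, tolerance = 0.15)
})
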