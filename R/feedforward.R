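#' Place cortical sampling sites on ON/OFF dipoles
#'
#' Following the statistical wiring model, every pair of *data* ON/OFF RGCs
#' closer than `1.5 * d_off` defines a cortical sampling site at the pair
#' midpoint; the dipole axis seeds the site's preferred orientation (edge
#' orientation perpendicular to the ON->OFF axis). A cell may parent several
#' sites.
#'
#' @param mosaic An `rgc_mosaic`.
#' @return A `cortical_sites` tibble: `site`, `x`, `y`, `parent_on`,
#'   `parent_off` (indices into the ON / OFF data cells), `theta` (degrees in
#'   `[0, 180)`).
#' @export
place_cortical_sites <- function(mosaic) {
  on <- mosaic_positions(mosaic, "on")
  off <- mosaic_positions(mosaic, "off")
  if (nrow(on) < 1L || nrow(off) < 1L) stop("need ON and OFF data cells", call. = FALSE)
  d_off <- mosaic_spacings(mosaic)["d_off"]
  nb <- radius_pairs(on, off, 1.5 * d_off)
  parent_on <- rep(seq_len(nrow(on)), lengths(nb))
  parent_off <- unlist(nb, use.names = FALSE)
  # the radius search is inclusive; the dipole rule is strict (< 1.5 d_off)
  if (length(parent_on)) {
    d <- sqrt(rowSums((on[parent_on, , drop = FALSE] - off[parent_off, , drop = FALSE])^2))
    keep <- d < 1.5 * d_off
    parent_on <- parent_on[keep]; parent_off <- parent_off[keep]
  }
  if (!length(parent_on)) stop("no dipoles", call. = FALSE)
  p_on <- on[parent_on, , drop = FALSE]
  p_off <- off[parent_off, , drop = FALSE]
  sites <- tibble::tibble(
    site = seq_along(parent_on),
    x = (p_on[, 1] + p_off[, 1]) / 2,
    y = (p_on[, 2] + p_off[, 2]) / 2,
    parent_on = parent_on, parent_off = parent_off,
    theta = site_orientation(p_on, p_off)
  )
  structure(sites, class = c("cortical_sites", class(tibble::tibble())),
            d_off = unname(d_off))
}

#' Initialize the RGC-to-V1 feedforward network
#'
#' Weights pool data RGCs of both polarities with an exponential spatial
#' decay, `w_ik = w_init * exp(-|p_i - x_k| / d_ff)`, so that each receptive
#' field subregion is initially dominated by roughly one RGC.
#'
#' @param sites A `cortical_sites` tibble from [place_cortical_sites()].
#' @param mosaic The `rgc_mosaic` the sites were placed on.
#' @param d_ff Spatial decay constant (um): 18 for cat-like, 24 for
#'   monkey-like mosaics.
#' @param w_init Initial weight at zero distance (0.05).
#' @param w_limit Per-connection resource limit used during learning (0.14).
#' @param theta_v1,delta_v1 Sigmoid response threshold and slope.
#' @param retina_v1_ratio Retina-to-V1 magnification (metadata only; the
#'   model's computations are carried out in retinal coordinates).
#' @return An `ff_network` holding the `n_rgc x n_site` weight matrix (ON
#'   rows first, then OFF rows), the site table and response parameters.
#' @export
init_feedforward <- function(sites, mosaic, d_ff = 18, w_init = 0.05,
                             w_limit = 0.14, theta_v1 = 0.5, delta_v1 = 0.15,
                             retina_v1_ratio = 0.75) {
  pos_on <- mosaic_positions(mosaic, "on")
  pos_off <- mosaic_positions(mosaic, "off")
  xy <- cbind(sites$x, sites$y)
  dist_to_sites <- function(p) {
    sqrt(outer(p[, 1], xy[, 1], "-")^2 + outer(p[, 2], xy[, 2], "-")^2)
  }
  W <- w_init * exp(-rbind(dist_to_sites(pos_on), dist_to_sites(pos_off)) / d_ff)
  structure(list(W = W, sites = sites, pos_on = pos_on, pos_off = pos_off,
                 n_on = nrow(pos_on), n_off = nrow(pos_off),
                 d_ff = d_ff, w_init = w_init, w_limit = w_limit,
                 theta_v1 = theta_v1, delta_v1 = delta_v1,
                 retina_v1_ratio = retina_v1_ratio, trained = FALSE),
            class = "ff_network")
}

#' @export
print.ff_network <- function(x, ...) {
  cat(sprintf("<ff_network> %d sites x %d RGCs (%d ON + %d OFF), d_ff = %g um%s\n",
              nrow(x$sites), nrow(x$W), x$n_on, x$n_off, x$d_ff,
              if (x$trained) ", trained" else ""))
  invisible(x)
}

v1_sigmoid <- function(u, theta = 0.5, delta = 0.15) 1 / (1 + exp(-(u - theta) / delta))

#' Sigmoidal V1 response to retinal activation
#'
#' `response_k = sigmoid((u_k - theta_v1) / delta_v1)` with
#' `u_k = sum_i w_ik R_i + extra_input_k`. Feedforward input is the only
#' drive by default; horizontal input or a direct cortical stimulus enters
#' through `extra_input`.
#'
#' @param ff An `ff_network`.
#' @param rgc_activation Either a numeric vector of length `n_on + n_off`
#'   (ON cells first) or an activation matrix `n_rgc x T`.
#' @param extra_input Per-site additional input (scalar, vector, or
#'   `n_site x T` matrix).
#' @return Per-site responses in `[0, 1]` (vector or `n_site x T` matrix).
#' @export
compute_response <- function(ff, rgc_activation, extra_input = 0) {
  u <- crossprod(ff$W, as.matrix(rgc_activation)) + extra_input
  r <- v1_sigmoid(u, ff$theta_v1, ff$delta_v1)
  if (ncol(r) == 1L) drop(r) else r
}

dataset_activation <- function(rec) rbind(rec$A_on, rec$A_off)

#' Develop feedforward weights with the covariance rule
#'
#' For each wave presented, every site samples its peak response (earliest
#' peak on ties) together with the concurrent RGC activations, and updates
#' `dw_ik = eps * R_i(t*) * (R_k(t*) - Rbar_k)`, where `Rbar_k` is the
#' running average of sampled peaks (EMA with time constant `tau` learning
#' steps, initialised at the first sampled peak). Weights are clipped to
#' `[0, w_limit]` after every wave. Wave order is reshuffled each epoch.
#'
#' @param ff An `ff_network`.
#' @param dataset A `wave_dataset`.
#' @param epochs Number of passes over the dataset (15).
#' @param eps Learning rate (0.005).
#' @param tau Learning-threshold time constant in learning steps (15).
#' @param seed Integer seed for the epoch shuffles.
#' @return The trained `ff_network` (with `Rbar` retained).
#' @export
train_feedforward <- function(ff, dataset, epochs = 15, eps = 0.005, tau = 15,
                              seed = 1L) {
  set.seed(seed)
  W <- ff$W
  n_rgc <- nrow(W)
  Rbar <- NULL
  for (e in seq_len(epochs)) {
    for (w in sample(seq_along(dataset$recordings))) {
      A <- dataset_activation(dataset$recordings[[w]])
      if (ncol(A) == 0L) next
      R <- v1_sigmoid(crossprod(W, A), ff$theta_v1, ff$delta_v1)
      tstar <- max.col(R, ties.method = "first")
      peaks <- R[cbind(seq_len(ncol(W)), tstar)]
      if (is.null(Rbar)) Rbar <- peaks
      dev <- peaks - Rbar
      W <- W + A[, tstar, drop = FALSE] * rep(eps * dev, each = n_rgc)
      W[W < 0] <- 0
      W[W > ff$w_limit] <- ff$w_limit
      Rbar <- (1 - 1 / tau) * Rbar + (1 / tau) * peaks
    }
  }
  ff$W <- W
  ff$Rbar <- Rbar
  ff$trained <- TRUE
  ff
}

#' Per-site preferred orientations of a feedforward network
#'
#' Before training, orientations follow the parent dipole geometry; after
#' training, the default derives each site's ON and OFF centers of mass from
#' the learned weights and recomputes the orientation from their axis.
#'
#' @param ff An `ff_network`.
#' @param method `"weights"` (weight-weighted ON/OFF centers of mass) or
#'   `"parents"` (original dipole geometry).
#' @return Numeric vector of orientations in degrees, `[0, 180)`.
#' @export
site_orientations <- function(ff, method = c("auto", "weights", "parents")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (ff$trained) "weights" else "parents"
  if (method == "parents") return(ff$sites$theta)
  W_on <- ff$W[seq_len(ff$n_on), , drop = FALSE]
  W_off <- ff$W[ff$n_on + seq_len(ff$n_off), , drop = FALSE]
  com <- function(Wp, pos) {
    tot <- colSums(Wp)
    cbind(crossprod(Wp, pos[, 1]) / tot, crossprod(Wp, pos[, 2]) / tot)
  }
  c_on <- com(W_on, ff$pos_on)
  c_off <- com(W_off, ff$pos_off)
  d <- c_off - c_on
  # sites whose ON/OFF centers of mass are degenerate (all weights decayed to
  # zero, or coincident centers) keep their parent-dipole orientation
  bad <- !is.finite(d[, 1]) | !is.finite(d[, 2]) | rowSums(d^2) == 0
  theta <- ff$sites$theta
  if (any(!bad))
    theta[!bad] <- site_orientation(c_on[!bad, , drop = FALSE],
                                    c_off[!bad, , drop = FALSE])
  theta
}

#' Feedforward drive matrices for a wave dataset
#'
#' Precomputes, for every wave, the frozen feedforward input
#' `u_k(t) = sum_i w_ik R_i(t)` (an `n_site x T` matrix). These are the
#' inputs to horizontal-network development and are reused across repeated
#' trainings.
#'
#' @param ff A (trained) `ff_network`.
#' @param dataset A `wave_dataset`.
#' @return List of `n_site x T` matrices.
#' @export
ff_drives <- function(ff, dataset) {
  lapply(dataset$recordings, function(rec) {
    unname(crossprod(ff$W, dataset_activation(rec)))
  })
}

#' @export
tidy.ff_network <- function(x, ...) {
  tibble::tibble(
    rgc = rep(seq_len(nrow(x$W)), ncol(x$W)),
    polarity = rep(rep(c("on", "off"), c(x$n_on, x$n_off)), ncol(x$W)),
    site = rep(seq_len(ncol(x$W)), each = nrow(x$W)),
    weight = as.vector(x$W)
  )
}

#' @export
glance.ff_network <- function(x, ...) {
  tibble::tibble(n_sites = ncol(x$W), n_rgc = nrow(x$W), trained = x$trained,
                 mean_weight = mean(x$W), max_weight = max(x$W),
                 frac_at_cap = mean(x$W >= x$w_limit - 1e-12))
}
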