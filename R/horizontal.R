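#' Initialize the V1 horizontal network
#'
#' All-to-all random weights: each off-diagonal entry is proportional to a
#' draw from `N(1, 0.1)` (negative draws clipped to 0), the diagonal is zero,
#' and every row (a cell's outgoing weights) is rescaled to sum to `w_init`.
#'
#' @param n_sites Number of cortical sites.
#' @param seed Integer seed.
#' @param w_init Outgoing weight sum after initialization (0.01).
#' @param w_limit Per-connection resource limit during learning (5e-4).
#' @return An `lhc_network` holding the `n x n` weight matrix `W`
#'   (`W[i, j]` = weight from site i to site j).
#' @export
init_horizontal <- function(n_sites, seed, w_init = 0.01, w_limit = 5e-4) {
  stopifnot(n_sites >= 2)
  set.seed(seed)
  W <- matrix(pmax(stats::rnorm(n_sites^2, 1, 0.1), 0), n_sites, n_sites)
  diag(W) <- 0
  W <- W / rowSums(W) * w_init
  structure(list(W = W, w_init = w_init, w_limit = w_limit,
                 trained = FALSE, finalized = FALSE, Rbar = NULL, seed = seed),
            class = "lhc_network")
}

#' @export
print.lhc_network <- function(x, ...) {
  cat(sprintf("<lhc_network> %d sites%s%s, mean weight %.3g, %.1f%% at cap\n",
              nrow(x$W), if (x$trained) ", trained" else "",
              if (x$finalized) ", finalized" else "",
              mean(x$W), 100 * mean(x$W >= x$w_limit * (1 - 1e-9))))
  invisible(x)
}

#' Develop the horizontal network with wave-evoked responses
#'
#' Feedforward weights are frozen; per wave, responses evolve as
#' `r_t = sigmoid(ff_drive_t + W' r_{t-1})` (one-step-delayed recurrent
#' horizontal input). Each site's peak response over the wave is sampled and
#' the covariance rule applied:
#' `dw_ij = eps * R_i,peak * (R_j,peak - Rbar_j)` with `Rbar` the running
#' average of sampled peaks (EMA, time constant `tau`, initialised at the
#' first sample). Weights are clipped to `[0, w_limit]` and the diagonal
#' pinned to zero after every wave. Wave order is reshuffled each epoch.
#'
#' @param hn An `lhc_network`.
#' @param ff The trained, frozen `ff_network` (used for drive and sigmoid
#'   parameters). May be `NULL` when `drives` is supplied, in which case the
#'   standard sigmoid (theta 0.5, delta 0.15) is used.
#' @param dataset A `wave_dataset`. Ignored when `drives` is supplied.
#' @param epochs Passes over the dataset (30 cat/monkey, 10 mouse).
#' @param eps Learning rate (2e-7 cat/monkey, 2e-5 mouse).
#' @param tau Learning-threshold time constant in learning steps (10).
#' @param seed Integer seed for epoch shuffles.
#' @param drives Optional precomputed [ff_drives()] list (reused across
#'   repeated trainings).
#' @param checkpoint_every Optionally run `checkpoint_fn(hn, n_waves_seen)`
#'   every this many waves.
#' @param checkpoint_fn Callback; its results are returned in
#'   `$checkpoints`.
#' @param stop_fn Optional callback on the list of checkpoints so far;
#'   returning `TRUE` stops training early (used by development-time
#'   experiments).
#' @param precision `"double"` (default) or `"single"`: precision of the
#'   within-wave response recurrence. Weights and updates always accumulate
#'   in double precision; `"single"` roughly halves the run time of long
#'   trainings.
#' @return The trained `lhc_network`.
#' @export
train_horizontal <- function(hn, ff, dataset, epochs = 30, eps = 2e-7,
                             tau = 10, seed = 1L, drives = NULL,
                             checkpoint_every = NULL, checkpoint_fn = NULL,
                             stop_fn = NULL,
                             precision = c("double", "single")) {
  precision <- match.arg(precision)
  if (is.null(drives)) drives <- ff_drives(ff, dataset)
  theta <- if (!is.null(ff)) ff$theta_v1 else 0.5
  delta <- if (!is.null(ff)) ff$delta_v1 else 0.15
  n_waves <- length(drives)
  set.seed(seed)
  order_all <- unlist(lapply(seq_len(epochs), function(e) sample.int(n_waves)))
  W <- hn$W
  Rbar <- hn$Rbar %||% numeric(nrow(W))
  seen <- !is.null(hn$Rbar)
  checkpoints <- list()
  chunk <- checkpoint_every %||% length(order_all)
  done <- 0L
  while (done < length(order_all)) {
    take <- order_all[(done + 1L):min(done + chunk, length(order_all))]
    res <- lhc_train_cpp(W, Rbar, seen, drives, take, eps, tau, hn$w_limit,
                         theta, delta, single = precision == "single")
    W <- res$W; Rbar <- as.numeric(res$Rbar); seen <- res$seen
    done <- done + length(take)
    if (!is.null(checkpoint_fn)) {
      hn_now <- hn; hn_now$W <- W; hn_now$trained <- TRUE
      checkpoints[[length(checkpoints) + 1L]] <-
        list(n_waves = done, value = checkpoint_fn(hn_now, done))
      if (!is.null(stop_fn) && isTRUE(stop_fn(checkpoints))) break
    }
  }
  hn$W <- W
  hn$Rbar <- Rbar
  hn$trained <- TRUE
  if (length(checkpoints)) hn$checkpoints <- checkpoints
  hn
}

#' Normalize incoming connection sums before spontaneous activity
#'
#' Rescales each column (a cell's incoming weights) to sum to `w_final`;
#' within-column ratios are preserved. All-zero columns are left zero with a
#' warning. Idempotent.
#'
#' @param hn A trained `lhc_network`.
#' @param w_final Incoming weight sum (3).
#' @export
finalize_incoming <- function(hn, w_final = 3) {
  cs <- colSums(hn$W)
  zero <- cs == 0
  if (any(zero)) warning(sprintf("%d zero incoming columns left unscaled", sum(zero)))
  cs[zero] <- 1
  hn$W <- sweep(hn$W, 2, cs / w_final, "/")
  hn$w_final <- w_final
  hn$finalized <- TRUE
  hn
}

#' Boolean coupling by thresholding at the resource limit
#'
#' A directed pair is coupled when its weight exceeds
#' `(1 - 1e-5) * w_limit`, i.e. the connection has (numerically) saturated
#' its resource limit.
#'
#' @param hn A trained `lhc_network`.
#' @return Logical `n x n` matrix (diagonal `FALSE`).
#' @export
boolean_coupling <- function(hn) {
  A <- hn$W > (1 - 1e-5) * hn$w_limit
  diag(A) <- FALSE
  A
}

#' @export
tidy.lhc_network <- function(x, ...) {
  n <- nrow(x$W)
  out <- tibble::tibble(
    from = rep(seq_len(n), n),
    to = rep(seq_len(n), each = n),
    weight = as.vector(x$W)
  )
  dplyr::filter(out, .data$from != .data$to)
}

#' @export
glance.lhc_network <- function(x, ...) {
  off <- x$W[row(x$W) != col(x$W)]
  tibble::tibble(n_sites = nrow(x$W), trained = x$trained,
                 finalized = x$finalized, mean_weight = mean(off),
                 frac_at_cap = mean(off >= x$w_limit * (1 - 1e-5)))
}
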