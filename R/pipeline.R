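#' Species presets for the full developmental pipeline
#'
#' Bundles the per-species simulation constants: feedforward spatial decay
#' `d_ff` (18/24/18 um for cat/monkey/mouse), image filter `sigma_img`
#' (36/56 um; none for mouse, which has no columnar map), horizontal
#' learning rate `eps_v1` (2e-7 cat/monkey, 2e-5 mouse), epochs (30/30/10)
#' and the retina-to-V1 magnification ratio (0.75/1.98/0.20).
#'
#' @param species `"cat"`, `"monkey"` or `"mouse"`.
#' @return Named list of preset values.
#' @export
species_preset <- function(species = c("cat", "monkey", "mouse")) {
  species <- tryCatch(match.arg(species), error = function(e)
    stop(sprintf("unknown species '%s'; valid presets: cat, monkey, mouse",
                 species[1]), call. = FALSE))
  switch(species,
    cat = list(species = "cat", d_ff = 18, sigma_img = 36, eps_v1 = 2e-7,
               epochs_v1 = 30L, retina_v1_ratio = 0.75, salt_and_pepper = FALSE),
    monkey = list(species = "monkey", d_ff = 24, sigma_img = 56, eps_v1 = 2e-7,
                  epochs_v1 = 30L, retina_v1_ratio = 1.98, salt_and_pepper = FALSE),
    mouse = list(species = "mouse", d_ff = 18, sigma_img = NA_real_, eps_v1 = 2e-5,
                 epochs_v1 = 10L, retina_v1_ratio = 0.20, salt_and_pepper = TRUE)
  )
}

#' Assemble a full run configuration
#'
#' Every simulation parameter with its default, resolvable against a species
#' preset. Unknown keys raise an error; overrides are honored and echoed in
#' the run manifest.
#'
#' @param species Species preset name.
#' @param ... Overrides of any configuration field.
#' @return An `rw_config` list.
#' @export
rw_config <- function(species = "cat", ...) {
  preset <- species_preset(species)
  cfg <- list(
    species = preset$species,
    # synthetic mosaic
    density_on = 9.64e-5, density_off = 1.253e-4, jitter_fraction = 0.45,
    extent = 670, boundary_radius = 3000,
    # waves
    dt = 0.1, r_on = 400, r_ac = 40, theta_on = 14, theta_ac = 0.5,
    theta_off = -0.2, t_active = 1, delta_c = 0.2, waiting_fraction = 0.8,
    r_init = 400, max_steps = 600L, stage = "III", n_waves = 720L,
    # feedforward
    d_ff = preset$d_ff, w_init_ff = 0.05, w_limit_ff = 0.14,
    theta_v1 = 0.5, delta_v1 = 0.15, tau_ff = 15, eps_ff = 0.005,
    epochs_ff = 15L,
    # horizontal
    w_init_v1 = 0.01, w_limit_v1 = 5e-4, tau_v1 = 10,
    eps_v1 = preset$eps_v1, epochs_v1 = preset$epochs_v1, w_final_v1 = 3,
    # spontaneous activity + imaging
    sigma_img = preset$sigma_img, i_local = 10, sigma_local = 20,
    i_background = 0.01, sigma_background = 30, n_images = 200L,
    # rodent variant
    salt_and_pepper = preset$salt_and_pepper, sparse_fraction = 0.11,
    retina_v1_ratio = preset$retina_v1_ratio,
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop(sprintf("unknown configuration key '%s'", bad[1]), call. = FALSE)
  cfg[names(overrides)] <- overrides
  numeric_pos <- c("density_on", "density_off", "extent", "boundary_radius",
                   "dt", "r_on", "r_ac", "t_active", "d_ff", "w_init_ff",
                   "w_limit_ff", "delta_v1", "tau_ff", "eps_ff", "w_init_v1",
                   "w_limit_v1", "tau_v1", "eps_v1", "w_final_v1", "i_local",
                   "sigma_local", "i_background", "sigma_background",
                   "sparse_fraction")
  for (k in numeric_pos) {
    if (!is.na(cfg[[k]]) && cfg[[k]] <= 0)
      stop(sprintf("configuration key '%s' must be positive", k), call. = FALSE)
  }
  structure(cfg, class = "rw_config")
}

#' Load a run configuration from YAML
#'
#' Unspecified fields fall back to the species preset defaults; the resolved
#' configuration is returned (and echoed into the run manifest by
#' [run_pipeline()]).
#'
#' @param path YAML file; may contain a `species` key plus overrides.
#' @param species Default species when the file names none.
#' @export
load_config <- function(path, species = "cat") {
  raw <- yaml::read_yaml(path) %||% list()
  sp <- raw$species %||% species
  raw$species <- NULL
  do.call(rw_config, c(list(species = sp), raw))
}

derive_seed <- function(master, stage_index) {
  (as.integer(master) * 97L + stage_index * 7919L) %% (.Machine$integer.max - 1L) + 1L
}

#' Run the end-to-end developmental pipeline
#'
#' mosaic -> waves -> feedforward -> horizontal (wave-trained and
#' permuted-control) -> orientation map -> analyses, with per-stage seeds
#' derived from the master seed and all artifacts plus a provenance manifest
#' written to `out_dir`. The mouse (salt-and-pepper) preset subsamples
#' cortical sites sparsely and skips the clustering-index and
#' spontaneous-activity stages, which presuppose a columnar orientation map.
#'
#' @param config An `rw_config`.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main stage objects and summary tibble.
#' @export
run_pipeline <- function(config, out_dir = tempfile("rw_run_"), quiet = FALSE) {
  stopifnot(inherits(config, "rw_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- vapply(1:8, function(i) derive_seed(config$seed, i), integer(1))

  say("stage 1/6: mosaic")
  mosaic <- generate_synthetic_mosaic(config$density_on, config$density_off,
                                      config$jitter_fraction, config$extent,
                                      seed = seeds[1])
  write_mosaic(mosaic, file.path(out_dir, "mosaic.csv"))
  ext <- extend_mosaic(mosaic, config$boundary_radius)

  say("stage 2/6: retinal waves")
  params <- wave_params(dt = config$dt, r_on = config$r_on, r_ac = config$r_ac,
                        theta_on = config$theta_on, theta_ac = config$theta_ac,
                        theta_off = config$theta_off, t_active = config$t_active,
                        delta_c = config$delta_c,
                        waiting_fraction = config$waiting_fraction,
                        r_init = config$r_init, stage = config$stage,
                        max_steps = config$max_steps)
  dataset <- assemble_wave_dataset(ext, params, config$n_waves, seed = seeds[2])
  saveRDS(dataset, file.path(out_dir, "waves.rds"))

  say("stage 3/6: feedforward development")
  sites <- place_cortical_sites(mosaic)
  if (config$salt_and_pepper) {
    set.seed(seeds[3])
    keep <- sort(sample.int(nrow(sites), ceiling(config$sparse_fraction * nrow(sites))))
    sites <- sites[keep, ]
    sites$site <- seq_len(nrow(sites))
  }
  ff <- init_feedforward(sites, mosaic, d_ff = config$d_ff,
                         w_init = config$w_init_ff, w_limit = config$w_limit_ff,
                         theta_v1 = config$theta_v1, delta_v1 = config$delta_v1,
                         retina_v1_ratio = config$retina_v1_ratio)
  ff <- train_feedforward(ff, dataset, epochs = config$epochs_ff,
                          eps = config$eps_ff, tau = config$tau_ff,
                          seed = seeds[4])
  saveRDS(ff, file.path(out_dir, "feedforward.rds"))
  thetas <- site_orientations(ff)

  say("stage 4/6: horizontal development (waves + permuted control)")
  permuted <- permute_activity(dataset, seed = seeds[5])
  hn0 <- init_horizontal(nrow(sites), seed = seeds[6],
                         w_init = config$w_init_v1, w_limit = config$w_limit_v1)
  hn <- train_horizontal(hn0, ff, dataset, epochs = config$epochs_v1,
                         eps = config$eps_v1, tau = config$tau_v1,
                         seed = seeds[7])
  hn_perm <- train_horizontal(hn0, ff, permuted, epochs = config$epochs_v1,
                              eps = config$eps_v1, tau = config$tau_v1,
                              seed = seeds[7])
  saveRDS(list(initial = hn0, developed = hn, permuted = hn_perm),
          file.path(out_dir, "horizontal.rds"))

  say("stage 5/6: trend analyses")
  min_len <- NULL
  if (!config$salt_and_pepper) {
    min_len <- tryCatch(
      estimate_map_period(dplyr::mutate(sites, theta = thetas),
                          filter_sizes = config$sigma_img * c(0.75, 1, 1.25, 1.5, 1.75)),
      error = function(e) NULL)
  }
  trend_of <- function(h) {
    ct <- dplyr::filter(connection_table(h, thetas, sites), .data$weight > 0)
    glance(cuzick_trend(ct$weight, ct$delta_theta, ct$length, min_len))
  }
  trends <- dplyr::bind_rows(
    dplyr::mutate(trend_of(hn), network = "developed"),
    dplyr::mutate(trend_of(hn_perm), network = "permuted"),
    dplyr::mutate(trend_of(hn0), network = "initial"))
  readr::write_csv(trends, file.path(out_dir, "trend_tests.csv"), progress = FALSE)

  result <- list(mosaic = mosaic, dataset = dataset, ff = ff, sites = sites,
                 thetas = thetas, hn = hn, hn_perm = hn_perm, hn0 = hn0,
                 trends = trends, min_length = min_len, out_dir = out_dir)

  if (!config$salt_and_pepper) {
    say("stage 6/6: clustering + spontaneous activity")
    d_off <- mosaic_spacings(mosaic)["d_off"]
    cis <- dplyr::bind_rows(
      dplyr::mutate(clustering_indices(hn, sites, d_off, seed = seeds[8]),
                    network = "developed"),
      dplyr::mutate(clustering_indices(hn_perm, sites, d_off, seed = seeds[8]),
                    network = "permuted"),
      dplyr::mutate(clustering_indices(hn0, sites, d_off, seed = seeds[8]),
                    network = "initial"))
    readr::write_csv(cis, file.path(out_dir, "clustering_indices.csv"),
                     progress = FALSE)
    hn_fin <- finalize_incoming(hn, config$w_final_v1)
    acts <- simulate_spontaneous_set(hn_fin, sites, n_images = config$n_images,
                                     sigma_img = config$sigma_img,
                                     seed = seeds[8],
                                     i_local = config$i_local,
                                     sigma_local = config$sigma_local,
                                     i_background = config$i_background,
                                     sigma_background = config$sigma_background)
    saveRDS(acts, file.path(out_dir, "activity_set.rds"))
    result$cis <- cis
    result$activity <- acts
  } else {
    say("stage 6/6: skipped (salt-and-pepper preset: no columnar map)")
    ct <- connection_table(hn, thetas, sites)
    ca <- cochran_armitage_trend(boolean_coupling(hn)[cbind(ct$from, ct$to)],
                                 ct$delta_theta)
    readr::write_csv(glance(ca), file.path(out_dir, "cochran_armitage.csv"),
                     progress = FALSE)
    result$cochran_armitage <- ca
  }

  manifest <- c(unclass(config),
                list(stage_seeds = as.list(seeds),
                     n_sites = nrow(sites),
                     package_version = as.character(utils::packageVersion("retwave")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %s", out_dir)
  invisible(result)
}
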