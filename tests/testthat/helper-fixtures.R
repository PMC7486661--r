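# Shared small fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A tiny cat-like mosaic + extension usable for fast structural tests.
tiny_mosaic <- function() fixture("tiny_mosaic", function() {
  generate_synthetic_mosaic(density_on = 1.85e-4, density_off = 2.4e-4,
                            jitter_fraction = 0.15, extent = 450, seed = 42)
})

tiny_ext <- function() fixture("tiny_ext", function() {
  extend_mosaic(tiny_mosaic(), boundary_radius = 1200)
})

tiny_params <- function() wave_params()

tiny_history <- function() fixture("tiny_history", function() {
  ext <- tiny_ext()
  simulate_wave(ext, tiny_params(),
                init_center = attr(ext, "center") + c(0.9 * 1200, 0),
                seed = 99, record_states = TRUE)
})

tiny_recording <- function() fixture("tiny_recording", function() {
  classify_direction(postprocess_wave(tiny_history(), tiny_ext(), tiny_params()))
})

tiny_dataset <- function() fixture("tiny_dataset", function() {
  assemble_wave_dataset(tiny_ext(), tiny_params(), n_waves = 24, seed = 7)
})

tiny_sites <- function() fixture("tiny_sites", function() place_cortical_sites(tiny_mosaic()))

tiny_ff <- function() fixture("tiny_ff", function() {
  init_feedforward(tiny_sites(), tiny_mosaic(), d_ff = 18)
})

# ---- shared acceptance-scale fixture -------------------------------------
# One reduced-scale developmental run reused by the acceptance criteria:
# default synthetic cat-like mosaic, 1.5 mm padding, 600 balanced Stage III
# waves, feedforward (15 epochs) then horizontal (30 epochs) development
# plus the permuted-activity control.
acc <- function() fixture("acc", function() {
  m <- generate_synthetic_mosaic(seed = 1)
  ext <- extend_mosaic(m, boundary_radius = 1500)
  params <- wave_params()
  ds <- assemble_wave_dataset(ext, params, n_waves = 600, seed = 7)
  sites <- place_cortical_sites(m)
  ff <- train_feedforward(init_feedforward(sites, m, d_ff = 18), ds, seed = 3)
  drives <- ff_drives(ff, ds)
  hn0 <- init_horizontal(nrow(sites), seed = 11)
  hn <- train_horizontal(hn0, ff, ds, epochs = 30, seed = 12, drives = drives,
                         precision = "single")
  perm <- permute_activity(ds, seed = 5)
  hn_perm <- train_horizontal(hn0, ff, perm, epochs = 30, seed = 12,
                              precision = "single")
  list(m = m, ext = ext, params = params, ds = ds, sites = sites, ff = ff,
       drives = drives, hn0 = hn0, hn = hn, hn_perm = hn_perm,
       thetas = site_orientations(ff),
       d_off = unname(mosaic_spacings(m)["d_off"]))
})

acc_trend <- function(hn, a = acc()) {
  ct <- connection_table(hn, a$thetas, a$sites)
  ct <- ct[ct$weight > 0, ]
  cuzick_trend(ct$weight, ct$delta_theta)
}
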