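# Shared fixtures, generated once per test run (seed fixed at 42).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

fx_config <- function() fixture("cfg", function() synthetic_config(seed = 42))

fx_samples <- function() fixture("samples", function() generate_sites(fx_config()))

fx_met <- function() fixture("met", function() generate_meteorology(fx_config()))

fx_scenes <- function() fixture("scenes", function() generate_scenes(fx_config()))

fx_truth <- function() fixture("truth", function() synthetic_truth(fx_config()))

fx_run <- function() {
  fixture("run", function() {
    cfg <- fx_config()
    suppressMessages(run_pipeline(
      fx_samples(), fx_met(), dry_gaps = cfg$dry_gaps,
      region_sites = cfg$region_sites, scene_set = fx_scenes(), quiet = TRUE
    ))
  })
}

oracle_grid <- function() {
  fixture("oracle", function() {
    path <- system.file("extdata", "carbonate_oracle_grid.csv", package = "wetflux")
    readr::read_csv(path, show_col_types = FALSE)
  })
}

# the annual per-site fluxes (mol m-2 y-1) and regional transports
# (Gg C y-1) of the published field study, used as precomputed inputs to the
# summary operations
published_site_fluxes <- c(1.1, -0.3, -1.6, 0.5, 11.9, 1.4, 13.4, 8.8, 5.1, 11.1, 6.0)
published_region_transports <- c(12.95, 0.21, 0.004, -0.06)
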