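# Shared fixtures: all test imagery is generated in code. Expensive
# cohorts (the acceptance-scale wild-type cohort and the full screen) are
# built once per test run and cached.

.cache <- new.env(parent = emptyenv())

noise_free <- function(cfg) {
  config_update(cfg, psf_sigma_px = 0,
                noise = c(poisson_scale = 0, read_noise_sd = 0))
}

small_wt_config <- function(...) {
  config_update(default_wt_config(), field_size_px = c(512L, 512L),
                n_cells = 25L, ...)
}

# Match measured records to truth cells by nearest centre.
match_truth <- function(tab, truth, max_dist = 6) {
  tr <- truth$cells
  vapply(seq_len(nrow(tab)), function(i) {
    d2 <- (tr$x - tab$x[i])^2 + (tr$y - tab$y[i])^2
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) j else NA_integer_
  }, integer(1))
}

# Analyze one simulated field and append the matched truth columns.
analyze_with_truth <- function(sim, params = analysis_params(),
                               seg = seg_params()) {
  tab <- analyze_field(sim$field, params = params, seg = seg)
  m <- match_truth(tab, sim$truth)
  tab$true_phenotype <- sim$truth$cells$phenotype[m]
  tab$true_age <- sim$truth$cells$age_group[m]
  tab$true_scars <- sim$truth$cells$scar_count[m]
  tab$true_psg <- sim$truth$cells$psg_count[m]
  tab$matched <- !is.na(m)
  tab
}

# Acceptance-scale starved wild-type cohort: 16 default fields (~1600
# cells) through the full pipeline, with matched truth.
wt_cohort <- function() {
  if (!is.null(.cache$cohort)) return(.cache$cohort)
  tabs <- lapply(1:16, function(i) {
    sim <- simulate_field(default_wt_config(), derive_seed(101L, "cohort", i))
    tab <- analyze_with_truth(sim)
    tab$replicate_id <- sprintf("field_%02d", i)
    as.data.frame(tab)
  })
  .cache$cohort <- do.call(rbind, tabs)
  .cache$cohort
}

# Full-size simulated screen: 96 strains x 3 rounds, 3 planted
# nuclear-retention hits.
screen_config <- function() {
  config_update(default_wt_config(), field_size_px = c(640L, 640L),
                n_cells = 40L, channels = c("gfp", "dna"))
}

planted_hits <- c("strain_003", "strain_017", "strain_042")

wt_screen <- function() {
  if (!is.null(.cache$screen)) return(.cache$screen)
  lib <- simulate_strain_library(screen_config(), 96L, planted_hits,
                                 rounds = 3L, seed = 424L)
  .cache$screen <- run_screen(lib)
  .cache$screen
}

# Hand-built single-cell rasters, independent of the package's renderer,
# for feature oracles: a disc cell with optional wall outline, bud-scar
# rings and cytoplasmic Gaussian puncta.
test_cell <- function(size = 96L, r = 25, base = 100, rho = 1,
                      nucleus_r = 10, outline = 0, scars = 0,
                      scar_int = 200, scar_r = 4,
                      puncta = NULL, punctum_amp = 300, punctum_sigma = 3) {
  c0 <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+"))
  cell <- d <= r
  nuc <- d <= nucleus_r
  gfp <- base * cell + base * (rho - 1) * nuc
  if (!is.null(puncta)) {
    for (k in seq_len(nrow(puncta))) {
      pd2 <- outer((seq_len(size) - c0 - puncta[k, 1])^2,
                   (seq_len(size) - c0 - puncta[k, 2])^2, "+")
      gfp <- gfp + punctum_amp * exp(-pd2 / (2 * punctum_sigma^2)) * cell
    }
  }
  cfw <- outline * exp(-(d - r)^2 / 2) * (abs(d - r) <= 3)
  if (scars > 0) {
    angs <- 2 * pi * (seq_len(scars) - 1) / scars
    for (a in angs) {
      sx <- c0 + r * cos(a); sy <- c0 + r * sin(a)
      sd <- sqrt(outer((seq_len(size) - sx)^2, (seq_len(size) - sy)^2, "+"))
      cfw <- cfw + scar_int * exp(-(sd - scar_r)^2 / 2) * (sd <= scar_r + 3)
    }
  }
  list(gfp = gfp, cfw = cfw, cell = cell, nucleus = nuc)
}
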