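#' Phenotype and age-group level sets
#'
#' The four mutually exclusive proteasome localization phenotypes scored per
#' cell, and the three replicative-age groups defined from bud-scar counts.
#'
#' @format Character vectors.
#' @export
PHENOTYPE_LEVELS <- c("NUCLEAR", "PSG", "NUCLEAR_PSG", "EQUAL")

#' @rdname PHENOTYPE_LEVELS
#' @export
AGE_GROUP_LEVELS <- c("V", "YM", "OM")

default_phenotype_prevalence <- function() {
  m <- rbind(
    V  = c(NUCLEAR = 0.02, PSG = 0.65, NUCLEAR_PSG = 0.03, EQUAL = 0.30),
    YM = c(NUCLEAR = 0.03, PSG = 0.60, NUCLEAR_PSG = 0.04, EQUAL = 0.33),
    OM = c(NUCLEAR = 0.12, PSG = 0.30, NUCLEAR_PSG = 0.08, EQUAL = 0.50)
  )
  m
}

#' Build a simulator configuration
#'
#' Collects every parameter of the synthetic starved-yeast field generator:
#' field geometry, per-cell optics, the age-group composition of the
#' culture, the per-age-group phenotype prevalences, bud-scar law, point
#' spread function and camera noise. All lengths are in the units stated;
#' intensities are in arbitrary camera units (ADU).
#'
#' @param field_size_px integer pair, raster size (x, y) in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param n_cells number of cells placed per field.
#' @param cell_radius_um named pair `c(mean=, sd=)` of the cell radius draw
#'   (truncated at mean +/- 2 sd).
#' @param nucleus_fraction nucleus diameter as a fraction of cell diameter.
#' @param age_group_weights probability triple over `c(V, YM, OM)`.
#' @param phenotype_prevalence 3 x 4 matrix (rows `V`, `YM`, `OM`; columns
#'   `NUCLEAR`, `PSG`, `NUCLEAR_PSG`, `EQUAL`) of per-age-group phenotype
#'   probabilities; each row must sum to 1.
#' @param nuclear_enrichment_factor intensity multiplier (rho > 1) applied
#'   inside the nucleus of Nuclear-type cells.
#' @param psg_count_range integer range of punctum counts for PSG-type cells.
#' @param psg_amplitude_factor punctum peak intensity over cytoplasm mean.
#' @param psg_sigma_px Gaussian width of a rendered punctum, pixels.
#' @param scar_count_law named list mapping each age group to the set of
#'   admissible scar counts (drawn uniformly); must respect V = 0 scars,
#'   YM in 1-2, OM > 2.
#' @param scar_ring_radius_px,scar_ring_sigma_px radius and radial Gaussian
#'   width of a rendered bud-scar ring.
#' @param cfw_outline_intensity,cfw_outline_sigma_px amplitude and width of
#'   the Calcofluor White cell-wall outline.
#' @param cfw_scar_intensity peak amplitude of a scar ring in the CFW channel.
#' @param gfp_baseline mean cytoplasmic GFP intensity of a cell.
#' @param dna_intensity nuclear intensity in the DNA (Hoechst) channel.
#' @param cell_margin_px minimum edge-to-edge clearance enforced between
#'   placed cells, so each cell's boundary annulus stays free of neighbours.
#' @param psf_sigma_px Gaussian point-spread blur width; 0 disables blur.
#' @param noise named pair `c(poisson_scale=, read_noise_sd=)`; a
#'   `poisson_scale` of 0 disables shot noise, `read_noise_sd` 0 disables
#'   additive read noise.
#' @param rfp_enabled render the mRFP (new-proteasome) channel?
#' @param rfp_baseline constant mRFP intensity emulating little/no synthesis
#'   of new proteasomes during deep starvation.
#' @param channels which channels to render, subset of
#'   `c("gfp", "dna", "cfw")`; `"rfp"` is appended when `rfp_enabled`.
#' @param strain_label free-form strain annotation carried into metadata.
#'
#' @return A validated object of class `sim_config`.
#' @seealso [default_wt_config()], [simulate_field()]
#' @export
sim_config <- function(field_size_px = c(1024L, 1024L),
                       pixel_size_um = 0.1,
                       n_cells = 100L,
                       cell_radius_um = c(mean = 2.5, sd = 0.4),
                       nucleus_fraction = 0.4,
                       age_group_weights = c(V = 0.45, YM = 0.30, OM = 0.25),
                       phenotype_prevalence = default_phenotype_prevalence(),
                       nuclear_enrichment_factor = 2.5,
                       psg_count_range = c(1L, 3L),
                       psg_amplitude_factor = 4,
                       psg_sigma_px = 3,
                       scar_count_law = list(V = 0L, YM = 1:2, OM = 3:8),
                       scar_ring_radius_px = 4,
                       scar_ring_sigma_px = 1,
                       cfw_outline_intensity = 50,
                       cfw_outline_sigma_px = 1,
                       cfw_scar_intensity = 200,
                       gfp_baseline = 100,
                       dna_intensity = 150,
                       cell_margin_px = 12,
                       psf_sigma_px = 1,
                       noise = c(poisson_scale = 1, read_noise_sd = 2),
                       rfp_enabled = FALSE,
                       rfp_baseline = 5,
                       channels = c("gfp", "dna", "cfw"),
                       strain_label = "WT") {
  cfg <- list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    n_cells = as.integer(n_cells),
    cell_radius_um = cell_radius_um,
    nucleus_fraction = nucleus_fraction,
    age_group_weights = age_group_weights,
    phenotype_prevalence = phenotype_prevalence,
    nuclear_enrichment_factor = nuclear_enrichment_factor,
    psg_count_range = as.integer(psg_count_range),
    psg_amplitude_factor = psg_amplitude_factor,
    psg_sigma_px = psg_sigma_px,
    scar_count_law = scar_count_law,
    scar_ring_radius_px = scar_ring_radius_px,
    scar_ring_sigma_px = scar_ring_sigma_px,
    cfw_outline_intensity = cfw_outline_intensity,
    cfw_outline_sigma_px = cfw_outline_sigma_px,
    cfw_scar_intensity = cfw_scar_intensity,
    gfp_baseline = gfp_baseline,
    dna_intensity = dna_intensity,
    cell_margin_px = cell_margin_px,
    psf_sigma_px = psf_sigma_px,
    noise = noise,
    rfp_enabled = isTRUE(rfp_enabled),
    rfp_baseline = rfp_baseline,
    channels = channels,
    strain_label = strain_label
  )
  if (cfg$rfp_enabled && !("rfp" %in% cfg$channels))
    cfg$channels <- c(cfg$channels, "rfp")
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Update fields of an existing simulator configuration
#'
#' @param config a `sim_config`.
#' @param ... named fields to replace; unknown names are an error.
#' @return the modified, re-validated `sim_config`.
#' @export
config_update <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  new <- list(...)
  unknown <- setdiff(names(new), names(unclass(config)))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  out <- unclass(config)
  for (nm in names(new)) out[[nm]] <- new[[nm]]
  out$field_size_px <- as.integer(out$field_size_px)
  out$n_cells <- as.integer(out$n_cells)
  out$psg_count_range <- as.integer(out$psg_count_range)
  if (isTRUE(out$rfp_enabled) && !("rfp" %in% out$channels))
    out$channels <- c(out$channels, "rfp")
  class(out) <- "sim_config"
  validate_sim_config(out)
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$strain_label, "\n")
  cat("  field:", paste(x$field_size_px, collapse = " x "), "px,",
      x$n_cells, "cells,", x$pixel_size_um, "um/px\n")
  cat("  age weights (V/YM/OM):",
      paste(format(x$age_group_weights), collapse = " / "), "\n")
  cat("  phenotype prevalence:\n")
  print(round(x$phenotype_prevalence, 3))
  cat("  rho =", x$nuclear_enrichment_factor,
      "| PSF sigma =", x$psf_sigma_px, "px",
      "| noise =", paste(x$noise, collapse = "/"), "\n")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$field_size_px) == 2, all(cfg$field_size_px > 0))
  stopifnot(cfg$pixel_size_um > 0, cfg$n_cells >= 0)
  stopifnot(all(cfg$cell_radius_um > 0), cfg$nucleus_fraction > 0,
            cfg$nucleus_fraction < 1)
  w <- cfg$age_group_weights
  if (length(w) != 3 || !identical(names(w), AGE_GROUP_LEVELS))
    stop("age_group_weights must be a named triple over V, YM, OM")
  if (abs(sum(w) - 1) > 1e-9)
    stop("age_group_weights must sum to 1 (got ", sum(w), ")")
  pp <- cfg$phenotype_prevalence
  if (!is.matrix(pp) || !identical(rownames(pp), AGE_GROUP_LEVELS) ||
      !identical(colnames(pp), PHENOTYPE_LEVELS))
    stop("phenotype_prevalence must be a 3x4 matrix with rows V/YM/OM and ",
         "columns NUCLEAR/PSG/NUCLEAR_PSG/EQUAL")
  if (any(pp < 0) || any(abs(rowSums(pp) - 1) > 1e-9))
    stop("each phenotype_prevalence row must be a probability vector ",
         "summing to 1 within 1e-9")
  if (cfg$nuclear_enrichment_factor <= 1)
    stop("nuclear_enrichment_factor (rho) must exceed 1")
  if (cfg$psg_amplitude_factor <= 1)
    stop("psg_amplitude_factor must exceed 1")
  stopifnot(length(cfg$psg_count_range) == 2,
            cfg$psg_count_range[1] >= 1,
            cfg$psg_count_range[2] >= cfg$psg_count_range[1],
            cfg$psg_sigma_px > 0,
            cfg$scar_ring_radius_px > 0, cfg$scar_ring_sigma_px > 0,
            cfg$gfp_baseline > 0, cfg$dna_intensity > 0,
            cfg$cell_margin_px >= 0, cfg$psf_sigma_px >= 0,
            all(cfg$noise >= 0), cfg$rfp_baseline >= 0)
  law <- cfg$scar_count_law
  if (!identical(sort(names(law)), sort(AGE_GROUP_LEVELS)))
    stop("scar_count_law must name V, YM and OM")
  if (!all(law$V == 0L))
    stop("scar_count_law: virgin (V) cells must have 0 bud scars")
  if (!all(law$YM %in% 1:2))
    stop("scar_count_law: young mothers (YM) must have 1-2 bud scars")
  if (!all(law$OM > 2))
    stop("scar_count_law: old mothers (OM) must have more than 2 bud scars")
  bad <- setdiff(cfg$channels, c("gfp", "dna", "cfw", "rfp"))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (!("gfp" %in% cfg$channels)) stop("the gfp channel cannot be disabled")
  invisible(cfg)
}

#' Canonical starved wild-type configuration
#'
#' The default study condition: a starved wild-type culture in which the
#' PSG phenotype is carried by about 65% of virgin cells, 60% of young
#' mothers and 30% of old mothers, with the residual per-age-group mass
#' split over Nuclear, Nuclear+PSG and Equal such that nuclear accumulation
#' increases with replicative age. Deterministic; takes no arguments.
#'
#' @return a `sim_config`.
#' @export
default_wt_config <- function() {
  sim_config(strain_label = "WT")
}

#' Knockout-like phenotype profiles
#'
#' `natB_like_config()` emulates loss of the NatB N-acetyltransferase
#' complex: the Nuclear population is strongly increased while PSG and
#' Nuclear+PSG cells almost disappear. `natC_like_config()` emulates loss
#' of NatC: Nuclear and Nuclear+PSG mass increase at the expense of Equal
#' cells while the PSG class stays at its wild-type prevalence in every age
#' group. `nuclear_retention_config()` is the strong whole-population
#' nuclear-retention profile used for planted screen hits.
#'
#' @return a `sim_config`.
#' @export
natB_like_config <- function() {
  pp <- rbind(
    V  = c(NUCLEAR = 0.22, PSG = 0.02, NUCLEAR_PSG = 0.01, EQUAL = 0.75),
    YM = c(NUCLEAR = 0.28, PSG = 0.02, NUCLEAR_PSG = 0.01, EQUAL = 0.69),
    OM = c(NUCLEAR = 0.40, PSG = 0.02, NUCLEAR_PSG = 0.01, EQUAL = 0.57)
  )
  sim_config(phenotype_prevalence = pp, strain_label = "natB-like")
}

#' @rdname natB_like_config
#' @export
natC_like_config <- function() {
  pp <- rbind(
    V  = c(NUCLEAR = 0.15, PSG = 0.65, NUCLEAR_PSG = 0.12, EQUAL = 0.08),
    YM = c(NUCLEAR = 0.17, PSG = 0.60, NUCLEAR_PSG = 0.13, EQUAL = 0.10),
    OM = c(NUCLEAR = 0.30, PSG = 0.30, NUCLEAR_PSG = 0.20, EQUAL = 0.20)
  )
  sim_config(phenotype_prevalence = pp, strain_label = "natC-like")
}

#' @rdname natB_like_config
#' @export
nuclear_retention_config <- function() {
  pp <- rbind(
    V  = c(NUCLEAR = 0.55, PSG = 0.10, NUCLEAR_PSG = 0.20, EQUAL = 0.15),
    YM = c(NUCLEAR = 0.55, PSG = 0.10, NUCLEAR_PSG = 0.20, EQUAL = 0.15),
    OM = c(NUCLEAR = 0.55, PSG = 0.10, NUCLEAR_PSG = 0.20, EQUAL = 0.15)
  )
  sim_config(phenotype_prevalence = pp, strain_label = "nuclear-retention")
}
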