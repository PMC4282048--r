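# Categorical calls: replicative-age groups from bud-scar counts and the
# four-class localization phenotype from (N:C ratio, punctum count).

#' Phenotype-calling thresholds
#'
#' The manual scoring the calls reproduce had no published numeric cutoff;
#' `r_nuclear` is calibrated so that it clears the Equal-cell ratio noise
#' tail while sitting well below the simulated nuclear enrichment factor.
#' A cell exactly at `r_nuclear` counts as nuclear-enriched (>= rule).
#'
#' @param r_nuclear N:C ratio cutoff for "nuclear enrichment" (> 1).
#' @param psg_min_count minimum punctum count for PSG positivity (>= 1).
#' @return list of class `thresholds`.
#' @export
thresholds <- function(r_nuclear = 1.5, psg_min_count = 1L) {
  stopifnot(r_nuclear > 1, psg_min_count >= 1)
  structure(list(r_nuclear = r_nuclear,
                 psg_min_count = as.integer(psg_min_count)),
            class = "thresholds")
}

#' Assign replicative-age group from a bud-scar count
#'
#' Virgin daughters carry no bud scars (V), young mothers 1-2 (YM) and old
#' mothers more than two (OM). Vectorized and total over non-negative
#' counts.
#'
#' @param scar_count integer vector of bud-scar counts (>= 0).
#' @return character vector over `c("V", "YM", "OM")`.
#' @export
assign_age_group <- function(scar_count) {
  if (any(!is.finite(scar_count)) || any(scar_count < 0) ||
      any(scar_count != floor(scar_count)))
    stop("scar_count must be non-negative integers")
  AGE_GROUP_LEVELS[1L + (scar_count >= 1) + (scar_count >= 3)]
}

#' Classify the proteasome localization phenotype of one cell
#'
#' Two binary axes: nuclear enrichment (`nc_ratio >= r_nuclear`) and PSG
#' positivity (`psg_count >= psg_min_count`). Their conjunction table maps
#' to the four classes: enriched only -> NUCLEAR, puncta only -> PSG,
#' both -> NUCLEAR_PSG, neither -> EQUAL. Deterministic and vectorized.
#'
#' @param nc_ratio positive finite ratio(s).
#' @param psg_count non-negative punctum count(s).
#' @param t a [thresholds()].
#' @return character vector over `PHENOTYPE_LEVELS`.
#' @export
classify_phenotype <- function(nc_ratio, psg_count, t = thresholds()) {
  if (any(!is.finite(nc_ratio)) || any(!is.finite(psg_count)))
    stop("nc_ratio and psg_count must be finite")
  if (any(nc_ratio <= 0)) stop("nc_ratio must be positive")
  nuc <- nc_ratio >= t$r_nuclear
  psg <- psg_count >= t$psg_min_count
  out <- rep("EQUAL", length(nuc))
  out[nuc & !psg] <- "NUCLEAR"
  out[!nuc & psg] <- "PSG"
  out[nuc & psg] <- "NUCLEAR_PSG"
  out
}

#' Per-cell analysis parameters
#'
#' Bundles the feature and calling parameters used by
#' [build_cell_table()] / [analyze_field()].
#'
#' @param spot a [spot_params()].
#' @param scar a [scar_params()].
#' @param thresholds a [thresholds()].
#' @param exclude_puncta exclude detected punctum footprints from the
#'   cytoplasm mean of the N:C ratio? Off by default: the ratio then
#'   matches the plain two-compartment mean quotient.
#' @param measure which optional features to compute; subset of
#'   `c("puncta", "scars", "rfp")`. The N:C ratio is always computed.
#'   Phenotypes are only called when `"puncta"` is measured; age groups
#'   only when `"scars"` is measured and a CFW channel exists.
#' @param cfw_dilate_px dilation of the cell mask used for the total-CFW
#'   summary, so the wall outline and scar rings straddling the boundary
#'   are integrated.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(spot = spot_params(), scar = scar_params(),
                            thresholds = proteoloc::thresholds(),
                            exclude_puncta = FALSE,
                            measure = c("puncta", "scars", "rfp"),
                            cfw_dilate_px = 4) {
  structure(list(spot = spot, scar = scar, thresholds = thresholds,
                 exclude_puncta = isTRUE(exclude_puncta), measure = measure,
                 cfw_dilate_px = cfw_dilate_px),
            class = "analysis_params")
}

crop_pad <- function(params) {
  ceiling(max(params$scar$annulus_width_px / 2 + params$scar$ring_radius_px +
                3 * params$scar$ring_sigma_px,
              3 * params$spot$sigma_px)) + 2L
}

#' Build the per-cell measurement table of one field
#'
#' One record per segmented cell: area, N:C ratio, punctum count, bud-scar
#' count, total and mean CFW, mean mRFP, the derived age group and
#' phenotype call, and QC flags. Feature failures (no nucleus, empty
#' cytoplasm) become QC flags on the affected record; the field is never
#' aborted. QC-flagged cells carry no phenotype or age call. Records are
#' ordered by `cell_id` and the output is deterministic given its inputs.
#'
#' @param field a `field_image`.
#' @param cells a `label_map` of kind `"cell"`.
#' @param nuclei a matching `label_map` of kind `"nucleus"`.
#' @param params an [analysis_params()].
#' @param field_id,strain_id annotations copied into every record
#'   (defaults from the field metadata).
#' @return data.frame of class `cell_table`; detected puncta are attached
#'   as `attr(, "puncta")`.
#' @export
build_cell_table <- function(field, cells, nuclei,
                             params = analysis_params(),
                             field_id = NULL, strain_id = NULL) {
  stopifnot(inherits(field, "field_image"),
            inherits(cells, "label_map"), cells$kind == "cell",
            inherits(nuclei, "label_map"), nuclei$kind == "nucleus")
  gfp <- field$channels$gfp
  if (!identical(dim(gfp), dim(cells$labels)) ||
      !identical(dim(gfp), dim(nuclei$labels)))
    stop("label maps and field rasters must share one shape")
  if (is.null(field_id))
    field_id <- if (!is.null(field$metadata$field_id))
      field$metadata$field_id else NA_character_
  if (is.null(strain_id))
    strain_id <- if (!is.null(field$metadata$strain))
      field$metadata$strain else NA_character_
  cfw <- field$channels$cfw
  rfp <- field$channels$rfp
  do_puncta <- "puncta" %in% params$measure
  do_scars <- "scars" %in% params$measure && !is.null(cfw)
  do_rfp <- "rfp" %in% params$measure && !is.null(rfp)

  idx <- label_indices(cells$labels)
  nidx <- label_indices(nuclei$labels)
  no_nuc_qc <- nuclei$qc$cell_id[nuclei$qc$flag == "no_nucleus"]
  nx <- nrow(gfp); ny <- ncol(gfp)
  pad <- crop_pad(params)
  dil_brush <- EBImage::makeBrush(2L * as.integer(params$cfw_dilate_px) + 1L,
                                  "disc")

  rows <- vector("list", length(idx))
  puncta_out <- list()
  for (k in seq_along(idx)) {
    id <- as.integer(names(idx)[k])
    px <- idx[[k]]
    xi <- (px - 1L) %% nx + 1L
    yi <- (px - 1L) %/% nx + 1L
    x0 <- max(1L, min(xi) - pad); x1 <- min(nx, max(xi) + pad)
    y0 <- max(1L, min(yi) - pad); y1 <- min(ny, max(yi) + pad)
    cmask <- matrix(FALSE, x1 - x0 + 1L, y1 - y0 + 1L)
    cmask[cbind(xi - x0 + 1L, yi - y0 + 1L)] <- TRUE
    nmask <- matrix(FALSE, nrow(cmask), ncol(cmask))
    npx <- nidx[[as.character(id)]]
    if (!is.null(npx)) {
      nxi <- (npx - 1L) %% nx + 1L
      nyi <- (npx - 1L) %/% nx + 1L
      nmask[cbind(nxi - x0 + 1L, nyi - y0 + 1L)] <- TRUE
    }
    gcrop <- gfp[x0:x1, y0:y1, drop = FALSE]
    flags <- character(0)
    if (id %in% no_nuc_qc || !any(nmask)) flags <- c(flags, "no_nucleus")

    ratio <- NA_real_
    psg_n <- NA_integer_
    pt <- NULL
    if (!length(flags)) {
      if (do_puncta) {
        pt <- detect_psg_puncta(gcrop, cmask, nmask, params$spot)
        psg_n <- nrow(pt)
        if (psg_n > 0) {
          pt$x <- pt$x + x0 - 1L; pt$y <- pt$y + y0 - 1L
          pt$cell_id <- id
          puncta_out[[length(puncta_out) + 1L]] <- pt
        }
      }
      excl <- NULL
      if (params$exclude_puncta && !is.null(pt) && nrow(pt) > 0) {
        excl <- matrix(FALSE, nrow(cmask), ncol(cmask))
        rr <- 2 * params$spot$sigma_px
        for (j in seq_len(nrow(pt))) {
          ex <- pt$x[j] - x0 + 1L; ey <- pt$y[j] - y0 + 1L
          xs <- pmax(1L, ex - ceiling(rr)):pmin(nrow(excl), ex + ceiling(rr))
          ys <- pmax(1L, ey - ceiling(rr)):pmin(ncol(excl), ey + ceiling(rr))
          sub <- outer((xs - ex)^2, (ys - ey)^2, "+") <= rr^2
          excl[xs, ys] <- excl[xs, ys] | sub
        }
      }
      ratio <- tryCatch(nc_ratio(gcrop, cmask, nmask, exclude_mask = excl),
                        proteoloc_qc_error = function(e) {
                          flags <<- c(flags, e$flag)
                          NA_real_
                        })
    }
    scar_n <- NA_integer_
    cfw_total <- NA_real_
    cfw_mean <- NA_real_
    if (do_scars) {
      ccrop <- cfw[x0:x1, y0:y1, drop = FALSE]
      scar_n <- count_bud_scars(ccrop, cmask, params$scar)
      dmask <- as_mat(EBImage::dilate(cmask * 1, dil_brush)) > 0
      cfw_total <- sum(ccrop[dmask])
      cfw_mean <- mean(ccrop[dmask])
    }
    rfp_mean <- if (do_rfp)
      mean_channel_intensity(rfp[x0:x1, y0:y1, drop = FALSE], cmask)
    else NA_real_

    ok <- !length(flags)
    age <- if (ok && do_scars) assign_age_group(scar_n) else NA_character_
    phen <- if (ok && do_puncta && is.finite(ratio))
      classify_phenotype(ratio, psg_n, params$thresholds)
    else NA_character_

    rows[[k]] <- data.frame(
      cell_id = id, field_id = field_id, strain_id = strain_id,
      x = mean(xi), y = mean(yi), area_px = length(px),
      nc_ratio = ratio, psg_count = psg_n, scar_count = scar_n,
      cfw_total = cfw_total, cfw_mean = cfw_mean, rfp_mean = rfp_mean,
      age_group = age, phenotype = phen,
      qc_flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(cell_id = integer(0), field_id = character(0),
                  strain_id = character(0), x = numeric(0), y = numeric(0),
                  area_px = integer(0), nc_ratio = numeric(0),
                  psg_count = integer(0), scar_count = integer(0),
                  cfw_total = numeric(0), cfw_mean = numeric(0),
                  rfp_mean = numeric(0), age_group = character(0),
                  phenotype = character(0), qc_flags = character(0))
  tab <- tab[order(tab$cell_id), ]
  rownames(tab) <- NULL
  attr(tab, "puncta") <- if (length(puncta_out)) do.call(rbind, puncta_out)
  else data.frame(x = integer(0), y = integer(0),
                  peak_intensity = numeric(0), response = numeric(0),
                  sigma_est_px = numeric(0), cell_id = integer(0))
  attr(tab, "params") <- params
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Segment and measure one field in a single call
#'
#' Convenience wrapper chaining [segment_cells()], [segment_nuclei()] and
#' [build_cell_table()].
#'
#' @inheritParams build_cell_table
#' @param seg a [seg_params()].
#' @return a `cell_table` (see [build_cell_table()]).
#' @export
analyze_field <- function(field, params = analysis_params(),
                          seg = seg_params(), field_id = NULL,
                          strain_id = NULL) {
  cells <- segment_cells(field, seg)
  nuclei <- segment_nuclei(field, cells, seg)
  build_cell_table(field, cells, nuclei, params = params,
                   field_id = field_id, strain_id = strain_id)
}
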