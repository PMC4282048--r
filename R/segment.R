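# Cell and nucleus segmentation. The whole-cell GFP signal is the primary
# segmentation evidence (every phenotype class has cytoplasmic GFP); the
# DNA channel yields at most one nucleus per cell, relabelled with its
# parent cell id.

#' Segmentation parameters
#'
#' @param smooth_sigma_px Gaussian smoothing applied before thresholding.
#' @param threshold manual intensity threshold; `NULL` uses Otsu's method
#'   on the smoothed raster.
#' @param min_area_px minimum object area kept; `NULL` uses the area of a
#'   1.2 um-radius disc at the field's pixel size.
#' @param watershed_tolerance minimum distance-transform depth separating
#'   two objects before the watershed splits them (px).
#' @param min_snr with the automatic (Otsu) threshold, the foreground must
#'   exceed the background by at least this many background standard
#'   deviations; otherwise the image is treated as cell-free. Guards
#'   against "segmenting" pure noise, where Otsu always finds a split.
#' @param clear_border drop objects touching the image border (their
#'   cytoplasm is truncated, biasing the N:C ratio)?
#' @param require_cells error (rather than return an empty map) when no
#'   foreground is found?
#' @param min_nucleus_area_px smallest DNA component accepted as a nucleus.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma_px = 2,
                       threshold = NULL,
                       min_area_px = NULL,
                       watershed_tolerance = 2,
                       min_snr = 5,
                       clear_border = TRUE,
                       require_cells = FALSE,
                       min_nucleus_area_px = 20) {
  p <- list(smooth_sigma_px = smooth_sigma_px, threshold = threshold,
            min_area_px = min_area_px,
            watershed_tolerance = watershed_tolerance,
            min_snr = min_snr,
            clear_border = clear_border, require_cells = require_cells,
            min_nucleus_area_px = min_nucleus_area_px)
  class(p) <- "seg_params"
  p
}

label_map <- function(labels, kind, params = list(),
                      qc = data.frame(cell_id = integer(0),
                                      flag = character(0))) {
  stopifnot(kind %in% c("cell", "nucleus"))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind, params = params, qc = qc),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map>", x$kind, ":", length(setdiff(unique(as.vector(x$labels)), 0L)),
      "objects on", paste(dim(x$labels), collapse = " x "), "px\n")
  invisible(x)
}

# pixel indices per label id, in one pass
label_indices <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(list())
  split(idx, labels[idx])
}

relabel_sequential <- function(labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(ids)) return(labels)
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- seq_along(ids)
  out <- labels
  pos <- labels > 0L
  out[pos] <- lut[labels[pos] + 1L]
  out
}

#' Segment cells from the GFP channel
#'
#' Smooths the GFP raster, thresholds it (Otsu by default), fills holes,
#' splits touching cells by a distance-transform watershed, and removes
#' objects below the minimum area or touching the image border.
#'
#' @param field a `field_image` with a `gfp` channel.
#' @param params a [seg_params()].
#' @return a `label_map` of kind `"cell"` with objects labelled 1..K.
#' @export
segment_cells <- function(field, params = seg_params()) {
  stopifnot(inherits(field, "field_image"))
  gfp <- field$channels$gfp
  if (is.null(gfp)) stop("field has no gfp channel")
  sm <- if (params$smooth_sigma_px > 0)
    as_mat(EBImage::gblur(gfp, sigma = params$smooth_sigma_px)) else gfp
  thr <- params$threshold
  if (is.null(thr)) {
    mx <- max(sm)
    if (mx <= 0) {
      if (params$require_cells) stop("no cells found: blank image")
      return(label_map(matrix(0L, nrow(gfp), ncol(gfp)), "cell", params))
    }
    thr <- EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
    fg <- sm > thr
    snr <- (mean(sm[fg]) - mean(sm[!fg])) / (stats::sd(sm[!fg]) + 1e-9)
    if (!any(fg) || is.na(snr) || snr < params$min_snr) {
      if (params$require_cells)
        stop("no cells found: foreground indistinguishable from noise")
      return(label_map(matrix(0L, nrow(gfp), ncol(gfp)), "cell", params))
    }
  }
  mask <- sm > thr
  if (!any(mask)) {
    if (params$require_cells) stop("no cells found above threshold")
    return(label_map(matrix(0L, nrow(gfp), ncol(gfp)), "cell", params))
  }
  mask <- as_mat(EBImage::fillHull(EBImage::Image(mask * 1)))
  dm <- EBImage::distmap(mask)
  labels <- as_mat(EBImage::watershed(dm,
                                         tolerance = params$watershed_tolerance,
                                         ext = 1))
  min_area <- params$min_area_px
  if (is.null(min_area))
    min_area <- pi * (1.2 / field$pixel_size_um)^2
  idx <- label_indices(labels)
  nx <- nrow(labels); ny <- ncol(labels)
  drop <- vapply(idx, function(px) {
    if (length(px) < min_area) return(TRUE)
    if (params$clear_border) {
      xi <- (px - 1L) %% nx + 1L
      yi <- (px - 1L) %/% nx + 1L
      if (any(xi == 1L | xi == nx | yi == 1L | yi == ny)) return(TRUE)
    }
    FALSE
  }, logical(1))
  for (id in names(idx)[drop]) labels[idx[[id]]] <- 0L
  labels <- relabel_sequential(labels)
  if (params$require_cells && max(labels) == 0)
    stop("no cells found after filtering")
  label_map(labels, "cell", params)
}

#' Segment nuclei within segmented cells
#'
#' Thresholds the DNA channel (Otsu over the field) and keeps, within each
#' cell footprint, at most the largest connected DNA component above the
#' minimum nucleus area. Each detected nucleus is relabelled with its
#' parent cell id. Cells without a detectable nucleus are listed in the
#' returned map's `qc` table (flag `no_nucleus`), never silently dropped.
#'
#' @param field a `field_image` with a `dna` channel.
#' @param cells a `label_map` of kind `"cell"` over the same raster shape.
#' @param params a [seg_params()].
#' @return a `label_map` of kind `"nucleus"`; nucleus ids equal parent cell
#'   ids, with a `qc` data.frame (cell_id, flag) attached.
#' @export
segment_nuclei <- function(field, cells, params = seg_params()) {
  stopifnot(inherits(field, "field_image"), inherits(cells, "label_map"),
            cells$kind == "cell")
  dna <- field$channels$dna
  if (is.null(dna)) stop("field has no dna channel")
  if (!identical(dim(dna), dim(cells$labels)))
    stop("shape mismatch between field and cell label map")
  mx <- max(dna)
  dmask <- if (mx > 0)
    dna > EBImage::otsu(EBImage::Image(dna / mx), range = c(0, 1)) * mx
  else matrix(FALSE, nrow(dna), ncol(dna))
  nuc <- matrix(0L, nrow(dna), ncol(dna))
  qc_ids <- integer(0)
  idx <- label_indices(cells$labels)
  nx <- nrow(dna)
  for (id_chr in names(idx)) {
    id <- as.integer(id_chr)
    px <- idx[[id_chr]]
    xi <- (px - 1L) %% nx + 1L
    yi <- (px - 1L) %/% nx + 1L
    x0 <- min(xi); x1 <- max(xi); y0 <- min(yi); y1 <- max(yi)
    sub <- matrix(FALSE, x1 - x0 + 1L, y1 - y0 + 1L)
    sub[cbind(xi - x0 + 1L, yi - y0 + 1L)] <- TRUE
    dsub <- dmask[x0:x1, y0:y1, drop = FALSE] & sub
    if (!any(dsub)) { qc_ids <- c(qc_ids, id); next }
    comp <- as_mat(EBImage::bwlabel(dsub * 1))
    sizes <- tabulate(comp[comp > 0])
    best <- which.max(sizes)
    if (sizes[best] < params$min_nucleus_area_px) {
      qc_ids <- c(qc_ids, id); next
    }
    sel <- which(comp == best)
    gx <- (sel - 1L) %% nrow(comp) + x0
    gy <- (sel - 1L) %/% nrow(comp) + y0
    nuc[cbind(gx, gy)] <- id
  }
  qc <- data.frame(cell_id = qc_ids,
                   flag = rep("no_nucleus", length(qc_ids)))
  label_map(nuc, "nucleus", params, qc = qc)
}
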