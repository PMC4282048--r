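# Per-cell measurements: nuclear:cytoplasmic GFP ratio, PSG punctum
# detection (Laplacian-of-Gaussian), bud-scar counting in a boundary
# annulus of the CFW channel, and plain masked channel means.

qc_error <- function(flag, msg) {
  structure(class = c("proteoloc_qc_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), flag = flag))
}

#' Nuclear:cytoplasmic GFP ratio
#'
#' The core per-cell statistic: mean GFP fluorescence over the nucleus mask
#' divided by mean GFP fluorescence over the cytoplasm (cell mask minus
#' nucleus mask). By default the cytoplasm mean includes punctum (PSG)
#' pixels, so a PSG-bearing cell has a slightly depressed ratio; pass
#' `exclude_mask` to remove detected puncta from the cytoplasm.
#'
#' The ratio is invariant under multiplication of the raster by any
#' positive gain.
#'
#' @param gfp intensity raster (matrix).
#' @param cell_mask,nucleus_mask logical matrices; the nucleus must lie
#'   inside the cell.
#' @param exclude_mask optional logical matrix of pixels to drop from the
#'   cytoplasm (for example punctum footprints).
#' @return positive scalar ratio.
#' @export
nc_ratio <- function(gfp, cell_mask, nucleus_mask, exclude_mask = NULL) {
  stopifnot(identical(dim(gfp), dim(cell_mask)),
            identical(dim(gfp), dim(nucleus_mask)))
  cell_mask <- cell_mask > 0
  nucleus_mask <- nucleus_mask > 0
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus_mask must be contained in cell_mask")
  if (!any(nucleus_mask))
    stop(qc_error("no_nucleus", "empty nucleus mask: ratio undefined"))
  cyto <- cell_mask & !nucleus_mask
  if (!is.null(exclude_mask)) cyto <- cyto & !(exclude_mask > 0)
  if (!any(cyto))
    stop(qc_error("empty_cytoplasm", "empty cytoplasm mask: ratio undefined"))
  mean(gfp[nucleus_mask]) / mean(gfp[cyto])
}

#' Punctum (spot) detection parameters
#'
#' @param sigma_px expected punctum Gaussian scale.
#' @param amplitude_factor_min accepted peaks must reach this multiple of
#'   the median cytoplasm intensity.
#' @param min_separation_px minimum distance between accepted maxima.
#' @return list of class `spot_params`.
#' @export
spot_params <- function(sigma_px = 3, amplitude_factor_min = 2,
                        min_separation_px = 6) {
  stopifnot(sigma_px > 0, amplitude_factor_min > 0, min_separation_px > 0)
  structure(list(sigma_px = sigma_px,
                 amplitude_factor_min = amplitude_factor_min,
                 min_separation_px = min_separation_px),
            class = "spot_params")
}

#' Bud-scar counting parameters
#'
#' @param annulus_width_px width of the boundary band searched for scars.
#' @param ring_radius_px radius of the ring template matched against scars.
#' @param ring_sigma_px radial Gaussian width of the template shell
#'   (slightly wider than the rendered shell to absorb PSF blur).
#' @param match_min minimum normalized cross-correlation (in [-1, 1])
#'   between the local CFW patch and the ring template for an accepted
#'   scar. The cell-wall outline correlates at about 0.3, true scar rings
#'   above 0.9, so the default separates them with a wide margin at any
#'   staining intensity.
#' @param peak_factor_min accepted peaks must additionally reach this
#'   multiple of the median smoothed CFW level along the boundary band
#'   (guards against matches in near-dark regions).
#' @param min_separation_px minimum distance between accepted scar peaks.
#' @param max_count saturation cap on the reported count.
#' @return list of class `scar_params`.
#' @export
scar_params <- function(annulus_width_px = 8, ring_radius_px = 4,
                        ring_sigma_px = 1.4, match_min = 0.6,
                        peak_factor_min = 1, min_separation_px = 8,
                        max_count = 12) {
  stopifnot(annulus_width_px > 0, ring_radius_px > 0, ring_sigma_px > 0,
            match_min > 0, match_min < 1, peak_factor_min > 0,
            min_separation_px > 0, max_count >= 1)
  structure(list(annulus_width_px = annulus_width_px,
                 ring_radius_px = ring_radius_px,
                 ring_sigma_px = ring_sigma_px,
                 match_min = match_min,
                 peak_factor_min = peak_factor_min,
                 min_separation_px = min_separation_px,
                 max_count = max_count),
            class = "scar_params")
}

ring_template <- function(r0, sr) {
  half <- ceiling(r0 + 3 * sr)
  d <- -half:half
  D <- sqrt(outer(d^2, d^2, "+"))
  exp(-(D - r0)^2 / (2 * sr^2))
}

# Normalized cross-correlation of img against template K at every pixel
# (Pearson correlation over the sliding kernel window). Flat windows get 0.
ncc_filter <- function(img, K) {
  n <- length(K)
  ones <- matrix(1 / n, nrow(K), ncol(K))
  mu <- as_mat(EBImage::filter2(img, ones, boundary = "replicate"))
  mu2 <- as_mat(EBImage::filter2(img^2, ones, boundary = "replicate"))
  var_i <- pmax(mu2 - mu^2, 0)
  Kc <- K - mean(K)
  num <- as_mat(EBImage::filter2(img, Kc / n, boundary = "replicate"))
  den <- sqrt(var_i * mean(Kc^2))
  out <- num / pmax(den, 1e-9)
  out[den < 1e-6] <- 0
  out
}

log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  d <- -half:half
  D2 <- outer(d^2, d^2, "+")
  k <- (D2 - 2 * sigma^2) / sigma^4 * exp(-D2 / (2 * sigma^2))
  k <- k - mean(k)
  -k   # positive response on bright blobs
}

# Greedy maxima selection: candidates ordered by response, accepted if at
# least min_sep from every already accepted peak.
select_peaks <- function(xs, ys, score, min_sep) {
  ord <- order(-score, xs, ys)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep)) {
      d2 <- (xs[keep] - xs[i])^2 + (ys[keep] - ys[i])^2
      if (min(d2) < min_sep^2) next
    }
    keep <- c(keep, i)
  }
  sort(keep)
}

local_maxima <- function(resp, window_px) {
  sz <- 2L * as.integer(ceiling(window_px / 2)) + 1L
  mx <- as_mat(EBImage::dilate(resp, EBImage::makeBrush(sz, "disc")))
  resp >= mx - 1e-9
}

#' Detect PSG puncta in the cytoplasm of one cell
#'
#' Band-pass (Laplacian-of-Gaussian at `sigma_px`) response within the
#' cytoplasm; local maxima separated by at least `min_separation_px` are
#' kept when their raw peak intensity reaches `amplitude_factor_min` times
#' the median cytoplasm intensity. Maxima inside the nucleus mask are
#' excluded. The accepted count is monotonically non-increasing in
#' `amplitude_factor_min`.
#'
#' @param gfp intensity raster.
#' @param cell_mask,nucleus_mask logical matrices as in [nc_ratio()].
#' @param params a [spot_params()].
#' @return data.frame of puncta: `x`, `y`, `peak_intensity`, `response`,
#'   `sigma_est_px`.
#' @export
detect_psg_puncta <- function(gfp, cell_mask, nucleus_mask,
                              params = spot_params()) {
  stopifnot(identical(dim(gfp), dim(cell_mask)),
            identical(dim(gfp), dim(nucleus_mask)))
  cell_mask <- cell_mask > 0; nucleus_mask <- nucleus_mask > 0
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus_mask must be contained in cell_mask")
  cyto <- cell_mask & !nucleus_mask
  empty <- data.frame(x = integer(0), y = integer(0),
                      peak_intensity = numeric(0), response = numeric(0),
                      sigma_est_px = numeric(0))
  if (!any(cyto)) return(empty)
  resp <- as_mat(EBImage::filter2(gfp, log_kernel(params$sigma_px),
                                     boundary = "replicate"))
  ismax <- local_maxima(resp, params$min_separation_px)
  cand <- which(ismax & cyto & resp > 0)
  if (!length(cand)) return(empty)
  med <- stats::median(gfp[cyto])
  cand <- cand[gfp[cand] >= params$amplitude_factor_min * med]
  if (!length(cand)) return(empty)
  nx <- nrow(gfp)
  xs <- (cand - 1L) %% nx + 1L
  ys <- (cand - 1L) %/% nx + 1L
  keep <- select_peaks(xs, ys, resp[cand], params$min_separation_px)
  data.frame(x = xs[keep], y = ys[keep],
             peak_intensity = gfp[cand][keep],
             response = resp[cand][keep],
             sigma_est_px = params$sigma_px)
}

#' Count bud scars on the cell boundary
#'
#' Matched-filter ring detection: the CFW channel is correlated against a
#' Gaussian-shell ring template (normalized cross-correlation, so the
#' statistic is independent of staining intensity), and local correlation
#' maxima within a boundary annulus of width `annulus_width_px` are
#' accepted when they reach `match_min` and clear a weak intensity gate
#' (`peak_factor_min` times the median smoothed boundary level). The
#' normalized statistic keeps crowded scars countable: unlike an adaptive
#' intensity threshold, it is unaffected by many rings raising the overall
#' boundary brightness. The count saturates at `max_count`.
#'
#' @param cfw Calcofluor White raster.
#' @param cell_mask logical cell footprint (non-empty).
#' @param params a [scar_params()].
#' @return integer scar count.
#' @export
count_bud_scars <- function(cfw, cell_mask, params = scar_params()) {
  stopifnot(identical(dim(cfw), dim(cell_mask)))
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) stop("empty cell mask")
  if (max(cfw) <= 0) return(0L)
  hw <- params$annulus_width_px / 2
  din <- as_mat(EBImage::distmap(cell_mask * 1))
  dout <- as_mat(EBImage::distmap((!cell_mask) * 1))
  band <- (cell_mask & din <= hw) | (!cell_mask & dout <= hw)
  resp <- ncc_filter(cfw, ring_template(params$ring_radius_px,
                                        params$ring_sigma_px))
  sm <- as_mat(EBImage::gblur(cfw, sigma = params$ring_sigma_px))
  # intensity at a ring's centre is a dip; gate on the shell peak instead
  shell_sz <- 2L * as.integer(ceiling(params$ring_radius_px)) + 1L
  shell_max <- as_mat(EBImage::dilate(sm, EBImage::makeBrush(shell_sz, "disc")))
  ismax <- local_maxima(resp, params$min_separation_px)
  thr_int <- params$peak_factor_min * stats::median(sm[band])
  cand <- which(ismax & band & resp >= params$match_min & shell_max >= thr_int)
  if (!length(cand)) return(0L)
  nx <- nrow(cfw)
  xs <- (cand - 1L) %% nx + 1L
  ys <- (cand - 1L) %/% nx + 1L
  keep <- select_peaks(xs, ys, resp[cand], params$min_separation_px)
  min(length(keep), as.integer(params$max_count))
}

#' Mean channel intensity over a mask
#'
#' Used as the per-cell new-synthesis index on the mRFP channel, and for
#' total-CFW style summaries.
#'
#' @param raster intensity matrix.
#' @param mask logical matrix, non-empty.
#' @return arithmetic mean of `raster` over `mask`.
#' @export
mean_channel_intensity <- function(raster, mask) {
  stopifnot(identical(dim(raster), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  mean(raster[mask])
}
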