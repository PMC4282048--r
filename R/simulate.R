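# Field rendering. Rasters are matrices indexed [x, y] (dim1 = x = first
# coordinate), matching EBImage's convention. All intensities are digitized
# to integer 16-bit camera counts (ADU) as the final rendering step, so a
# written TIFF round-trips bit-identically.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Stable 31-bit polynomial string hash, so any single field of a large
#' simulated experiment (for example one strain/round of a screen) can be
#' regenerated without generating the rest.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(as.integer(master)),
                 vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (31 * h + code) %% 2147483647
  as.integer(h)
}

digitize_adu <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  x
}

# Truncated normal radius draw (mean +/- 2 sd), in pixels.
draw_radius_px <- function(n, cfg) {
  m <- cfg$cell_radius_um[["mean"]] / cfg$pixel_size_um
  s <- cfg$cell_radius_um[["sd"]] / cfg$pixel_size_um
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      r <- stats::rnorm(1, m, s)
      if (abs(r - m) <= 2 * s) break
    }
    out[i] <- r
  }
  out
}

place_cells <- function(cfg) {
  n <- cfg$n_cells
  nx <- cfg$field_size_px[1]; ny <- cfg$field_size_px[2]
  if (n == 0)
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      radius_px = numeric(0), a_px = numeric(0),
                      b_px = numeric(0), theta = numeric(0)))
  r <- draw_radius_px(n, cfg)
  q <- stats::runif(n, 0.85, 1.0)          # axis ratio b/a
  a <- r / sqrt(q); b <- r * sqrt(q)
  theta <- stats::runif(n, 0, pi)
  ring_ext <- cfg$scar_ring_radius_px + 3 * cfg$scar_ring_sigma_px
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    edge <- a[i] + ring_ext + 2
    if (2 * edge >= min(nx, ny))
      stop("field too small to contain a cell")
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      cx <- stats::runif(1, edge + 1, nx - edge)
      cy <- stats::runif(1, edge + 1, ny - edge)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        d2 <- (xs[j] - cx)^2 + (ys[j] - cy)^2
        lim <- (pmax(a[j], b[j]) + max(a[i], b[i]) + cfg$cell_margin_px)^2
        ok <- all(d2 >= lim)
      }
      if (ok) { xs[i] <- cx; ys[i] <- cy; placed <- TRUE; break }
    }
    if (!placed)
      stop("cell placement failed: could not place cell ", i, " of ", n,
           " without overlap in 10000 attempts; reduce n_cells or enlarge ",
           "the field")
  }
  data.frame(cell_id = seq_len(n), x = xs, y = ys, radius_px = r,
             a_px = a, b_px = b, theta = theta)
}

sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Draw per-cell ground-truth labels from a configuration
#'
#' Samples age group, bud-scar count, localization phenotype and punctum
#' count for `n` cells under the configured laws, without rendering any
#' image. This is the biological half of [simulate_field()] and is useful
#' for checking the configured marginal laws at large `n`.
#'
#' @param config a [sim_config()].
#' @param n number of cells to draw.
#' @param seed integer seed.
#' @return data.frame with columns `age_group`, `scar_count`, `phenotype`,
#'   `psg_count`.
#' @export
sample_cell_truth <- function(config, n, seed) {
  validate_sim_config(config)
  with_seed(seed, draw_cell_truth(config, n))
}

draw_cell_truth <- function(cfg, n) {
  if (n == 0)
    return(data.frame(age_group = character(0), scar_count = integer(0),
                      phenotype = character(0), psg_count = integer(0)))
  age <- sample(AGE_GROUP_LEVELS, n, replace = TRUE,
                prob = cfg$age_group_weights)
  scar <- vapply(age, function(g) as.integer(sample_one(cfg$scar_count_law[[g]])),
                 integer(1))
  phen <- vapply(age, function(g)
    sample(PHENOTYPE_LEVELS, 1, prob = cfg$phenotype_prevalence[g, ]),
    character(1))
  psg <- ifelse(phen %in% c("PSG", "NUCLEAR_PSG"),
                vapply(seq_len(n), function(i)
                  as.integer(sample_one(seq(cfg$psg_count_range[1],
                                            cfg$psg_count_range[2]))),
                  integer(1)),
                0L)
  data.frame(age_group = age, scar_count = scar, phenotype = phen,
             psg_count = as.integer(psg), row.names = NULL)
}

# Place puncta in the cytoplasmic annulus of one cell; returns x/y offsets
# from the cell centre. Radial band adapts to small cells.
place_puncta <- function(k, r_nuc, min_ax, sigma) {
  lo <- r_nuc + sigma + 2
  hi <- min_ax - sigma - 1
  if (hi <= lo) { lo <- (r_nuc + min_ax) / 2 - 0.5; hi <- lo + 1 }
  px <- numeric(0); py <- numeric(0)
  for (i in seq_len(k)) {
    best <- NULL; best_d <- -Inf
    for (attempt in seq_len(200L)) {
      d <- stats::runif(1, lo, hi)
      ang <- stats::runif(1, 0, 2 * pi)
      cx <- d * cos(ang); cy <- d * sin(ang)
      if (length(px) == 0) { best <- c(cx, cy); break }
      sep <- min(sqrt((px - cx)^2 + (py - cy)^2))
      if (sep >= 10) { best <- c(cx, cy); break }
      if (sep > best_d) { best_d <- sep; best <- c(cx, cy) }
    }
    px <- c(px, best[1]); py <- c(py, best[2])
  }
  cbind(px, py)
}

# Parametric angles for scar rings: evenly spaced around the boundary with
# a random rotation and bounded jitter, so a minimum arc separation (14 px,
# shrunk on small crowded cells) is guaranteed even for 8 scars.
place_scar_angles <- function(k, perimeter) {
  if (k == 0) return(numeric(0))
  arc_sep <- min(14, perimeter / k - 2)
  dt <- 2 * pi * arc_sep / perimeter
  spacing <- 2 * pi / k
  jit <- max(0, (spacing - dt) / 2) * 0.9
  offset <- stats::runif(1, 0, 2 * pi)
  (offset + spacing * (seq_len(k) - 1) +
      stats::runif(k, -jit, jit)) %% (2 * pi)
}

#' Simulate one multi-channel yeast field with ground truth
#'
#' Places non-overlapping elliptical cells by rejection sampling, draws each
#' cell's replicative-age group, bud-scar count and localization phenotype
#' from the configured laws, and renders the channels: GFP (cytoplasmic
#' baseline, multiplied by rho inside the nucleus of Nuclear-type cells,
#' plus Gaussian cytoplasmic puncta for PSG-type cells), DNA (bright
#' nucleus), CFW (cell-wall outline plus one bright ring per bud scar on
#' the boundary) and optionally a constant-baseline mRFP channel. A
#' Gaussian PSF blur, Poisson shot noise and Gaussian read noise are then
#' applied, and the rasters digitized to integer camera counts. The same
#' `(config, seed)` pair always yields bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with elements `field` (a `field_image`: named channel
#'   rasters + pixel size + metadata) and `truth` (a `ground_truth`:
#'   per-cell records, label rasters for cells and nuclei, punctum and
#'   scar-ring centre tables).
#' @export
simulate_field <- function(config, seed) {
  validate_sim_config(config)
  with_seed(seed, {
    cfg <- config
    nx <- cfg$field_size_px[1]; ny <- cfg$field_size_px[2]
    cells <- place_cells(cfg)
    n <- nrow(cells)
    truth <- draw_cell_truth(cfg, n)

    zero <- matrix(0, nx, ny)
    ch <- list()
    for (nm in cfg$channels) ch[[nm]] <- zero
    cell_labels <- matrix(0L, nx, ny)
    nucleus_labels <- matrix(0L, nx, ny)
    psg_centers <- list(); scar_centers <- list()
    rho <- cfg$nuclear_enrichment_factor
    base <- cfg$gfp_baseline
    ring_r <- cfg$scar_ring_radius_px
    ring_s <- cfg$scar_ring_sigma_px
    out_s <- cfg$cfw_outline_sigma_px

    for (i in seq_len(n)) {
      a <- cells$a_px[i]; b <- cells$b_px[i]; th <- cells$theta[i]
      r <- cells$radius_px[i]
      cx <- cells$x[i]; cy <- cells$y[i]
      r_nuc <- cfg$nucleus_fraction * r
      ext <- ceiling(max(a, b) + ring_r + 3 * ring_s + 1)
      x0 <- max(1L, floor(cx - ext)); x1 <- min(nx, ceiling(cx + ext))
      y0 <- max(1L, floor(cy - ext)); y1 <- min(ny, ceiling(cy + ext))
      dx <- (x0:x1) - cx; dy <- (y0:y1) - cy
      DX <- matrix(dx, length(dx), length(dy))
      DY <- matrix(dy, length(dx), length(dy), byrow = TRUE)
      RX <- (DX * cos(th) + DY * sin(th)) / a
      RY <- (-DX * sin(th) + DY * cos(th)) / b
      u <- RX^2 + RY^2
      cmask <- u <= 1
      d2 <- DX^2 + DY^2
      nmask <- d2 <= r_nuc^2

      xi <- x0:x1; yi <- y0:y1
      if ("gfp" %in% cfg$channels) {
        g <- base * cmask
        if (truth$phenotype[i] %in% c("NUCLEAR", "NUCLEAR_PSG"))
          g <- g + base * (rho - 1) * nmask
        if (truth$psg_count[i] > 0) {
          pp <- place_puncta(truth$psg_count[i], r_nuc, min(a, b),
                             cfg$psg_sigma_px)
          amp <- (cfg$psg_amplitude_factor - 1) * base
          for (k in seq_len(nrow(pp))) {
            pd2 <- (DX - pp[k, 1])^2 + (DY - pp[k, 2])^2
            g <- g + amp * exp(-pd2 / (2 * cfg$psg_sigma_px^2)) * cmask
          }
          psg_centers[[length(psg_centers) + 1L]] <-
            data.frame(cell_id = i, x = cx + pp[, 1], y = cy + pp[, 2])
        }
        ch$gfp[xi, yi] <- ch$gfp[xi, yi] + g
      }
      if ("dna" %in% cfg$channels)
        ch$dna[xi, yi] <- ch$dna[xi, yi] + cfg$dna_intensity * nmask
      if ("cfw" %in% cfg$channels) {
        edist <- (sqrt(u) - 1) * r   # approx signed distance to the wall
        w <- cfg$cfw_outline_intensity * exp(-edist^2 / (2 * out_s^2))
        w[abs(edist) > 3 * out_s] <- 0
        if (truth$scar_count[i] > 0) {
          per <- 2 * pi * r
          ts <- place_scar_angles(truth$scar_count[i], per)
          for (t0 in ts) {
            sx <- a * cos(t0) * cos(th) - b * sin(t0) * sin(th)
            sy <- a * cos(t0) * sin(th) + b * sin(t0) * cos(th)
            sd2 <- sqrt((DX - sx)^2 + (DY - sy)^2)
            rng <- sd2 <= ring_r + 3 * ring_s
            w <- w + cfg$cfw_scar_intensity *
              exp(-(sd2 - ring_r)^2 / (2 * ring_s^2)) * rng
            scar_centers[[length(scar_centers) + 1L]] <-
              data.frame(cell_id = i, x = cx + sx, y = cy + sy)
          }
        }
        ch$cfw[xi, yi] <- ch$cfw[xi, yi] + w
      }
      cl <- cell_labels[xi, yi]; cl[cmask] <- i; cell_labels[xi, yi] <- cl
      nl <- nucleus_labels[xi, yi]; nl[nmask] <- i; nucleus_labels[xi, yi] <- nl
    }

    if ("rfp" %in% cfg$channels)
      ch$rfp <- matrix(cfg$rfp_baseline, nx, ny)

    if (cfg$psf_sigma_px > 0)
      for (nm in names(ch))
        ch[[nm]] <- as_mat(EBImage::gblur(ch[[nm]],
                                             sigma = cfg$psf_sigma_px))
    ps <- cfg$noise[["poisson_scale"]]
    rs <- cfg$noise[["read_noise_sd"]]
    for (nm in names(ch)) {
      x <- ch[[nm]]
      if (ps > 0) {
        lam <- pmax(as.vector(x) * ps, 0)
        x <- matrix(stats::rpois(length(lam), lam) / ps, nx, ny)
      }
      if (rs > 0) x <- x + matrix(stats::rnorm(nx * ny, 0, rs), nx, ny)
      ch[[nm]] <- digitize_adu(x)
    }

    field <- field_image(ch, cfg$pixel_size_um,
                         metadata = list(seed = seed,
                                         strain = cfg$strain_label,
                                         n_cells = n))
    truth_cells <- cbind(cells, truth)
    gt <- structure(list(cells = truth_cells,
                         cell_labels = cell_labels,
                         nucleus_labels = nucleus_labels,
                         psg_centers = if (length(psg_centers))
                           do.call(rbind, psg_centers)
                         else data.frame(cell_id = integer(0),
                                         x = numeric(0), y = numeric(0)),
                         scar_centers = if (length(scar_centers))
                           do.call(rbind, scar_centers)
                         else data.frame(cell_id = integer(0),
                                         x = numeric(0), y = numeric(0))),
                    class = "ground_truth")
    list(field = field, truth = gt)
  })
}

#' Construct a multi-channel field image
#'
#' @param channels named list of equally sized non-negative matrices
#'   (subset of gfp, dna, cfw, rfp).
#' @param pixel_size_um physical pixel size.
#' @param metadata free-form provenance list.
#' @return object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size_um, metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop("all channel rasters must share one shape")
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("channel '", nm, "' contains negative or non-finite intensities")
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 metadata = metadata),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<field_image>", paste(d, collapse = " x "), "px,",
      x$pixel_size_um, "um/px; channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a multi-round knockout strain library
#'
#' Builds the manifest of a screen: `n_strains` strains imaged over
#' `rounds` successive rounds, with the strains named in `hit_strains`
#' rendered under a nuclear-retention phenotype profile and all others
#' under `base`. Each (strain, round) field gets its own seed derived
#' deterministically from the master seed, so any single field can be
#' regenerated in isolation.
#'
#' @param base `sim_config` for non-hit strains.
#' @param n_strains number of strains, or a character vector of strain ids.
#' @param hit_strains character vector of strain ids to plant as hits
#'   (must be a subset of the strain ids).
#' @param rounds number of screening rounds (>= 1).
#' @param seed master integer seed.
#' @param hit_config `sim_config` used for hit strains; defaults to
#'   [nuclear_retention_config()] with `base`'s geometry fields.
#' @param materialize if `TRUE`, also render every field (memory-heavy for
#'   large libraries); default is the manifest only.
#' @return object of class `strain_library`: `manifest` data.frame
#'   (strain_id, round, seed, is_hit), configs, master seed, and when
#'   materialized a list `fields` keyed by `"<strain>/<round>"`.
#' @export
simulate_strain_library <- function(base, n_strains, hit_strains = character(0),
                                    rounds = 3L, seed = 1L,
                                    hit_config = NULL,
                                    materialize = FALSE) {
  validate_sim_config(base)
  stopifnot(rounds >= 1)
  ids <- if (is.character(n_strains)) n_strains
         else sprintf("strain_%03d", seq_len(n_strains))
  if (anyDuplicated(ids)) stop("duplicate strain ids")
  if (!all(hit_strains %in% ids))
    stop("hit_strains must be a subset of the strain ids")
  if (is.null(hit_config)) {
    hit_config <- nuclear_retention_config()
    for (nm in c("field_size_px", "n_cells", "cell_radius_um",
                 "pixel_size_um", "channels", "psf_sigma_px", "noise",
                 "cell_margin_px"))
      hit_config[[nm]] <- base[[nm]]
    hit_config <- config_update(hit_config)
  }
  manifest <- expand.grid(strain_id = ids, round = seq_len(rounds),
                          stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$strain_id, manifest$round), ]
  rownames(manifest) <- NULL
  manifest$is_hit <- manifest$strain_id %in% hit_strains
  manifest$seed <- mapply(function(s, r) derive_seed(seed, s, r),
                          manifest$strain_id, manifest$round)
  lib <- structure(list(manifest = manifest, base_config = base,
                        hit_config = hit_config, master_seed = seed,
                        hit_strains = hit_strains),
                   class = "strain_library")
  if (materialize) {
    lib$fields <- lapply(seq_len(nrow(manifest)), function(i)
      library_field(lib, manifest$strain_id[i], manifest$round[i]))
    names(lib$fields) <- paste(manifest$strain_id, manifest$round, sep = "/")
  }
  lib
}

#' Render one field of a simulated strain library
#'
#' @param lib a `strain_library`.
#' @param strain_id,round which field to render.
#' @return as [simulate_field()].
#' @export
library_field <- function(lib, strain_id, round) {
  stopifnot(inherits(lib, "strain_library"))
  row <- lib$manifest[lib$manifest$strain_id == strain_id &
                        lib$manifest$round == round, ]
  if (nrow(row) != 1) stop("no such strain/round in the library manifest")
  cfg <- if (row$is_hit) lib$hit_config else lib$base_config
  cfg$strain_label <- strain_id
  simulate_field(cfg, row$seed)
}

#' @export
print.strain_library <- function(x, ...) {
  cat("<strain_library>", length(unique(x$manifest$strain_id)), "strains x",
      max(x$manifest$round), "rounds;",
      length(x$hit_strains), "planted hits; master seed", x$master_seed, "\n")
  invisible(x)
}
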