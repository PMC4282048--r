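# File formats and the reproducible-run surface. Images travel as 16-bit
# multi-page TIFF (one page per channel) with a JSON sidecar carrying
# channel names, pixel size and provenance; tables as plain CSV with a
# fixed numeric format so reruns are byte-identical.

TIFF_SCALE <- 65535

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write a field image as multi-page TIFF (+ JSON sidecar)
#'
#' One 16-bit page per channel, in the field's channel order. Channel
#' names, pixel size and metadata are written to `<path>.json`. Integer
#' camera counts round-trip bit-identically through [read_field_tiff()].
#'
#' @param field a `field_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(field$channels, function(ch) {
    if (max(ch) > TIFF_SCALE)
      stop("channel exceeds the 16-bit range")
    ch / TIFF_SCALE
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  reduce = FALSE)
  sidecar <- list(channels = names(field$channels),
                  pixel_size_um = field$pixel_size_um,
                  metadata = field$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a field image from a multi-page TIFF
#'
#' Pages are mapped to named channels via the JSON sidecar written by
#' [write_field_tiff()], or via an explicit `channel_map` (a character
#' vector naming the pages in file order), which takes precedence. A
#' missing CFW or RFP channel is allowed; downstream age-group / RFP
#' features are then simply absent.
#'
#' @param path TIFF path (>= 2 pages).
#' @param channel_map optional character vector, one name per page.
#' @return a `field_image`.
#' @export
read_field_tiff <- function(path, channel_map = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("expected a multi-page TIFF with >= 2 channel pages")
  sidecar_path <- paste0(path, ".json")
  pixel_size <- NA_real_
  metadata <- list()
  if (is.null(channel_map)) {
    if (!file.exists(sidecar_path))
      stop("no channel metadata: provide channel_map or the JSON sidecar")
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    channel_map <- sc$channels
    pixel_size <- sc$pixel_size_um
    metadata <- as.list(sc$metadata)
  } else if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    pixel_size <- sc$pixel_size_um
    metadata <- as.list(sc$metadata)
  }
  if (length(channel_map) != length(pages))
    stop("channel_map names ", length(channel_map), " channels but the ",
         "file has ", length(pages), " pages")
  bad <- setdiff(channel_map, c("gfp", "dna", "cfw", "rfp"))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  ch <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * TIFF_SCALE)
  })
  names(ch) <- channel_map
  if (!("cfw" %in% channel_map))
    message("no cfw channel: bud-scar and age-group features will be skipped")
  field_image(ch, pixel_size, metadata)
}

#' Write / read per-cell ground truth as CSV
#'
#' One row per simulated cell: id, centre, radius, age group, scar count,
#' phenotype and punctum count. Label rasters are not serialized.
#'
#' @param truth a `ground_truth` from [simulate_field()].
#' @param path CSV path.
#' @return `path` invisibly (write) / a data.frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- truth$cells
  out <- data.frame(cell_id = df$cell_id,
                    x = fmt_num(df$x, 3), y = fmt_num(df$y, 3),
                    radius_px = fmt_num(df$radius_px, 3),
                    age_group = df$age_group,
                    scar_count = df$scar_count,
                    phenotype = df$phenotype,
                    psg_count = df$psg_count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a per-cell measurement table as CSV
#'
#' Stable documented column order; fractions and ratios with 6 decimals so
#' identical analyses yield byte-identical files.
#'
#' @param tab a `cell_table`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path) {
  out <- data.frame(cell_id = tab$cell_id, field_id = tab$field_id,
                    strain_id = tab$strain_id,
                    x = fmt_num(tab$x, 2), y = fmt_num(tab$y, 2),
                    area_px = tab$area_px,
                    nc_ratio = fmt_num(tab$nc_ratio),
                    psg_count = tab$psg_count,
                    scar_count = tab$scar_count,
                    cfw_total = fmt_num(tab$cfw_total, 1),
                    rfp_mean = fmt_num(tab$rfp_mean, 3),
                    age_group = tab$age_group,
                    phenotype = tab$phenotype,
                    qc_flags = tab$qc_flags)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' All knobs of a reproducible [run_pipeline()] run. Unknown keys passed
#' via `...` are rejected with the offending key named.
#'
#' @param seed master integer seed (mandatory when simulating).
#' @param n_fields number of replicate fields to simulate.
#' @param sim a [sim_config()] used when `input_paths` is `NULL`.
#' @param input_paths optional character vector of TIFF paths to analyze
#'   instead of simulating.
#' @param channel_map optional channel map for the input TIFFs.
#' @param analysis an [analysis_params()].
#' @param seg a [seg_params()].
#' @param gate_fraction if non-`NULL`, also gate the CFW extremes at this
#'   tail fraction and write the gated subsets.
#' @param ... must be empty; catches misspelled keys.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_fields = 3L, sim = default_wt_config(),
                       input_paths = NULL, channel_map = NULL,
                       analysis = analysis_params(), seg = seg_params(),
                       gate_fraction = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown run_config key(s): ",
         paste(names(extra), collapse = ", "))
  structure(list(seed = as.integer(seed), n_fields = as.integer(n_fields),
                 sim = sim, input_paths = input_paths,
                 channel_map = channel_map, analysis = analysis, seg = seg,
                 gate_fraction = gate_fraction),
            class = "run_config")
}

config_echo <- function(config) {
  list(tool = "proteoloc",
       version = as.character(utils::packageVersion("proteoloc")),
       seed = config$seed, n_fields = config$n_fields,
       simulated = is.null(config$input_paths),
       strain = config$sim$strain_label,
       sim = unclass(config$sim),
       thresholds = unclass(config$analysis$thresholds),
       spot = unclass(config$analysis$spot),
       scar = unclass(config$analysis$scar),
       seg = unclass(config$seg),
       gate_fraction = config$gate_fraction)
}

#' Run the full analysis pipeline into an output directory
#'
#' Simulates (or reads) the replicate fields, analyzes each one
#' (segmentation, features, phenotype and age calls), and writes: one
#' per-cell CSV per field, the prevalence-by-age table, the paired
#' age-comparison t-tests, a markdown report, and the effective
#' configuration echo (JSON). All randomness derives from the config seed;
#' rerunning with an identical config reproduces every output
#' byte-identically. Per-field failures are logged and skipped.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list: `cells` (combined table), `prevalence`,
#'   `tests`, `gated` (or `NULL`), `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulate <- is.null(config$input_paths)
  n <- if (simulate) config$n_fields else length(config$input_paths)
  all_tabs <- list()
  for (i in seq_len(n)) {
    fid <- sprintf("field_%02d", i)
    tab <- tryCatch({
      field <- if (simulate)
        simulate_field(config$sim, derive_seed(config$seed, "field", i))$field
      else read_field_tiff(config$input_paths[i], config$channel_map)
      analyze_field(field, params = config$analysis, seg = config$seg,
                    field_id = fid)
    }, error = function(e) {
      message("field ", fid, " failed and was skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(tab)) next
    write_cell_table(tab, file.path(out_dir, paste0("cells_", fid, ".csv")))
    tab$replicate_id <- fid
    all_tabs[[fid]] <- as.data.frame(tab)
  }
  if (!length(all_tabs)) stop("every field failed; nothing to aggregate")
  cells <- do.call(rbind, all_tabs)
  rownames(cells) <- NULL
  prev <- prevalence_table(cells)
  tests <- age_prevalence_tests(prev)
  prev_out <- prev
  prev_out$fraction <- fmt_num(prev_out$fraction)
  utils::write.csv(prev_out, file.path(out_dir, "prevalence.csv"),
                   row.names = FALSE, quote = FALSE)
  tests_out <- tests
  tests_out$t_statistic <- fmt_num(tests_out$t_statistic, 4)
  tests_out$p_two_tailed <- fmt_num(tests_out$p_two_tailed)
  utils::write.csv(tests_out, file.path(out_dir, "t_tests.csv"),
                   row.names = FALSE, quote = FALSE)
  gated <- NULL
  if (!is.null(config$gate_fraction) &&
      any(is.finite(cells$cfw_total))) {
    ok <- cells[is.finite(cells$cfw_total), ]
    gated <- gate_cfw_extremes(ok, fraction = config$gate_fraction)
    write_cell_table(gated$young, file.path(out_dir, "gated_young.csv"))
    write_cell_table(gated$old, file.path(out_dir, "gated_old.csv"))
  }
  writeLines(render_report(prev, tests), file.path(out_dir, "report.md"))
  jsonlite::write_json(config_echo(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cells = cells, prevalence = prev, tests = tests,
                 gated = gated,
                 paths = list.files(out_dir, full.names = TRUE)))
}

# Markdown report: per-age-group phenotype prevalence (mean +/- sd across
# replicates) and the paired-test star annotations.
render_report <- function(prev, tests) {
  lines <- c("# Proteasome localization phenotype report", "")
  lines <- c(lines, "## Prevalence by age group (mean ± sd across replicates)",
             "", "| age group | phenotype | prevalence | n replicates |",
             "|---|---|---|---|")
  for (a in intersect(AGE_GROUP_LEVELS, unique(prev$age_group))) {
    for (ph in PHENOTYPE_LEVELS) {
      f <- prev$fraction[prev$age_group == a & prev$phenotype == ph]
      if (!length(f)) next
      lines <- c(lines, sprintf("| %s | %s | %.3f ± %.3f | %d |",
                                a, ph, mean(f),
                                if (length(f) > 1) stats::sd(f) else 0,
                                length(f)))
    }
  }
  lines <- c(lines, "", "## Paired age-group comparisons (two-tailed t-test)",
             "", "*P < 0.05 is marked `*`, P < 0.01 `**`.*", "",
             "| phenotype | comparison | t | df | p | |", "|---|---|---|---|---|---|")
  if (nrow(tests)) {
    for (i in seq_len(nrow(tests))) {
      lines <- c(lines, sprintf("| %s | %s vs %s | %.3f | %d | %.4f | %s |",
                                tests$phenotype[i], tests$group1[i],
                                tests$group2[i], tests$t_statistic[i],
                                as.integer(tests$degrees_of_freedom[i]),
                                tests$p_two_tailed[i], tests$stars[i]))
    }
  }
  lines
}
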