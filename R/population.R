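# Population-level aggregation: prevalence-by-age tables, paired t-tests
# across replicates, CFW-extreme gating, and robust z-score screen scoring
# with multi-round hit calling.

#' Phenotype prevalence per replicate and age group
#'
#' For each (replicate, age group) stratum, the fraction of cells with each
#' phenotype: the number of cells with the phenotype in that age group
#' divided by the total number of cells in the age group. Strata with zero
#' cells are omitted and listed in `attr(, "omitted")`.
#'
#' @param records data.frame with columns `replicate_id`, `age_group`,
#'   `phenotype` (extra columns ignored). Records with missing calls or
#'   non-empty `qc_flags` are dropped first.
#' @return data.frame (class `prevalence_table`) with columns
#'   `replicate_id`, `age_group`, `phenotype`, `count`, `n_cells`,
#'   `fraction`; the four fractions of each stratum sum to 1.
#' @export
prevalence_table <- function(records) {
  stopifnot(all(c("replicate_id", "age_group", "phenotype") %in%
                  names(records)))
  keep <- !is.na(records$age_group) & !is.na(records$phenotype)
  if ("qc_flags" %in% names(records))
    keep <- keep & (is.na(records$qc_flags) | records$qc_flags == "")
  rec <- records[keep, , drop = FALSE]
  reps <- sort(unique(rec$replicate_id))
  out <- list()
  omitted <- list()
  for (r in reps) {
    sub <- rec[rec$replicate_id == r, ]
    for (a in AGE_GROUP_LEVELS) {
      inA <- sub$age_group == a
      n <- sum(inA)
      if (n == 0) {
        omitted[[length(omitted) + 1L]] <-
          data.frame(replicate_id = r, age_group = a)
        next
      }
      cnt <- table(factor(sub$phenotype[inA], levels = PHENOTYPE_LEVELS))
      out[[length(out) + 1L]] <- data.frame(
        replicate_id = r, age_group = a, phenotype = PHENOTYPE_LEVELS,
        count = as.integer(cnt), n_cells = n,
        fraction = as.numeric(cnt) / n, row.names = NULL)
    }
  }
  tab <- if (length(out)) do.call(rbind, out)
  else data.frame(replicate_id = character(0), age_group = character(0),
                  phenotype = character(0), count = integer(0),
                  n_cells = integer(0), fraction = numeric(0))
  attr(tab, "omitted") <- if (length(omitted)) do.call(rbind, omitted)
  else data.frame(replicate_id = character(0), age_group = character(0))
  class(tab) <- c("prevalence_table", "data.frame")
  tab
}

#' Paired two-tailed Student's t-test
#'
#' Tests whether the mean paired difference of two per-replicate fraction
#' vectors is zero: t = mean(d) / (sd(d)/sqrt(n)) on d = x - y with the
#' sample (n-1) standard deviation, p two-tailed from the t distribution
#' with n-1 degrees of freedom. A zero-variance difference vector is
#' reported with a `degenerate` flag (t = 0, p = 1 when the mean is also
#' zero; p = 0 at the +/-Inf limit otherwise) instead of erroring.
#'
#' @param x,y numeric vectors of equal length n >= 2, paired by replicate.
#' @return list of class `paired_t_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_two_tailed`, `n_pairs`, `mean_difference`,
#'   `flag` (`NA` unless degenerate).
#' @export
paired_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  d <- x - y
  # constant differences (up to floating-point dust) have no t statistic
  if (stats::sd(d) <= 1e-12 * max(abs(mean(d)), 1e-12)) {
    res <- list(t_statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                degrees_of_freedom = n - 1,
                p_two_tailed = if (mean(d) == 0) 1 else 0,
                n_pairs = n, mean_difference = mean(d),
                flag = "degenerate")
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(t_statistic = unname(tt$statistic),
                degrees_of_freedom = unname(tt$parameter),
                p_two_tailed = tt$p.value, n_pairs = n,
                mean_difference = unname(tt$estimate), flag = NA_character_)
  }
  class(res) <- "paired_t_result"
  res
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t-test: t = %.4f, df = %d, p = %.4g %s (n = %d)\n",
              x$t_statistic, as.integer(x$degrees_of_freedom), x$p_two_tailed,
              significance_stars(x$p_two_tailed), x$n_pairs))
  invisible(x)
}

#' Significance stars
#'
#' `"*"` for P < 0.05, `"**"` for P < 0.01, `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Paired age-group comparisons of phenotype prevalence
#'
#' For each phenotype, compares its per-replicate prevalence between every
#' pair of age groups with [paired_t_test()], replicating the
#' prevalence-by-age significance analysis.
#'
#' @param prev a [prevalence_table()].
#' @return data.frame: `phenotype`, `group1`, `group2`, `t_statistic`,
#'   `degrees_of_freedom`, `p_two_tailed`, `stars`, `n_pairs`.
#' @export
age_prevalence_tests <- function(prev) {
  stopifnot(inherits(prev, "prevalence_table") ||
              all(c("replicate_id", "age_group", "phenotype", "fraction")
                  %in% names(prev)))
  pairs <- list(c("V", "YM"), c("V", "OM"), c("YM", "OM"))
  out <- list()
  for (ph in PHENOTYPE_LEVELS) {
    for (pr in pairs) {
      a <- prev[prev$phenotype == ph & prev$age_group == pr[1], ]
      b <- prev[prev$phenotype == ph & prev$age_group == pr[2], ]
      reps <- intersect(a$replicate_id, b$replicate_id)
      if (length(reps) < 2) next
      x <- a$fraction[match(reps, a$replicate_id)]
      y <- b$fraction[match(reps, b$replicate_id)]
      tt <- paired_t_test(x, y)
      out[[length(out) + 1L]] <- data.frame(
        phenotype = ph, group1 = pr[1], group2 = pr[2],
        t_statistic = tt$t_statistic,
        degrees_of_freedom = tt$degrees_of_freedom,
        p_two_tailed = tt$p_two_tailed,
        stars = significance_stars(tt$p_two_tailed),
        n_pairs = tt$n_pairs, row.names = NULL)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(phenotype = character(0), group1 = character(0),
                  group2 = character(0), t_statistic = numeric(0),
                  degrees_of_freedom = numeric(0),
                  p_two_tailed = numeric(0), stars = character(0),
                  n_pairs = integer(0))
}

#' Robust z-score of a strain against controls
#'
#' z = (median strain ratio - median control ratio) /
#' (1.4826 x MAD of the control per-cell ratios). Robust to the skewed,
#' multi-modal per-cell ratio distribution of a mixed phenotype population.
#' Strata below the cell-count floor are flagged, not scored.
#'
#' @param strain_ratios,control_ratios numeric vectors of per-cell N:C
#'   ratios (QC-passing cells of one round).
#' @param min_cells cell-count floor for both vectors.
#' @param summary `"median"` (default) or `"mean"` for the per-strain
#'   location summary; the scale is always the scaled control MAD.
#' @return list: `z`, `strain_median`, `control_median`, `control_mad`,
#'   `n_strain`, `n_control`, `flag` (`NA` or `"too_few_cells"`).
#' @export
screen_score_strain <- function(strain_ratios, control_ratios,
                                min_cells = 20L,
                                summary = c("median", "mean")) {
  summary <- match.arg(summary)
  loc <- if (summary == "median") stats::median else mean
  strain_ratios <- strain_ratios[is.finite(strain_ratios)]
  control_ratios <- control_ratios[is.finite(control_ratios)]
  ns <- length(strain_ratios); nc <- length(control_ratios)
  if (ns < min_cells || nc < min_cells)
    return(list(z = NA_real_, strain_median = NA_real_,
                control_median = NA_real_, control_mad = NA_real_,
                n_strain = ns, n_control = nc, flag = "too_few_cells"))
  ms <- loc(strain_ratios)
  mc <- loc(control_ratios)
  s <- stats::mad(control_ratios)  # 1.4826 * MAD
  list(z = (ms - mc) / s, strain_median = ms, control_median = mc,
       control_mad = s, n_strain = ns, n_control = nc, flag = NA_character_)
}

#' Call screen hits across rounds
#'
#' A strain is a hit iff its z-score reaches `z_threshold` in every
#' required round. Raising the threshold can only remove hits.
#'
#' @param scores data.frame with columns `strain_id`, `round`, `z`.
#' @param z_threshold robust z cutoff (default 2.5).
#' @param rounds_required rounds a hit must clear; default all rounds
#'   present in `scores`.
#' @return sorted character vector of hit strain ids.
#' @export
call_hits <- function(scores, z_threshold = 2.5, rounds_required = NULL) {
  stopifnot(all(c("strain_id", "round", "z") %in% names(scores)))
  if (is.null(rounds_required)) rounds_required <- sort(unique(scores$round))
  hits <- character(0)
  for (s in unique(scores$strain_id)) {
    sub <- scores[scores$strain_id == s & scores$round %in% rounds_required, ]
    if (!setequal(sub$round, rounds_required)) next
    if (all(!is.na(sub$z)) && all(sub$z >= z_threshold))
      hits <- c(hits, s)
  }
  sort(hits)
}

#' Gate the CFW-extreme tails of a cell population
#'
#' Emulates flow sorting of a stained starved culture: the
#' `fraction` of cells with the lowest total CFW signal (young, scar-poor)
#' and the `fraction` with the highest (old, scar-rich) are isolated. Ties
#' are broken by stable record order; each tail holds exactly
#' `floor(fraction * n)` records.
#'
#' @param records data.frame of cell records.
#' @param fraction tail fraction (default 0.025, i.e. 2.5% per tail).
#' @param value_col column holding the per-cell total CFW signal.
#' @return list with data.frames `young` and `old`.
#' @export
gate_cfw_extremes <- function(records, fraction = 0.025,
                              value_col = "cfw_total") {
  stopifnot(fraction > 0, fraction <= 0.5,
            value_col %in% names(records))
  v <- records[[value_col]]
  if (any(!is.finite(v))) stop("non-finite values in ", value_col)
  n <- nrow(records)
  if (n < 1 / fraction)
    stop("need at least 1/fraction = ", ceiling(1 / fraction), " records")
  k <- floor(fraction * n)
  ord <- order(v, seq_len(n))          # stable
  young <- records[ord[seq_len(k)], , drop = FALSE]
  old <- records[ord[seq.int(n - k + 1L, n)], , drop = FALSE]
  rownames(young) <- rownames(old) <- NULL
  list(young = young, old = old)
}

#' Run a simulated multi-round screen
#'
#' Renders and analyzes every (strain, round) field of a
#' [simulate_strain_library()] manifest one at a time, scores each strain
#' per round against control cells with [screen_score_strain()], and calls
#' hits with [call_hits()]. Controls default to the pooled cells of the
#' whole round (the library-as-control convention of high-content screens;
#' robust when hits are rare), or to `control_strains` when given.
#'
#' @param lib a `strain_library`.
#' @param params an [analysis_params()]; the default measures only the
#'   N:C ratio, which is all the screen statistic needs.
#' @param seg a [seg_params()].
#' @param z_threshold,min_cells see [screen_score_strain()], [call_hits()].
#' @param control_strains optional character vector of control strain ids.
#' @param summary per-strain location summary, `"median"` or `"mean"`.
#' @param verbose print per-round progress to stderr?
#' @return list of class `screen_result`: `scores` data.frame (strain_id,
#'   round, n_cells, strain_median, z, flag), `hits`, `z_threshold`.
#' @export
run_screen <- function(lib, params = analysis_params(measure = character(0)),
                       seg = seg_params(), z_threshold = 2.5,
                       min_cells = 20L, control_strains = NULL,
                       summary = c("median", "mean"), verbose = FALSE) {
  summary <- match.arg(summary)
  stopifnot(inherits(lib, "strain_library"))
  man <- lib$manifest
  ratios <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sim <- library_field(lib, man$strain_id[i], man$round[i])
    tab <- analyze_field(sim$field, params = params, seg = seg,
                         strain_id = man$strain_id[i])
    ok <- tab$qc_flags == "" & is.finite(tab$nc_ratio)
    ratios[[i]] <- tab$nc_ratio[ok]
    if (verbose && i %% 25 == 0)
      message("screen: ", i, "/", nrow(man), " fields analyzed")
  }
  rounds <- sort(unique(man$round))
  out <- list()
  for (r in rounds) {
    in_r <- which(man$round == r)
    ctrl_idx <- if (is.null(control_strains)) in_r
    else in_r[man$strain_id[in_r] %in% control_strains]
    ctrl <- unlist(ratios[ctrl_idx], use.names = FALSE)
    for (i in in_r) {
      sc <- screen_score_strain(ratios[[i]], ctrl, min_cells = min_cells,
                                summary = summary)
      out[[length(out) + 1L]] <- data.frame(
        strain_id = man$strain_id[i], round = r,
        n_cells = sc$n_strain, strain_median = sc$strain_median,
        control_median = sc$control_median, z = sc$z,
        flag = if (is.na(sc$flag)) "" else sc$flag, row.names = NULL)
    }
  }
  scores <- do.call(rbind, out)
  scores <- scores[order(scores$strain_id, scores$round), ]
  rownames(scores) <- NULL
  res <- list(scores = scores,
              hits = call_hits(scores, z_threshold = z_threshold),
              z_threshold = z_threshold)
  class(res) <- "screen_result"
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", length(unique(x$scores$strain_id)), "strains,",
      length(unique(x$scores$round)), "rounds; hits at z >=",
      x$z_threshold, ":",
      if (length(x$hits)) paste(x$hits, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
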