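make_records <- function(age, phen, rep_id = "r1") {
  data.frame(replicate_id = rep_id, age_group = age, phenotype = phen,
             qc_flags = "")
}

test_that("prevalence fractions are per-stratum counts over stratum totals", {
  rec <- make_records("OM", c(rep("PSG", 13), rep("EQUAL", 6), "NUCLEAR"))
  tab <- prevalence_table(rec)
  f <- tab$fraction[match(PHENOTYPE_LEVELS, tab$phenotype)]
  expect_equal(f, c(0.05, 0.65, 0.00, 0.30))
  expect_true(all(tab$n_cells == 20))
  # a single cell gives its phenotype fraction 1, the rest 0
  one <- prevalence_table(make_records("V", "NUCLEAR_PSG"))
  expect_equal(sum(one$fraction), 1)
  expect_equal(one$fraction[one$phenotype == "NUCLEAR_PSG"], 1)
})

test_that("every stratum's fractions sum to one and empty strata are reported", {
  set.seed(1)
  rec <- do.call(rbind, lapply(c("r1", "r2", "r3"), function(r)
    make_records(sample(c("V", "YM"), 40, TRUE),
                 sample(PHENOTYPE_LEVELS, 40, TRUE), r)))
  tab <- prevalence_table(rec)
  sums <- tapply(tab$fraction,
                 paste(tab$replicate_id, tab$age_group), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # no OM cells anywhere: three omitted strata
  expect_equal(nrow(attr(tab, "omitted")), 3)
  expect_true(all(attr(tab, "omitted")$age_group == "OM"))
  # QC-flagged records are excluded
  rec$qc_flags[1] <- "no_nucleus"
  tab2 <- prevalence_table(rec)
  expect_equal(sum(tab2$count), nrow(rec) - 1)
})

test_that("prevalence over sampled truth recovers the configured PSG fraction", {
  tr <- sample_cell_truth(default_wt_config(), 2000L, seed = 88L)
  tr$replicate_id <- "r1"
  tr$qc_flags <- ""
  tab <- prevalence_table(tr)
  v <- tab[tab$age_group == "V" & tab$phenotype == "PSG", ]
  se <- sqrt(0.65 * 0.35 / v$n_cells)
  expect_lt(abs(v$fraction - 0.65), 3 * se)
})

test_that("the paired t-test matches its closed form", {
  # d = (0.1, 0.2, 0.3): mean 0.2, sd 0.1 -> t = 0.2/(0.1/sqrt(3))
  res <- paired_t_test(c(1.1, 1.2, 1.3), c(1.0, 1.0, 1.0))
  expect_equal(res$t_statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_identical(res$degrees_of_freedom, 2)
  # closed-form agreement on random paired samples
  set.seed(9)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (sd(x - y) == 0) next
    res <- paired_t_test(x, y)
    d <- x - y
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_ref), n - 1)
    expect_equal(res$t_statistic, t_ref, tolerance = 1e-10)
    expect_equal(res$p_two_tailed, p_ref, tolerance = 1e-10)
    expect_equal(res$degrees_of_freedom, n - 1)
  }
})

test_that("degenerate paired differences are flagged, not mis-scored", {
  x <- c(0.2, 0.4, 0.6)
  same <- paired_t_test(x, x)
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_two_tailed, 1)
  expect_identical(same$flag, "degenerate")
  shifted <- paired_t_test(x + 0.1, x)
  expect_identical(shifted$t_statistic, Inf)
  expect_identical(shifted$p_two_tailed, 0)
  expect_identical(paired_t_test(c(1, 2), c(2, 1))$degrees_of_freedom, 1)
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("significance stars follow the figure-legend convention", {
  expect_identical(significance_stars(c(0.2, 0.049, 0.009)),
                   c("", "*", "**"))
})

test_that("age comparisons are computed per phenotype over matched replicates", {
  prev <- rbind(
    data.frame(replicate_id = rep(c("r1", "r2", "r3"), each = 2),
               age_group = rep(c("V", "OM"), 3), phenotype = "PSG",
               fraction = c(0.66, 0.31, 0.63, 0.28, 0.65, 0.33)))
  tt <- age_prevalence_tests(prev)
  expect_equal(nrow(tt), 1)
  expect_identical(tt$group1, "V")
  expect_identical(tt$group2, "OM")
  expect_identical(tt$stars, "**")
  expect_gt(tt$t_statistic, 10)
})

test_that("robust z-scores behave at the null, under a unit shift, and at the floor", {
  set.seed(31)
  ctrl <- rnorm(200, 1, 0.12)
  null_strain <- rnorm(200, 1, 0.12)
  expect_lt(abs(screen_score_strain(null_strain, ctrl)$z), 0.5)
  # a shift of exactly one scaled control MAD scores z = 1
  shifted <- ctrl + mad(ctrl)
  expect_equal(screen_score_strain(shifted, ctrl)$z, 1, tolerance = 1e-12)
  starving <- screen_score_strain(rnorm(10), ctrl)
  expect_identical(starving$flag, "too_few_cells")
  expect_true(is.na(starving$z))
  # mean summary variant
  expect_equal(screen_score_strain(ctrl + 0.3, ctrl, summary = "mean")$z,
               0.3 / mad(ctrl), tolerance = 1e-12)
})

test_that("hits require clearing the threshold in every round", {
  sc <- data.frame(strain_id = rep(c("a", "b", "c"), each = 3),
                   round = rep(1:3, 3),
                   z = c(3.1, 2.9, 4.0,   3.1, 1.0, 4.0,   2.5, 2.5, 2.5))
  expect_identical(call_hits(sc), c("a", "c"))
  expect_identical(call_hits(sc, z_threshold = 3.0), character(0))
  # monotonicity: raising the threshold never adds hits
  set.seed(4)
  rand <- data.frame(strain_id = rep(sprintf("s%02d", 1:20), each = 3),
                     round = rep(1:3, 20), z = rnorm(60, 1, 1.5))
  ths <- seq(0, 4, by = 0.25)
  hit_sets <- lapply(ths, function(th) call_hits(rand, th))
  for (i in seq_along(ths)[-1])
    expect_true(all(hit_sets[[i]] %in% hit_sets[[i - 1]]))
  # a strain missing a required round is never a hit
  expect_identical(call_hits(sc[-2, ]), "c")
})

test_that("CFW gating returns exact tail counts with stable tie-breaking", {
  set.seed(77)
  rec <- data.frame(cell_id = 1:1000, cfw_total = sample(runif(1000)))
  g <- gate_cfw_extremes(rec, 0.025)
  expect_equal(nrow(g$young), 25)
  expect_equal(nrow(g$old), 25)
  expect_true(max(g$young$cfw_total) <= min(g$old$cfw_total))
  tiny <- data.frame(cell_id = 1:4, cfw_total = c(5, 5, 1, 9))
  h <- gate_cfw_extremes(tiny, 0.5)
  expect_equal(nrow(h$young), 2)
  expect_equal(nrow(h$old), 2)
  expect_equal(length(intersect(h$young$cell_id, h$old$cell_id)), 0)
  # ties broken by record order: first 5 goes young, second goes old
  expect_identical(h$young$cell_id, c(3L, 1L))
  expect_error(gate_cfw_extremes(rec[1:30, ], 0.025), "at least")
})

test_that("small repeated screens recover exactly the planted strains", {
  base <- config_update(default_wt_config(), field_size_px = c(512L, 512L),
                        n_cells = 26L, channels = c("gfp", "dna"))
  fp <- fn <- 0L
  for (rep in 1:3) {
    planted <- sprintf("strain_%03d", c(2, 11))
    lib <- simulate_strain_library(base, 16L, planted, rounds = 3L,
                                   seed = 500L + rep)
    res <- run_screen(lib)
    fp <- fp + length(setdiff(res$hits, planted))
    fn <- fn + length(setdiff(planted, res$hits))
  }
  expect_identical(fp, 0L)
  expect_identical(fn, 0L)
})
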