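test_that("the N:C ratio matches its defining arithmetic exactly", {
  cell <- matrix(TRUE, 20, 20)
  nuc <- matrix(FALSE, 20, 20); nuc[8:12, 8:12] <- TRUE
  expect_identical(nc_ratio(matrix(37.5, 20, 20), cell, nuc), 1)
  two <- matrix(100, 20, 20); two[nuc] <- 200
  expect_identical(nc_ratio(two, cell, nuc), 2)
  # gain invariance under positive rescaling
  g <- matrix(runif(400, 10, 300), 20, 20)
  r1 <- nc_ratio(g, cell, nuc)
  for (k in c(1e-6, 0.37, 4, 1e6))
    expect_equal(nc_ratio(k * g, cell, nuc), r1, tolerance = 1e-12)
})

test_that("undefined ratios raise QC-flagged errors, never a silent 1.0", {
  g <- matrix(100, 20, 20)
  cell <- matrix(TRUE, 20, 20)
  none <- matrix(FALSE, 20, 20)
  err <- tryCatch(nc_ratio(g, cell, none), condition = identity)
  expect_s3_class(err, "proteoloc_qc_error")
  expect_identical(err$flag, "no_nucleus")
  err2 <- tryCatch(nc_ratio(g, cell, cell), condition = identity)
  expect_identical(err2$flag, "empty_cytoplasm")
  # nucleus leaking outside the cell is a caller bug, not a QC case
  out <- none; out[1, 1] <- TRUE
  expect_error(nc_ratio(g, !out, out), "contained")
})

test_that("punctum detection finds planted spots and only planted spots", {
  flat <- test_cell()
  expect_equal(nrow(detect_psg_puncta(flat$gfp, flat$cell, flat$nucleus)), 0)
  planted <- rbind(c(17, 0), c(-12, 10))   # offsets from the cell centre
  two <- test_cell(puncta = planted)
  pt <- detect_psg_puncta(two$gfp, two$cell, two$nucleus)
  expect_equal(nrow(pt), 2)
  ctr <- (96 + 1) / 2
  hits <- vapply(seq_len(2), function(k)
    min(sqrt((pt$x - ctr - planted[k, 1])^2 +
               (pt$y - ctr - planted[k, 2])^2)), numeric(1))
  expect_true(all(hits <= 2))
  # all puncta lie in the cytoplasm
  expect_true(all(two$cell[cbind(pt$x, pt$y)]))
  expect_false(any(two$nucleus[cbind(pt$x, pt$y)]))
})

test_that("a bright spot inside the nucleus is not a punctum", {
  inside <- test_cell(puncta = rbind(c(0, 0)))   # dead centre of the nucleus
  pt <- detect_psg_puncta(inside$gfp, inside$cell, inside$nucleus)
  expect_equal(nrow(pt), 0)
})

test_that("punctum count never increases with a stricter amplitude threshold", {
  set.seed(42)
  cellr <- test_cell(puncta = rbind(c(16, 3), c(-10, -12), c(0, 17)))
  cellr$gfp <- cellr$gfp + matrix(rnorm(length(cellr$gfp), 0, 3),
                                  nrow(cellr$gfp))
  counts <- vapply(c(1.2, 1.5, 2, 2.5, 3, 4, 6), function(a)
    nrow(detect_psg_puncta(cellr$gfp, cellr$cell, cellr$nucleus,
                           spot_params(amplitude_factor_min = a))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("bud-scar counts equal the number of planted rings", {
  virgin <- test_cell(outline = 50)
  expect_identical(count_bud_scars(virgin$cfw, virgin$cell), 0L)
  for (k in c(1L, 4L, 8L)) {
    cellk <- test_cell(outline = 50, scars = k)
    expect_identical(count_bud_scars(cellk$cfw, cellk$cell), k)
  }
  # saturation at the configured cap
  crowded <- test_cell(outline = 50, scars = 8)
  expect_identical(count_bud_scars(crowded$cfw, crowded$cell,
                                   scar_params(max_count = 5)), 5L)
  # a blank CFW channel counts zero
  expect_identical(count_bud_scars(matrix(0, 96, 96), virgin$cell), 0L)
})

test_that("masked channel means reduce to plain arithmetic", {
  r <- matrix(0, 4, 4)
  m <- matrix(FALSE, 4, 4)
  r[1:4] <- 1:4; m[1:4] <- TRUE
  expect_identical(mean_channel_intensity(r, m), 2.5)
  expect_identical(mean_channel_intensity(matrix(0, 4, 4),
                                          matrix(TRUE, 4, 4)), 0)
  b <- matrix(7.25, 9, 9)
  expect_identical(mean_channel_intensity(b, matrix(TRUE, 9, 9)), 7.25)
  expect_error(mean_channel_intensity(r, matrix(FALSE, 4, 4)), "empty")
})
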