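test_that("noise-free fields are segmented into exactly the planted cells", {
  cfg <- noise_free(config_update(small_wt_config(), n_cells = 20L))
  sim <- simulate_field(cfg, 9L)
  cells <- segment_cells(sim$field)
  ids <- setdiff(unique(as.vector(cells$labels)), 0L)
  expect_length(ids, 20)
  expect_identical(sort(ids), 1:20)      # contiguous relabelling
  # each segmented object overlaps its truth mask with Jaccard >= 0.8
  tl <- sim$truth$cell_labels
  for (id in ids) {
    seg <- cells$labels == id
    tid <- as.integer(names(which.max(table(tl[seg & tl > 0]))))
    tru <- tl == tid
    jac <- sum(seg & tru) / sum(seg | tru)
    expect_gte(jac, 0.8)
  }
})

test_that("blank images yield empty maps unless cells are required", {
  blank <- field_image(list(gfp = matrix(0, 64, 64),
                            dna = matrix(0, 64, 64)), 0.1)
  cells <- segment_cells(blank)
  expect_equal(max(cells$labels), 0)
  expect_error(segment_cells(blank, seg_params(require_cells = TRUE)),
               "no cells")
})

test_that("the watershed splits two cells rendered a pixel apart", {
  gfp <- matrix(0, 128, 128)
  d1 <- sqrt(outer((1:128 - 45)^2, (1:128 - 64)^2, "+"))
  d2 <- sqrt(outer((1:128 - 86)^2, (1:128 - 64)^2, "+"))
  gfp[d1 <= 20] <- 100
  gfp[d2 <= 20] <- 100   # edges 1 px apart (centres 41 px, radii 20 + 20)
  f <- field_image(list(gfp = gfp, dna = matrix(0, 128, 128)), 0.1)
  cells <- segment_cells(f)
  expect_equal(max(cells$labels), 2)
})

test_that("nuclei are unique per cell, contained, and share the parent id", {
  cfg <- noise_free(config_update(small_wt_config(), n_cells = 15L))
  sim <- simulate_field(cfg, 14L)
  cells <- segment_cells(sim$field)
  nuclei <- segment_nuclei(sim$field, cells)
  nl <- nuclei$labels; cl <- cells$labels
  found <- setdiff(unique(as.vector(nl)), 0L)
  expect_identical(sort(found), sort(setdiff(unique(as.vector(cl)), 0L)))
  # containment: nucleus pixels carry their parent's cell label
  expect_true(all(cl[nl > 0] == nl[nl > 0]))
  expect_equal(nrow(nuclei$qc), 0)
})

test_that("a cell with no DNA signal lands in the no-nucleus QC list", {
  cfg <- noise_free(config_update(small_wt_config(), n_cells = 10L))
  sim <- simulate_field(cfg, 15L)
  cells <- segment_cells(sim$field)
  # erase the DNA of truth cell 4 inside the matching segmented footprint
  victim <- 4L
  tl <- sim$truth$cell_labels
  sim$field$channels$dna[tl == victim] <- 0
  seg_id <- as.integer(names(which.max(
    table(cells$labels[tl == victim & cells$labels > 0]))))
  nuclei <- segment_nuclei(sim$field, cells)
  expect_true(seg_id %in% nuclei$qc$cell_id)
  expect_true(all(nuclei$qc$flag == "no_nucleus"))
  expect_false(any(nuclei$labels == seg_id))
})

test_that("shape mismatches between field and cell map are rejected", {
  sim <- simulate_field(noise_free(config_update(small_wt_config(),
                                                 n_cells = 5L)), 2L)
  cells <- segment_cells(sim$field)
  shrunk <- field_image(list(gfp = matrix(0, 10, 10),
                             dna = matrix(0, 10, 10)), 0.1)
  expect_error(segment_nuclei(shrunk, cells), "mismatch")
})
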