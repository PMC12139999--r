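test_that("Hamming correction merges distance-1 minor barcodes into their parent", {
  bcs <- c("AACCGGTTA", "AACCGGTTT", "AACCGGAAT", "TTTTTTTTT")
  # minor (5 UMIs) within distance 1 of a 500-UMI parent; distance-2 pair
  # untouched; unrelated barcode untouched
  umi <- matrix(0, 30, 4, dimnames = list(sprintf("c%02d", 1:30), bcs))
  umi[1:5, 1] <- 1        # AACCGGTTA: 5 UMIs
  umi[1:25, 2] <- 20      # AACCGGTTT: 500 UMIs
  umi[6:20, 3] <- 10      # AACCGGAAT: distance 2 from parent
  umi[21:30, 4] <- 10
  ct <- toy_guide_triplet(umi, umi * 3, class = "organoid_bc")
  out <- correct_barcodes(ct, min_umi = 2, min_reads = 2)
  merged <- attr(out, "merged")
  expect_equal(merged$from, "AACCGGTTA")
  expect_equal(merged$into, "AACCGGTTT")
  expect_setequal(out$features$feature_id, bcs[-1])
  # counts summed into the parent
  expect_equal(sum(ct_umi(out, "organoid_bc")[, "AACCGGTTT"]), 505)
})

test_that("barcodes equidistant from two parents stay unmerged and are logged", {
  bcs <- c("AAAA", "AAAT", "AATT")
  umi <- matrix(0, 20, 3, dimnames = list(sprintf("c%02d", 1:20), bcs))
  umi[1:9, 1] <- 30       # parent 1
  umi[10, 2] <- 4         # distance 1 from both parents
  umi[11:20, 3] <- 30     # parent 2
  ct <- toy_guide_triplet(umi, umi * 3, class = "organoid_bc")
  out <- correct_barcodes(ct, min_umi = 2, min_reads = 2)
  expect_identical(attr(out, "ambiguous"), "AAAT")
  expect_setequal(out$features$feature_id, bcs)
})

test_that("barcodes below both count floors are removed before correction", {
  bcs <- c("AAAA", "CCCC")
  umi <- matrix(0, 10, 2, dimnames = list(sprintf("c%02d", 1:10), bcs))
  umi[1:5, 1] <- 30
  umi[6, 2] <- 3          # 3 UMIs, 9 reads: below both floors
  ct <- toy_guide_triplet(umi, umi * 3, class = "organoid_bc")
  out <- correct_barcodes(ct, min_umi = 10, min_reads = 10)
  expect_identical(out$features$feature_id, "AAAA")
  expect_error(correct_barcodes(toy_guide_triplet(
    matrix(1, 2, 2, dimnames = list(c("a", "b"), c("AA", "CCC"))),
    class = "organoid_bc"), 0, 0), "same length")
})

test_that("barcode-to-cell assignment honours its three thresholds", {
  bcs <- random_bc(3, seed = 2)
  umi <- matrix(0, 4, 3, dimnames = list(paste0("c", 1:4), bcs))
  reads <- umi
  # bc1 total reads exactly 2^15; bc2 one short; bc3 large
  umi[, 1] <- c(20, 10, 9, 9); reads[, 1] <- c(2^15 - 39, 10, 20, 9)
  umi[, 2] <- c(5, 1, 0, 0);   reads[, 2] <- c(2^15 - 2, 1, 0, 0)
  umi[, 3] <- c(0, 20, 0, 9);  reads[, 3] <- c(0, 2^15, 0, 2^15)
  ct <- toy_guide_triplet(umi, reads, class = "organoid_bc")
  asg <- assign_bcs_to_cells(ct, min_log2_reads = 15, min_umi = 10,
                             min_prop = 1 / 3)
  expect_setequal(attr(asg, "selected_bcs"), bcs[c(1, 3)])  # 2^15-1 excluded
  # cell1: bc1 umi 20, prop 1 -> assigned
  expect_true(any(asg$cell_id == "c1" & asg$bc == bcs[1]))
  # cell2: bc1 10/30 = 1/3 >= min_prop -> assigned; bc3 20/30 assigned
  expect_true(any(asg$cell_id == "c2" & asg$bc == bcs[1]))
  expect_true(any(asg$cell_id == "c2" & asg$bc == bcs[3]))
  # cell3 and cell4 fail the UMI floor (9 < 10)
  expect_false(any(asg$cell_id %in% c("c3", "c4")))
})

test_that("co-occurring barcodes merge and disjoint ones do not", {
  bcs <- random_bc(4, seed = 3)
  n <- 120
  umi <- matrix(0, n, 4, dimnames = list(sprintf("c%03d", 1:n), bcs))
  umi[1:40, 1] <- 20; umi[1:40, 2] <- 10       # perfectly co-occurring pair
  umi[41:80, 3] <- 20                           # disjoint
  umi[81:120, 4] <- 20
  umi[81, 3] <- 15                              # one genuine doublet cell
  ct <- toy_guide_triplet(umi, umi * 2000, class = "organoid_bc")
  asg <- assign_bcs_to_cells(ct, min_log2_reads = 10, min_umi = 10,
                             min_prop = 0.3)
  mg <- merge_correlated_bcs(ct, asg, r_threshold = 0.1)
  grp <- stats::setNames(mg$groups$group_id, mg$groups$bc)
  expect_identical(unname(grp[bcs[1]]), unname(grp[bcs[2]]))
  expect_false(grp[bcs[3]] == grp[bcs[4]])
  # r = 1 for the co-occurring pair, negative for disjoint ones
  expect_gt(mg$correlations[bcs[1], bcs[2]], 0.99)
  expect_lt(mg$correlations[bcs[3], bcs[4]], 0)
  # the doublet cell (bc3+bc4, r <= 0.1) is excluded from grouping
  doublet <- mg$cells$group_id[mg$cells$cell_id == "c081"]
  expect_true(is.na(doublet))
})

test_that("clonotype calling drops undersized groups at the printed boundary", {
  bcs <- random_bc(2, seed = 4)
  umi <- matrix(0, 99, 2, dimnames = list(sprintf("c%03d", 1:99), bcs))
  umi[1:49, 1] <- 20   # 49 cells: dropped
  umi[50:99, 2] <- 20  # 50 cells: kept
  ct <- toy_guide_triplet(umi, umi * 2000, class = "organoid_bc")
  asg <- assign_bcs_to_cells(ct, min_log2_reads = 10)
  mg <- merge_correlated_bcs(ct, asg)
  map <- call_clonotypes(mg, min_cells = 50)
  expect_equal(nrow(map), 1)
  expect_identical(map$bcs[[1]], bcs[2])
  st <- attr(map, "cells")
  expect_equal(sum(st$status == "too_small"), 49)
})

test_that("the 26-barcode worked example yields 20 clonotypes", {
  ct <- bc26_fixture()
  res <- run_clonotype_pipeline(ct, min_log2_reads = 15, min_cells = 50,
                                guide_calls = FALSE)
  expect_equal(nrow(res$map), 20)
  # the four co-occurring pairs each collapse into one clonotype
  expect_equal(sum(lengths(res$map$bcs) == 2), 4)
  expect_equal(sum(lengths(res$map$bcs) == 1), 16)
})

test_that("guide assignment to clonotypes follows the 70% / top-two rule", {
  # three clonotypes of 12 cells; per-cell guide proportions engineered
  guides <- c("gA", "gB", "gC")
  cells <- sprintf("c%03d", 1:36)
  umi <- matrix(0, 36, 3, dimnames = list(cells, guides))
  umi[1:12, 1] <- 30; umi[1:12, 2] <- 10            # means {0.75, 0.25}
  umi[13:24, 1] <- 10; umi[13:24, 2] <- 8; umi[13:24, 3] <- 2  # {.5,.4,.1}
  umi[25:33, 1] <- 40                                # only 9 eligible cells
  ct <- toy_guide_triplet(umi, umi * 10)
  map <- tibble::tibble(
    clonotype_id = c("clonotype_1", "clonotype_2", "clonotype_3"),
    bcs = list("b1", "b2", "b3"),
    n_cells = c(12, 12, 12),
    cell_ids = list(cells[1:12], cells[13:24], cells[25:36])
  )
  class(map) <- c("clonotype_map", class(map))
  out <- assign_guide_to_clonotype(map, ct, min_eligible_cells = 10,
                                   cell_umi_floor = 10, unique_threshold = 0.7)
  expect_identical(out$guide_call[[1]], "gA")
  expect_identical(out$call_class[1], "unique")
  expect_setequal(out$guide_call[[2]], c("gA", "gB"))
  expect_identical(out$call_class[2], "double")
  expect_identical(out$call_class[3], "discarded")
})

test_that("the pipeline is deterministic and returns a partition", {
  lib <- library_design(5, ntc_fraction = 0.1, seed = 8)
  cfg <- screen_config("monoclonal", n_ebs = 15, cells_per_eb = c(400, 700),
                       capture_cells_per_eb = 80)
  sim <- simulate_monoclonal_screen(lib, cfg, seed = 12)
  r1 <- run_clonotype_pipeline(sim$counts, min_cells = 30)
  r2 <- run_clonotype_pipeline(sim$counts, min_cells = 30)
  expect_identical(tidy(r1$map), tidy(r2$map))
  # member cells partition: no cell in two clonotypes
  all_cells <- unlist(r1$map$cell_ids)
  expect_false(anyDuplicated(all_cells) > 0)
  # merged barcode sets disjoint across clonotypes
  all_bcs <- unlist(r1$map$bcs)
  expect_false(anyDuplicated(all_bcs) > 0)
})
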