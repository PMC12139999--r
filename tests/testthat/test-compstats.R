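# synthetic label table: m targets x 3 guides, G ntc guides, iid cell types
null_label_table <- function(n_targets = 10, cells_per_target = 120,
                             n_ntc = 30, cells_per_ntc = 60, seed = 1,
                             comp = default_eb_composition()) {
  set.seed(seed)
  guides <- c(paste0("T", rep(seq_len(n_targets), each = 3), "_g", 1:3),
              paste0("NTC_", seq_len(n_ntc)))
  targets <- c(rep(paste0("T", seq_len(n_targets)), each = 3),
               rep("NTC", n_ntc))
  reps <- c(rep(ceiling(cells_per_target / 3), 3 * n_targets),
            rep(cells_per_ntc, n_ntc))
  g <- rep(guides, reps)
  tibble::tibble(
    cell_id = sprintf("c%06d", seq_along(g)),
    guide_id = g,
    target_id = rep(targets, reps),
    is_ntc = rep(targets == "NTC", reps),
    cell_type = sample(names(comp), length(g), replace = TRUE, prob = comp)
  )
}

test_that("the chi-square statistic matches the direct formula and chisq.test", {
  # worked two-category example: (50,50) against background (0.9,0.1)
  stat <- ebscreen:::chisq_stat(c(50, 50), c(0.9, 0.1))
  expect_equal(stat, (50 - 90)^2 / 90 + (50 - 10)^2 / 10, tolerance = 1e-12)
  expect_equal(stat, 177.7778, tolerance = 1e-4)
  # random tables against stats::chisq.test as the independent oracle
  set.seed(21)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    obs <- rmultinom(1, 100, rgamma(k, 1))[, 1]
    p <- rgamma(k, 1); p <- p / sum(p)
    ours <- ebscreen:::chisq_stat(obs, p)
    ref <- suppressWarnings(stats::chisq.test(obs, p = p))
    expect_equal(ours, unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("a unit matching the background exactly gets chi-square 0 and p 1", {
  cells <- null_label_table(n_targets = 2, seed = 3)
  # force one target's composition identical to the NTC background proportions
  st0 <- screen_composition(cells, min_target_cells = 10, min_ntc_cells = 10,
                            downsample = 1e9, seed = 5)
  bg <- st0$background
  n_bg <- table(cells$cell_type[cells$is_ntc])
  copy <- cells[cells$is_ntc, ]
  copy$target_id <- "Tcopy"; copy$is_ntc <- FALSE
  copy$guide_id <- "Tcopy_g1"
  copy$cell_id <- paste0(copy$cell_id, "_copy")
  st <- screen_composition(dplyr::bind_rows(cells, copy),
                           min_target_cells = 10, min_ntc_cells = 10,
                           downsample = 1e9, seed = 5)
  row <- st$targets[st$targets$target_id == "Tcopy", ]
  expect_equal(row$statistic, 0, tolerance = 1e-12)
  expect_equal(row$p_value, 1)
  expect_false(row$significant)
})

test_that("the empirical cutoff flags the q fraction of NTC groups by construction", {
  cells <- null_label_table(n_targets = 4, n_ntc = 90, seed = 7)
  st <- screen_composition(cells, seed = 2)
  frac_ntc_flagged <- mean(st$ntc_groups$p_value < st$cutoff)
  expect_lte(abs(frac_ntc_flagged - 0.05), 1 / nrow(st$ntc_groups))
  # cutoff is the type-7 q-quantile of the NTC p-values
  expect_equal(st$cutoff,
               unname(stats::quantile(st$ntc_groups$p_value, 0.05, type = 7)))
  # flag definition: p below cutoff
  expect_identical(st$targets$significant, st$targets$p_value < st$cutoff)
})

test_that("screen_composition enforces its preconditions", {
  cells <- null_label_table(n_targets = 3, n_ntc = 4, seed = 2)
  expect_error(screen_composition(cells), "fewer than 2 NTC groups")
  cells2 <- null_label_table(n_targets = 3, n_ntc = 30, seed = 2)
  cells2$cell_type[cells2$is_ntc & cells2$cell_type == "epiblast"] <- "neuroectoderm"
  expect_warning(screen_composition(cells2, min_target_cells = 10),
                 "absent from NTC background")
})

test_that("odds ratios match hand arithmetic and the zero correction", {
  mk <- function(n_t, t_in, n_n, n_in, type = "epiblast") {
    tibble::tibble(
      target_id = c(rep("T1", n_t), rep("NTC", n_n)),
      is_ntc = c(rep(FALSE, n_t), rep(TRUE, n_n)),
      cell_type = c(rep(type, t_in), rep("other", n_t - t_in),
                    rep(type, n_in), rep("other", n_n - n_in))
    )
  }
  or1 <- celltype_odds_ratios(mk(100, 10, 100, 10), "T1")
  expect_equal(or1$odds_ratio[or1$cell_type == "epiblast"], 1)
  or2 <- celltype_odds_ratios(mk(100, 20, 100, 10), "T1")
  expect_equal(or2$odds_ratio[or2$cell_type == "epiblast"],
               (20 * 90) / (80 * 10))
  or3 <- celltype_odds_ratios(mk(100, 0, 100, 10), "T1")
  v <- or3$odds_ratio[or3$cell_type == "epiblast"]
  expect_true(is.finite(v) && v < 1)
})

test_that("knn scores match a naive double-loop neighbour search", {
  set.seed(31)
  emb <- matrix(rnorm(80 * 3), 80, 3)
  labels <- sample(c("a", "b"), 80, replace = TRUE)
  res <- knn_enrichment(emb, labels, k = 5, min_target_cells = 10,
                        per_target_downsample = 1e9)
  # oracle: full distance matrix, order() per row
  d <- as.matrix(dist(emb)); diag(d) <- Inf
  same <- vapply(seq_len(80), function(i) {
    nn <- order(d[i, ])[1:5]
    mean(labels[nn] == labels[i])
  }, numeric(1))
  for (t in c("a", "b")) {
    expect_equal(res$score[res$target_id == t], mean(same[labels == t]),
                 tolerance = 1e-12)
  }
})

test_that("knn enrichment behaves at its limits and under rotation", {
  set.seed(32)
  # single target: score 1
  emb <- matrix(rnorm(120 * 2), 120, 2)
  one <- knn_enrichment(emb, rep("a", 120), k = 10, min_target_cells = 10)
  expect_equal(one$score, 1)
  # well-separated blobs: both scores near 1
  emb2 <- rbind(matrix(rnorm(200 * 2), 200, 2),
                matrix(rnorm(200 * 2, mean = 25), 200, 2))
  lab2 <- rep(c("a", "b"), each = 200)
  two <- knn_enrichment(emb2, lab2, k = 20, seed = 1)
  expect_true(all(two$score > 0.95))
  # invariance under rigid rotation
  theta <- 0.73
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot <- knn_enrichment(emb2 %*% R, lab2, k = 20, seed = 1)
  expect_equal(two$score, rot$score, tolerance = 1e-12)
  # random labels at fraction f: mean score -> f within 3 SE
  set.seed(33)
  n <- 2000; f <- 0.1
  emb3 <- matrix(rnorm(n * 5), n, 5)
  lab3 <- ifelse(runif(n) < f, "rare", "common")
  r3 <- knn_enrichment(emb3, lab3, k = 20, per_target_downsample = 1e9,
                       min_target_cells = 10)
  sc <- r3$score[r3$target_id == "rare"]
  exp_f <- r3$expected[r3$target_id == "rare"]
  se <- sqrt(exp_f * (1 - exp_f) / (20 * sum(lab3 == "rare")))
  expect_lt(abs(sc - exp_f), 3 * se * sqrt(20))  # neighbours are correlated
  expect_error(knn_enrichment(emb[1:10, ], rep("a", 10), k = 10,
                              min_target_cells = 2), "smaller")
})

test_that("the clonotype fraction test reproduces exact rank-sum p-values", {
  mk_cells <- function(fracs, target, n = 10) {
    purrr::imap_dfr(fracs, function(f, i) {
      tibble::tibble(clonotype_id = paste0(target, "_", i),
                     target_id = target,
                     cell_type = c(rep("lpm", round(f * n)),
                                   rep("other", n - round(f * n))))
    })
  }
  cells <- dplyr::bind_rows(mk_cells(c(0.1, 0.2, 0.3), "T1"),
                            mk_cells(c(0.7, 0.8, 0.9), "NTC"))
  ft <- clonotype_fraction_test(cells, "T1", "NTC", "lpm")
  # exhaustive enumeration over all choose(6,3) rank assignments gives 0.1
  expect_equal(ft$p_value, 0.1, tolerance = 1e-12)
  combs <- utils::combn(6, 3)
  w_obs <- sum(rank(ft$fractions$fraction)[ft$fractions$group == "target"])
  w_all <- apply(combs, 2, function(ix) sum(rank(1:6)[ix]))
  p_enum <- mean(abs(w_all - 10.5) >= abs(w_obs - 10.5))
  expect_equal(ft$p_value, p_enum, tolerance = 1e-12)
  # identical fraction multisets give p = 1
  same <- dplyr::bind_rows(mk_cells(c(0.2, 0.4, 0.6), "T1"),
                           mk_cells(c(0.2, 0.4, 0.6), "NTC"))
  expect_equal(clonotype_fraction_test(same, "T1", "NTC", "lpm")$p_value, 1)
  expect_error(clonotype_fraction_test(cells[1:12, ], "T1", "NTC", "lpm"),
               "at least 2 clonotypes")
})

test_that("exact rank-sum p-values match enumeration for several small designs", {
  set.seed(41)
  for (rep in 1:6) {
    n1 <- sample(3:4, 1); n2 <- sample(3:4, 1)
    x <- sample(100, n1); y <- sample(200, n2) + 0.5  # untied
    p_ref <- stats::wilcox.test(x, y)$p.value
    ranks <- rank(c(x, y)); n <- n1 + n2
    w_obs <- sum(ranks[1:n1])
    mu <- n1 * (n + 1) / 2
    w_all <- apply(utils::combn(n, n1), 2, function(ix) sum(ranks[ix]))
    p_enum <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    expect_equal(p_ref, p_enum, tolerance = 1e-9)
  }
})

test_that("pseudobulk comparison separates clone-driven from real effects", {
  set.seed(51)
  # one jackpot-sized target clonotype plus seven small ones, vs eight NTC
  clones <- c(paste0("T_cl", 1:8), paste0("N_cl", 1:8))
  sizes <- c(300, rep(30, 7), rep(60, 8))
  cells <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(sum(sizes))),
    clonotype_id = rep(clones, sizes),
    target_id = rep(c("T1", "NTC"), c(510, 480))
  )
  # gene001 shifted in every target cell (true effect); gene002 shifted only
  # in one large target clonotype (EB-to-EB heterogeneity artefact)
  gm <- make_gene_counts(cells, n_genes = 60, clone_sd = 0.25, depth = 6,
                         seed = 52,
                         shift_genes = "gene001",
                         shift_cells = cells$cell_id[cells$target_id == "T1"],
                         fold = 6)
  gm2 <- make_gene_counts(cells, n_genes = 60, clone_sd = 0.25, depth = 6,
                          seed = 52,
                          shift_genes = "gene002",
                          shift_cells = cells$cell_id[cells$clonotype_id == "T_cl1"],
                          fold = 30)
  gm[, "gene002"] <- gm2[, "gene002"]
  res <- pseudobulk_de_compare(gm, cells, "T1", "NTC")
  expect_true("gene001" %in% res$sc_genes)
  expect_true("gene001" %in% res$clonotype_genes)
  expect_false("gene001" %in% res$unsupported_genes)
  expect_true("gene002" %in% res$sc_genes)
  expect_true("gene002" %in% res$unsupported_genes)
})

test_that("pseudobulk comparison is quiet under the null", {
  set.seed(53)
  clones <- c(paste0("T_cl", 1:6), paste0("N_cl", 1:6))
  cells <- tibble::tibble(
    cell_id = sprintf("c%05d", 1:720),
    clonotype_id = rep(clones, each = 60),
    target_id = rep(c("T1", "NTC"), each = 360)
  )
  gm <- make_gene_counts(cells, n_genes = 80, clone_sd = 0, depth = 4, seed = 54)
  res <- pseudobulk_de_compare(gm, cells, "T1", "NTC")
  # FDR control: call sets essentially empty without injected effects
  expect_lte(length(res$sc_genes), 2)
  expect_lte(length(res$clonotype_genes), 2)
  if (length(res$sc_genes) == 0) expect_true(is.na(res$unsupported_fraction))
})
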