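#' Fraction of construct-positive cells carrying exactly one integration
#'
#' Lentiviral integrations per cell are modelled as Poisson with rate
#' \eqn{\lambda} calibrated so that a fraction `p` of cells carries at least
#' one integration (\eqn{1 - e^{-\lambda}} = p). The fraction of positive
#' cells with exactly one integration is then
#' \eqn{\lambda e^{-\lambda} / (1 - e^{-\lambda})}. At the usual titration
#' target of 10% positivity this is ~0.95, the basis for treating
#' reporter-positive cells as single-guide cells.
#'
#' @param p fraction of cells positive for the construct, in (0, 1).
#' @return Fraction of positive cells with exactly one integration.
#' @examples
#' poisson_single_integration(0.10) # ~0.948
#' @export
poisson_single_integration <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly between 0 and 1")
  }
  lambda <- -log1p(-p)
  lambda * exp(-lambda) / (1 - exp(-lambda))
}

#' Default embryoid-body cell-type composition
#'
#' A ten-type simplex loosely patterned on day-8/day-21 EB annotations
#' (epiblast, germ-layer derivatives, cardiomyocytes, primordial germ cells).
#' Used as the simulator's baseline composition.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_eb_composition <- function() {
  c(epiblast = 0.18, primitive_streak = 0.08, neuroectoderm = 0.20,
    neural_crest = 0.07, definitive_endoderm = 0.10,
    lateral_plate_mesoderm = 0.12, paraxial_mesoderm = 0.10,
    cardiomyocytes = 0.06, endothelium = 0.04, primordial_germ_cells = 0.05)
}

#' Design a pooled guide library
#'
#' Builds a guide table with `n_targets` targets at `guides_per_target`
#' guides each plus non-targeting controls (NTCs) making up `ntc_fraction`
#' of the library (the standard 80:20 targeting:NTC mix). Each guide carries
#' a distinct fixed barcode prefix (the predefined 8N section of the organoid
#' barcode that identifies the guide) and a relative abundance drawn
#' log-normally: real cloned libraries, after ES-cell culture, span two to
#' three orders of magnitude in guide representation, and that spread is what
#' makes aggregate guide frequencies reproducible between replicates even
#' when per-EB clonal composition is not.
#'
#' @param n_targets number of targeted genes.
#' @param guides_per_target guides per target (default 3).
#' @param ntc_fraction fraction of the library that is non-targeting
#'   (default 0.2).
#' @param freq_sdlog sdlog of the log-normal guide abundance spread
#'   (default 1.5; 0 gives a uniform library).
#' @param bc_prefix_len,bc_suffix_len lengths of the fixed (guide-identifying)
#'   and random (EB-identifying) organoid-barcode parts (defaults 8 and 9).
#' @param seed RNG seed for frequencies and prefixes.
#' @return A tibble of class `library_design` with columns `guide_id`,
#'   `target_id`, `is_ntc`, `frequency`, `bc_prefix`.
#' @export
library_design <- function(n_targets, guides_per_target = 3, ntc_fraction = 0.2,
                           freq_sdlog = 1.5, bc_prefix_len = 8,
                           bc_suffix_len = 9, seed = 1) {
  stopifnot(n_targets >= 1, guides_per_target >= 1,
            ntc_fraction >= 0, ntc_fraction < 1)
  n_targeting <- n_targets * guides_per_target
  n_ntc <- round(n_targeting * ntc_fraction / (1 - ntc_fraction))
  guides <- tibble::tibble(
    guide_id = c(paste0("T", rep(seq_len(n_targets), each = guides_per_target),
                        "_g", rep(seq_len(guides_per_target), n_targets)),
                 if (n_ntc > 0) paste0("NTC_", seq_len(n_ntc))),
    target_id = c(rep(paste0("T", seq_len(n_targets)), each = guides_per_target),
                  rep("NTC", n_ntc)),
    is_ntc = c(rep(FALSE, n_targeting), rep(TRUE, n_ntc))
  )
  n <- nrow(guides)
  set.seed(seed)
  freq <- if (freq_sdlog > 0) stats::rlnorm(n, 0, freq_sdlog) else rep(1, n)
  guides$frequency <- freq / sum(freq)
  # distinct fixed prefixes; 4^8 >> realistic library sizes
  repeat {
    pref <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), bc_prefix_len, replace = TRUE),
            collapse = "")
    }, character(1))
    if (!anyDuplicated(pref)) break
  }
  guides$bc_prefix <- pref
  attr(guides, "bc_suffix_len") <- bc_suffix_len
  attr(guides, "guides_per_target") <- guides_per_target
  class(guides) <- c("library_design", class(guides))
  guides
}

#' Configure a synthetic EB screen
#'
#' Collects the knobs of the EB clonal-dynamics generator. Mosaic EBs are
#' founded by `founders_per_eb` cells whose final clone sizes follow a
#' symmetric Dirichlet with concentration `clone_concentration`; small values
#' give the "jackpot" regime in which a handful of clones dominate each EB
#' (the default 0.005 with 500 founders reproduces 2-10 clones covering 90%
#' of an EB's guide reads, each 2+ orders of magnitude above the rest).
#' Monoclonal EBs are founded by a single cell carrying one guide and one
#' organoid barcode. Per-EB cell-type composition is drawn from a Dirichlet
#' around `baseline_composition` with concentration `eb_heterogeneity`;
#' perturbation effects multiply the per-EB composition and renormalise.
#' Guide/barcode UMI counts per cell are zero-truncated negative binomial,
#' reads per UMI geometric, and with probability `ambient_rate` a cell gains
#' one UMI of a random foreign guide (floating-cell ambient contamination).
#' Construct silencing is all-or-none per cell with cell-type-dependent
#' detection probability.
#'
#' @param design `"mosaic"` or `"monoclonal"`.
#' @param n_ebs number of EBs.
#' @param founders_per_eb founding cells per mosaic EB (default 500).
#' @param cells_per_eb inclusive integer range of final EB size
#'   (default `c(10000, 30000)`).
#' @param clone_concentration Dirichlet concentration for founder clone
#'   sizes (default 0.005, the jackpot regime).
#' @param baseline_composition named simplex over cell types
#'   (default [default_eb_composition()]).
#' @param eb_heterogeneity Dirichlet concentration of per-EB composition
#'   around the baseline (default 30; smaller = more EB-to-EB variation).
#' @param effects named list: `target_id` -> named vector of multiplicative
#'   cell-type factors (missing types default to 1). Empty list = null screen.
#' @param detection_prob probability a cell's construct transcripts are
#'   detectable: scalar or named per-cell-type vector (default 0.9).
#' @param capture_cells_per_eb cells profiled per EB (default 300).
#' @param umi_mean,umi_size mean and dispersion (NB size) of guide/BC UMI
#'   counts per expressing cell (defaults 12 and 2).
#' @param reads_per_umi_mean mean of the geometric reads-per-UMI distribution
#'   (default 40).
#' @param ambient_rate per-cell probability of one ambient foreign-guide UMI
#'   (default 0.02).
#' @param multi_integrant_prob monoclonal only: probability a founder carries
#'   two (guide, barcode) integrations (default 0.05).
#' @param founder_guides monoclonal only: optional character vector (length
#'   `n_ebs`) fixing each EB's founder guide, as in an arrayed experiment;
#'   `NULL` samples founders from the library frequencies.
#' @param embedding_dim if > 0, emit a per-cell Gaussian-blob embedding with
#'   one blob per cell type (for neighbourhood-enrichment tests); 0 disables.
#' @param embedding_sep distance scale between blob centres (default 6).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(design = c("mosaic", "monoclonal"), n_ebs,
                          founders_per_eb = 500,
                          cells_per_eb = c(10000, 30000),
                          clone_concentration = 0.005,
                          baseline_composition = default_eb_composition(),
                          eb_heterogeneity = 30, effects = list(),
                          detection_prob = 0.9, capture_cells_per_eb = 300,
                          umi_mean = 12, umi_size = 2, reads_per_umi_mean = 40,
                          ambient_rate = 0.02, multi_integrant_prob = 0.05,
                          founder_guides = NULL, embedding_dim = 0,
                          embedding_sep = 6) {
  design <- match.arg(design)
  stopifnot(n_ebs >= 1, founders_per_eb >= 1, length(cells_per_eb) == 2,
            cells_per_eb[1] <= cells_per_eb[2], clone_concentration > 0,
            eb_heterogeneity > 0, umi_mean > 1, umi_size > 0,
            reads_per_umi_mean >= 1, ambient_rate >= 0, ambient_rate <= 1,
            multi_integrant_prob >= 0, multi_integrant_prob <= 1)
  if (abs(sum(baseline_composition) - 1) > 1e-8) {
    stop("`baseline_composition` must sum to 1")
  }
  if (is.null(names(baseline_composition))) {
    stop("`baseline_composition` must be named by cell type")
  }
  if (any(unlist(effects) <= 0)) stop("effect multipliers must be > 0")
  if (any(detection_prob < 0) || any(detection_prob > 1)) {
    stop("`detection_prob` must lie in [0, 1]")
  }
  structure(list(
    design = design, n_ebs = n_ebs, founders_per_eb = founders_per_eb,
    cells_per_eb = cells_per_eb, clone_concentration = clone_concentration,
    baseline_composition = baseline_composition,
    eb_heterogeneity = eb_heterogeneity, effects = effects,
    detection_prob = detection_prob,
    capture_cells_per_eb = capture_cells_per_eb, umi_mean = umi_mean,
    umi_size = umi_size, reads_per_umi_mean = reads_per_umi_mean,
    ambient_rate = ambient_rate, multi_integrant_prob = multi_integrant_prob,
    founder_guides = founder_guides, embedding_dim = embedding_dim,
    embedding_sep = embedding_sep
  ), class = "screen_config")
}

#' Round-trip a screen configuration through YAML
#'
#' @param config a [screen_config()].
#' @param path file path.
#' @return `path` invisibly / the restored [screen_config()].
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  raw <- unclass(config)
  # yaml drops names of atomic vectors; store named vectors as maps
  raw$baseline_composition <- as.list(raw$baseline_composition)
  raw$effects <- lapply(raw$effects, as.list)
  if (!is.null(names(raw$detection_prob))) {
    raw$detection_prob <- as.list(raw$detection_prob)
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$baseline_composition <- unlist(raw$baseline_composition)
  raw$effects <- lapply(raw$effects, unlist)
  if (length(raw$detection_prob) > 1) raw$detection_prob <- unlist(raw$detection_prob)
  do.call(screen_config, raw)
}

## per-cell-type detection probability vector
detection_vector <- function(config) {
  types <- names(config$baseline_composition)
  dp <- config$detection_prob
  if (length(dp) == 1 && is.null(names(dp))) {
    return(stats::setNames(rep(dp, length(types)), types))
  }
  out <- stats::setNames(rep(1, length(types)), types)
  out[names(dp)] <- dp
  out
}

## effect multiplier matrix: targets x types (1 where unspecified)
effect_matrix <- function(config, targets) {
  types <- names(config$baseline_composition)
  m <- matrix(1, length(targets), length(types), dimnames = list(targets, types))
  for (tg in intersect(names(config$effects), targets)) {
    e <- config$effects[[tg]]
    m[tg, names(e)] <- e
  }
  m
}

## zero-truncated NB UMIs plus geometric reads per UMI
draw_counts <- function(n, config) {
  umi <- 1L + stats::rnbinom(n, size = config$umi_size, mu = config$umi_mean - 1)
  reads <- umi + stats::rnbinom(n, size = umi, prob = 1 / config$reads_per_umi_mean)
  list(umi = umi, reads = reads)
}

random_suffixes <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

## assemble a sparse cells x features matrix from triplet vectors
sparse_from_triplets <- function(i, j, x, cells, feats) {
  Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x),
                       dims = c(length(cells), length(feats)),
                       dimnames = list(cells, feats))
}

## per-cell-type Gaussian blob embedding
blob_embedding <- function(types, all_types, dim, sep) {
  centers <- matrix(stats::rnorm(length(all_types) * dim, sd = sep),
                    length(all_types), dim, dimnames = list(all_types, NULL))
  coords <- centers[types, , drop = FALSE] +
    matrix(stats::rnorm(length(types) * dim), length(types), dim)
  colnames(coords) <- paste0("dim", seq_len(dim))
  rownames(coords) <- NULL
  coords
}

#' Simulate a mosaic EB CRISPR screen
#'
#' Each EB is founded by `founders_per_eb` cells drawn from the library by
#' guide frequency; founder clone sizes follow a symmetric Dirichlet with
#' concentration `clone_concentration` multinomially realised over the EB's
#' final cell count, reproducing the stochastic clonal jackpotting of mosaic
#' EBs. Captured cells are sampled without replacement from the EB; each
#' cell's type is drawn from the EB's Dirichlet composition tilted by its
#' clone's perturbation effect, and guide UMI/read counts follow the
#' configured count model with cell-type-dependent silencing and ambient
#' contamination.
#'
#' @param library a [library_design()].
#' @param config a [screen_config()] with `design = "mosaic"`.
#' @param seed integer RNG seed; identical inputs and seed give identical
#'   output.
#' @return A list of class `eb_screen_sim`: `counts` (a [counts_triplet()]
#'   with guide features), `truth` (per-cell tibble: `cell_id`, `eb_id`,
#'   `clone_id`, `guide_id`, `organoid_bc`, `cell_type`, `silenced`),
#'   `founders` (per-EB clone table: `eb_id`, `clone_id`, `guide_id`,
#'   `n_cells` over the full EB, before capture), and `embedding` (matrix or
#'   `NULL`).
#' @export
simulate_mosaic_screen <- function(library, config, seed) {
  stopifnot(inherits(library, "library_design"), inherits(config, "screen_config"))
  if (config$design != "mosaic") stop("config design must be 'mosaic'")
  if (min(config$cells_per_eb) < config$founders_per_eb) {
    stop("cells_per_eb must be at least founders_per_eb")
  }
  set.seed(seed)
  types <- names(config$baseline_composition)
  detect <- detection_vector(config)
  emat <- effect_matrix(config, unique(library$target_id))
  n_guides <- nrow(library)

  truth <- vector("list", config$n_ebs)
  founder_tabs <- vector("list", config$n_ebs)
  for (e in seq_len(config$n_ebs)) {
    K <- config$founders_per_eb
    fg <- sample.int(n_guides, K, replace = TRUE, prob = library$frequency)
    w <- stats::rgamma(K, config$clone_concentration)
    w <- w / sum(w)
    n_cells <- sample(seq(config$cells_per_eb[1], config$cells_per_eb[2]), 1)
    sizes <- as.vector(stats::rmultinom(1, n_cells, w))
    eb_id <- sprintf("EB%04d", e)
    founder_tabs[[e]] <- tibble::tibble(
      eb_id = eb_id, clone_id = paste0(eb_id, "_c", seq_len(K)),
      guide_id = library$guide_id[fg], n_cells = sizes
    )
    ncap <- min(config$capture_cells_per_eb, n_cells)
    picked <- sample.int(n_cells, ncap)
    clone <- findInterval(picked - 1L, cumsum(sizes)) + 1L
    comp <- stats::rgamma(length(types),
                          config$eb_heterogeneity * config$baseline_composition)
    comp <- comp / sum(comp)
    tilt <- emat[library$target_id[fg[clone]], , drop = FALSE] *
      rep(comp, each = ncap)
    tilt <- tilt / rowSums(tilt)
    cum <- tilt %*% upper.tri(diag(length(types)), diag = TRUE)
    ct_idx <- max.col(stats::runif(ncap) <= cum, ties.method = "first")
    truth[[e]] <- tibble::tibble(
      eb_id = eb_id, clone_id = paste0(eb_id, "_c", clone),
      guide_idx = fg[clone], cell_type = types[ct_idx]
    )
  }
  truth <- dplyr::bind_rows(truth)
  truth$cell_id <- sprintf("cell_%06d", seq_len(nrow(truth)))
  truth$guide_id <- library$guide_id[truth$guide_idx]
  truth$silenced <- stats::runif(nrow(truth)) > detect[truth$cell_type]
  truth$organoid_bc <- NA_character_

  counts <- guide_count_matrices(truth$guide_idx, truth$silenced, library, config,
                                 truth$cell_id)
  embedding <- NULL
  if (config$embedding_dim > 0) {
    embedding <- blob_embedding(truth$cell_type, types, config$embedding_dim,
                                config$embedding_sep)
    rownames(embedding) <- truth$cell_id
  }
  truth <- truth[, c("cell_id", "eb_id", "clone_id", "guide_id", "organoid_bc",
                     "cell_type", "silenced")]
  structure(list(counts = counts, truth = truth,
                 founders = dplyr::bind_rows(founder_tabs),
                 embedding = embedding, library = library, config = config),
            class = "eb_screen_sim")
}

## guide UMI/read matrices for one integration per cell, plus ambient
guide_count_matrices <- function(guide_idx, silenced, library, config, cell_ids) {
  n <- length(guide_idx)
  expr <- which(!silenced)
  d <- draw_counts(length(expr), config)
  i <- expr; j <- guide_idx[expr]; u <- d$umi; r <- d$reads
  amb <- which(stats::runif(n) < config$ambient_rate)
  if (length(amb) > 0) {
    foreign <- vapply(guide_idx[amb], function(g) {
      s <- sample.int(nrow(library) - 1L, 1)
      if (s >= g) s + 1L else s
    }, integer(1))
    amb_reads <- 1L + stats::rnbinom(length(amb), size = 1,
                                     prob = 1 / config$reads_per_umi_mean)
    i <- c(i, amb); j <- c(j, foreign)
    u <- c(u, rep(1L, length(amb))); r <- c(r, amb_reads)
  }
  umi <- sparse_from_triplets(i, j, u, cell_ids, library$guide_id)
  reads <- sparse_from_triplets(i, j, r, cell_ids, library$guide_id)
  counts_triplet(umi,
                 tibble::tibble(feature_id = library$guide_id, class = "guide"),
                 reads)
}

#' Simulate a monoclonal EB CRISPR screen
#'
#' Each EB derives from a single founder cell carrying one guide plus an
#' organoid barcode built from the guide's fixed prefix and a random suffix
#' (with probability `multi_integrant_prob` the founder carries two
#' integrations, hence two guide/barcode pairs present in every cell).
#' Cell types follow the per-EB Dirichlet composition tilted by the founder
#' target's effect. Guide and barcode counts are drawn per construct from
#' the count model; silencing is all-or-none per cell and applies to every
#' construct in that cell; ambient contamination adds single foreign
#' guide/barcode UMIs.
#'
#' @inheritParams simulate_mosaic_screen
#' @param config a [screen_config()] with `design = "monoclonal"`.
#' @return As [simulate_mosaic_screen()]; `counts` additionally carries
#'   `organoid_bc` features, and `truth$organoid_bc` the true barcode(s)
#'   (comma-joined for multi-integrant EBs, as is `guide_id`).
#' @export
simulate_monoclonal_screen <- function(library, config, seed) {
  stopifnot(inherits(library, "library_design"), inherits(config, "screen_config"))
  if (config$design != "monoclonal") stop("config design must be 'monoclonal'")
  set.seed(seed)
  types <- names(config$baseline_composition)
  detect <- detection_vector(config)
  emat <- effect_matrix(config, unique(library$target_id))
  suffix_len <- attr(library, "bc_suffix_len") %||% 9
  n_guides <- nrow(library)

  # founder integrations per EB
  if (!is.null(config$founder_guides)) {
    if (length(config$founder_guides) != config$n_ebs) {
      stop("`founder_guides` must have one guide per EB")
    }
    g1 <- match(config$founder_guides, library$guide_id)
    if (anyNA(g1)) stop("unknown guide in `founder_guides`")
  } else {
    g1 <- sample.int(n_guides, config$n_ebs, replace = TRUE,
                     prob = library$frequency)
  }
  multi <- stats::runif(config$n_ebs) < config$multi_integrant_prob
  g2 <- ifelse(multi,
               vapply(g1, function(g) {
                 s <- sample.int(n_guides - 1L, 1)
                 if (s >= g) s + 1L else s
               }, integer(1)),
               NA_integer_)
  eb_ids <- sprintf("EB%04d", seq_len(config$n_ebs))
  bc1 <- paste0(library$bc_prefix[g1], random_suffixes(config$n_ebs, suffix_len))
  bc2 <- ifelse(multi,
                paste0(library$bc_prefix[ifelse(is.na(g2), 1L, g2)],
                       random_suffixes(config$n_ebs, suffix_len)),
                NA_character_)

  truth <- vector("list", config$n_ebs)
  for (e in seq_len(config$n_ebs)) {
    n_cells <- sample(seq(config$cells_per_eb[1], config$cells_per_eb[2]), 1)
    ncap <- min(config$capture_cells_per_eb, n_cells)
    comp <- stats::rgamma(length(types),
                          config$eb_heterogeneity * config$baseline_composition)
    comp <- comp / sum(comp)
    tilt <- comp * emat[library$target_id[g1[e]], ]
    if (multi[e]) tilt <- tilt * emat[library$target_id[g2[e]], ]
    tilt <- tilt / sum(tilt)
    ct <- types[sample.int(length(types), ncap, replace = TRUE, prob = tilt)]
    truth[[e]] <- tibble::tibble(eb_id = eb_ids[e], cell_type = ct)
  }
  truth <- dplyr::bind_rows(truth)
  truth$cell_id <- sprintf("cell_%06d", seq_len(nrow(truth)))
  e_of <- match(truth$eb_id, eb_ids)
  truth$clone_id <- paste0(truth$eb_id, "_c1")
  truth$silenced <- stats::runif(nrow(truth)) > detect[truth$cell_type]
  truth$guide_id <- ifelse(multi[e_of],
                           paste(library$guide_id[g1[e_of]],
                                 library$guide_id[g2[e_of]], sep = ","),
                           library$guide_id[g1[e_of]])
  truth$organoid_bc <- ifelse(multi[e_of], paste(bc1[e_of], bc2[e_of], sep = ","),
                              bc1[e_of])

  # per-construct counts: first integration for all cells, second for multi EBs
  all_bcs <- unique(c(bc1, bc2[multi]))
  n_cells_tot <- nrow(truth)
  expr <- !truth$silenced
  gi <- list(); gj <- list(); gu <- list(); gr <- list()
  bi <- list(); bj <- list(); bu <- list(); br <- list()
  add_construct <- function(cells, gidx, bcs) {
    d1 <- draw_counts(length(cells), config)  # guide transcript
    d2 <- draw_counts(length(cells), config)  # barcode transcript
    list(gi = cells, gj = gidx, gu = d1$umi, gr = d1$reads,
         bi = cells, bj = match(bcs, all_bcs), bu = d2$umi, br = d2$reads)
  }
  c1 <- which(expr)
  a1 <- add_construct(c1, g1[e_of[c1]], bc1[e_of[c1]])
  c2 <- which(expr & multi[e_of])
  a2 <- if (length(c2) > 0) add_construct(c2, g2[e_of[c2]], bc2[e_of[c2]]) else NULL
  gi <- c(a1$gi, a2$gi); gj <- c(a1$gj, a2$gj)
  gu <- c(a1$gu, a2$gu); gr <- c(a1$gr, a2$gr)
  bi <- c(a1$bi, a2$bi); bj <- c(a1$bj, a2$bj)
  bu <- c(a1$bu, a2$bu); br <- c(a1$br, a2$br)
  # ambient: single foreign-guide and foreign-barcode UMIs
  amb_g <- which(stats::runif(n_cells_tot) < config$ambient_rate)
  if (length(amb_g) > 0) {
    fg <- vapply(g1[e_of[amb_g]], function(g) {
      s <- sample.int(n_guides - 1L, 1); if (s >= g) s + 1L else s
    }, integer(1))
    gi <- c(gi, amb_g); gj <- c(gj, fg)
    gu <- c(gu, rep(1L, length(amb_g)))
    gr <- c(gr, 1L + stats::rnbinom(length(amb_g), size = 1,
                                    prob = 1 / config$reads_per_umi_mean))
  }
  amb_b <- which(stats::runif(n_cells_tot) < config$ambient_rate)
  if (length(amb_b) > 0 && length(all_bcs) > 1) {
    own <- match(bc1[e_of[amb_b]], all_bcs)
    fb <- vapply(own, function(b) {
      s <- sample.int(length(all_bcs) - 1L, 1); if (s >= b) s + 1L else s
    }, integer(1))
    bi <- c(bi, amb_b); bj <- c(bj, fb)
    bu <- c(bu, rep(1L, length(amb_b)))
    br <- c(br, 1L + stats::rnbinom(length(amb_b), size = 1,
                                    prob = 1 / config$reads_per_umi_mean))
  }
  feats <- c(library$guide_id, all_bcs)
  umi <- sparse_from_triplets(c(gi, bi), c(gj, bj + n_guides), c(gu, bu),
                              truth$cell_id, feats)
  reads <- sparse_from_triplets(c(gi, bi), c(gj, bj + n_guides), c(gr, br),
                                truth$cell_id, feats)
  features <- tibble::tibble(
    feature_id = feats,
    class = c(rep("guide", n_guides), rep("organoid_bc", length(all_bcs)))
  )
  counts <- counts_triplet(umi, features, reads)
  embedding <- NULL
  if (config$embedding_dim > 0) {
    embedding <- blob_embedding(truth$cell_type, types, config$embedding_dim,
                                config$embedding_sep)
    rownames(embedding) <- truth$cell_id
  }
  founders <- tibble::tibble(
    eb_id = rep(eb_ids, ifelse(multi, 2L, 1L)),
    clone_id = paste0(rep(eb_ids, ifelse(multi, 2L, 1L)), "_c1"),
    guide_id = library$guide_id[unlist(Map(function(a, b, m) if (m) c(a, b) else a,
                                           g1, g2, multi))],
    n_cells = NA_integer_
  )
  truth <- truth[, c("cell_id", "eb_id", "clone_id", "guide_id", "organoid_bc",
                     "cell_type", "silenced")]
  structure(list(counts = counts, truth = truth, founders = founders,
                 embedding = embedding, library = library, config = config),
            class = "eb_screen_sim")
}

#' @export
print.eb_screen_sim <- function(x, ...) {
  cat("<eb_screen_sim> ", x$config$design, " design: ",
      dplyr::n_distinct(x$truth$eb_id), " EBs, ", nrow(x$truth),
      " captured cells\n", sep = "")
  invisible(x)
}

#' Whole-EB guide abundance (genomic-DNA amplicon analogue)
#'
#' Aggregates the simulator's full founder clone table to per-EB guide
#' template (UMI) counts over all cells of the EB - the analogue of
#' quantifying guide representation from the genomic DNA of hand-picked
#' EBs - and draws sequencing reads per template geometrically.
#'
#' @param sim an `eb_screen_sim` from [simulate_mosaic_screen()].
#' @param reads_per_umi_mean mean reads per template molecule (default from
#'   the simulation config).
#' @param seed RNG seed.
#' @return Tibble `eb_id`, `guide_id`, `umi`, `reads`.
#' @export
eb_guide_counts <- function(sim, reads_per_umi_mean = NULL, seed = 1) {
  stopifnot(inherits(sim, "eb_screen_sim"))
  if (is.null(reads_per_umi_mean)) reads_per_umi_mean <- sim$config$reads_per_umi_mean
  set.seed(seed)
  out <- sim$founders |>
    dplyr::group_by(.data$eb_id, .data$guide_id) |>
    dplyr::summarise(umi = sum(.data$n_cells), .groups = "drop") |>
    dplyr::filter(.data$umi > 0)
  out$reads <- out$umi + stats::rnbinom(nrow(out), size = out$umi,
                                        prob = 1 / reads_per_umi_mean)
  out
}

#' Expand guide UMI counts into read-level amplicon records
#'
#' Produces one row per sequencing read with a UMI tag and guide id, for
#' exercising UMI deduplication: each of `n_umi` templates of a guide gets a
#' distinct random UMI sequence and a geometric number of reads. Intended
#' for small inputs.
#'
#' @param guide_umis tibble with `guide_id` and `n_umi`.
#' @param reads_per_umi_mean mean reads per UMI (default 5).
#' @param umi_length UMI tag length (default 10).
#' @param seed RNG seed.
#' @return Tibble `umi`, `guide_id`, one row per read.
#' @export
simulate_amplicon_reads <- function(guide_umis, reads_per_umi_mean = 5,
                                    umi_length = 10, seed = 1) {
  stopifnot(all(c("guide_id", "n_umi") %in% names(guide_umis)))
  set.seed(seed)
  recs <- lapply(seq_len(nrow(guide_umis)), function(i) {
    n <- guide_umis$n_umi[i]
    if (n == 0) return(NULL)
    umis <- random_suffixes(n, umi_length)
    reps <- 1L + stats::rgeom(n, 1 / reads_per_umi_mean)
    tibble::tibble(umi = rep(umis, reps),
                   guide_id = guide_umis$guide_id[i])
  })
  out <- dplyr::bind_rows(recs)
  out[sample.int(nrow(out)), ]
}
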