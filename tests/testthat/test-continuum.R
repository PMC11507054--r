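test_that("hurdle log2FC follows the pseudocount-1 definition", {
  # identical groups: duplicate cells -> log2fc exactly 0
  set.seed(2)
  vals <- matrix(abs(rnorm(40 * 60, 1, 0.5)), 40, 60)
  cells <- tibble::tibble(barcode = sprintf("c%02d", 1:40),
                          sample_id = rep(c("s1", "s2"), each = 20),
                          stage = rep(c("tumor", "normal"), each = 20),
                          cell_type = "SLC1")
  vals[21:40, ] <- vals[1:20, ]
  norm <- make_norm(vals, cells = cells)
  de <- hurdle_de(norm, cells$barcode[1:20], cells$barcode[21:40])
  expect_true(all(de$log2fc == 0))

  # de-logged target mean 3 vs reference mean 1 -> log2(4/2) = 1
  vals2 <- rbind(matrix(log(4), 12, 60), matrix(log(2), 12, 60))
  cells2 <- tibble::tibble(barcode = sprintf("c%02d", 1:24),
                           sample_id = rep(c("t", "r"), each = 12),
                           stage = rep(c("tumor", "normal"), each = 12),
                           cell_type = "SLC1")
  norm2 <- make_norm(vals2, cells = cells2)
  de2 <- hurdle_de(norm2, cells2$barcode[1:12], cells2$barcode[13:24])
  expect_equal(de2$log2fc, rep(1, 60))

  # matches the brute-force oracle on mixed values
  de3 <- hurdle_de(norm, cells$barcode[1:20], cells$barcode[21:40])
  g5 <- de3$gene[5]
  j <- match(g5, colnames(norm$values))
  expect_equal(de3$log2fc[5],
               oracle_log2fc(vals[1:20, j], vals[21:40, j]), tolerance = 1e-12)

  # groups below min_cells yield NULL, not an error
  expect_null(hurdle_de(norm, cells$barcode[1:3], cells$barcode[21:40]))
})

test_that("per-sample profiling pools the reference and adjusts within sample", {
  sim <- quick_sim(seed = 3)
  norm <- normalize_counts(sim$dataset)
  prof <- profile_all_samples(norm, "SLC1")
  expect_false("normal" %in% prof$stage)
  expect_setequal(unique(prof$sample_id),
                  unique(norm$cells$sample_id[norm$cells$stage != "normal"]))
  expect_true(all(prof$p_adj >= prof$p_value, na.rm = TRUE))
  expect_true(all(prof$pct_expr_target >= 0 & prof$pct_expr_target <= 1))
  # BH within sample: max p_adj per sample equals max p (BH keeps the top)
  one <- prof[prof$sample_id == prof$sample_id[1], ]
  expect_equal(one$p_adj, p.adjust(one$p_value, "BH"))

  # under-sized sample is skipped with a message, not an error
  small <- sim$dataset
  drop <- small$cells$barcode[small$cells$sample_id == "SSL_1"][-(1:3)]
  keep <- !small$cells$barcode %in% drop
  small <- count_dataset(small$counts[keep, ], small$cells[keep, ], small$genes)
  norm_small <- normalize_counts(small)
  expect_message(prof2 <- profile_all_samples(norm_small, "SLC1"), "SSL_1")
  expect_false("SSL_1" %in% prof2$sample_id)
})

test_that("continuum gene selection enforces the two-sample rule", {
  profile <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:3), each = 3),
    stage = "SSL",
    gene = rep(c("g1", "g2", "g3"), 3),
    log2fc = 1,
    p_value = 0.01,
    p_adj = c(0.01, 0.2, 0.01,   # s1: g1, g3 significant
              0.5,  0.9, 0.04,   # s2: g3 significant
              0.9,  0.9, 0.9)    # s3: none
  )
  sel <- select_continuum_genes(profile, alpha = 0.05, min_samples = 2)
  expect_equal(sel, "g3")            # significant in exactly 2 samples
  expect_false("g1" %in% sel)        # significant in only 1 sample
  expect_setequal(select_continuum_genes(profile, alpha = 1, min_samples = 1),
                  c("g1", "g2", "g3"))
  expect_error(select_continuum_genes(profile, alpha = 0.001, min_samples = 3),
               "no gene")
})

test_that("continuum PCA matches a dense eigendecomposition oracle", {
  set.seed(9)
  m <- matrix(rnorm(12), 4, 3)
  profile <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:4), each = 3),
    stage = "SSL",
    gene = rep(c("g1", "g2", "g3"), 4),
    log2fc = as.vector(t(m)),
    p_value = 0.01, p_adj = 0.01
  )
  pca <- continuum_pca(profile, c("g1", "g2", "g3"))
  oracle <- oracle_pca_scores(m, k = 2)
  for (k in 1:2) {
    got <- pca$scores[[paste0("PC", k)]]
    want <- oracle$scores[, k]
    expect_true(max(abs(got - want)) < 1e-10 || max(abs(got + want)) < 1e-10)
  }
  expect_equal(pca$explained_variance,
               (oracle$values / sum(oracle$values))[1:2], tolerance = 1e-10)

  # permuting gene columns leaves coordinates unchanged (fixed sign rule)
  profile_perm <- profile[order(rep(c(2, 3, 1), 4), rep(1:4, each = 3)), ]
  pca2 <- continuum_pca(profile_perm, c("g1", "g2", "g3"))
  expect_equal(pca2$scores[match(pca$scores$sample_id, pca2$scores$sample_id), ]$PC1,
               pca$scores$PC1, tolerance = 1e-10)

  # samples exactly on a line in gene space: PC2 explains nothing
  line <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:4), each = 2),
    stage = "SSL",
    gene = rep(c("g1", "g2"), 4),
    log2fc = as.vector(rbind(1:4, 2 * (1:4))),
    p_value = 0.01, p_adj = 0.01
  )
  pca3 <- continuum_pca(line, c("g1", "g2"))
  expect_lt(pca3$explained_variance[2], 1e-12)

  expect_error(continuum_pca(profile[1:6, ], c("g1", "g2", "g3")), "3 profiled")
})

test_that("principal curve on collinear points reduces to line projection", {
  # points exactly on a slanted line in the PC plane
  t_true <- c(0.9, 0.1, 0.5, 0.30, 0.7, 0)
  coords <- tibble::tibble(
    sample_id = sprintf("s%d", seq_along(t_true)),
    stage = c("tumor", "normal", "SSL", "SSL", "TSA", "normal"),
    PC1 = 2 * t_true - 1,
    PC2 = -1 * (2 * t_true - 1) + 0.5
  )
  fit <- fit_principal_curve(coords)
  expect_true(fit$converged)
  pos <- fit$positions$position[match(coords$sample_id, fit$positions$sample_id)]
  # arc-length positions equal normalized projections onto the line
  expect_equal(pos, (t_true - min(t_true)) / (max(t_true) - min(t_true)),
               tolerance = 1e-8)
  # orientation anchored: normal samples before tumor samples
  expect_lt(mean(pos[coords$stage == "normal"]), mean(pos[coords$stage == "tumor"]))

  # permuting the input rows leaves per-sample positions unchanged
  fit2 <- fit_principal_curve(coords[c(3, 1, 6, 2, 5, 4), ])
  pos2 <- fit2$positions$position[match(coords$sample_id, fit2$positions$sample_id)]
  expect_equal(pos2, pos, tolerance = 1e-8)

  expect_error(fit_principal_curve(coords[1:3, ]), "4 samples")
})

test_that("gene trends recover monotone relationships and match the rank oracle", {
  ax <- tibble::tibble(sample_id = sprintf("s%d", 1:6), stage = "SSL",
                       PC1 = rnorm(6), PC2 = c(0.3, -1, 2, 0.8, -0.2, 1.4))
  pca_like <- structure(list(scores = ax), class = "continuum_pca")
  lfc_inc <- rank(ax$PC2) / 2            # strictly increasing with the axis
  set.seed(8)
  lfc_rand <- rnorm(6)
  profile <- dplyr::bind_rows(
    tibble::tibble(sample_id = ax$sample_id, stage = "SSL", gene = "inc",
                   log2fc = lfc_inc, p_value = 0.01, p_adj = 0.01),
    tibble::tibble(sample_id = ax$sample_id, stage = "SSL", gene = "rnd",
                   log2fc = lfc_rand, p_value = 0.01, p_adj = 0.01),
    tibble::tibble(sample_id = ax$sample_id, stage = "SSL", gene = "flat",
                   log2fc = 0.7, p_value = 0.01, p_adj = 0.01)
  )
  tr <- gene_trends(profile, pca_like, axis = "PC2")
  expect_equal(tr$spearman_rho[tr$gene == "inc"], 1)
  expect_equal(tr$spearman_rho[tr$gene == "rnd"],
               oracle_spearman(lfc_rand, ax$PC2), tolerance = 1e-12)
  expect_true(is.na(tr$spearman_rho[tr$gene == "flat"]))
  expect_true(tr$degenerate[tr$gene == "flat"])
})

test_that("null gene trends are centred with uniform p-values", {
  set.seed(31)
  n_genes <- 400
  ax <- tibble::tibble(sample_id = sprintf("s%d", 1:10), stage = "SSL",
                       PC1 = 0, PC2 = rnorm(10))
  pca_like <- structure(list(scores = ax), class = "continuum_pca")
  profile <- tidyr::crossing(sample_id = ax$sample_id,
                             gene = sprintf("g%03d", 1:n_genes)) %>%
    dplyr::mutate(stage = "SSL", log2fc = rnorm(dplyr::n()),
                  p_value = 0.01, p_adj = 0.01)
  tr <- gene_trends(profile, pca_like, axis = "PC2")
  expect_lt(abs(median(tr$spearman_rho)), 0.15)
  ks <- suppressWarnings(ks.test(tr$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("one-vs-rest markers surface planted type-specific genes", {
  set.seed(6)
  n <- 60; g <- 80
  vals <- matrix(abs(rnorm(n * g, 1, 0.3)), n, g)
  cells <- tibble::tibble(barcode = sprintf("c%02d", 1:n),
                          sample_id = "s1", stage = "normal",
                          cell_type = rep(c("A", "B"), each = n / 2))
  vals[31:60, 7] <- vals[31:60, 7] + 3   # gene 7 specific to type B
  norm <- make_norm(vals, cells = cells)
  mk <- one_vs_rest_markers(norm, top_n = 5)
  b_top <- mk$gene[mk$cell_type == "B" & mk$rank == 1]
  expect_equal(b_top, norm$genes$gene_id[7])

  expect_equal(nrow(one_vs_rest_markers(norm, top_n = 0)), 0)

  # two statistically identical types: no marker flood at FDR 0.05
  cells_null <- cells
  vals_null <- matrix(abs(rnorm(n * g, 1, 0.3)), n, g)
  mk_null <- one_vs_rest_markers(make_norm(vals_null, cells = cells_null), top_n = 50)
  expect_lt(nrow(mk_null), 0.1 * g)
})

test_that("the full continuum wrapper recovers a planted ordering", {
  sim <- simulate_dataset(sim_config(
    n_samples_per_stage = c(normal = 2L, SSL = 3L, SSLD = 1L, TSA = 2L, tumor = 2L),
    n_cells_per_sample = 100L, n_genes = 800L, n_continuum_genes = 100L,
    seed = 51
  ))
  norm <- normalize_counts(sim$dataset)
  suppressMessages(mc <- malignant_continuum(norm, "SLC1"))
  pos <- tidy(mc)
  s_true <- setNames(sim$truth$samples$s_true, sim$truth$samples$sample_id)
  rho <- cor(pos$position, s_true[pos$sample_id], method = "spearman")
  expect_gt(abs(rho), 0.8)
  # selection soundness: every selected gene re-passes the rule
  counts <- mc$profile %>%
    dplyr::filter(.data$gene %in% mc$selected_genes, .data$p_adj < 0.05) %>%
    dplyr::count(.data$gene)
  expect_true(all(counts$n >= 2))
  expect_setequal(counts$gene, mc$selected_genes)
  # glance/tidy wiring
  g <- glance(mc)
  expect_equal(g$n_samples, nrow(pos))
  expect_true(g$n_selected_genes > 0)
})
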