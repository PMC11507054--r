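#' Synthetic gene annotation covering all autosomal arms
#'
#' Assigns `n_genes` genes to chromosome arms 1p..22q with at least one gene
#' per arm and strictly increasing positions within each chromosome (the p arm
#' precedes the q arm). Used by the simulator and available on its own for
#' constructing CNV test fixtures.
#'
#' @param n_genes Number of genes; must be at least 44 (one per arm).
#' @param seed Integer seed; the same seed always yields the same table.
#' @return Tibble with columns `gene_id`, `gene_name`, `chromosome`, `start`,
#'   `end`, `arm`, ordered by (chromosome, start).
#' @examples
#' synthetic_gene_annotation(100, seed = 1)
#' @export
synthetic_gene_annotation <- function(n_genes, seed = 1L) {
  if (n_genes < 44) abort("n_genes must be >= 44 so every arm gets a gene")
  with_seed(seed, {
    arms <- arm_levels()
    extra <- n_genes - length(arms)
    # one guaranteed gene per arm, remainder spread with random arm weights
    w <- runif(length(arms), 0.5, 1.5)
    add <- if (extra > 0) {
      tabulate(sample(seq_along(arms), extra, replace = TRUE, prob = w),
               nbins = length(arms))
    } else {
      integer(length(arms))
    }
    n_per_arm <- 1L + add
    chrom <- rep(sub("[pq]$", "", arms), n_per_arm)
    arm <- rep(arms, n_per_arm)
    tab <- tibble(chromosome = chrom, arm = arm)
    # strictly increasing positions within a chromosome, p arm before q
    tab <- tab %>%
      group_by(.data$chromosome) %>%
      mutate(
        start = {
          gaps <- ceiling(runif(dplyr::n(), 1e4, 1e6))
          cumsum(gaps)
        },
        end = .data$start + ceiling(runif(dplyr::n(), 500, 5000))
      ) %>%
      ungroup()
    ord <- order(as.integer(tab$chromosome), tab$start)
    tab <- tab[ord, ]
    tab %>%
      mutate(
        gene_id = sprintf("g%05d", row_number()),
        gene_name = sprintf("GENE%d", row_number())
      ) %>%
      select("gene_id", "gene_name", "chromosome", "start", "end", "arm")
  })
}

#' Simulation configuration
#'
#' Describes a multi-sample scRNA-seq dataset with three kinds of planted
#' structure: (a) a latent per-sample progression score in `[0, 1]` driving
#' monotone log2 fold changes in a subset of "continuum" genes, (b)
#' chromosome-arm copy-number segments multiplying expression in designated
#' cells, and (c) gene programs (e.g. EMT, S, G2M) elevated in designated
#' cells. Counts are negative binomial with per-cell lognormal library-size
#' factors and a shared dispersion (Var = mu + mu^2 * dispersion).
#'
#' Defaults emulate a 12-sample serrated-pathway cohort: 2 normal reference
#' samples and 10 lesion/tumor samples of 150 target-subtype cells each, 2000
#' genes of which 200 carry continuum slopes with |beta| in `[1, 3]` log2
#' units per unit progression, NB dispersion 0.5.
#'
#' @param n_samples_per_stage Named integer vector, stage -> number of samples.
#' @param n_cells_per_sample Cells per sample.
#' @param n_genes Total genes.
#' @param n_continuum_genes Genes given a progression-linked slope; drawn only
#'   from genes outside planted CNV arms and outside program gene sets, so the
#'   planted factors stay identifiable.
#' @param slope_range Length-2 nonnegative range of |slope| in log2 units per
#'   unit progression; each continuum gene gets a uniform draw with random sign.
#' @param progression_scores `"auto"` (samples ranked by stage order then
#'   index, mapped equispaced on `[0, 1]`) or a named numeric vector
#'   sample_id -> score in `[0, 1]`.
#' @param cnv_segments List of segments, each a list with elements `arm`
#'   (e.g. "7p"), `copy_ratio` (> 0), `stages` (character; stages whose cells
#'   carry the segment) and optional `cell_types` (default all).
#' @param program_defs Named list program -> list(`n_genes`, `log2_elevation`,
#'   `cell_fraction`, optional `stages`). Program cell masks are disjoint
#'   across programs.
#' @param cell_type_props Named numeric vector of cell-type sampling weights.
#' @param baseline_mean_lognormal `c(meanlog, sdlog)` of the per-gene baseline
#'   mean expression.
#' @param nb_dispersion Shared NB dispersion; 0 gives Poisson counts.
#' @param libsize_lognormal `c(meanlog, sdlog)` of the per-cell library-size
#'   factor.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_stage = c(normal = 2L, HP = 2L, SSL = 3L,
                                               SSLD = 1L, TSA = 2L, tumor = 2L),
                       n_cells_per_sample = 150L,
                       n_genes = 2000L,
                       n_continuum_genes = 200L,
                       slope_range = c(1, 3),
                       progression_scores = "auto",
                       cnv_segments = list(),
                       program_defs = list(),
                       cell_type_props = c(SLC1 = 1),
                       baseline_mean_lognormal = c(log(2), 1.2),
                       nb_dispersion = 0.5,
                       libsize_lognormal = c(0, 0.35),
                       seed = 1L) {
  cfg <- list(
    n_samples_per_stage = n_samples_per_stage,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_genes = as.integer(n_genes),
    n_continuum_genes = as.integer(n_continuum_genes),
    slope_range = as.numeric(slope_range),
    progression_scores = progression_scores,
    cnv_segments = cnv_segments,
    program_defs = program_defs,
    cell_type_props = cell_type_props,
    baseline_mean_lognormal = as.numeric(baseline_mean_lognormal),
    nb_dispersion = as.numeric(nb_dispersion),
    libsize_lognormal = as.numeric(libsize_lognormal),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad_stage <- setdiff(names(cfg$n_samples_per_stage), stage_levels())
  if (length(bad_stage)) abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  if (any(cfg$n_samples_per_stage < 0)) abort("sample counts must be nonnegative")
  if (sum(cfg$n_samples_per_stage) < 1) abort("need at least one sample")
  assert_scalar_number(cfg$n_cells_per_sample, "n_cells_per_sample", lower = 1)
  assert_scalar_number(cfg$n_genes, "n_genes", lower = 44)
  assert_scalar_number(cfg$nb_dispersion, "nb_dispersion", lower = 0)
  if (length(cfg$slope_range) != 2 || any(cfg$slope_range < 0) ||
      cfg$slope_range[1] > cfg$slope_range[2]) {
    abort("slope_range must be a nondecreasing pair of nonnegative values")
  }
  prog_genes <- sum(vapply(cfg$program_defs, function(p) as.numeric(p$n_genes), 0))
  if (cfg$n_continuum_genes + prog_genes > cfg$n_genes) {
    abort("gene budget exceeded: n_continuum_genes + program genes > n_genes")
  }
  for (seg in cfg$cnv_segments) {
    if (is.null(seg$arm) || is.null(seg$copy_ratio) || is.null(seg$stages)) {
      abort("each cnv segment needs `arm`, `copy_ratio` and `stages`")
    }
    if (seg$copy_ratio <= 0) abort("copy_ratio must be > 0")
    if (!seg$arm %in% arm_levels()) {
      abort(paste0("planted arm ", seg$arm, " is not a valid chromosome arm"))
    }
  }
  if (!identical(cfg$progression_scores, "auto")) {
    s <- cfg$progression_scores
    if (is.null(names(s)) || any(s < 0 | s > 1)) {
      abort("progression_scores must be 'auto' or a named vector with values in [0, 1]")
    }
  }
  invisible(cfg)
}

# Sample table (sample_id, stage) in progression order, plus scores.
sim_sample_table <- function(cfg) {
  stages <- intersect(stage_levels(), names(cfg$n_samples_per_stage))
  rows <- lapply(stages, function(st) {
    k <- cfg$n_samples_per_stage[[st]]
    if (k == 0) return(NULL)
    tibble(sample_id = sprintf("%s_%d", st, seq_len(k)), stage = st)
  })
  samples <- bind_rows(rows)
  if (identical(cfg$progression_scores, "auto")) {
    n <- nrow(samples)
    samples$s_true <- if (n == 1) 0 else seq(0, 1, length.out = n)
  } else {
    missing <- setdiff(samples$sample_id, names(cfg$progression_scores))
    if (length(missing)) {
      abort(paste0("progression_scores missing for: ", paste(missing, collapse = ", ")))
    }
    samples$s_true <- unname(cfg$progression_scores[samples$sample_id])
  }
  samples
}

#' Generate a synthetic multi-sample scRNA-seq dataset with planted truth
#'
#' Draws counts for every cell c and gene g as
#' `NB(mean = libsize_c * baseline_g * 2^(beta_g * s_sample(c)) * copy_ratio
#' * 2^(elevation), dispersion)`, where the copy-ratio factor applies when the
#' cell is in a planted CNV segment's mask and the gene lies on its arm, and
#' the elevation factor when both cell and gene belong to a planted program.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a [count_dataset()]) and `truth`
#'   (class `sim_truth`: tibbles `samples` with the latent progression scores,
#'   `beta` with per-gene continuum slopes, `cnv` with planted segments and
#'   their cell masks, `programs` with gene lists and cell masks).
#' @examples
#' sim <- simulate_dataset(sim_config(
#'   n_samples_per_stage = c(normal = 1L, tumor = 1L),
#'   n_cells_per_sample = 20L, n_genes = 50L, n_continuum_genes = 5L, seed = 7
#' ))
#' sim$dataset
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  cfg <- config
  with_seed(cfg$seed, {
    genes <- synthetic_gene_annotation(cfg$n_genes,
                                       seed = derive_seed(cfg$seed, "annotation"))
    samples <- sim_sample_table(cfg)

    cells <- samples %>%
      tidyr::uncount(cfg$n_cells_per_sample, .remove = FALSE) %>%
      mutate(
        barcode = sprintf("%s_c%04d", .data$sample_id,
                          stats::ave(rep(1, dplyr::n()), .data$sample_id, FUN = seq_along)),
        cell_type = sample(names(cfg$cell_type_props), dplyr::n(), replace = TRUE,
                           prob = cfg$cell_type_props)
      ) %>%
      select("barcode", "sample_id", "stage", "cell_type", "s_true")

    n_cells <- nrow(cells)
    n_genes <- cfg$n_genes

    baseline <- rlnorm(n_genes, cfg$baseline_mean_lognormal[1],
                       cfg$baseline_mean_lognormal[2])
    libsize <- rlnorm(n_cells, cfg$libsize_lognormal[1], cfg$libsize_lognormal[2])

    # program gene sets first (disjoint), then continuum genes from what is
    # left outside planted CNV arms, keeping the planted factors identifiable
    cnv_arms <- unique(vapply(cfg$cnv_segments, `[[`, "", "arm"))
    taken <- integer(0)
    program_rows <- list()
    free_cells <- seq_len(n_cells)
    for (pn in names(cfg$program_defs)) {
      pd <- cfg$program_defs[[pn]]
      pool <- setdiff(which(!genes$arm %in% cnv_arms), taken)
      if (length(pool) < pd$n_genes) abort("gene budget exceeded for program genes")
      pg <- sort(sample(pool, pd$n_genes))
      taken <- c(taken, pg)
      eligible <- free_cells
      if (!is.null(pd$stages)) {
        eligible <- intersect(eligible, which(cells$stage %in% pd$stages))
      }
      k <- round(pd$cell_fraction * length(eligible))
      pc <- sort(sample(eligible, k))
      free_cells <- setdiff(free_cells, pc)
      program_rows[[pn]] <- list(genes = genes$gene_id[pg], cell_idx = pc,
                                 log2_elevation = pd$log2_elevation)
    }

    cont_pool <- setdiff(which(!genes$arm %in% cnv_arms), taken)
    if (length(cont_pool) < cfg$n_continuum_genes) {
      abort("gene budget exceeded: not enough genes outside CNV arms/programs")
    }
    cont_idx <- sort(sample(cont_pool, cfg$n_continuum_genes))
    beta <- numeric(n_genes)
    if (cfg$n_continuum_genes > 0) {
      mag <- runif(cfg$n_continuum_genes, cfg$slope_range[1], cfg$slope_range[2])
      sgn <- sample(c(-1, 1), cfg$n_continuum_genes, replace = TRUE)
      beta[cont_idx] <- mag * sgn
    }

    # log2 of the NB mean, assembled factor by factor
    log2mu <- outer(log2(libsize), log2(baseline), `+`) +
      outer(cells$s_true, beta)
    cnv_rows <- list()
    for (seg in cfg$cnv_segments) {
      cmask <- cells$stage %in% seg$stages
      if (!is.null(seg$cell_types)) cmask <- cmask & cells$cell_type %in% seg$cell_types
      gmask <- !is.na(genes$arm) & genes$arm == seg$arm
      if (!any(gmask)) abort(paste0("planted arm ", seg$arm, " has no genes in the annotation"))
      log2mu[cmask, gmask] <- log2mu[cmask, gmask] + log2(seg$copy_ratio)
      cnv_rows[[length(cnv_rows) + 1L]] <- tibble(
        arm = seg$arm, copy_ratio = seg$copy_ratio,
        cells = list(cells$barcode[cmask]), genes = list(genes$gene_id[gmask])
      )
    }
    for (pn in names(program_rows)) {
      pr <- program_rows[[pn]]
      gmask <- genes$gene_id %in% pr$genes
      log2mu[pr$cell_idx, gmask] <- log2mu[pr$cell_idx, gmask] + pr$log2_elevation
    }

    mu <- 2^log2mu
    counts <- if (cfg$nb_dispersion <= 1e-12) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    }
    counts <- matrix(counts, nrow = n_cells)

    dataset <- count_dataset(counts, select(cells, -"s_true"), genes)
    truth <- structure(list(
      samples = select(samples, "sample_id", "stage", "s_true"),
      baseline = tibble(gene_id = genes$gene_id, baseline = baseline),
      beta = tibble(gene_id = genes$gene_id[cont_idx], beta = beta[cont_idx]),
      cnv = if (length(cnv_rows)) bind_rows(cnv_rows) else
        tibble(arm = character(), copy_ratio = numeric(),
               cells = list(), genes = list()),
      programs = tibble(
        program = names(program_rows),
        log2_elevation = vapply(program_rows, `[[`, 0, "log2_elevation"),
        genes = lapply(program_rows, `[[`, "genes"),
        cells = lapply(program_rows, function(p) cells$barcode[p$cell_idx])
      )
    ), class = "sim_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' @exportS3Method base::print
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d samples, %d continuum genes, %d CNV segments, %d programs\n",
              nrow(x$samples), nrow(x$beta), nrow(x$cnv), nrow(x$programs)))
  invisible(x)
}
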