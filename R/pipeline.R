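# Full schema of the run configuration: every known key with its default.
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "slcontinuum_results",
    stages = list(simulate = TRUE, qc = TRUE, composition = TRUE,
                  cnv = TRUE, score = TRUE, continuum = TRUE),
    input = NULL,
    simulate = list(
      n_samples_per_stage = list(normal = 2L, HP = 2L, SSL = 3L, SSLD = 1L,
                                 TSA = 2L, tumor = 2L),
      n_cells_per_sample = 150L,
      n_genes = 2000L,
      n_continuum_genes = 200L,
      slope_range = c(1, 3),
      progression_scores = "auto",
      cnv_segments = list(),
      program_defs = list(),
      cell_type_props = list(SLC1 = 1),
      baseline_mean_lognormal = c(log(2), 1.2),
      nb_dispersion = 0.5,
      libsize_lognormal = c(0, 0.35)
    ),
    qc = list(min_genes = 200, max_mito_pct = 20, mito_prefix = "MT-"),
    normalize = list(scale = 1e4),
    composition = list(pairs = "normal:SL,SL:tumor", merge_sl = TRUE,
                       adjust = FALSE),
    cnv = list(reference_stage = "normal", reference_cell_type = NULL,
               window = 101, cap = 3, gain_thr = 0.1, loss_thr = 0.1),
    score = list(gmt = NULL, n_bins = 25, n_ctrl = 100),
    continuum = list(target_subtype = "SLC1", reference_stage = "normal",
                     alpha = 0.05, min_samples = 2, axis = "PC2",
                     min_cells = 10, min_pct = 0.05, method = "hurdle")
  )
}

# merge user config over defaults, collecting unknown-key errors
merge_config <- function(user, defaults, path = "") {
  errors <- character()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    errors <- paste0("unknown config key(s): ",
                     paste0(if (nzchar(path)) paste0(path, ".") else "", unknown,
                            collapse = ", "))
  }
  out <- defaults
  for (k in intersect(names(user), names(defaults))) {
    sub_path <- if (nzchar(path)) paste0(path, ".", k) else k
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k %in% c("stages", "qc", "normalize", "composition", "cnv", "score",
                 "continuum", "simulate")) {
      m <- merge_config(user[[k]], defaults[[k]], sub_path)
      out[[k]] <- m$config
      errors <- c(errors, m$errors)
    } else {
      out[[k]] <- user[[k]]
    }
  }
  list(config = out, errors = errors)
}

#' Validate a pipeline run configuration
#'
#' Full schema and cross-field checks without executing any stage: unknown
#' keys are errors (no silent typo tolerance), numeric parameters must lie in
#' their valid ranges, and referenced input files must exist.
#'
#' @param config A list, or the path of a YAML file.
#' @return The merged (defaults-filled) configuration, invisibly, of class
#'   `run_config`. Errors list every violation at once.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  m <- merge_config(config, default_run_config())
  cfg <- m$config
  errors <- m$errors

  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  a <- cfg$continuum$alpha
  chk(is.numeric(a) && length(a) == 1 && a > 0 && a <= 1,
      "continuum.alpha must be in (0, 1]")
  ms <- cfg$continuum$min_samples
  chk(is.numeric(ms) && length(ms) == 1 && ms >= 1,
      "continuum.min_samples must be >= 1")
  chk(cfg$continuum$axis %in% c("PC2", "position"),
      "continuum.axis must be 'PC2' or 'position'")
  w <- cfg$cnv$window
  chk(is.numeric(w) && w >= 3 && w %% 2 == 1, "cnv.window must be an odd integer >= 3")
  chk(cfg$cnv$cap > 0, "cnv.cap must be > 0")
  chk(cfg$cnv$gain_thr >= 0 && cfg$cnv$loss_thr >= 0,
      "cnv thresholds must be nonnegative")
  chk(cfg$qc$min_genes >= 0, "qc.min_genes must be >= 0")
  chk(cfg$qc$max_mito_pct >= 0 && cfg$qc$max_mito_pct <= 100,
      "qc.max_mito_pct must be in [0, 100]")
  chk(cfg$normalize$scale > 0, "normalize.scale must be > 0")
  chk(cfg$score$n_bins >= 2, "score.n_bins must be >= 2")
  chk(cfg$score$n_ctrl >= 1, "score.n_ctrl must be >= 1")
  if (!isTRUE(cfg$stages$simulate)) {
    chk(!is.null(cfg$input) && dir.exists(cfg$input),
        "input directory must exist when the simulate stage is disabled")
  }
  if (!is.null(cfg$score$gmt)) {
    chk(file.exists(cfg$score$gmt), paste0("score.gmt file not found: ", cfg$score$gmt))
  }
  if (length(errors)) {
    abort(paste0("invalid run configuration:\n  - ",
                 paste(errors, collapse = "\n  - ")))
  }
  invisible(structure(cfg, class = "run_config"))
}

provenance_lines <- function(cfg, stage, params) {
  c(sprintf("# slcontinuum %s", as.character(utils::packageVersion("slcontinuum"))),
    sprintf("# stage=%s seed=%d", stage, cfg$seed),
    sprintf("# %s", paste(names(params), unlist(lapply(params, function(p)
      paste(format(p, digits = 10), collapse = ","))), sep = "=", collapse = " ")))
}

write_result_tsv <- function(df, path, cfg, stage, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(cfg, stage, params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> qc -> normalize -> composition -> cnv ->
#' score -> continuum in dependency order, writing provenance-headed TSV
#' result tables plus `report.json` into the output directory. A failing
#' stage halts its dependents but a partial report is still written. One
#' global seed is fanned out into a named substream per stage, so toggling a
#' stage never perturbs another stage's randomness, and re-running with an
#' unchanged configuration rewrites byte-identical result tables.
#'
#' @param config Run configuration: a list or YAML path; see
#'   [validate_run_config()].
#' @param out_dir Optional override of the configured output directory.
#' @return The run report, invisibly: per-stage status and parameters, output
#'   file digests, and headline metrics (cells kept, genes selected, and the
#'   continuum-truth Spearman correlation when planted truth is available).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_run_config(if (inherits(config, "run_config")) unclass(config) else config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("slcontinuum")),
    seed = cfg$seed,
    stages = list(), outputs = list(), metrics = list()
  )
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logit <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    message(msg)
  }

  stage_status <- function(name, status, params = NULL) {
    report$stages[[name]] <<- list(status = status, params = params)
  }
  run_stage <- function(name, enabled, deps_ok, params, fun) {
    if (!enabled) {
      stage_status(name, "skipped", params)
      logit("stage ", name, ": skipped (disabled)")
      return(NULL)
    }
    if (!deps_ok) {
      stage_status(name, "skipped_dependency", params)
      logit("stage ", name, ": skipped (failed dependency)")
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) {
      stage_status(name, paste0("failed: ", conditionMessage(e)), params)
      logit("stage ", name, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      stage_status(name, "done", params)
      logit("stage ", name, ": done")
    }
    res
  }

  # -- data: simulate or load -------------------------------------------
  truth <- NULL
  sim_res <- run_stage("simulate", isTRUE(cfg$stages$simulate), TRUE, cfg$simulate, function() {
    sc <- cfg$simulate
    config_obj <- sim_config(
      n_samples_per_stage = unlist(sc$n_samples_per_stage),
      n_cells_per_sample = sc$n_cells_per_sample,
      n_genes = sc$n_genes,
      n_continuum_genes = sc$n_continuum_genes,
      slope_range = unlist(sc$slope_range),
      progression_scores = if (identical(sc$progression_scores, "auto")) "auto"
                           else unlist(sc$progression_scores),
      cnv_segments = sc$cnv_segments,
      program_defs = sc$program_defs,
      cell_type_props = unlist(sc$cell_type_props),
      baseline_mean_lognormal = unlist(sc$baseline_mean_lognormal),
      nb_dispersion = sc$nb_dispersion,
      libsize_lognormal = unlist(sc$libsize_lognormal),
      seed = derive_seed(cfg$seed, "simulate")
    )
    sim <- simulate_dataset(config_obj)
    write_dataset(sim$dataset, file.path(cfg$out_dir, "dataset"), truth = sim$truth)
    sim
  })
  dataset <- if (!is.null(sim_res)) {
    truth <- sim_res$truth
    sim_res$dataset
  } else if (!isTRUE(cfg$stages$simulate) && !is.null(cfg$input)) {
    ds <- read_counts(cfg$input)
    tp <- file.path(cfg$input, "truth.json")
    if (file.exists(tp)) truth <- read_truth(tp)
    ds
  } else {
    NULL
  }

  # -- qc + normalization -----------------------------------------------
  norm <- run_stage("qc", isTRUE(cfg$stages$qc) || TRUE, !is.null(dataset),
                    c(cfg$qc, cfg$normalize), function() {
    d <- if (isTRUE(cfg$stages$qc)) {
      qc_filter(dataset, min_genes = cfg$qc$min_genes,
                max_mito_pct = cfg$qc$max_mito_pct,
                mito_prefix = cfg$qc$mito_prefix)
    } else {
      dataset
    }
    report$metrics$n_cells_kept <<- nrow(d$counts)
    normalize_counts(d, scale = cfg$normalize$scale)
  })

  # -- composition --------------------------------------------------------
  run_stage("composition", isTRUE(cfg$stages$composition), !is.null(norm),
            cfg$composition, function() {
    prop <- proportions_by_sample(norm$cells)
    tests <- composition_tests(prop, cfg$composition$pairs,
                               merge_sl = isTRUE(cfg$composition$merge_sl),
                               adjust = isTRUE(cfg$composition$adjust))
    write_result_tsv(prop, file.path(cfg$out_dir, "proportions.tsv"),
                     cfg, "composition")
    write_result_tsv(tests, file.path(cfg$out_dir, "composition_tests.tsv"),
                     cfg, "composition", cfg$composition["pairs"])
    TRUE
  })

  # -- cnv ----------------------------------------------------------------
  run_stage("cnv", isTRUE(cfg$stages$cnv), !is.null(norm), cfg$cnv, function() {
    p <- cfg$cnv
    ref <- cells_matching(norm$cells, stage = p$reference_stage,
                          cell_type = p$reference_cell_type)
    centered <- relative_expression(norm, ref, cap = p$cap)
    profile <- smooth_by_position(centered, window = min(p$window, make_odd(ncol(norm$values))))
    scores <- cnv_score(profile)
    arms <- arm_events(profile, gain_thr = p$gain_thr, loss_thr = p$loss_thr)
    kw <- score_group_test(scores, "stage")
    write_result_tsv(scores, file.path(cfg$out_dir, "cnv_scores.tsv"), cfg, "cnv", p)
    write_result_tsv(arms, file.path(cfg$out_dir, "arm_events.tsv"), cfg, "cnv", p)
    report$metrics$cnv_stage_kruskal_p <<- kw$p_value
    TRUE
  })

  # -- module scoring -----------------------------------------------------
  run_stage("score", isTRUE(cfg$stages$score), !is.null(norm), cfg$score, function() {
    sets <- if (!is.null(cfg$score$gmt)) {
      read_gmt(cfg$score$gmt)
    } else if (!is.null(truth) && nrow(truth$programs)) {
      tibble(set = truth$programs$program, description = "planted program",
             genes = truth$programs$genes)
    } else {
      abort("no gene sets: supply score.gmt or simulated truth with programs")
    }
    scores <- module_scores(norm, sets, n_bins = cfg$score$n_bins,
                            n_ctrl = cfg$score$n_ctrl,
                            seed = derive_seed(cfg$seed, "score"))
    write_result_tsv(scores, file.path(cfg$out_dir, "module_scores.tsv"),
                     cfg, "score", cfg$score[c("n_bins", "n_ctrl")])
    if (all(c("S", "G2M") %in% scores$program)) {
      phases <- assign_phase(scores)
      write_result_tsv(phases, file.path(cfg$out_dir, "phases.tsv"), cfg, "score")
    }
    TRUE
  })

  # -- continuum ----------------------------------------------------------
  run_stage("continuum", isTRUE(cfg$stages$continuum), !is.null(norm),
            cfg$continuum, function() {
    p <- cfg$continuum
    mc <- malignant_continuum(norm, p$target_subtype,
                              reference_stage = p$reference_stage,
                              alpha = p$alpha, min_samples = p$min_samples,
                              axis = p$axis, min_cells = p$min_cells,
                              min_pct = p$min_pct, method = p$method)
    write_result_tsv(mc$profile, file.path(cfg$out_dir, "log2fc_profiles.tsv"),
                     cfg, "continuum", p)
    write_result_tsv(tidy(mc), file.path(cfg$out_dir, "continuum_positions.tsv"),
                     cfg, "continuum", p)
    write_result_tsv(mc$trends, file.path(cfg$out_dir, "gene_trends.tsv"),
                     cfg, "continuum", p)
    jsonlite::write_json(list(curve = mc$fit$curve,
                              converged = mc$fit$converged,
                              n_iter = mc$fit$n_iter),
                         file.path(cfg$out_dir, "curve.json"),
                         auto_unbox = TRUE, digits = NA)
    report$metrics$n_genes_selected <<- length(mc$selected_genes)
    if (!is.null(truth)) {
      pos <- tidy(mc)
      s <- setNames(truth$samples$s_true, truth$samples$sample_id)
      report$metrics$continuum_truth_spearman <<-
        unname(cor(pos$position, s[pos$sample_id], method = "spearman"))
    }
    TRUE
  })

  # -- report -------------------------------------------------------------
  outs <- setdiff(list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE),
                  c(log_path, file.path(cfg$out_dir, "report.json")))
  report$outputs <- as.list(tools::md5sum(outs))
  names(report$outputs) <- substring(names(report$outputs), nchar(cfg$out_dir) + 2)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}

make_odd <- function(n) if (n %% 2 == 0) n - 1L else n
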