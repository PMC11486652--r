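# tiny FNV-1a style hash of a deparsed object, for table header comments
param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_stamped_table <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d params=%s", as.integer(seed), hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_schema <- function() {
  list(
    seed = "integer", outdir = "character",
    sc = names(formals(sc_sim_params)),
    bulk = names(formals(bulk_sim_params)),
    preprocess = c("min_genes_per_cell", "max_genes_per_cell",
                   "min_cells_per_gene", "n_hvg", "n_pcs", "n_neighbors",
                   "resolution", "perplexity"),
    nmf = c("k", "n_runs", "density_threshold", "max_iter", "tol",
            "run_k_selection", "k_min", "k_max"),
    modules = c("mode", "n_meta", "top_n"),
    panels = c("contamination"),
    train = c("algorithms", "min_cindex"),
    associate = c("test", "cor_method", "alpha"),
    skip = c("preprocess", "nmf", "train", "associate")
  )
}

validate_config <- function(config) {
  schema <- pipeline_schema()
  bad <- setdiff(names(config), names(schema))
  abort_if(length(bad) > 0,
           sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  for (sec in intersect(names(config), c("sc", "bulk", "preprocess", "nmf",
                                         "modules", "panels", "train",
                                         "associate", "skip"))) {
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    abort_if(length(bad) > 0,
             sprintf("unknown config key(s) under '%s': %s", sec,
                     paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' The bundled small-scale demonstration configuration
#'
#' Problem sizes are chosen so the full pipeline finishes in a few minutes
#' on one CPU while every stage still has planted signal to recover.
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, outdir = tempfile("lnmeta_run_")) {
  list(
    seed = as.integer(seed), outdir = outdir,
    sc = list(n_cells = 500, n_genes = 300, n_cell_types = 3, n_programs = 4,
              markers_per_type = 15, genes_per_program = 20,
              program_activity_fraction = 0.3, effect_log2fc = 2,
              lib_size_mean = 2000, nb_dispersion = 10),
    bulk = list(n_cohorts = 4, samples_per_arm = 30, n_genes = 300,
                delta = 1.5, gfr_beta = 1, stage_beta = 1.5, noise_sd = 1,
                cohort_shift_sd = 0.5),
    preprocess = list(min_genes_per_cell = 10, max_genes_per_cell = NULL,
                      min_cells_per_gene = 3, n_hvg = 200, n_pcs = 10,
                      n_neighbors = 15, resolution = 1.0, perplexity = 30),
    nmf = list(k = 4, n_runs = 6, density_threshold = 0.5, max_iter = 150,
               tol = 1e-4, run_k_selection = FALSE, k_min = 4, k_max = 9),
    modules = list(mode = "stop", n_meta = 4, top_n = 50),
    panels = list(contamination = 0.2),
    train = list(algorithms = c("lasso", "glmboost", "rf", "lda",
                                "naive_bayes"),
                 min_cindex = NULL),
    associate = list(test = "ranksum", cor_method = "spearman",
                     alpha = 0.05)
  )
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> preprocess -> consensus NMF -> module assignment ->
#' meta-programs -> feature panels -> selector x classifier training ->
#' clinical associations, writing stamped TSV tables, GMT files and a JSON
#' run manifest under `config$outdir`. Identical config and seed reproduce
#' identical tables.
#'
#' @param config a config list (see [demo_config()]) or a path to a YAML
#'   file with the same structure.
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% tempfile("lnmeta_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- param_hash(config[setdiff(names(config), "outdir")])
  skip <- config$skip %||% list()
  log_info <- function(...) message(sprintf(...))

  # ---- simulate -----------------------------------------------------------
  sc_par <- do.call(sc_sim_params, c(config$sc %||% list(),
                                     list(seed = derive_seed(seed, 1L))))
  sim <- generate_sc_dataset(sc_par)
  signal_genes <- sim$truth$program_gene_sets[[1]]
  bulk_args <- c(config$bulk %||% list(),
                 list(seed = derive_seed(seed, 2L)))
  if (is.null(bulk_args$signal_genes)) bulk_args$signal_genes <- signal_genes
  cohorts <- generate_bulk_cohorts(do.call(bulk_sim_params, bulk_args))
  log_info("simulated %d cells x %d genes and %d bulk cohorts",
           ncol(sim$counts$counts), nrow(sim$counts$counts), length(cohorts))

  pp <- config$preprocess %||% list()
  norm <- NULL; clusters <- NULL; markers <- NULL
  if (!isTRUE(skip$preprocess)) {
    filtered <- qc_filter(sim$counts,
                          min_genes_per_cell = pp$min_genes_per_cell %||% 200,
                          max_genes_per_cell = pp$max_genes_per_cell,
                          min_cells_per_gene = pp$min_cells_per_gene %||% 3)
    norm <- normalize_log(filtered)
    norm <- select_hvg(norm, min(pp$n_hvg %||% 2000, nrow(norm$values)))
    pca <- pca_embed(norm, n_components = min(pp$n_pcs %||% 30,
                                              min(dim(norm$values)) - 1L))
    clusters <- cluster_cells(pca$embedding,
                              n_neighbors = pp$n_neighbors %||% 15,
                              resolution = pp$resolution %||% 1.0,
                              seed = derive_seed(seed, 3L))
    clusters$embedding <- tsne_embed(
      pca$embedding,
      perplexity = min(pp$perplexity %||% 30,
                       floor((nrow(pca$embedding) - 2) / 3)),
      seed = derive_seed(seed, 4L))
    markers <- rank_markers(norm, clusters)
    log_info("preprocess: %d HVGs, %d clusters",
             nrow(norm$values), length(unique(clusters$labels)))
    write_stamped_table(markers, file.path(outdir, "markers.tsv"), seed, hash)
  }

  # ---- consensus NMF ------------------------------------------------------
  nmf_cfg <- config$nmf %||% list()
  cp <- NULL; diag_tab <- NULL; metaprograms <- NULL; modules <- NULL
  if (!isTRUE(skip$nmf)) {
    X <- prepare_matrix(norm %||% normalize_log(sim$counts))
    if (isTRUE(nmf_cfg$run_k_selection)) {
      kd <- k_selection_diagnostics(X, k_min = nmf_cfg$k_min %||% 4,
                                    k_max = nmf_cfg$k_max %||% 9,
                                    n_runs = nmf_cfg$n_runs %||% 10,
                                    density_threshold =
                                      nmf_cfg$density_threshold %||% 0.5,
                                    seed = derive_seed(seed, 5L),
                                    max_iter = nmf_cfg$max_iter %||% 200,
                                    tol = nmf_cfg$tol %||% 1e-4)
      diag_tab <- kd$table
      write_stamped_table(diag_tab, file.path(outdir, "k_diagnostics.tsv"),
                          seed, hash)
      log_info("k-selection suggests k = %d", kd$suggested_k)
    }
    cp <- consensus_factorize(X, k = nmf_cfg$k %||% 4,
                              n_runs = nmf_cfg$n_runs %||% 30,
                              density_threshold =
                                nmf_cfg$density_threshold %||% 0.5,
                              seed = derive_seed(seed, 6L),
                              max_iter = nmf_cfg$max_iter %||% 200,
                              tol = nmf_cfg$tol %||% 1e-4)
    log_info("consensus NMF: k = %d, kept %d/%d components, rel. error %.3f",
             cp$k, cp$kept_components, cp$n_runs * cp$k, cp$rel_error)
    write_stamped_table(
      data.frame(program = rownames(cp$consensus_spectra),
                 cp$consensus_spectra, check.names = FALSE),
      file.path(outdir, "consensus_spectra.tsv"), seed, hash)
    write_stamped_table(
      data.frame(cell = rownames(cp$refit_usages), cp$refit_usages,
                 check.names = FALSE),
      file.path(outdir, "usages.tsv"), seed, hash)

    mod_cfg <- config$modules %||% list()
    modules <- assign_disjoint_modules(cp$consensus_spectra,
                                       mode = mod_cfg$mode %||% "stop")
    mod_sets <- stats::setNames(lapply(modules, `[[`, "genes"),
                                vapply(modules, `[[`, "", "factor_id"))
    mod_sets <- mod_sets[lengths(mod_sets) > 0]
    write_gmt(mod_sets, file.path(outdir, "modules.gmt"))

    corr <- correlate_programs(list(consensus = cp$consensus_spectra))
    metaprograms <- cluster_into_metaprograms(
      corr, n_meta = min(mod_cfg$n_meta %||% 4, nrow(corr)),
      top_n = mod_cfg$top_n %||% 50,
      spectra_collection = list(consensus = cp$consensus_spectra))
    mp_sets <- stats::setNames(lapply(metaprograms, `[[`, "top_genes"),
                               vapply(metaprograms, `[[`, "", "mp_id"))
    write_gmt(mp_sets, file.path(outdir, "metaprograms.gmt"))
    log_info("assigned %d nonoverlapping modules; %d meta-programs",
             length(mod_sets), length(metaprograms))
  }

  # ---- panels + training --------------------------------------------------
  leaderboard <- NULL; panels <- NULL
  if (!isTRUE(skip$train) && !is.null(metaprograms)) {
    gsc <- generate_gene_set_collection(
      sim$truth, contamination = (config$panels %||% list())$contamination %||% 0,
      seed = derive_seed(seed, 7L))
    write_gmt(gsc, file.path(outdir, "gene_sets.gmt"))
    harmonized <- harmonize_cohorts(cohorts)
    bulk_genes <- colnames(harmonized[[1]]$expression)
    # cross every meta-program with every curated set; validation scoring
    # ranks the combinations, so the disease-relevant panel is discovered
    panels <- unlist(lapply(metaprograms, function(mp) {
      lapply(names(gsc), function(nm) {
        intersect_panel(mp, intersect(gsc[[nm]], bulk_genes),
                        set_name = nm)
      })
    }), recursive = FALSE)
    panels <- Filter(function(p) p$usable, panels)
    train_cfg <- config$train %||% list()
    registry <- default_algorithm_registry()
    if (!is.null(train_cfg$algorithms)) {
      registry <- registry[registry$name %in% train_cfg$algorithms, ,
                           drop = FALSE]
    }
    tr <- Filter(function(co) co$role == "train", harmonized)
    va <- Filter(function(co) co$role == "validation", harmonized)
    results <- list()
    for (p in panels) {
      specs <- enumerate_combinations(registry, p)
      for (i in seq_along(specs)) {
        results[[length(results) + 1L]] <-
          fit_and_score(specs[[i]], tr, va,
                        seed = derive_seed(seed, 8000L + length(results)))
      }
    }
    leaderboard <- build_leaderboard(results,
                                     min_cindex = train_cfg$min_cindex)
    log_info("trained %d models over %d panel(s); best validation C-index %.3f",
             length(results), length(panels),
             max(leaderboard$mean_validation_cindex, na.rm = TRUE))
    write_stamped_table(leaderboard, file.path(outdir, "leaderboard.tsv"),
                        seed, hash)
  }

  # ---- clinical associations ----------------------------------------------
  assoc <- NULL; gfr_tab <- NULL; stage_tab <- NULL; ora_tab <- NULL
  if (!isTRUE(skip$associate)) {
    as_cfg <- config$associate %||% list()
    genes <- intersect(signal_genes, colnames(cohorts[[1]]$expression))
    assoc <- do.call(rbind, lapply(cohorts, function(co) {
      case_control_test(co, genes, test = as_cfg$test %||% "ranksum")
    }))
    gfr_tab <- do.call(rbind, lapply(cohorts, function(co) {
      do.call(rbind, lapply(genes, function(g) {
        ct <- correlate_clinical(co$expression[, g], co$gfr,
                                 method = as_cfg$cor_method %||% "spearman")
        data.frame(gene = g, cohort_id = co$cohort_id, r = ct$r, p = ct$p,
                   stringsAsFactors = FALSE)
      }))
    }))
    st <- compare_stages(cohorts[[1]]$expression[, genes[1]],
                         cohorts[[1]]$stage)
    stage_tab <- st$pairwise
    stage_tab$gene <- genes[1]
    stage_tab$trend_statistic <- st$trend$statistic
    if (!is.null(modules)) {
      gsc <- generate_gene_set_collection(sim$truth, contamination = 0,
                                          seed = derive_seed(seed, 7L))
      ora_tab <- ora_hypergeometric(modules[[1]]$genes, gsc,
                                    universe = sim$truth$program_spectra |>
                                      colnames())
    }
    write_stamped_table(assoc, file.path(outdir, "associations.tsv"),
                        seed, hash)
    write_stamped_table(gfr_tab, file.path(outdir, "gfr_correlations.tsv"),
                        seed, hash)
    write_stamped_table(stage_tab, file.path(outdir, "stage_comparisons.tsv"),
                        seed, hash)
    if (!is.null(ora_tab)) {
      write_stamped_table(ora_tab, file.path(outdir, "ora.tsv"), seed, hash)
    }
    log_info("associations: %d/%d gene-cohort tests at p_adj < %.2f",
             sum(assoc$p_adj < (as_cfg$alpha %||% 0.05)), nrow(assoc),
             as_cfg$alpha %||% 0.05)
  }

  files <- list.files(outdir, recursive = TRUE)
  manifest <- list(
    tool = "lnmeta",
    version = as.character(utils::packageVersion("lnmeta")),
    master_seed = seed,
    param_hash = hash,
    config = config[setdiff(names(config), "outdir")],
    derived_seeds = stats::setNames(
      as.list(vapply(1:8, function(i) derive_seed(seed, i), integer(1))),
      c("sc", "bulk", "cluster", "tsne", "k_selection", "consensus",
        "gene_sets", "train_base")),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, sim = sim, cohorts = cohorts,
                 norm = norm, clusters = clusters, markers = markers,
                 consensus = cp, k_diagnostics = diag_tab,
                 modules = modules, metaprograms = metaprograms,
                 panels = panels, leaderboard = leaderboard,
                 associations = assoc, gfr = gfr_tab, stages = stage_tab,
                 ora = ora_tab, outdir = outdir))
}

#' Reference bookkeeping for the four curated pathway gene groups
#'
#' The per-group counts of retained predictive models and the curated set
#' sizes for the MTOR-signaling, autophagy, Toll-like-receptor and
#' adaptive-immune-system gene groups, shipped as package data so the
#' model-count arithmetic (the per-group counts summing to the full suite)
#' can be checked reproducibly.
#'
#' @return data frame with `group`, `models`, `set_size`.
#' @export
reported_model_counts <- function() {
  path <- system.file("extdata", "reported_model_counts.tsv",
                      package = "lnmeta")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
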