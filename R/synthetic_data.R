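#' Parameters for the single-cell count simulator
#'
#' The simulator plants two kinds of structure in a negative-binomial count
#' matrix: discrete cell types (via disjoint marker-gene blocks) and shared
#' activity programs (via disjoint program-gene blocks whose expression is
#' gated on a per-cell binary activity state). Program spectra are recoverable
#' by non-negative matrix factorization, which is what downstream recovery
#' tests exploit.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_cell_types number of discrete cell types.
#' @param n_programs number of planted activity programs (the true K).
#' @param markers_per_type marker genes per cell type (blocks are disjoint).
#' @param genes_per_program genes per program (disjoint from each other and
#'   from marker blocks).
#' @param program_activity_fraction fraction of cells in (0,1) in which each
#'   program is active.
#' @param effect_log2fc elevation of marker/program genes, in log2 fold-change
#'   units, for a cell carrying the type / an active program at unit usage.
#' @param lib_size_mean mean library size (total counts per cell).
#' @param nb_dispersion negative-binomial size parameter; larger is closer to
#'   Poisson.
#' @param seed master seed; all randomness derives from it.
#' @return a validated parameter list of class `sc_sim_params`.
#' @export
sc_sim_params <- function(n_cells = 2000, n_genes = 1000, n_cell_types = 4,
                          n_programs = 4, markers_per_type = 25,
                          genes_per_program = 30,
                          program_activity_fraction = 0.3,
                          effect_log2fc = 2, lib_size_mean = 2000,
                          nb_dispersion = 10, seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
            n_cell_types = as.integer(n_cell_types),
            n_programs = as.integer(n_programs),
            markers_per_type = as.integer(markers_per_type),
            genes_per_program = as.integer(genes_per_program),
            program_activity_fraction = program_activity_fraction,
            effect_log2fc = effect_log2fc, lib_size_mean = lib_size_mean,
            nb_dispersion = nb_dispersion, seed = as.integer(seed))
  counts <- c("n_cells", "n_genes", "n_cell_types", "n_programs",
              "markers_per_type", "genes_per_program")
  abort_if(any(vapply(p[counts], function(x) x < 1L, logical(1))),
           "all count parameters must be >= 1")
  abort_if(p$program_activity_fraction <= 0 || p$program_activity_fraction >= 1,
           "program_activity_fraction must lie strictly in (0, 1)")
  abort_if(p$effect_log2fc < 0, "effect_log2fc must be nonnegative")
  abort_if(p$lib_size_mean <= 0 || p$nb_dispersion <= 0,
           "lib_size_mean and nb_dispersion must be positive")
  needed <- p$n_cell_types * p$markers_per_type +
    p$n_programs * p$genes_per_program
  abort_if(needed > p$n_genes,
           sprintf("disjoint marker + program blocks need %d genes but n_genes = %d",
                   needed, p$n_genes))
  structure(p, class = "sc_sim_params")
}

#' Simulate a single-cell count matrix with planted types and programs
#'
#' Counts are negative binomial with per-cell mean
#' `lib_size * softmax(log-baseline + marker elevation + usage %*% spectra)`.
#' Gene baselines are log-normal; library sizes are log-normal around
#' `lib_size_mean`. Program activity is binary-gated: a cell either carries a
#' Gamma-distributed usage for a program or exactly zero, which gives NMF a
#' block structure to recover.
#'
#' @param params an [sc_sim_params()] object.
#' @return a list with `counts` (a [count_matrix()]) and `truth`, a list of
#'   class `sc_truth` holding `type_labels`, `program_usage` (cells x K),
#'   `program_spectra` (K x genes, the planted log-scale elevations),
#'   `marker_sets` and `program_gene_sets`.
#' @export
generate_sc_dataset <- function(params) {
  stopifnot(inherits(params, "sc_sim_params"))
  p <- params
  gene_ids <- sprintf("g%04d", seq_len(p$n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(p$n_cells))

  # disjoint blocks: markers first, then program genes
  idx <- seq_len(p$n_genes)
  marker_sets <- vector("list", p$n_cell_types)
  pos <- 0L
  for (t in seq_len(p$n_cell_types)) {
    marker_sets[[t]] <- gene_ids[pos + seq_len(p$markers_per_type)]
    pos <- pos + p$markers_per_type
  }
  names(marker_sets) <- sprintf("type%d", seq_len(p$n_cell_types))
  program_gene_sets <- vector("list", p$n_programs)
  for (k in seq_len(p$n_programs)) {
    program_gene_sets[[k]] <- gene_ids[pos + seq_len(p$genes_per_program)]
    pos <- pos + p$genes_per_program
  }
  names(program_gene_sets) <- sprintf("program%d", seq_len(p$n_programs))

  eff <- p$effect_log2fc * log(2)

  # moderate baseline spread: programs, not per-gene scale, must carry the
  # dominant variance structure for the planted K to be identifiable
  set.seed(derive_seed(p$seed, 0L))
  log_baseline <- stats::rnorm(p$n_genes, mean = 0, sd = 0.5)

  set.seed(derive_seed(p$seed, 1L))
  type_labels <- sample(rep_len(seq_len(p$n_cell_types), p$n_cells))

  # planted spectra: program k elevates its block by eff per unit usage
  spectra <- matrix(0, p$n_programs, p$n_genes,
                    dimnames = list(names(program_gene_sets), gene_ids))
  for (k in seq_len(p$n_programs)) spectra[k, program_gene_sets[[k]]] <- eff

  usage <- matrix(0, p$n_cells, p$n_programs,
                  dimnames = list(cell_ids, names(program_gene_sets)))
  for (k in seq_len(p$n_programs)) {
    set.seed(derive_seed(p$seed, 10L + k))
    n_active <- max(1L, round(p$program_activity_fraction * p$n_cells))
    active <- sample.int(p$n_cells, n_active)
    usage[active, k] <- stats::rgamma(n_active, shape = 2, scale = 0.5)
  }
  # every cell expresses at least one program: a leukocyte is always in some
  # transcriptional state, and full coverage is what makes the planted K the
  # effective NMF rank (no pure-background component competes)
  idle <- which(rowSums(usage) == 0)
  if (length(idle) > 0) {
    set.seed(derive_seed(p$seed, 10L))
    forced <- sample.int(p$n_programs, length(idle), replace = TRUE)
    usage[cbind(idle, forced)] <- stats::rgamma(length(idle), shape = 2,
                                                scale = 0.5)
  }

  # per-cell log-rate: baseline + type markers + program activity
  eta <- matrix(log_baseline, p$n_genes, p$n_cells)
  marker_col <- lapply(marker_sets, function(g) match(g, gene_ids))
  for (t in seq_len(p$n_cell_types)) {
    cells_t <- which(type_labels == t)
    eta[marker_col[[t]], cells_t] <- eta[marker_col[[t]], cells_t] + eff
  }
  eta <- eta + t(usage %*% spectra)

  # narrow library-size spread keeps counts near the pure NB/Poisson
  # marginal (variance/mean -> 1 as dispersion grows) instead of adding a
  # dominant depth dimension on top of the planted structure
  set.seed(derive_seed(p$seed, 2L))
  lib_size <- stats::rlnorm(p$n_cells, meanlog = log(p$lib_size_mean) - 0.1^2 / 2,
                            sdlog = 0.1)

  # softmax over genes within each cell, then NB sampling
  pm <- exp(sweep(eta, 2L, apply(eta, 2L, max)))
  pm <- sweep(pm, 2L, colSums(pm), "/")
  mu <- sweep(pm, 2L, lib_size, "*")
  set.seed(derive_seed(p$seed, 3L))
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = p$nb_dispersion),
                   p$n_genes, p$n_cells, dimnames = list(gene_ids, cell_ids))

  meta <- data.frame(cell_id = cell_ids,
                     sample = sprintf("s%02d", (seq_len(p$n_cells) %% 8L) + 1L),
                     group = ifelse(type_labels %% 2L == 0L, "LN", "control"),
                     type = sprintf("type%d", type_labels),
                     stringsAsFactors = FALSE)
  truth <- structure(list(type_labels = sprintf("type%d", type_labels),
                          program_usage = usage,
                          program_spectra = spectra,
                          marker_sets = marker_sets,
                          program_gene_sets = program_gene_sets),
                     class = "sc_truth")
  list(counts = count_matrix(counts, cell_meta = meta), truth = truth)
}

#' Parameters for the bulk case/control cohort simulator
#'
#' @param n_cohorts number of cohorts (first half train, second half
#'   validation).
#' @param samples_per_arm cases and controls per cohort (>= 3).
#' @param n_genes gene universe size.
#' @param signal_genes character vector of genes carrying the disease signal;
#'   must be a subset of the universe `g0001..`.
#' @param delta case-minus-control shift on signal genes, in noise-SD units.
#' @param gfr_beta strength of the negative coupling between the disease score
#'   and the glomerular filtration rate (GFR, mL/min/1.73 m^2).
#' @param stage_beta ordinal pathological-class coupling (proportional odds on
#'   the disease score).
#' @param noise_sd residual SD of expression values.
#' @param cohort_shift_sd SD of the per-cohort, per-gene batch offset.
#' @param seed master seed.
#' @export
bulk_sim_params <- function(n_cohorts = 4, samples_per_arm = 30,
                            n_genes = 500,
                            signal_genes = sprintf("g%04d", 1:30),
                            delta = 1.5, gfr_beta = 1, stage_beta = 1.5,
                            noise_sd = 1, cohort_shift_sd = 0.5, seed = 1L) {
  p <- list(n_cohorts = as.integer(n_cohorts),
            samples_per_arm = as.integer(samples_per_arm),
            n_genes = as.integer(n_genes), signal_genes = signal_genes,
            delta = delta, gfr_beta = gfr_beta, stage_beta = stage_beta,
            noise_sd = noise_sd, cohort_shift_sd = cohort_shift_sd,
            seed = as.integer(seed))
  abort_if(p$n_cohorts < 1L, "n_cohorts must be >= 1")
  abort_if(p$samples_per_arm < 3L, "samples_per_arm must be >= 3")
  universe <- sprintf("g%04d", seq_len(p$n_genes))
  abort_if(!all(p$signal_genes %in% universe),
           "signal_genes must be a subset of the gene universe g0001..")
  abort_if(p$noise_sd <= 0, "noise_sd must be positive")
  abort_if(p$gfr_beta < 0 || p$stage_beta < 0 || p$cohort_shift_sd < 0,
           "gfr_beta, stage_beta and cohort_shift_sd must be nonnegative")
  structure(p, class = "bulk_sim_params")
}

#' Simulate case/control bulk cohorts with clinical covariates
#'
#' Expression is generated on a log-like continuous scale: per cohort,
#' `baseline_g + batch offset + delta * label` on signal genes plus Gaussian
#' noise. Each sample carries a latent disease score (higher in cases); GFR is
#' negatively coupled to the score around a healthy baseline of
#' 100 mL/min/1.73 m^2, and the pathological class (II/III/IV, cases only) is
#' drawn from a proportional-odds model on the score.
#'
#' @param params a [bulk_sim_params()] object.
#' @return a list of cohorts; each element has class `bulk_cohort` with fields
#'   `cohort_id`, `expression` (samples x genes), `labels` (1 = case), `gfr`,
#'   `stage` (factor II/III/IV, `NA` for controls), `role`
#'   (train/validation), and `truth` (per-sample disease score).
#' @export
generate_bulk_cohorts <- function(params) {
  stopifnot(inherits(params, "bulk_sim_params"))
  p <- params
  universe <- sprintf("g%04d", seq_len(p$n_genes))
  set.seed(derive_seed(p$seed, 0L))
  baseline <- stats::rnorm(p$n_genes, 0, 1)
  names(baseline) <- universe
  n_train <- ceiling(p$n_cohorts / 2)

  lapply(seq_len(p$n_cohorts), function(ci) {
    set.seed(derive_seed(p$seed, 100L + ci))
    n <- 2L * p$samples_per_arm
    labels <- rep(c(0L, 1L), each = p$samples_per_arm)
    score <- labels + stats::rnorm(n, 0, 0.5)
    offset <- stats::rnorm(p$n_genes, 0, p$cohort_shift_sd)
    expr <- matrix(stats::rnorm(n * p$n_genes, 0, p$noise_sd), n, p$n_genes)
    expr <- sweep(expr, 2L, baseline + offset, "+")
    # signal genes track the continuous disease score (mean gap between
    # arms = delta), so severity gradients reach the stage/GFR couplings
    sig <- match(p$signal_genes, universe)
    expr[, sig] <- expr[, sig] + p$delta * score
    dimnames(expr) <- list(sprintf("c%d_s%03d", ci, seq_len(n)), universe)

    gfr <- 100 - 20 * p$gfr_beta * score + stats::rnorm(n, 0, 8)
    # proportional-odds draw of the ordinal class, cases only
    z <- p$stage_beta * score[labels == 1L] + stats::rlogis(p$samples_per_arm)
    stage_case <- cut(z, breaks = c(-Inf, 0.75, 2.0, Inf),
                      labels = c("II", "III", "IV"))
    stage <- factor(rep(NA_character_, n), levels = c("II", "III", "IV"))
    stage[labels == 1L] <- stage_case

    structure(list(cohort_id = sprintf("cohort%d", ci),
                   expression = expr, labels = labels, gfr = gfr,
                   stage = stage,
                   role = if (ci <= n_train) "train" else "validation",
                   truth = data.frame(sample_id = rownames(expr),
                                      score = score, label = labels,
                                      gfr = gfr, stage = stage,
                                      cohort_id = sprintf("cohort%d", ci),
                                      stringsAsFactors = FALSE)),
              class = "bulk_cohort")
  })
}

#' Build a gene-set collection from planted program truth
#'
#' One named set per planted program: its genes plus a fraction of random
#' decoy genes, mimicking curated pathway lists that contain the signal plus
#' unrelated members. Writable as GMT via [write_gmt()].
#'
#' @param truth an `sc_truth` object from [generate_sc_dataset()].
#' @param contamination decoy fraction in `[0, 1)`: `round(contamination *
#'   set size)` decoys are added per set.
#' @param seed integer seed.
#' @return named list of character vectors (a gene-set collection).
#' @export
generate_gene_set_collection <- function(truth, contamination = 0, seed = 1L) {
  stopifnot(inherits(truth, "sc_truth"))
  abort_if(contamination < 0 || contamination >= 1,
           "contamination must lie in [0, 1)")
  universe <- colnames(truth$program_spectra)
  sets <- truth$program_gene_sets
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (k in seq_along(sets)) {
    core <- sets[[k]]
    n_decoy <- round(contamination * length(core))
    decoys <- character(0)
    if (n_decoy > 0) {
      set.seed(derive_seed(seed, 200L + k))
      pool <- setdiff(universe, unlist(sets))
      decoys <- sample(pool, n_decoy)
    }
    out[[k]] <- c(core, decoys)
  }
  out
}
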