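#' Construct a genes x cells count matrix container
#'
#' @param counts genes x cells matrix of nonnegative integers with rownames
#'   (gene symbols) and colnames (cell barcodes); base or `Matrix` sparse.
#' @param cell_meta optional data frame keyed by `cell_id`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must carry gene rownames and cell colnames")
  abort_if(anyDuplicated(rownames(counts)) > 0, "duplicate gene ids")
  abort_if(anyDuplicated(colnames(counts)) > 0, "duplicate cell ids")
  abort_if(min(counts) < 0, "counts must be nonnegative")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts),
                            stringsAsFactors = FALSE)
  }
  abort_if(!identical(cell_meta$cell_id, colnames(counts)),
           "cell_meta$cell_id must match counts colnames in order")
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_ids = colnames(counts), cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate genes within a set are dropped with a warning; empty sets and
#' lines with fewer than three fields are rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors; set descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  abort_if(!file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    abort_if(length(f) < 3L,
             sprintf("malformed GMT line %d: fewer than 3 fields", i))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    abort_if(length(genes) == 0L,
             sprintf("empty gene set '%s' at line %d", f[[1]], i))
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' deduplicated", f[[1]]),
              call. = FALSE)
      genes <- unique(genes)
    }
    sets[[f[[1]]]] <- genes
    desc[[f[[1]]]] <- f[[2]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  abort_if(is.null(names(sets)) || any(!nzchar(names(sets))),
           "sets must be named")
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||%
      stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a count matrix as an MTX triplet plus name files
#'
#' Produces `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cell_meta.tsv`
#' under `dir` (MatrixMarket keeps its native 1-based convention).
#'
#' @param cm a [count_matrix()].
#' @param dir output directory, created if missing.
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(cm$counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()] or a dense TSV
#'
#' @param path for `mtx_triplet`, the directory holding `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv` (and optionally `cell_meta.tsv`); for
#'   `dense_tsv`, a genes x cells TSV with a header of cell ids and gene ids
#'   in the first column.
#' @param layout `"mtx_triplet"` or `"dense_tsv"`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, layout = c("mtx_triplet", "dense_tsv")) {
  layout <- match.arg(layout)
  if (layout == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) {
      abort_if(!file.exists(f), sprintf("expected companion file: %s", f))
    }
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(gf)
    cells <- readLines(bf)
    abort_if(nrow(m) != length(genes) || ncol(m) != length(cells),
             sprintf("dimension mismatch: matrix %dx%d vs %d genes, %d cells",
                     nrow(m), ncol(m), length(genes), length(cells)))
    abort_if(any(m != round(m)), "counts must be integers")
    dimnames(m) <- list(genes, cells)
    meta <- NULL
    mf <- file.path(path, "cell_meta.tsv")
    if (file.exists(mf)) {
      meta <- utils::read.delim(mf, stringsAsFactors = FALSE)
    }
    count_matrix(m, cell_meta = meta)
  } else {
    tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    bad <- which(!is.finite(m) | m != round(m), arr.ind = TRUE)
    abort_if(nrow(bad) > 0,
             sprintf("non-integer value at row %d, column %d",
                     bad[1, 1], bad[1, 2]))
    count_matrix(m)
  }
}

#' Write a bulk cohort as expression + phenotype TSV pair
#'
#' Expression is samples x genes with a gene-symbol header; the phenotype
#' table carries `sample_id`, `label` (0/1), `gfr`, `stage` (II/III/IV or NA)
#' and `cohort_id`.
#'
#' @param cohort a `bulk_cohort`.
#' @param dir output directory.
#' @export
write_bulk_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(sample_id = rownames(cohort$expression),
               cohort$expression, check.names = FALSE),
    file.path(dir, paste0(cohort$cohort_id, "_expression.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  pheno <- data.frame(sample_id = rownames(cohort$expression),
                      label = cohort$labels, gfr = cohort$gfr,
                      stage = as.character(cohort$stage),
                      cohort_id = cohort$cohort_id,
                      stringsAsFactors = FALSE)
  utils::write.table(pheno,
                     file.path(dir, paste0(cohort$cohort_id, "_phenotype.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bulk cohort written by [write_bulk_cohort()]
#'
#' @param dir directory holding the TSV pair.
#' @param cohort_id cohort identifier (file prefix).
#' @param role `"train"` or `"validation"`.
#' @return a `bulk_cohort`.
#' @export
read_bulk_cohort <- function(dir, cohort_id, role = "train") {
  ef <- file.path(dir, paste0(cohort_id, "_expression.tsv"))
  pf <- file.path(dir, paste0(cohort_id, "_phenotype.tsv"))
  abort_if(!file.exists(ef), sprintf("missing expression table: %s", ef))
  abort_if(!file.exists(pf), sprintf("missing phenotype table: %s", pf))
  etab <- utils::read.delim(ef, check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(etab[, -1, drop = FALSE])
  rownames(expr) <- etab$sample_id
  pheno <- utils::read.delim(pf, stringsAsFactors = FALSE)
  abort_if(!identical(pheno$sample_id, rownames(expr)),
           "phenotype sample ids do not match expression rows")
  structure(list(cohort_id = cohort_id, expression = expr,
                 labels = as.integer(pheno$label), gfr = pheno$gfr,
                 stage = factor(pheno$stage, levels = c("II", "III", "IV")),
                 role = role, truth = NULL),
            class = "bulk_cohort")
}
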