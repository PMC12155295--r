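STAGE_LEVELS <- c("I", "II", "III", "IV", "NAT")
TUMOR_STAGES <- c("I", "II", "III", "IV")

#' Staged expression matrix
#'
#' Container for a nonnegative genes x samples expression matrix (raw counts
#' or normalized units) with one pathological stage label per sample: AJCC
#' tumor stages I-IV, or NAT for normal adjacent tissue controls.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No negative values.
#' @param stages character vector of stage labels, one per column, each one
#'   of `"I", "II", "III", "IV", "NAT"`. May be named by sample id.
#' @return An object of class `staged_expression`: a list with elements
#'   `counts` and `stages` (named character vector).
#' @export
staged_expression <- function(counts, stages) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in matrix")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("expression values must be numeric and non-missing")
  }
  if (any(counts < 0)) stop("expression values must be nonnegative")
  stages <- as.character(stages)
  if (length(stages) != ncol(counts)) {
    stop("one stage label per sample required: ", length(stages),
         " labels for ", ncol(counts), " samples")
  }
  bad <- !(stages %in% STAGE_LEVELS)
  if (any(bad)) {
    stop("invalid stage label(s): ",
         paste(unique(stages[bad]), collapse = ", "),
         " (expected I, II, III, IV or NAT; see normalize_stage_label())")
  }
  structure(list(counts = counts,
                 stages = stats::setNames(stages, colnames(counts))),
            class = "staged_expression")
}

#' @export
print.staged_expression <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGE_LEVELS))
  cat("<staged_expression> ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples\n  samples per stage: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Library-size normalization (counts per `scale`)
#'
#' Scales every sample column so its total equals `scale` (counts-per-million
#' for the default `scale = 1e6`). Per-sample indices are invariant to this,
#' but across-sample averaging of expression (stage-mean aggregation) is not,
#' so profiles are computed on normalized columns.
#'
#' @param x a [staged_expression()].
#' @param scale positive target column total.
#' @return a [staged_expression()] with scaled columns.
#' @export
normalize_library <- function(x, scale = 1e6) {
  stopifnot(inherits(x, "staged_expression"), is.numeric(scale), scale > 0)
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("all-zero expression column(s): ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "))
  }
  x$counts <- sweep(x$counts, 2L, totals / scale, "/")
  x
}

#' Expression-weighted mean stratum of one sample
#'
#' The core phylotranscriptomic index: with `s_i` the stratum (phylostratum
#' for TAI, divergence decile for TDI) and `e_i` the expression of gene `i`,
#' returns `sum(s_i * e_i) / sum(e_i)` over the genes that carry a stratum
#' annotation. Unannotated genes are excluded; their count is available via
#' [compute_profile()]. The index is invariant to rescaling the expression
#' vector and always lies between the smallest and largest contributing
#' stratum.
#'
#' @param expr named nonnegative numeric vector of expression values
#'   (names = gene ids).
#' @param strata an [age_map()] or [rank_deciles()] result (any named
#'   integer stratum vector works).
#' @return the index value (a single number).
#' @examples
#' am <- age_map(c("g1", "g2"), c(1L, 3L))
#' compute_index_sample(c(g1 = 3, g2 = 1), am)  # (1*3 + 3*1) / 4 = 1.5
#' @export
compute_index_sample <- function(expr, strata) {
  if (is.null(names(expr))) stop("`expr` must be named by gene id")
  if (any(expr < 0)) stop("expression must be nonnegative")
  common <- intersect(names(expr), names(strata))
  e <- expr[common]
  s <- as.numeric(strata[common])
  tot <- sum(e)
  if (length(e) == 0L || tot <= 0) {
    stop("no annotated gene with positive expression in sample")
  }
  sum(s * e) / tot
}

#' Per-sample and per-stage index profile
#'
#' Computes the index for every sample and aggregates it per stage in one of
#' two ways: `"mean_expression"` (default) takes, per stage, the index of the
#' across-sample mean of the normalized expression columns — the index of the
#' stage's pooled transcriptome; `"mean_of_sample_indices"` averages the
#' per-sample index values, matching per-stage boxplot summaries. The two
#' agree only in special cases.
#'
#' Genes lacking a stratum annotation are dropped (never imputed) and counted
#' in `n_genes_dropped`.
#'
#' @param x a [staged_expression()].
#' @param strata an [age_map()] (TAI) or [rank_deciles()] strata (TDI).
#' @param aggregation `"mean_expression"` or `"mean_of_sample_indices"`.
#' @param normalize apply [normalize_library()] first (default TRUE; set
#'   FALSE if `x` is already in comparable units).
#' @param scale column total used when `normalize` is TRUE.
#' @param log_transform apply `log2(1 + e)` to (normalized) expression before
#'   computing indices. Off by default: raw relative expression mass weights
#'   the strata.
#' @return An object of class `index_profile`: list with `per_sample`
#'   (named numeric), `per_stage` (named numeric in stage order
#'   I, II, III, IV, NAT restricted to stages present), `index_kind`
#'   ("TAI", "TDI" or "index"), `aggregation`, `n_genes_used`,
#'   `n_genes_dropped`.
#' @export
compute_profile <- function(x, strata,
                            aggregation = c("mean_expression",
                                            "mean_of_sample_indices"),
                            normalize = TRUE, scale = 1e6,
                            log_transform = FALSE) {
  stopifnot(inherits(x, "staged_expression"))
  aggregation <- match.arg(aggregation)
  if (ncol(x$counts) == 0L) stop("no samples in expression matrix")
  if (normalize) x <- normalize_library(x, scale = scale)

  keep <- rownames(x$counts) %in% names(strata)
  n_used <- sum(keep)
  n_dropped <- nrow(x$counts) - n_used
  if (n_used == 0L) stop("no gene in the expression matrix has a stratum")
  mat <- x$counts[keep, , drop = FALSE]
  if (log_transform) mat <- log2(1 + mat)
  s <- as.numeric(strata[rownames(mat)])

  col_tot <- colSums(mat)
  if (any(col_tot <= 0)) {
    stop("no annotated gene with positive expression in sample(s): ",
         paste(colnames(mat)[col_tot <= 0], collapse = ", "))
  }
  per_sample <- as.numeric(crossprod(mat, s)) / col_tot
  names(per_sample) <- colnames(mat)

  stages_present <- STAGE_LEVELS[STAGE_LEVELS %in% x$stages]
  per_stage <- vapply(stages_present, function(st) {
    cols <- which(x$stages == st)
    if (aggregation == "mean_expression") {
      m <- rowMeans(mat[, cols, drop = FALSE])
      sum(s * m) / sum(m)
    } else {
      mean(per_sample[cols])
    }
  }, numeric(1))

  kind <- if (inherits(strata, "age_map")) "TAI"
          else if (inherits(strata, "divergence_strata")) "TDI"
          else "index"
  structure(list(per_sample = per_sample,
                 per_stage = per_stage,
                 index_kind = kind,
                 aggregation = aggregation,
                 n_genes_used = n_used,
                 n_genes_dropped = n_dropped),
            class = "index_profile")
}

#' @export
print.index_profile <- function(x, digits = 4, ...) {
  cat("<index_profile> ", x$index_kind, " (", x$aggregation, "), ",
      x$n_genes_used, " genes used, ", x$n_genes_dropped, " dropped\n",
      sep = "")
  print(round(x$per_stage, digits))
  invisible(x)
}
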