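#' Stage module definition for hourglass tests
#'
#' Partitions the ordered tumor stages into early / mid / late modules. The
#' default mirrors the usual reading of tumor progression profiles: early =
#' stage I, mid = stages II and III, late = stage IV. The three sets must be
#' disjoint and non-empty, and together they must cover every tumor stage in
#' the profile being tested (checked at test time).
#'
#' @param early,mid,late character vectors of stage labels from
#'   `"I", "II", "III", "IV"`.
#' @return an object of class `stage_modules`.
#' @export
stage_modules <- function(early = "I", mid = c("II", "III"), late = "IV") {
  mods <- list(early = as.character(early), mid = as.character(mid),
               late = as.character(late))
  all_st <- unlist(mods, use.names = FALSE)
  if (any(lengths(mods) == 0L)) stop("every stage module must be non-empty")
  if (!all(all_st %in% TUMOR_STAGES)) {
    stop("stage modules may only contain tumor stages I-IV, got: ",
         paste(setdiff(all_st, TUMOR_STAGES), collapse = ", "))
  }
  if (anyDuplicated(all_st)) stop("stage modules must be disjoint")
  structure(mods, class = "stage_modules")
}

# Per-stage values restricted to tumor stages, from a named vector or an
# index_profile. NAT never enters a pattern statistic.
tumor_profile <- function(per_stage) {
  if (inherits(per_stage, "index_profile")) per_stage <- per_stage$per_stage
  per_stage[names(per_stage) %in% TUMOR_STAGES]
}

#' Flat-line statistic of a stage profile
#'
#' Dispersion of the index values across ordered tumor stages, used to test
#' deviation from a flat (no-pattern) profile. The statistic is the
#' population variance of the per-stage values — monotone-equivalent to
#' their standard deviation, so the permutation p-value is identical.
#'
#' @param per_stage named numeric vector of per-stage index values (or an
#'   [compute_profile()] result). NAT is excluded; at least 3 tumor stages
#'   are required.
#' @return the variance (single number).
#' @export
flat_line_stat <- function(per_stage) {
  v <- tumor_profile(per_stage)
  if (length(v) < 3L) {
    stop("flat-line statistic needs >= 3 tumor stages, got ", length(v))
  }
  mean(v^2) - mean(v)^2
}

#' Hourglass score of a stage profile
#'
#' With `e`, `m`, `l` the arithmetic means of the index over the early, mid
#' and late stage modules, the reductive (classic hourglass: high-low-high)
#' score is `min(e - m, l - m)` and the reverse (low-high-low) score is
#' `min(m - e, m - l)`. A positive score means both flanks of the pattern
#' point the right way; the worse flank is the score, so the test is
#' conservative.
#'
#' @param per_stage named numeric per-stage index values (NAT ignored), or an
#'   [compute_profile()] result.
#' @param modules a [stage_modules()] partition; must cover all tumor stages
#'   present.
#' @param direction `"reductive"` or `"reverse"`.
#' @return the score (single number).
#' @export
hourglass_score <- function(per_stage, modules = stage_modules(),
                            direction = c("reductive", "reverse")) {
  direction <- match.arg(direction)
  v <- tumor_profile(per_stage)
  check_modules(modules, names(v))
  e <- mean(v[names(v) %in% modules$early])
  m <- mean(v[names(v) %in% modules$mid])
  l <- mean(v[names(v) %in% modules$late])
  if (direction == "reductive") min(e - m, l - m) else min(m - e, m - l)
}

check_modules <- function(modules, stages_present) {
  if (!inherits(modules, "stage_modules")) stop("`modules` must come from stage_modules()")
  covered <- unlist(modules, use.names = FALSE)
  miss <- setdiff(stages_present, covered)
  if (length(miss)) {
    stop("stage modules do not cover stage(s): ", paste(miss, collapse = ", "))
  }
  for (nm in names(modules)) {
    if (!any(modules[[nm]] %in% stages_present)) {
      stop("stage module '", nm, "' has no sample in the profile")
    }
  }
  invisible(TRUE)
}

#' Permutation test for flat, hourglass and reverse-hourglass patterns
#'
#' Computes the observed pattern statistic on the true gene -> stratum
#' assignment, then permutes that assignment uniformly at random `B` times
#' (expression held fixed), recomputing the stage profile with the same
#' aggregation each time. This null keeps the full expression structure —
#' library sizes, gene means, stage composition — and breaks only the link
#' between a gene's expression and its evolutionary stratum. All three tests
#' are one-sided, rejecting for large statistics: large profile variance
#' (flat-line test), large reductive score (hourglass), large reverse score
#' (reverse hourglass). The empirical p-value uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so `p >= 1/(B+1)` always.
#'
#' NAT samples never enter the tested profile.
#'
#' @param x a [staged_expression()].
#' @param strata an [age_map()] or [rank_deciles()] strata vector.
#' @param test_kind `"flat_line"`, `"reductive_hourglass"` or
#'   `"reverse_hourglass"`.
#' @param modules a [stage_modules()] partition (hourglass tests only).
#' @param B number of permutations (>= 100).
#' @param seed integer RNG seed; identical seed and inputs give a
#'   bit-identical result.
#' @param aggregation stage aggregation, as in [compute_profile()].
#' @param normalize,scale,log_transform passed to [compute_profile()]
#'   semantics (normalization of columns before aggregation).
#' @param keep_null keep the full vector of permuted statistics.
#' @param parametric_p also report a Gaussian-approximation p-value from the
#'   null mean/sd (diagnostic only; the empirical p is authoritative).
#' @return An object of class `pattern_test`: list with `statistic`,
#'   `p_value`, `null_mean`, `null_sd`, `n_permutations`, `seed`,
#'   `test_kind`, `per_stage` (the observed tumor-stage profile), and
#'   optionally `null_values` and `parametric_p`.
#' @export
permutation_test <- function(x, strata,
                             test_kind = c("flat_line", "reductive_hourglass",
                                           "reverse_hourglass"),
                             modules = stage_modules(), B = 1000L, seed,
                             aggregation = c("mean_expression",
                                             "mean_of_sample_indices"),
                             normalize = TRUE, scale = 1e6,
                             log_transform = FALSE,
                             keep_null = FALSE, parametric_p = FALSE) {
  stopifnot(inherits(x, "staged_expression"))
  test_kind <- match.arg(test_kind)
  aggregation <- match.arg(aggregation)
  if (missing(seed)) stop("`seed` is required for a reproducible null")
  B <- as.integer(B)
  if (B < 100L) stop("B must be >= 100")

  tumor <- x$stages %in% TUMOR_STAGES
  if (!any(tumor)) stop("no tumor-stage (I-IV) samples in the data")
  x <- staged_expression(x$counts[, tumor, drop = FALSE], x$stages[tumor])
  if (normalize) x <- normalize_library(x, scale = scale)

  keep <- rownames(x$counts) %in% names(strata)
  if (!any(keep)) stop("no gene in the expression matrix has a stratum")
  mat <- x$counts[keep, , drop = FALSE]
  if (log_transform) mat <- log2(1 + mat)
  s <- as.numeric(strata[rownames(mat)])
  stages_present <- TUMOR_STAGES[TUMOR_STAGES %in% x$stages]
  if (test_kind == "flat_line") {
    if (length(stages_present) < 3L) {
      stop("flat-line test needs >= 3 tumor stages, got ",
           length(stages_present))
    }
  } else {
    check_modules(modules, stages_present)
  }

  # Profiles for the observed strata and all permutations in one pass:
  # per-stage index = (t(W) %*% s) / colSums(W) with W either the stage-mean
  # expression matrix (mean_expression) or, for mean_of_sample_indices, the
  # per-sample weighting followed by within-stage averaging. Both reduce to
  # matrix products, so the B nulls cost one genes x B multiply.
  stage_f <- factor(x$stages, levels = stages_present)
  if (aggregation == "mean_expression") {
    W <- vapply(stages_present, function(st) {
      rowMeans(mat[, x$stages == st, drop = FALSE])
    }, numeric(nrow(mat)))
    wtot <- colSums(W)
    if (any(wtot <= 0)) stop("stage with no annotated expression")
    profile_of <- function(S) {
      p <- crossprod(W, S) / wtot   # stages x B (wtot recycled by column)
      p
    }
  } else {
    ctot <- colSums(mat)
    if (any(ctot <= 0)) {
      stop("no annotated gene with positive expression in sample(s): ",
           paste(colnames(mat)[ctot <= 0], collapse = ", "))
    }
    counts_per_stage <- as.integer(table(stage_f))
    profile_of <- function(S) {
      idx <- crossprod(mat, S) / ctot          # samples x B
      rowsum(idx, stage_f) / counts_per_stage  # stages x B
    }
  }

  stat_of <- function(P) {
    # P: stages x k matrix of profiles; one-sided statistic per column
    if (test_kind == "flat_line") {
      colMeans(P^2) - colMeans(P)^2
    } else {
      e <- colMeans(P[stages_present %in% modules$early, , drop = FALSE])
      m <- colMeans(P[stages_present %in% modules$mid, , drop = FALSE])
      l <- colMeans(P[stages_present %in% modules$late, , drop = FALSE])
      if (test_kind == "reductive_hourglass") pmin(e - m, l - m)
      else pmin(m - e, m - l)
    }
  }

  P_obs <- profile_of(matrix(s, ncol = 1L))
  observed <- stat_of(P_obs)
  if (!is.finite(observed)) stop("non-finite observed statistic")

  set.seed(seed)
  S <- vapply(seq_len(B), function(b) sample(s), numeric(length(s)))
  null_stats <- stat_of(profile_of(S))
  p <- (1 + sum(null_stats >= observed)) / (B + 1)

  res <- list(statistic = unname(observed),
              p_value = p,
              null_mean = mean(null_stats),
              null_sd = stats::sd(null_stats),
              n_permutations = B,
              seed = as.integer(seed),
              test_kind = test_kind,
              aggregation = aggregation,
              per_stage = stats::setNames(as.numeric(P_obs), stages_present))
  if (keep_null) res$null_values <- null_stats
  if (parametric_p) {
    res$parametric_p <- stats::pnorm(observed, mean = res$null_mean,
                                     sd = res$null_sd, lower.tail = FALSE)
  }
  structure(res, class = "pattern_test")
}

#' @export
print.pattern_test <- function(x, ...) {
  cat("<pattern_test> ", x$test_kind, "\n",
      "  statistic = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p_value, digits = 5),
      " (B = ", x$n_permutations, ", seed = ", x$seed, ")\n",
      "  null: mean = ", format(x$null_mean, digits = 4),
      ", sd = ", format(x$null_sd, digits = 4), "\n", sep = "")
  invisible(x)
}
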