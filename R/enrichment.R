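#' 2x2 contingency table for one phylostratum
#'
#' Cross-tabulates DEG membership against membership of one stratum within
#' the background gene universe:
#' `(a, b; c, d)` = (#DEG in stratum, #DEG not in stratum, #non-DEG
#' background in stratum, #non-DEG background not in stratum).
#'
#' @param deg character vector of DEG identifiers (must all be in the
#'   background).
#' @param background an [age_map()] covering the gene universe.
#' @param stratum integer stratum to test.
#' @return 2x2 integer matrix with dimnames deg/background x in/out.
#' @export
stratum_contingency <- function(deg, background, stratum) {
  deg <- unique(as.character(deg))
  missing_genes <- setdiff(deg, names(background))
  if (length(missing_genes)) {
    stop("DEG gene(s) absent from background: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  in_stratum <- names(background)[unclass(background) == stratum]
  a <- sum(deg %in% in_stratum)
  b <- length(deg) - a
  c_ <- length(in_stratum) - a
  d <- length(background) - length(deg) - c_
  matrix(as.integer(c(a, c_, b, d)), nrow = 2L,
         dimnames = list(c("deg", "background"), c("in_stratum", "out")))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing, at fixed margins, the hypergeometric
#' probabilities of all tables no more probable than the observed one (the
#' usual `1 + 1e-7` relative tolerance guards ties against floating-point
#' noise). The odds ratio is the sample odds ratio `ad/bc`, reported as
#' `Inf` when `bc = 0` with `ad > 0`, `0` when `ad = 0` with `bc > 0`, and
#' `NaN` when both products vanish.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("`tab` must be 2x2")
  if (any(tab < 0)) stop("negative cell count")
  if (any(tab != floor(tab))) stop("non-integer cell count")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_          # column-1 margin ("white balls")
  n <- b + d           # column-2 margin
  k <- a + b           # row-1 margin (draws)
  support <- max(0, k - n):min(k, m)
  if (length(support) <= 1L) {
    p <- 1
  } else {
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  ad <- a * d; bc <- b * c_
  or <- if (bc == 0 && ad > 0) Inf
        else if (ad == 0 && bc == 0) NaN
        else ad / bc
  list(odds_ratio = or, p_value = p)
}

# Pearson chi-square against fixed expected counts (strata with expected 0
# are excluded by construction: only strata present in the background enter).
chi2_stat <- function(observed, expected) {
  sum((observed - expected)^2 / expected)
}

#' Phylostratum composition of a DEG list with a bootstrap null
#'
#' Compares the phylostratum composition of a DEG list against the
#' background gene universe three ways, mirroring the standard workflow:
#'
#' 1. Per-stratum 2x2 Fisher exact tests ([stratum_contingency()] +
#'    [fisher_exact()]) with Benjamini-Hochberg q-values across strata.
#' 2. A global Pearson chi-square of observed stratum counts against
#'    expected counts `|DEG| * background proportions`; strata absent from
#'    the background are dropped and `df = #strata present - 1`.
#' 3. A bootstrap null for that chi-square: `n_bootstrap` resamples of size
#'    `|DEG|`, drawn uniformly without replacement from the background gene
#'    identities, each scored with the same statistic;
#'    `bootstrap_p = (1 + #\{chi2_b >= chi2_obs\}) / (n_bootstrap + 1)`
#'    (add-one correction, ties count as exceedances, so p is never 0).
#'
#' @param deg character vector of DEG identifiers, all present in the
#'   background.
#' @param background an [age_map()] of the gene universe.
#' @param n_bootstrap number of resamples (>= 100; 1e5 for publication-grade
#'   runs).
#' @param seed integer RNG seed; fixed seed gives identical results.
#' @return An object of class `stratum_enrichment`: list with
#'   `per_stratum` (data.frame: stratum, count_deg, count_background,
#'   expected, odds_ratio, fisher_p, fisher_q), `chi2`, `chi2_df`,
#'   `bootstrap_p`, `analytic_p` (plain chi-square upper tail, the
#'   large-background limit), `analytic_p_finite` (chi-square tail of the
#'   statistic standardized by the finite-population factor
#'   `(N - |DEG|) / (N - 1)` — the analytic form matching the
#'   without-replacement null that the bootstrap estimates),
#'   `n_bootstrap`, `n_deg`, `seed`.
#' @export
chi2_bootstrap <- function(deg, background, n_bootstrap = 10000L, seed) {
  deg <- unique(as.character(deg))
  if (length(deg) < 1L) stop("DEG list is empty")
  n_bootstrap <- as.integer(n_bootstrap)
  if (n_bootstrap < 100L) stop("n_bootstrap must be >= 100")
  if (missing(seed)) stop("`seed` is required for a reproducible null")
  missing_genes <- setdiff(deg, names(background))
  if (length(missing_genes)) {
    stop("DEG gene(s) absent from background: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  N <- length(background)
  m <- length(deg)
  if (m > N) stop("DEG list larger than background")

  bg_strata <- unclass(background)
  strata_levels <- sort(unique(bg_strata))
  K <- length(strata_levels)
  stratum_idx <- match(bg_strata, strata_levels)
  bg_counts <- tabulate(stratum_idx, nbins = K)
  expected <- m * bg_counts / N

  obs_counts <- tabulate(stratum_idx[match(deg, names(background))],
                         nbins = K)
  chi2_obs <- chi2_stat(obs_counts, expected)

  fisher <- lapply(strata_levels, function(st) {
    fisher_exact(stratum_contingency(deg, background, st))
  })
  fisher_p <- vapply(fisher, `[[`, numeric(1), "p_value")
  per_stratum <- data.frame(
    stratum = strata_levels,
    count_deg = obs_counts,
    count_background = bg_counts,
    expected = expected,
    odds_ratio = vapply(fisher, `[[`, numeric(1), "odds_ratio"),
    fisher_p = fisher_p,
    fisher_q = stats::p.adjust(fisher_p, method = "BH")
  )

  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_bootstrap)) {
    draw <- sample.int(N, m)
    counts_b <- tabulate(stratum_idx[draw], nbins = K)
    if (chi2_stat(counts_b, expected) >= chi2_obs) exceed <- exceed + 1L
  }
  structure(list(per_stratum = per_stratum,
                 chi2 = chi2_obs,
                 chi2_df = K - 1L,
                 bootstrap_p = (1 + exceed) / (n_bootstrap + 1),
                 analytic_p = stats::pchisq(chi2_obs, df = K - 1L,
                                            lower.tail = FALSE),
                 analytic_p_finite = stats::pchisq(
                   chi2_obs / ((N - m) / (N - 1)), df = K - 1L,
                   lower.tail = FALSE),
                 n_bootstrap = n_bootstrap,
                 n_deg = m,
                 seed = as.integer(seed)),
            class = "stratum_enrichment")
}

#' @export
print.stratum_enrichment <- function(x, ...) {
  cat("<stratum_enrichment> ", x$n_deg, " DEGs vs ",
      sum(x$per_stratum$count_background), " background genes\n",
      "  chi2 = ", format(x$chi2, digits = 5), " (df = ", x$chi2_df,
      "), bootstrap p = ", format(x$bootstrap_p, digits = 4),
      " (", x$n_bootstrap, " resamples, seed ", x$seed, ")\n", sep = "")
  print(x$per_stratum, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Median log2 fold change by phylostratum and stage
#'
#' Summarizes a DEG table as the median log2FC per (stratum, stage) cell.
#' Cells with no DEG are `NA` (missing), never zero.
#'
#' @param deg_table data.frame with columns `gene_id`, `log2fc`, `stage`
#'   (and optionally `padj`, `cancer_type`; ignored here).
#' @param ages an [age_map()] covering all DEG genes.
#' @return numeric matrix, rows = strata 1..n_strata(ages), columns =
#'   tumor stages I-IV.
#' @export
median_log2fc_by_stratum <- function(deg_table, ages) {
  stopifnot(is.data.frame(deg_table),
            all(c("gene_id", "log2fc", "stage") %in% names(deg_table)))
  missing_genes <- setdiff(deg_table$gene_id, names(ages))
  if (length(missing_genes)) {
    stop("DEG gene(s) without age annotation: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  strata <- unclass(ages)[as.character(deg_table$gene_id)]
  out <- matrix(NA_real_, nrow = n_strata(ages), ncol = length(TUMOR_STAGES),
                dimnames = list(stratum = seq_len(n_strata(ages)),
                                stage = TUMOR_STAGES))
  for (st in TUMOR_STAGES) {
    sel <- deg_table$stage == st
    if (!any(sel)) next
    med <- tapply(deg_table$log2fc[sel], strata[sel], stats::median)
    out[as.integer(names(med)), st] <- med
  }
  out
}

#' Naive log2 fold change (fixture helper)
#'
#' Elementwise `log2((tumor + pc) / (normal + pc))` between mean expression
#' vectors. A convenience for building synthetic DEG fixtures only — it is
#' not a substitute for a proper differential-expression model and carries
#' no inference.
#'
#' @param tumor_means,normal_means nonnegative numeric vectors, equal length.
#' @param pseudocount positive stabilizer added to both (default 1).
#' @return numeric vector of log2 fold changes.
#' @export
naive_log2fc <- function(tumor_means, normal_means, pseudocount = 1) {
  if (length(tumor_means) != length(normal_means)) {
    stop("tumor and normal vectors must have equal length")
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((tumor_means + pseudocount) / (normal_means + pseudocount))
}
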