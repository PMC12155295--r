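#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' generator emulates a staged bulk RNA-seq study: a gene universe with a
#' configurable phylostratum distribution, negative-binomial counts with
#' log-normal gene baselines, a plantable hourglass / reverse-hourglass TAI
#' pattern of a chosen effect size, and DEG lists with plantable
#' phylostratum enrichment.
#'
#' Defaults describe a desk-scale study: 2,000 genes over 14 phylostrata
#' (uniform), 8 samples per tumor stage I-IV plus 4 NAT controls,
#' log-normal baseline means around 50 counts with `sdlog = 1`,
#' negative-binomial dispersion (size) 2 — typical bulk RNA-seq
#' overdispersion — and, when a pattern is planted, an effect size of 2
#' index units.
#'
#' @param n_genes number of genes in the universe.
#' @param n_strata number of phylostrata (default 14, the human
#'   Cellular-Organisms..newest ladder).
#' @param stratum_probs probability vector over strata (default uniform);
#'   must be nonnegative and sum to 1.
#' @param samples_per_stage named integer vector over
#'   `I, II, III, IV, NAT` (counts >= 0).
#' @param pattern `"flat"`, `"hourglass"` or `"reverse_hourglass"`.
#' @param effect_size planted early/late vs mid TAI separation, in index
#'   units (>= 0; ignored when `pattern = "flat"`).
#' @param baseline_mean median of the log-normal distribution of gene
#'   baseline means (counts).
#' @param baseline_sdlog log-scale sd of gene baseline means.
#' @param dispersion negative-binomial size parameter; `Inf` switches to
#'   Poisson counts.
#' @param dnds_meanlog,dnds_sdlog log-normal parameters of simulated dN/dS
#'   values (independent of stratum).
#' @param enriched_strata strata receiving planted DEG enrichment.
#' @param enrichment_fold sampling-weight fold for enriched strata (>= 1).
#' @param deg_size DEG list size per stage.
#' @param deg_log2fc_medians per-stratum median log2FC for DEG simulation;
#'   default: +0.8 for strata 1-2, -0.8 for 3-7, +2.0 for 8 and above
#'   (ancient genes mildly up, mid-age genes down, youngest genes with the
#'   largest shifts).
#' @param deg_log2fc_sd Gaussian sd of simulated log2FC.
#' @param seed integer master seed; each generator derives its own fixed
#'   substream (`seed` for the universe, `seed + 1` for expression,
#'   `seed + 2` for DEG tables) so the three outputs are independently
#'   reproducible.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_strata = 14L,
                              stratum_probs = NULL,
                              samples_per_stage = c(I = 8L, II = 8L,
                                                    III = 8L, IV = 8L,
                                                    NAT = 4L),
                              pattern = c("flat", "hourglass",
                                          "reverse_hourglass"),
                              effect_size = 2,
                              baseline_mean = 50,
                              baseline_sdlog = 1,
                              dispersion = 2,
                              dnds_meanlog = log(0.15),
                              dnds_sdlog = 0.8,
                              enriched_strata = integer(0),
                              enrichment_fold = 1,
                              deg_size = 300L,
                              deg_log2fc_medians = NULL,
                              deg_log2fc_sd = 1,
                              seed = 1L) {
  pattern <- match.arg(pattern)
  n_genes <- as.integer(n_genes)
  n_strata <- as.integer(n_strata)
  stopifnot(n_genes >= 1L, n_strata >= 1L,
            effect_size >= 0, baseline_mean > 0, baseline_sdlog >= 0,
            dispersion > 0, enrichment_fold >= 1, deg_log2fc_sd >= 0,
            deg_size >= 1L)
  if (is.null(stratum_probs)) stratum_probs <- rep(1 / n_strata, n_strata)
  if (length(stratum_probs) != n_strata) {
    stop("stratum_probs must have length n_strata")
  }
  if (any(stratum_probs < 0) || abs(sum(stratum_probs) - 1) > 1e-9) {
    stop("stratum_probs must be nonnegative and sum to 1")
  }
  if (!all(STAGE_LEVELS %in% names(samples_per_stage))) {
    stop("samples_per_stage must be named over I, II, III, IV, NAT")
  }
  samples_per_stage <- as.integer(samples_per_stage[STAGE_LEVELS])
  names(samples_per_stage) <- STAGE_LEVELS
  if (any(samples_per_stage < 0L)) stop("sample counts must be >= 0")
  enriched_strata <- as.integer(enriched_strata)
  if (length(enriched_strata) &&
      (any(enriched_strata < 1L) || any(enriched_strata > n_strata))) {
    stop("enriched_strata must lie in 1..n_strata")
  }
  if (is.null(deg_log2fc_medians)) {
    s <- seq_len(n_strata)
    deg_log2fc_medians <- ifelse(s <= 2, 0.8, ifelse(s <= 7, -0.8, 2.0))
  }
  if (length(deg_log2fc_medians) != n_strata) {
    stop("deg_log2fc_medians must have length n_strata")
  }
  structure(list(n_genes = n_genes, n_strata = n_strata,
                 stratum_probs = stratum_probs,
                 samples_per_stage = samples_per_stage,
                 pattern = pattern, effect_size = effect_size,
                 baseline_mean = baseline_mean,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 dnds_meanlog = dnds_meanlog, dnds_sdlog = dnds_sdlog,
                 enriched_strata = enriched_strata,
                 enrichment_fold = enrichment_fold,
                 deg_size = as.integer(deg_size),
                 deg_log2fc_medians = deg_log2fc_medians,
                 deg_log2fc_sd = deg_log2fc_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the gene universe: ages and divergence values
#'
#' Draws `n_genes` phylostrata from `stratum_probs` and dN/dS values from a
#' log-normal, independently of stratum. Gene ids are zero-padded
#' (`g0001`, ...) so lexicographic and numeric order agree.
#'
#' @param config a [simulation_config()].
#' @return list with `ages` (an [age_map()]) and `divergence`
#'   (a [divergence_map()]).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf(paste0("g%0", nchar(config$n_genes), "d"),
                 seq_len(config$n_genes))
  strata <- sample.int(config$n_strata, config$n_genes, replace = TRUE,
                       prob = config$stratum_probs)
  dnds <- stats::rlnorm(config$n_genes, meanlog = config$dnds_meanlog,
                        sdlog = config$dnds_sdlog)
  list(ages = age_map(ids, strata),
       divergence = divergence_map(ids, dnds))
}

# Multiplicative effect calibration. Young genes (top age tertile) get their
# mean multiplied by 2^(effect * w) in the boosted stages; w is solved so
# that the TAI separation between a young-boosted and an ancient-boosted
# stage, computed on expected (noise-free) expression, equals `effect`.
calibrate_effect_exponent <- function(mu, strata, young, ancient, effect) {
  tai_of <- function(f) sum(strata * mu * f) / sum(mu * f)
  sep <- function(w) {
    fE <- ifelse(young, 2^(effect * w), 1)      # early/late stage
    fM <- ifelse(ancient, 2^(effect * w), 1)    # mid stages
    tai_of(fE) - tai_of(fM)
  }
  # w -> Inf limit: young (resp. ancient) genes dominate their stages
  max_sep <- sum(strata[young] * mu[young]) / sum(mu[young]) -
    sum(strata[ancient] * mu[ancient]) / sum(mu[ancient])
  if (effect >= 0.999 * max_sep) {
    stop("effect_size ", effect, " exceeds the attainable TAI separation (",
         format(max_sep, digits = 3), ") for this gene universe")
  }
  ub <- 1
  while (sep(ub) < effect && ub < 500 / effect) ub <- ub * 2
  stats::uniroot(function(w) sep(w) - effect, c(0, ub), tol = 1e-10)$root
}

#' Simulate staged expression counts with a plantable TAI pattern
#'
#' Counts are negative binomial with gene-specific baseline means (log-normal
#' across genes) and the configured dispersion (`Inf` = Poisson). Under
#' `pattern = "hourglass"`, genes in the top age tertile ("young") have their
#' mean multiplied by `2^(effect_size * w)` in stages I and IV, and genes in
#' the bottom tertile ("ancient") by the same factor in stages II and III; w
#' is calibrated internally by root finding on the noise-free expected
#' profile so the expected TAI separation between boosted-young and
#' boosted-ancient stages equals `effect_size`. `"reverse_hourglass"` swaps
#' the stage sets; `"flat"` applies no multiplier. NAT columns always use
#' baseline means. The effect is planted on count means, not on the index, so
#' normalization and index computation are exercised end to end.
#'
#' @param config a [simulation_config()].
#' @param ages the [age_map()] from [generate_universe()] (same config).
#' @return a [staged_expression()]; sample ids are `<stage>_<k>`.
#' @export
generate_expression <- function(config, ages) {
  stopifnot(inherits(config, "sim_config"), inherits(ages, "age_map"))
  if (length(ages) != config$n_genes) {
    stop("age map size does not match config n_genes")
  }
  set.seed(config$seed + 1L)
  n <- config$n_genes
  ids <- names(ages)
  strata <- as.numeric(unclass(ages))
  mu <- stats::rlnorm(n, meanlog = log(config$baseline_mean),
                      sdlog = config$baseline_sdlog)

  mult <- matrix(1, nrow = n, ncol = length(STAGE_LEVELS),
                 dimnames = list(ids, STAGE_LEVELS))
  if (config$pattern != "flat" && config$effect_size > 0) {
    ord <- order(strata, ids, method = "radix")
    n3 <- n %/% 3L
    if (n3 < 1L) stop("too few genes to form age tertiles")
    ancient <- logical(n); ancient[ord[seq_len(n3)]] <- TRUE
    young <- logical(n); young[ord[seq.int(n - n3 + 1L, n)]] <- TRUE
    w <- calibrate_effect_exponent(mu, strata, young, ancient,
                                   config$effect_size)
    boost <- 2^(config$effect_size * w)
    if (config$pattern == "hourglass") {
      early_late <- c("I", "IV"); mid <- c("II", "III")
    } else {
      early_late <- c("II", "III"); mid <- c("I", "IV")
    }
    mult[young, early_late] <- boost
    mult[ancient, mid] <- boost
  }

  cols <- list()
  stage_labels <- character(0)
  for (st in STAGE_LEVELS) {
    k <- config$samples_per_stage[[st]]
    if (k == 0L) next
    mu_st <- mu * mult[, st]
    draws <- if (is.finite(config$dispersion)) {
      stats::rnbinom(n * k, size = config$dispersion, mu = rep(mu_st, k))
    } else {
      stats::rpois(n * k, lambda = rep(mu_st, k))
    }
    block <- matrix(draws, nrow = n, ncol = k)
    colnames(block) <- sprintf("%s_%02d", st, seq_len(k))
    cols[[st]] <- block
    stage_labels <- c(stage_labels, rep(st, k))
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- ids
  staged_expression(counts, stage_labels)
}

#' Simulate DEG tables with plantable phylostratum enrichment
#'
#' For every tumor stage, `deg_size` genes are sampled without replacement
#' from the universe with weight `enrichment_fold` for genes in
#' `enriched_strata` and 1 otherwise (fold 1 = uniform, matching the
#' bootstrap null of [chi2_bootstrap()] exactly). Each DEG gets a log2FC
#' drawn from a Gaussian centered at its stratum's configured median, and an
#' adjusted p-value drawn uniformly below 0.05 (fixture plumbing, not
#' inference).
#'
#' @param config a [simulation_config()].
#' @param ages the [age_map()] from [generate_universe()] (same config).
#' @return data.frame with columns `gene_id`, `log2fc`, `padj`, `stage`,
#'   `cancer_type`.
#' @export
generate_deg_table <- function(config, ages) {
  stopifnot(inherits(config, "sim_config"), inherits(ages, "age_map"))
  if (config$deg_size > length(ages)) {
    stop("deg_size exceeds the gene universe")
  }
  set.seed(config$seed + 2L)
  strata <- unclass(ages)
  weights <- ifelse(strata %in% config$enriched_strata,
                    config$enrichment_fold, 1)
  out <- vector("list", length(TUMOR_STAGES))
  for (i in seq_along(TUMOR_STAGES)) {
    idx <- sample.int(length(ages), config$deg_size, prob = weights)
    lfc <- stats::rnorm(config$deg_size,
                        mean = config$deg_log2fc_medians[strata[idx]],
                        sd = config$deg_log2fc_sd)
    out[[i]] <- data.frame(gene_id = names(ages)[idx],
                           log2fc = lfc,
                           padj = stats::runif(config$deg_size, 0, 0.05),
                           stage = TUMOR_STAGES[i],
                           cancer_type = "SYNTH")
  }
  do.call(rbind, out)
}
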