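#' Normalize clinical stage labels to I-IV / NAT
#'
#' Harmonizes AJCC-style labels: a leading "Stage" word is dropped, case is
#' ignored, and sub-stage suffixes (A/B/C) are stripped, so `"Stage IIIB"`,
#' `"stage iiib"` and `"IIIB"` all map to `"III"`. Control labels
#' (`"NAT"`, `"Solid Tissue Normal"`, `"Normal"`) map to `"NAT"`. Anything
#' else — including indefinite stages like `"Stage X"` — is rejected, since
#' only samples with definitive staging can be placed on the progression
#' axis.
#'
#' @param raw character vector of raw labels.
#' @return character vector of the same length over
#'   `"I", "II", "III", "IV", "NAT"`.
#' @export
normalize_stage_label <- function(raw) {
  if (any(!nzchar(trimws(raw)))) stop("empty stage label")
  x <- toupper(trimws(raw))
  x <- sub("^STAGE[ _]*", "", x)
  x[x %in% c("NAT", "NORMAL", "SOLID TISSUE NORMAL")] <- "NAT"
  core <- sub("^(IV|III|II|I)[ABC]?$", "\\1", x)
  ok <- core %in% STAGE_LEVELS
  if (any(!ok)) {
    stop("unmappable stage label(s): ",
         paste(unique(raw[!ok]), collapse = ", "),
         " (definitive stages I-IV or NAT required)")
  }
  core
}

#' Read / write an expression matrix
#'
#' TSV with first column `gene_id` and one column per sample.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") {
    stop("expression matrix must start with a 'gene_id' column: ", path)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$gene_id
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric or missing expression value in ", path)
  mat
}

#' @rdname read_expression_matrix
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write sample metadata
#'
#' TSV with columns `sample_id`, `stage` and optionally `patient_id`,
#' `batch`. Stage labels are normalized via [normalize_stage_label()] on
#' read.
#'
#' @param path file path.
#' @return data.frame with normalized `stage`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage") %in% names(df))) {
    stop("metadata must have 'sample_id' and 'stage' columns: ", path)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  }
  df$stage <- normalize_stage_label(df$stage)
  df
}

#' @rdname read_sample_metadata
#' @param meta data.frame with at least `sample_id` and `stage`.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble a staged expression object from matrix + metadata files
#'
#' Validates cross-consistency: every expression sample must appear in the
#' metadata (missing ones are named in the error).
#'
#' @param expr_path expression matrix TSV ([read_expression_matrix()]).
#' @param meta_path metadata TSV ([read_sample_metadata()]).
#' @return a [staged_expression()].
#' @export
read_staged_expression <- function(expr_path, meta_path) {
  mat <- read_expression_matrix(expr_path)
  meta <- read_sample_metadata(meta_path)
  missing_samples <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing_samples)) {
    stop("sample(s) in ", expr_path, " missing from ", meta_path, ": ",
         paste(missing_samples, collapse = ", "))
  }
  stages <- meta$stage[match(colnames(mat), meta$sample_id)]
  staged_expression(mat, stages)
}

#' Read / write a DEG table
#'
#' TSV with columns `gene_id`, `log2fc`, `padj`, `stage`, `cancer_type`.
#' Stage labels are normalized on read.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj", "stage")
  if (!all(need %in% names(df))) {
    stop("DEG table must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  df$stage <- normalize_stage_label(df$stage)
  if (any(df$padj < 0 | df$padj > 1)) stop("padj outside [0, 1] in ", path)
  key <- paste(df$cancer_type %||% "", df$stage, df$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate gene within a (cancer_type, stage) DEG list in ", path)
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_deg_table
#' @param deg data.frame as returned by [generate_deg_table()].
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an index profile
#'
#' One TSV with a `level` column distinguishing the per-sample and per-stage
#' blocks, plus an optional JSON mirror.
#'
#' @param profile an [compute_profile()] result.
#' @param path output TSV path.
#' @param json_path optional JSON mirror path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, json_path = NULL) {
  stopifnot(inherits(profile, "index_profile"))
  df <- rbind(
    data.frame(level = "sample", id = names(profile$per_sample),
               value = unname(profile$per_sample)),
    data.frame(level = "stage", id = names(profile$per_stage),
               value = unname(profile$per_stage))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(index_kind = profile$index_kind,
           aggregation = profile$aggregation,
           n_genes_used = profile$n_genes_used,
           n_genes_dropped = profile$n_genes_dropped,
           per_sample = as.list(profile$per_sample),
           per_stage = as.list(profile$per_stage)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Writes `expr.tsv`, `meta.tsv`, `ages.tsv`, `dnds.tsv`, `deg.tsv` and a
#' `provenance.json` recording the full configuration, so a simulation can
#' be reproduced from its output directory alone.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  uni <- generate_universe(config)
  expr <- generate_expression(config, uni$ages)
  deg <- generate_deg_table(config, uni$ages)
  write_expression_matrix(expr$counts, file.path(out_dir, "expr.tsv"))
  write_sample_metadata(
    data.frame(sample_id = names(expr$stages), stage = unname(expr$stages),
               patient_id = names(expr$stages)),
    file.path(out_dir, "meta.tsv"))
  write_gene_annotation(uni$ages, file.path(out_dir, "ages.tsv"))
  write_gene_annotation(uni$divergence, file.path(out_dir, "dnds.tsv"))
  write_deg_table(deg, file.path(out_dir, "deg.tsv"))
  jsonlite::write_json(unclass(config),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Pipeline configuration
#'
#' Validated bundle of every pipeline setting: which index to compute, how
#' to aggregate stages, the stage-module partition, replicate counts, seed
#' and input/output paths.
#'
#' @param expr,meta,ages paths to the expression matrix, sample metadata and
#'   age-map TSVs (required).
#' @param dnds optional dN/dS TSV (required when `index_kind = "TDI"`).
#' @param deg optional DEG table TSV; enables the enrichment analysis.
#' @param out_dir output directory.
#' @param index_kind `"TAI"` or `"TDI"`.
#' @param aggregation stage aggregation, as in [compute_profile()].
#' @param modules a [stage_modules()] partition.
#' @param B permutations for pattern tests (>= 100).
#' @param n_bootstrap resamples for enrichment (>= 100).
#' @param seed integer seed for all randomness.
#' @param alpha significance level in (0, 1) gating the hourglass tests.
#' @param gate_hourglass run hourglass tests only when the flat-line test
#'   rejects at `alpha` (default); `FALSE` always runs them.
#' @param scale library-size normalization target.
#' @param log_transform apply log2(1+x) before index computation.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr, meta, ages, dnds = NULL, deg = NULL,
                            out_dir = ".",
                            index_kind = c("TAI", "TDI"),
                            aggregation = c("mean_expression",
                                            "mean_of_sample_indices"),
                            modules = stage_modules(),
                            B = 1000L, n_bootstrap = 10000L, seed = 1L,
                            alpha = 0.05, gate_hourglass = TRUE,
                            scale = 1e6, log_transform = FALSE) {
  index_kind <- match.arg(index_kind)
  aggregation <- match.arg(aggregation)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (B < 100L || n_bootstrap < 100L) {
    stop("B and n_bootstrap must be >= 100")
  }
  if (index_kind == "TDI" && is.null(dnds)) {
    stop("TDI requires a dN/dS table (`dnds`)")
  }
  structure(list(expr = expr, meta = meta, ages = ages, dnds = dnds,
                 deg = deg, out_dir = out_dir, index_kind = index_kind,
                 aggregation = aggregation, modules = modules,
                 B = as.integer(B), n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), alpha = alpha,
                 gate_hourglass = gate_hourglass, scale = scale,
                 log_transform = log_transform),
            class = "pipeline_config")
}

#' Run the full staged phylotranscriptomics pipeline
#'
#' Orchestrates profile computation, the flat-line test, the (optionally
#' gated) hourglass tests and, when a DEG table is supplied, the
#' phylostratum enrichment analysis. Writes `profile.tsv` (+ JSON mirror),
#' `pattern_tests.json`, `enrichment.tsv` / `enrichment.json` and a
#' `manifest.json` with input hashes, settings and seed so any run is
#' reproducible bit for bit from its inputs.
#'
#' @param config a [pipeline_config()].
#' @return the report (list) invisibly; files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  x <- read_staged_expression(config$expr, config$meta)
  ages <- read_age_map(config$ages)
  strata <- if (config$index_kind == "TAI") {
    ages
  } else {
    rank_deciles(read_divergence_map(config$dnds))
  }

  profile <- compute_profile(x, strata, aggregation = config$aggregation,
                             scale = config$scale,
                             log_transform = config$log_transform)
  message("profile: ", profile$n_genes_used, " genes used, ",
          profile$n_genes_dropped, " dropped (no stratum annotation)")
  write_profile(profile, file.path(config$out_dir, "profile.tsv"),
                file.path(config$out_dir, "profile.json"))

  run_one <- function(kind) {
    permutation_test(x, strata, test_kind = kind, modules = config$modules,
                     B = config$B, seed = config$seed,
                     aggregation = config$aggregation,
                     scale = config$scale,
                     log_transform = config$log_transform)
  }
  flat <- run_one("flat_line")
  tests <- list(flat_line = pattern_test_report(flat))
  if (!config$gate_hourglass || flat$p_value <= config$alpha) {
    tests$reductive_hourglass <-
      pattern_test_report(run_one("reductive_hourglass"))
    tests$reverse_hourglass <-
      pattern_test_report(run_one("reverse_hourglass"))
  } else {
    tests$reductive_hourglass <- list(status = "not run",
                                      reason = "flat-line test not rejected")
    tests$reverse_hourglass <- tests$reductive_hourglass
  }
  jsonlite::write_json(
    c(list(index_kind = config$index_kind,
           aggregation = config$aggregation,
           modules = unclass(config$modules),
           alpha = config$alpha, B = config$B, seed = config$seed),
      tests),
    file.path(config$out_dir, "pattern_tests.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  enrichment <- NULL
  if (!is.null(config$deg)) {
    deg_tab <- read_deg_table(config$deg)
    enrichment <- chi2_bootstrap(unique(deg_tab$gene_id), ages,
                                 n_bootstrap = config$n_bootstrap,
                                 seed = config$seed)
    utils::write.table(enrichment$per_stratum,
                       file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    med <- median_log2fc_by_stratum(deg_tab, ages)
    utils::write.table(
      data.frame(stratum = rownames(med), med, check.names = FALSE),
      file.path(config$out_dir, "median_log2fc.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    jsonlite::write_json(
      list(chi2 = enrichment$chi2, chi2_df = enrichment$chi2_df,
           bootstrap_p = enrichment$bootstrap_p,
           analytic_p = enrichment$analytic_p,
           n_bootstrap = enrichment$n_bootstrap,
           n_deg = enrichment$n_deg, seed = enrichment$seed),
      file.path(config$out_dir, "enrichment.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  inputs <- c(expr = config$expr, meta = config$meta, ages = config$ages,
              dnds = config$dnds, deg = config$deg)
  manifest <- list(
    package = "phylostage",
    version = as.character(utils::packageVersion("phylostage")),
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(inputs)),
    settings = list(index_kind = config$index_kind,
                    aggregation = config$aggregation,
                    modules = unclass(config$modules),
                    B = config$B, n_bootstrap = config$n_bootstrap,
                    alpha = config$alpha, scale = config$scale,
                    log_transform = config$log_transform,
                    gate_hourglass = config$gate_hourglass),
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(profile = profile, tests = tests, enrichment = enrichment,
                 manifest = manifest))
}

pattern_test_report <- function(t) {
  list(statistic = t$statistic, p_value = t$p_value,
       null_mean = t$null_mean, null_sd = t$null_sd,
       n_permutations = t$n_permutations, seed = t$seed,
       per_stage = as.list(t$per_stage))
}
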