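#' Gene age map (phylostratum assignment)
#'
#' An `age_map` assigns every gene an integer phylostratum, the
#' Phylostratigraphic Age Index (PAI): the rank of the oldest taxonomic node
#' at which homologs of the gene are detectable. Higher values mean more
#' recent evolutionary origin; for the human gene universe the meaningful
#' range is 1 (Cellular Organisms) to 14, with e.g. 6 = Vertebrata,
#' 7 = Euteleostomi, 9 = Eutheria. The PAI is consumed as input, never
#' inferred here.
#'
#' @param genes character vector of unique gene identifiers.
#' @param strata integer vector of phylostrata (>= 1), same length as `genes`.
#' @return A named integer vector of class `age_map` (names are gene ids)
#'   with attribute `n_strata` = max stratum present.
#' @examples
#' am <- age_map(c("g1", "g2"), c(1L, 14L))
#' n_strata(am)
#' @export
age_map <- function(genes, strata) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene identifiers in age map: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (length(genes) != length(strata)) {
    stop("`genes` and `strata` must have the same length")
  }
  s <- suppressWarnings(as.numeric(strata))
  if (anyNA(s) || any(s != as.integer(s))) {
    bad <- which(is.na(s) | s != suppressWarnings(as.integer(s)))
    stop("non-integer phylostratum for gene(s): ",
         paste(utils::head(genes[bad], 5L), collapse = ", "))
  }
  s <- as.integer(s)
  if (any(s < 1L)) {
    stop("phylostratum must be >= 1; offending gene(s): ",
         paste(utils::head(genes[s < 1L], 5L), collapse = ", "))
  }
  if (length(s) == 0L) stop("age map is empty")
  structure(stats::setNames(s, genes),
            n_strata = max(s),
            class = "age_map")
}

#' @rdname age_map
#' @param x an `age_map`.
#' @export
n_strata <- function(x) attr(x, "n_strata")

#' Gene divergence map (dN/dS ratios)
#'
#' Maps each gene to a nonnegative dN/dS ratio (nonsynonymous over
#' synonymous substitution rate against close orthologs). One value per
#' gene; how multi-species values were aggregated is the data producer's
#' choice.
#'
#' @param genes character vector of unique gene identifiers.
#' @param dnds numeric vector of nonnegative dN/dS values.
#' @return A named numeric vector of class `divergence_map`.
#' @export
divergence_map <- function(genes, dnds) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene identifiers in divergence map: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (length(genes) != length(dnds)) {
    stop("`genes` and `dnds` must have the same length")
  }
  v <- as.numeric(dnds)
  if (anyNA(v)) stop("dN/dS values must be numeric and non-missing")
  if (any(v < 0)) {
    stop("dN/dS must be >= 0; offending gene(s): ",
         paste(utils::head(genes[v < 0], 5L), collapse = ", "))
  }
  structure(stats::setNames(v, genes), class = "divergence_map")
}

#' Rank genes into balanced divergence deciles
#'
#' Genes are ordered by dN/dS ascending (ties broken by gene identifier, byte
#' order, so the ranking is reproducible across platforms and locales) and
#' partitioned into 10 contiguous blocks whose sizes differ by at most one;
#' when `n mod 10 = r > 0` the extra members go to the `r` lowest strata.
#' Block `k` becomes Divergence Stratum `k`: stratum 1 holds the smallest
#' dN/dS values, stratum 10 the largest. These strata are the TDI weights.
#'
#' @param divergence a [divergence_map()].
#' @return A named integer vector of class `divergence_strata` (values in
#'   1..10, names are gene ids, in the order of the input).
#' @examples
#' dm <- divergence_map(paste0("g", 1:10), (1:10) / 100)
#' rank_deciles(dm)
#' @export
rank_deciles <- function(divergence) {
  if (!inherits(divergence, "divergence_map")) {
    divergence <- divergence_map(names(divergence), divergence)
  }
  n <- length(divergence)
  if (n < 10L) stop("decile ranking requires at least 10 genes, got ", n)
  ord <- order(unname(divergence), names(divergence), method = "radix")
  base <- n %/% 10L
  r <- n %% 10L
  sizes <- rep.int(base, 10L) + c(rep.int(1L, r), rep.int(0L, 10L - r))
  strata_sorted <- rep.int(seq_len(10L), sizes)
  out <- integer(n)
  out[ord] <- strata_sorted
  structure(stats::setNames(out, names(divergence)),
            n_strata = 10L,
            class = "divergence_strata")
}

#' Read a gene -> phylostratum table
#'
#' Expects two-column delimited text (`gene_id`, integer PAI), tab- or
#' whitespace-separated, optional header, `#` comment lines ignored. Exact
#' duplicate rows are deduplicated; duplicate genes with conflicting strata
#' are an error.
#'
#' @param path path to the table.
#' @return an [age_map()].
#' @export
read_age_map <- function(path) {
  tab <- read_two_column(path, value_name = "pai")
  s <- suppressWarnings(as.numeric(tab$value))
  bad <- is.na(s) | s != floor(s)
  if (any(bad)) {
    stop("non-integer PAI in ", path, " for gene(s): ",
         paste(utils::head(tab$gene[bad], 5L), collapse = ", "))
  }
  age_map(tab$gene, as.integer(s))
}

#' Read a gene -> dN/dS table
#'
#' Same format as [read_age_map()] with a numeric second column.
#'
#' @param path path to the table.
#' @return a [divergence_map()].
#' @export
read_divergence_map <- function(path) {
  tab <- read_two_column(path, value_name = "dnds")
  v <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(v)) {
    stop("non-numeric dN/dS in ", path, " for gene(s): ",
         paste(utils::head(tab$gene[is.na(v)], 5L), collapse = ", "))
  }
  divergence_map(tab$gene, v)
}

# Shared reader for 2-column gene annotation tables. Detects an optional
# header by a non-numeric second field in row 1; resolves exact duplicates,
# errors on conflicting ones naming the gene.
read_two_column <- function(path, value_name) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed row in ", path, " (need 2 columns): line ",
         which(nf < 2L)[1L])
  }
  gene <- vapply(fields, `[[`, "", 1L)
  value <- vapply(fields, `[[`, "", 2L)
  if (is.na(suppressWarnings(as.numeric(value[1L])))) {
    gene <- gene[-1L]
    value <- value[-1L]
    if (length(gene) == 0L) stop("no data rows in ", path)
  }
  key <- paste(gene, value, sep = "\r")
  keep <- !duplicated(key)
  gene <- gene[keep]
  value <- value[keep]
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    stop("conflicting annotation in ", path, " for gene(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  list(gene = gene, value = value)
}

#' Write gene annotation tables
#'
#' Two-column TSV `gene_id<TAB>value`, UTF-8, with a header line.
#'
#' @param x an [age_map()] or [divergence_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(x, path) {
  value_name <- if (inherits(x, "age_map")) "pai" else "dnds"
  df <- data.frame(gene_id = names(x), value = unname(unclass(x)))
  names(df)[2L] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.age_map <- function(x, ...) {
  cat("<age_map> ", length(x), " genes, strata 1..", n_strata(x), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.divergence_map <- function(x, ...) {
  cat("<divergence_map> ", length(x), " genes, dN/dS in [",
      format(min(x), digits = 3), ", ", format(max(x), digits = 3), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.divergence_strata <- function(x, ...) {
  cat("<divergence_strata> ", length(x), " genes in 10 deciles\n", sep = "")
  invisible(x)
}
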