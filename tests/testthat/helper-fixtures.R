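# Small in-code fixtures shared across test files.

# A tiny staged matrix with one sample per tumor stage plus NAT.
tiny_expression <- function() {
  counts <- matrix(
    c(10, 5, 1,   # I
      2, 8, 4,    # II
      1, 9, 5,    # III
      12, 4, 2,   # IV
      6, 6, 6),   # NAT
    nrow = 3,
    dimnames = list(c("g1", "g2", "g3"),
                    c("s1", "s2", "s3", "s4", "s5")))
  staged_expression(counts, c("I", "II", "III", "IV", "NAT"))
}

tiny_ages <- function() age_map(c("g1", "g2", "g3"), c(1L, 7L, 14L))

# Independent brute-force oracle for the expression-weighted mean stratum.
index_oracle <- function(expr, strata) {
  num <- 0; den <- 0
  for (g in names(expr)) {
    if (g %in% names(strata)) {
      num <- num + as.numeric(strata[[g]]) * expr[[g]]
      den <- den + expr[[g]]
    }
  }
  num / den
}

# Independent Fisher oracle: enumerate every table at the observed margins,
# probability via lchoose, sum those no more probable than the observed.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_; n <- b + d; k <- a + b; tot <- m + n
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(tot, k)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Write a staged_expression + annotation set to dir; returns the paths.
write_fixture_dataset <- function(x, ages, dir, dnds = NULL, deg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expr = file.path(dir, "expr.tsv"),
    meta = file.path(dir, "meta.tsv"),
    ages = file.path(dir, "ages.tsv"))
  write_expression_matrix(x$counts, paths$expr)
  write_sample_metadata(
    data.frame(sample_id = names(x$stages), stage = unname(x$stages)),
    paths$meta)
  write_gene_annotation(ages, paths$ages)
  if (!is.null(dnds)) {
    paths$dnds <- file.path(dir, "dnds.tsv")
    write_gene_annotation(dnds, paths$dnds)
  }
  if (!is.null(deg)) {
    paths$deg <- file.path(dir, "deg.tsv")
    write_deg_table(deg, paths$deg)
  }
  paths
}
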