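# Independent oracles and fixture builders for the test suite. Oracles are
# written as explicit sum formulas / eigensolves so they share no code path
# with the implementations they check.

# Pearson r and two-tailed p from the raw sum formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Wright-style ENC from first principles: explicit loops over families
oracle_enc <- function(counts, code) {
  F_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    k <- length(fam)
    if (k == 1L) next
    n <- 0
    for (cn in fam) n <- n + counts[[cn]]
    if (n < 2) next
    sum_p2 <- 0
    for (cn in fam) sum_p2 <- sum_p2 + (counts[[cn]] / n)^2
    F <- (n * sum_p2 - 1) / (n - 1)
    if (is.finite(F) && F > 0) {
      F_by_class[[as.character(k)]] <- c(F_by_class[[as.character(k)]], F)
    }
  }
  Fbar <- vapply(F_by_class, function(v) {
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (is.na(Fbar[["3"]])) Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  raw <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
    3 / Fbar[["6"]]
  min(raw, 61)
}

# PCA via direct eigendecomposition of the covariance matrix
oracle_pca_evr <- function(m) {
  centered <- sweep(m, 2L, colMeans(m))
  ev <- eigen(stats::cov(centered), symmetric = TRUE)$values
  ev <- ev[ev > -1e-12]
  ev / sum(ev)
}

reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# random codon count table over all 64 codons
random_counts <- function(max_count = 50L) {
  code <- genetic_code()
  counts <- stats::setNames(
    sample.int(max_count + 1L, 64L, replace = TRUE) - 1L,
    names(code$codon_to_aa)
  )
  counts
}

counts_as_table <- function(counts) {
  structure(list(counts = counts, total = sum(counts), n_ambiguous = 0L),
            class = "codon_counts")
}

# CDS built from an explicit codon vector
cds_from_codons <- function(codons, id = "gene") {
  cds(paste(codons, collapse = ""), id = id)
}

# random in-frame ACGT gene of n_codons codons
random_gene <- function(n_codons, id = "gene") {
  cds_from_codons(
    paste0(sample(c("A", "C", "G", "T"), n_codons, TRUE),
           sample(c("A", "C", "G", "T"), n_codons, TRUE),
           sample(c("A", "C", "G", "T"), n_codons, TRUE)),
    id = id
  )
}
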