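#' Relative synonymous codon usage (RSCU)
#'
#' For a codon c in a synonymous family of size k whose family total count
#' is T, \eqn{RSCU_c = k \, n_c / T}: the observed count divided by the
#' count expected were all family members used equally. Values above 1
#' mark preferred codons; the family mean is always 1. Stop codons and the
#' single-codon amino acids Met (ATG) and Trp (TGG) admit no synonymous
#' choice and are excluded, leaving the canonical 59-codon vector.
#'
#' A codon with zero count whose amino acid is otherwise used is *absent*
#' (RSCU 0); a codon whose whole amino-acid family is missing from the gene
#' is *undefined* (`NA`) -- the distinction matters for absent-codon
#' reporting, where only the former is evidence of codon avoidance.
#'
#' @param x a [cds()] object or `"codon_counts"` table.
#' @param code genetic code, from [genetic_code()].
#' @return An object of class `"rscu"`: list with `values` (named numeric
#'   over the 59 eligible codons, `NA` when undefined), `absent_codons` and
#'   `undefined_codons`.
#' @examples
#' g <- cds(paste(rep(c("GCT", "GCT", "GCC", "GCA"), 5), collapse = ""))
#' rscu(g)$values[c("GCT", "GCC", "GCA", "GCG")]   # 2, 1, 1, 0
#' @export
rscu <- function(x, code = genetic_code()) {
  counts <- as_codon_counts(x)$counts
  if (sum(counts[code$sense_codons]) == 0L) {
    stop("RSCU undefined: no sense codons in sequence")
  }
  values <- stats::setNames(rep(NA_real_, length(code$rscu_codons)),
                            code$rscu_codons)
  absent <- character(0)
  undefined <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    k <- length(fam)
    if (k < 2L) next
    total <- sum(counts[fam])
    if (total == 0L) {
      undefined <- c(undefined, fam)
    } else {
      values[fam] <- k * counts[fam] / total
      absent <- c(absent, fam[counts[fam] == 0L])
    }
  }
  structure(
    list(values = values, absent_codons = sort(absent),
         undefined_codons = sort(undefined)),
    class = "rscu"
  )
}

#' @export
print.rscu <- function(x, ...) {
  cat(sprintf("<rscu> 59-codon vector; %d absent, %d undefined\n",
              length(x$absent_codons), length(x$undefined_codons)))
  invisible(x)
}

#' Classify RSCU values by the 0.6 / 1.6 convention
#'
#' A codon with RSCU above 1.6 is overrepresented and one below 0.6 (but
#' used) is underrepresented; either is a biased codon. The thresholds are
#' strict inequalities, so boundary values are unbiased. RSCU exactly 0 is
#' `absent` (amino acid used, codon never chosen) and `NA` is `undefined`
#' (amino acid missing from the gene).
#'
#' @param value numeric vector of RSCU values (`NA` allowed).
#' @return Character vector over
#'   `{overrepresented, underrepresented, unbiased, absent, undefined}`.
#' @export
classify_rscu <- function(value) {
  stopifnot(is.numeric(value) || all(is.na(value)))
  out <- rep("unbiased", length(value))
  out[!is.na(value) & value > 1.6] <- "overrepresented"
  out[!is.na(value) & value < 0.6 & value > 0] <- "underrepresented"
  out[!is.na(value) & value == 0] <- "absent"
  out[is.na(value)] <- "undefined"
  if (!is.null(names(value))) names(out) <- names(value)
  out
}

#' Cohort RSCU matrix
#'
#' Stacks per-gene RSCU vectors into a genes x 59 matrix (rows named by
#' gene id), the substrate for dispersion and PCA analyses.
#'
#' @param x a `"cds_set"`, or a list of `"rscu"` objects.
#' @param code genetic code.
#' @return Numeric matrix, genes x 59, `NA` for undefined entries.
#' @export
rscu_matrix <- function(x, code = genetic_code()) {
  rs <- if (inherits(x, "cds_set")) {
    stats::setNames(lapply(x, rscu, code = code),
                    vapply(x, `[[`, character(1), "id"))
  } else {
    stopifnot(all(vapply(x, inherits, logical(1), "rscu")))
    x
  }
  m <- do.call(rbind, lapply(rs, `[[`, "values"))
  rownames(m) <- names(rs)
  m
}

#' Absent synonymous codons across a cohort
#'
#' Lists, per eligible codon, the species whose gene never uses the codon
#' while using its amino acid at least once -- true codon avoidance. A
#' species missing the whole amino-acid family is not evidence of
#' avoidance and is not listed.
#'
#' @param x a `"cds_set"`, or a named list of `"rscu"` objects (names =
#'   species labels).
#' @param code genetic code.
#' @return Data frame with one row per codon absent somewhere: `codon`,
#'   `amino_acid`, `n_species`, `species` (comma-separated). Empty when
#'   every codon is used by every species that uses its amino acid.
#' @export
absent_codon_report <- function(x, code = genetic_code()) {
  rs <- if (inherits(x, "cds_set")) {
    stats::setNames(lapply(x, rscu, code = code),
                    vapply(x, `[[`, character(1), "species"))
  } else {
    x
  }
  labels <- names(rs)
  if (is.null(labels)) labels <- paste0("gene", seq_along(rs))
  rows <- lapply(code$rscu_codons, function(codon) {
    hit <- vapply(rs, function(r) codon %in% r$absent_codons, logical(1))
    if (!any(hit)) return(NULL)
    data.frame(
      codon = codon,
      amino_acid = unname(code$codon_to_aa[codon]),
      n_species = sum(hit),
      species = paste(labels[hit], collapse = ", "),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(codon = character(0), amino_acid = character(0),
                      n_species = integer(0), species = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cross-species dispersion of codon usage (Vs)
#'
#' For each eligible codon, the coefficient of variation of its RSCU values
#' across the cohort: \eqn{V_s = \sigma / \bar{x}}, with \eqn{\sigma} the
#' sample standard deviation (denominator N - 1) over the species whose
#' gene defines an RSCU for the codon (undefined entries are skipped and
#' counted in `n_missing`). Lower Vs marks more stable usage of that
#' synonymous codon across species.
#'
#' @param m a genes x 59 RSCU matrix from [rscu_matrix()], or a `"cds_set"`.
#' @param code genetic code.
#' @return Data frame with one row per eligible codon: `codon`,
#'   `amino_acid`, `mean_rscu`, `sd_rscu`, `vs`, `n_species`, `n_missing`.
#'   `vs` is `NA` when fewer than 2 defined values or zero mean.
#' @export
vs_dispersion <- function(m, code = genetic_code()) {
  if (!is.matrix(m)) m <- rscu_matrix(m, code = code)
  stopifnot(identical(colnames(m), code$rscu_codons) ||
              setequal(colnames(m), code$rscu_codons))
  rows <- lapply(code$rscu_codons, function(codon) {
    x <- m[, codon]
    defined <- x[!is.na(x)]
    n <- length(defined)
    xbar <- if (n > 0) mean(defined) else NA_real_
    s <- if (n >= 2) stats::sd(defined) else NA_real_
    vs <- if (n >= 2 && !is.na(xbar) && xbar > 0) s / xbar else NA_real_
    data.frame(
      codon = codon, amino_acid = unname(code$codon_to_aa[codon]),
      mean_rscu = xbar, sd_rscu = s, vs = vs,
      n_species = n, n_missing = nrow(m) - n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' GC content at synonymous third codon positions (GC3)
#'
#' Fraction of G or C at the third position of sense codons, excluding ATG
#' and TGG (whose third position is not synonymous) and stop codons.
#'
#' @param x a [cds()] object or `"codon_counts"` table.
#' @param code genetic code.
#' @return Fraction in \[0, 1\].
#' @export
gc3 <- function(x, code = genetic_code()) {
  counts <- as_codon_counts(x)$counts
  eligible <- counts[code$rscu_codons]
  total <- sum(eligible)
  if (total == 0L) stop("GC3 undefined: no synonymously-coded codons")
  third <- substr(code$rscu_codons, 3L, 3L)
  sum(eligible[third %in% c("G", "C")]) / total
}

#' Expected ENC under GC-composition constraint alone
#'
#' The null curve for the ENC-GC3 diagnostic plot: the ENC a gene would
#' have if third-position GC content `s` alone (no selection among
#' synonymous codons) drove its codon usage,
#' \deqn{ENC_{exp}(s) = 2 + s + 29 / (s^2 + (1 - s)^2).}
#' Genes falling clearly below this curve use fewer codons than their
#' composition explains -- the signature read as selection.
#'
#' @param s GC3 fraction(s) in \[0, 1\].
#' @return Expected ENC value(s).
#' @examples
#' expected_enc(0.5)   # 60.5
#' @export
expected_enc <- function(s) {
  stopifnot(is.numeric(s))
  if (any(is.na(s)) || any(s < 0 | s > 1)) {
    stop("GC3 fraction must lie in [0, 1]")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Effective number of codons (ENC)
#'
#' Wright-style estimator of how far a gene's codon usage departs from
#' uniform use of synonymous codons, on a 20 (one codon per amino acid,
#' complete bias) to 61 (all sense codons used evenly) scale. Per amino
#' acid with family total \eqn{n \ge 2} and usage proportions \eqn{p_i},
#' the codon homozygosity is \deqn{F = (n \sum p_i^2 - 1) / (n - 1);}
#' \eqn{\bar F_k} averages F over the amino acids of degeneracy k with
#' defined positive F, and
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' When Ile (the only 3-fold family) is unestimable, \eqn{\bar F_3} is
#' imputed as \eqn{(\bar F_2 + \bar F_4)/2}. Finite-sample estimates above
#' 61 are truncated to 61. ENC below 35 is conventionally read as
#' significant codon usage bias.
#'
#' @param x a [cds()] object or `"codon_counts"` table.
#' @param code genetic code.
#' @return An object of class `"enc_result"`: list with `enc`, `gc3`,
#'   `expected_enc`, `class_homozygosities` (named over degeneracy classes
#'   2, 3, 4, 6), and `significant_bias` (`enc < 35`).
#' @export
enc <- function(x, code = genetic_code()) {
  counts <- as_codon_counts(x)$counts
  fam_F <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    k <- length(fam)
    if (k < 2L) return(NULL)
    n <- sum(counts[fam])
    if (n < 2L) return(NULL)
    p <- counts[fam] / n
    F <- (n * sum(p^2) - 1) / (n - 1)
    if (!is.finite(F) || F <= 0) return(NULL)
    data.frame(aa = aa, k = k, F = F, stringsAsFactors = FALSE)
  })
  fam_F <- do.call(rbind, fam_F)
  classes <- c(2L, 3L, 4L, 6L)
  n_aa <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  Fbar <- vapply(classes, function(k) {
    if (is.null(fam_F)) return(NA_real_)
    Fs <- fam_F$F[fam_F$k == k]
    if (length(Fs)) mean(Fs) else NA_real_
  }, numeric(1))
  names(Fbar) <- classes
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"])) {
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  }
  missing <- names(Fbar)[is.na(Fbar)]
  if (length(missing)) {
    stop("ENC unestimable: no usable family in degeneracy class(es) ",
         paste(missing, collapse = ", "))
  }
  raw <- 2 + sum(n_aa / Fbar)
  value <- min(raw, 61)
  g3 <- tryCatch(gc3(counts_object(counts), code), error = function(e) NA_real_)
  structure(
    list(
      enc = value, gc3 = g3,
      expected_enc = if (is.na(g3)) NA_real_ else expected_enc(g3),
      class_homozygosities = Fbar,
      significant_bias = value < 35
    ),
    class = "enc_result"
  )
}

# wrap a bare named count vector back into a codon_counts object
counts_object <- function(counts) {
  structure(list(counts = counts, total = sum(counts), n_ambiguous = 0L),
            class = "codon_counts")
}

#' @export
print.enc_result <- function(x, digits = 3, ...) {
  cat(sprintf("<enc_result> ENC = %.*f (GC3 = %.*f, expected %.*f)%s\n",
              digits, x$enc, digits, x$gc3, digits, x$expected_enc,
              if (isTRUE(x$significant_bias)) " [significant bias]" else ""))
  invisible(x)
}
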