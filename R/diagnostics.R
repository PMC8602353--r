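#' Parity rule 2 (PR2) bias coordinates
#'
#' Third-position base counts pooled over the five strictly fourfold
#' degenerate families (Ala, Gly, Pro, Thr, Val), where the third position
#' is fully synonymous, summarized as AT bias = A3/(A3 + T3) and GC bias =
#' G3/(G3 + C3). Under parity rule 2 -- no strand-specific asymmetry
#' between mutation and selection pressures -- A = T and G = C at these
#' positions, placing the gene at the plot center (0.5, 0.5).
#'
#' @param x a [cds()] object or `"codon_counts"` table.
#' @param code genetic code.
#' @return List with `at_bias`, `gc_bias` (in \[0, 1\], `NA` when the
#'   denominator is zero) and the pooled counts `a3`, `t3`, `g3`, `c3`.
#' @export
pr2_point <- function(x, code = genetic_code()) {
  counts <- as_codon_counts(x)$counts
  fourfold <- unlist(code$families[code$fourfold_aa], use.names = FALSE)
  third <- substr(fourfold, 3L, 3L)
  base_count <- function(b) sum(counts[fourfold[third == b]])
  a3 <- base_count("A"); t3 <- base_count("T")
  g3 <- base_count("G"); c3 <- base_count("C")
  list(
    at_bias = if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_,
    gc_bias = if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_,
    a3 = a3, t3 = t3, g3 = g3, c3 = c3
  )
}

#' Per-gene ENC vs GC3 table against the null curve
#'
#' Computes ENC, GC3, the expected ENC under composition constraint alone,
#' and the residual `enc - expected_enc(gc3)` for every gene of a cohort.
#' A negative residual places the gene below the null curve: stronger
#' codon usage bias than its GC3 alone explains, the pattern read as
#' selection-dominated.
#'
#' @param x a `"cds_set"`.
#' @param code genetic code.
#' @return Data frame with columns `id`, `species`, `gc3`, `enc`,
#'   `expected_enc`, `residual`, `significant_bias`; genes whose ENC is
#'   unestimable get `NA` statistics.
#' @export
enc_gc3_table <- function(x, code = genetic_code()) {
  rows <- lapply(x, function(s) {
    e <- tryCatch(enc(s, code), error = function(err) NULL)
    if (is.null(e)) {
      data.frame(id = s$id, species = s$species, gc3 = NA_real_,
                 enc = NA_real_, expected_enc = NA_real_,
                 residual = NA_real_, significant_bias = NA,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = s$id, species = s$species, gc3 = e$gc3,
                 enc = e$enc, expected_enc = e$expected_enc,
                 residual = e$enc - e$expected_enc,
                 significant_bias = e$significant_bias,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Overall-versus-positional skew correlations across a cohort
#'
#' For each of the six skew variants and each codon position, the Pearson
#' correlation (two-tailed test) across genes between the overall skew of
#' the gene and its skew at that position. Strong position-3 correlations
#' indicate that the whole-gene asymmetry is carried by the synonymous
#' position; genes with an undefined skew in a cell are dropped pairwise.
#'
#' @param skews a list of [skew_profile()] matrices (one per gene), or a
#'   `"cds_set"` from which they are computed.
#' @return Data frame with 18 rows: `skew_type`, `position`, `r`,
#'   `p_value`, `n`, `label` (`***` for p < 0.001, `*` for p <= 0.05,
#'   `NS` above 0.05). `r` is `NA` when fewer than 3 complete pairs or a
#'   constant column.
#' @export
skew_correlation_table <- function(skews) {
  if (inherits(skews, "cds_set")) skews <- lapply(skews, skew_profile)
  types <- names(.skew_pairs)
  rows <- list()
  for (type in types) {
    overall <- vapply(skews, function(m) m[type, "overall"], numeric(1))
    for (pos in 1:3) {
      positional <- vapply(skews, function(m) m[type, paste0("pos", pos)],
                           numeric(1))
      ok <- stats::complete.cases(overall, positional)
      n <- sum(ok)
      r <- NA_real_; p <- NA_real_
      if (n >= 3 && stats::sd(overall[ok]) > 0 &&
          stats::sd(positional[ok]) > 0) {
        ct <- stats::cor.test(overall[ok], positional[ok],
                              method = "pearson",
                              alternative = "two.sided")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      label <- if (is.na(p)) NA_character_
        else if (p < 0.001) "***" else if (p <= 0.05) "*" else "NS"
      rows[[length(rows) + 1L]] <- data.frame(
        skew_type = type, position = pos, r = r, p_value = p, n = n,
        label = label, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' PCA of codon or amino-acid usage across a cohort
#'
#' Column-mean-centered, unscaled principal component analysis of the
#' genes x features usage matrix -- either the 59-dimensional RSCU vectors
#' or the 20-dimensional amino-acid frequency vectors. RSCU entries
#' undefined for a gene (whole amino-acid family absent) are imputed by
#' the codon's cohort mean before centering, which preserves column means
#' without dropping genes; no variance scaling is applied since RSCU is
#' already family-normalized.
#'
#' @param m numeric matrix, genes x features (59 or 20 columns).
#' @param feature_space `"rscu59"` or `"aa20"` (recorded for plotting).
#' @return An object of class `"pca_usage"`: list with `coordinates`
#'   (genes x components scores, zero column means),
#'   `explained_variance_ratio`, `loadings` (features x components),
#'   `center`, `data` (the imputed matrix) and `feature_space`. Components
#'   run up to `min(genes - 1, features)`.
#' @export
pca_usage <- function(m, feature_space = c("rscu59", "aa20")) {
  feature_space <- match.arg(feature_space)
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) < 2L) stop("PCA requires at least 2 genes")
  imputed <- apply(m, 2L, function(col) {
    if (anyNA(col)) {
      mu <- mean(col, na.rm = TRUE)
      col[is.na(col)] <- if (is.nan(mu)) 0 else mu
    }
    col
  })
  rownames(imputed) <- rownames(m)
  fit <- stats::prcomp(imputed, center = TRUE, scale. = FALSE)
  ncomp <- min(nrow(m) - 1L, ncol(m))
  var <- fit$sdev^2
  structure(
    list(
      coordinates = fit$x[, seq_len(ncomp), drop = FALSE],
      explained_variance_ratio = (var / sum(var))[seq_len(ncomp)],
      loadings = fit$rotation[, seq_len(ncomp), drop = FALSE],
      center = fit$center,
      data = imputed,
      feature_space = feature_space
    ),
    class = "pca_usage"
  )
}

#' @export
print.pca_usage <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf(
    "<pca_usage> %s: %d genes x %d features; PC1 %.1f%%, PC2 %.1f%%\n",
    x$feature_space, nrow(x$coordinates), nrow(x$loadings),
    100 * evr[1], if (length(evr) > 1) 100 * evr[2] else NA
  ))
  invisible(x)
}
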