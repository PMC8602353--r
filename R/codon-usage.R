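#' Codon usage bias analysis of a CDS cohort
#'
#' The package's main entry point: runs the full codon-usage-bias analysis
#' over a cohort of orthologous coding sequences and returns one object
#' holding every per-gene and cohort-level result. Per gene: positional
#' nucleotide composition, the two entropy bias measures, the six skew
#' variants at four scopes, RSCU with bias classification, ENC, GC3, the
#' expected-ENC residual, and the PR2 point. Per cohort: the Vs dispersion
#' table, the absent-codon report, the 18-cell overall-vs-positional skew
#' correlation table, and PCA of both the RSCU and the amino-acid usage
#' matrices.
#'
#' Genes failing validation (or on which a statistic is unestimable) are
#' never dropped silently: they appear in the `skipped` table, and
#' `nrow(genes) + nrow(skipped)` always equals the number of input
#' records.
#'
#' @param x a FASTA file path, a `"cds_set"`, or a `"synthetic_cohort"`.
#' @param strictness validation mode passed to [read_cds_fasta()] when `x`
#'   is a path.
#' @param code genetic code.
#' @return An object of class `"codon_usage"` with components `genes` (the
#'   per-gene statistics data frame), `rscu` (genes x 59 matrix),
#'   `aa_freq` (genes x 20 matrix), `vs`, `absent_codons`, `skew_cor`,
#'   `pca_rscu`, `pca_aa`, `skipped`, `n_input` and `call`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_species = 5, protein_length = 120,
#'                                   seed = 11))
#' fit <- codon_usage(co$sequences)
#' summary(fit)
#' head(residuals(fit))
#' @export
codon_usage <- function(x, strictness = c("lenient", "strict"),
                        code = genetic_code()) {
  strictness <- match.arg(strictness)
  cl <- match.call()
  input_path <- if (is.character(x)) x else NA_character_
  if (inherits(x, "synthetic_cohort")) x <- x$sequences
  if (is.character(x)) x <- read_cds_fasta(x, strictness)
  if (!inherits(x, "cds_set")) x <- structure(x, class = "cds_set")
  n_input <- length(x)
  if (n_input == 0L) stop("empty cohort")

  skipped <- list()
  gene_rows <- list()
  rscu_rows <- list()
  aa_rows <- list()
  skews <- list()
  species_labels <- character(0)

  for (s in x) {
    rep <- validate_cds(s)
    if (!rep$ok) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        id = s$id, species = s$species,
        reason = paste(rep$issues$code[rep$issues$severity == "error"],
                       collapse = ","),
        stringsAsFactors = FALSE
      )
      next
    }
    counts <- count_codons(s)
    r <- tryCatch(rscu(counts, code), error = function(e) NULL)
    if (is.null(r)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        id = s$id, species = s$species, reason = "NO_SENSE_CODONS",
        stringsAsFactors = FALSE
      )
      next
    }
    comp <- nucleotide_composition(s)
    ent <- entropy_profile(comp)
    sk <- skew_profile(comp)
    e <- tryCatch(enc(counts, code), error = function(err) NULL)
    g3 <- tryCatch(gc3(counts, code), error = function(err) NA_real_)
    p2 <- pr2_point(counts, code)
    cls <- classify_rscu(r$values)

    row <- data.frame(
      id = s$id, species = s$species,
      length_nt = nchar(s$sequence), n_codons = counts$total,
      H_overall = ent$H_overall, H_pos1 = ent$H_pos1,
      H_pos2 = ent$H_pos2, H_pos3 = ent$H_pos3,
      H_A = ent$per_nucleotide[["A"]], H_T = ent$per_nucleotide[["T"]],
      H_G = ent$per_nucleotide[["G"]], H_C = ent$per_nucleotide[["C"]],
      stringsAsFactors = FALSE
    )
    for (type in rownames(sk)) {
      row[[paste0(type, "_skew")]] <- sk[type, "overall"]
      for (pos in 1:3) {
        row[[paste0(type, "_skew_pos", pos)]] <-
          sk[type, paste0("pos", pos)]
      }
    }
    row$enc <- if (is.null(e)) NA_real_ else e$enc
    row$gc3 <- g3
    row$expected_enc <- if (is.na(g3)) NA_real_ else expected_enc(g3)
    row$enc_residual <- row$enc - row$expected_enc
    row$significant_bias <- if (is.null(e)) NA else e$significant_bias
    row$pr2_at_bias <- p2$at_bias
    row$pr2_gc_bias <- p2$gc_bias
    row$n_overrepresented <- sum(cls == "overrepresented")
    row$n_underrepresented <- sum(cls == "underrepresented")
    row$n_absent <- sum(cls == "absent")
    row$n_undefined <- sum(cls == "undefined")

    gene_rows[[length(gene_rows) + 1L]] <- row
    rscu_rows[[s$id]] <- r
    aa_rows[[s$id]] <- amino_acid_frequencies(counts, code)
    skews[[s$id]] <- sk
    species_labels <- c(species_labels, s$species)
  }

  if (!length(gene_rows)) stop("no analyzable genes in cohort")
  genes <- do.call(rbind, c(gene_rows, list(make.row.names = FALSE)))
  skipped <- if (length(skipped)) {
    do.call(rbind, c(skipped, list(make.row.names = FALSE)))
  } else {
    data.frame(id = character(0), species = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }

  rm_ <- rscu_matrix(rscu_rows, code)
  aa_m <- do.call(rbind, aa_rows)
  names(rscu_rows) <- species_labels  # absent report keyed by species

  structure(
    list(
      genes = genes,
      rscu = rm_,
      aa_freq = aa_m,
      vs = vs_dispersion(rm_, code),
      absent_codons = absent_codon_report(rscu_rows, code),
      skew_cor = if (nrow(genes) >= 3L) skew_correlation_table(skews)
        else NULL,
      pca_rscu = if (nrow(genes) >= 2L) pca_usage(rm_, "rscu59")
        else NULL,
      pca_aa = if (nrow(genes) >= 2L) pca_usage(aa_m, "aa20") else NULL,
      skipped = skipped,
      n_input = n_input,
      input_path = input_path,
      call = cl
    ),
    class = "codon_usage"
  )
}

#' @export
print.codon_usage <- function(x, ...) {
  g <- x$genes
  cat(sprintf("Codon usage bias analysis: %d gene(s) (%d skipped)\n",
              nrow(g), nrow(x$skipped)))
  cat(sprintf("  ENC    median %.2f (range %.2f-%.2f), %d below 35\n",
              stats::median(g$enc, na.rm = TRUE),
              min(g$enc, na.rm = TRUE), max(g$enc, na.rm = TRUE),
              sum(g$significant_bias, na.rm = TRUE)))
  cat(sprintf("  GC3    median %.3f\n",
              stats::median(g$gc3, na.rm = TRUE)))
  cat(sprintf("  H(N)   median %.3f bits\n",
              stats::median(g$H_overall, na.rm = TRUE)))
  invisible(x)
}

tukey_outliers <- function(v, ids) {
  v_ok <- !is.na(v)
  if (!any(v_ok)) return(character(0))
  q <- stats::quantile(v[v_ok], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  out <- v_ok & (v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr)
  ids[out]
}

#' Summarize a codon usage analysis
#'
#' Cohort medians and interquartile ranges of the entropy, ENC and GC3
#' statistics, the count of genes with significant bias (ENC < 35), the
#' number of absent-codon events, and the genes lying beyond 1.5 x IQR of
#' each headline statistic (the usual boxplot outlier rule).
#'
#' @param object a `"codon_usage"` fit.
#' @param ... unused.
#' @return An object of class `"summary.codon_usage"`.
#' @export
summary.codon_usage <- function(object, ...) {
  g <- object$genes
  stat_cols <- c("H_overall", "H_pos1", "H_pos2", "H_pos3",
                 "enc", "gc3", "enc_residual")
  stats_tab <- t(vapply(stat_cols, function(col) {
    v <- g[[col]]
    c(median = stats::median(v, na.rm = TRUE),
      q1 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
      q3 = unname(stats::quantile(v, 0.75, na.rm = TRUE)))
  }, numeric(3)))
  outliers <- lapply(
    stats::setNames(nm = c("H_overall", "H_pos3", "enc", "enc_residual")),
    function(col) tukey_outliers(g[[col]], g$id)
  )
  structure(
    list(
      n_genes = nrow(g), n_skipped = nrow(object$skipped),
      stats = stats_tab,
      n_significant_bias = sum(g$significant_bias, na.rm = TRUE),
      n_absent_events = if (nrow(object$absent_codons)) {
        sum(object$absent_codons$n_species)
      } else 0L,
      n_below_curve = sum(g$enc_residual < 0, na.rm = TRUE),
      outliers = outliers
    ),
    class = "summary.codon_usage"
  )
}

#' @export
print.summary.codon_usage <- function(x, digits = 3, ...) {
  cat(sprintf("Codon usage bias summary: %d gene(s), %d skipped\n",
              x$n_genes, x$n_skipped))
  cat("\nCohort statistics (median [Q1, Q3]):\n")
  for (nm in rownames(x$stats)) {
    cat(sprintf("  %-13s %8.3f [%8.3f, %8.3f]\n", nm,
                x$stats[nm, "median"], x$stats[nm, "q1"],
                x$stats[nm, "q3"]))
  }
  cat(sprintf("\nGenes with significant bias (ENC < 35): %d\n",
              x$n_significant_bias))
  cat(sprintf("Genes below the expected-ENC curve:      %d\n",
              x$n_below_curve))
  cat(sprintf("Absent-codon events (codon x species):   %d\n",
              x$n_absent_events))
  any_out <- any(lengths(x$outliers) > 0)
  cat("\nBoxplot outliers (1.5 x IQR):\n")
  if (!any_out) cat("  none\n")
  for (nm in names(x$outliers)) {
    ids <- x$outliers[[nm]]
    if (length(ids)) {
      cat(sprintf("  %-13s %s\n", nm, paste(ids, collapse = ", ")))
    }
  }
  invisible(x)
}

#' ENC residuals against the composition-only null curve
#'
#' @param object a `"codon_usage"` fit.
#' @param ... unused.
#' @return Named numeric vector: per gene, observed ENC minus the expected
#'   ENC at the gene's GC3. Negative values lie below the null curve.
#' @export
residuals.codon_usage <- function(object, ...) {
  stats::setNames(object$genes$enc_residual, object$genes$id)
}

#' Diagnostic plots for a codon usage analysis
#'
#' Base-graphics analogues of the standard codon-bias figures: the
#' ENC-GC3 plot with the composition-only expected curve, the PR2 bias
#' plot with its (0.5, 0.5) parity center, PCA score plots, and boxplots
#' of the entropy measures.
#'
#' @param x a `"codon_usage"` fit.
#' @param which one of `"enc"`, `"pr2"`, `"pca_rscu"`, `"pca_aa"`,
#'   `"entropy"`.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.codon_usage <- function(x, which = c("enc", "pr2", "pca_rscu",
                                          "pca_aa", "entropy"), ...) {
  which <- match.arg(which)
  g <- x$genes
  if (which == "enc") {
    graphics::plot(g$gc3, g$enc, xlim = c(0, 1), ylim = c(20, 62),
                   xlab = "GC3", ylab = "ENC",
                   main = "ENC vs GC3", pch = 19,
                   col = grDevices::adjustcolor("steelblue", 0.7), ...)
    s <- seq(0.001, 0.999, length.out = 400)
    graphics::lines(s, expected_enc(s), lwd = 2)
    graphics::abline(h = 35, lty = 3)
  } else if (which == "pr2") {
    graphics::plot(g$pr2_gc_bias, g$pr2_at_bias, xlim = c(0, 1),
                   ylim = c(0, 1), xlab = "G3/(G3+C3)",
                   ylab = "A3/(A3+T3)", main = "PR2 bias plot",
                   pch = 19,
                   col = grDevices::adjustcolor("firebrick", 0.7), ...)
    graphics::abline(h = 0.5, v = 0.5, lty = 2)
  } else if (which %in% c("pca_rscu", "pca_aa")) {
    p <- if (which == "pca_rscu") x$pca_rscu else x$pca_aa
    if (is.null(p)) stop("PCA unavailable (fewer than 2 genes)")
    evr <- 100 * p$explained_variance_ratio
    graphics::plot(p$coordinates[, 1], p$coordinates[, 2],
                   xlab = sprintf("PC1 (%.1f%%)", evr[1]),
                   ylab = sprintf("PC2 (%.1f%%)", evr[2]),
                   main = sprintf("PCA of %s usage", p$feature_space),
                   pch = 19,
                   col = grDevices::adjustcolor("darkgreen", 0.7), ...)
  } else {
    graphics::boxplot(
      g[, c("H_overall", "H_pos1", "H_pos2", "H_pos3")],
      names = c("N", "N1", "N2", "N3"),
      ylab = "entropy (bits)",
      main = "Nucleotide usage bias by codon position", ...
    )
  }
  invisible(x)
}

format_tsv_num <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- round(df[[col]], 6)
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(format_tsv_num(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
}

#' Write all result tables of a codon usage analysis
#'
#' Writes the per-gene statistics and every cohort-level table as TSV
#' files (missing values as `NA`; numeric columns rounded to 6 decimals),
#' plus a run manifest recording the package version, the input checksum
#' when the input was a file, and per-stage record counts. Output is
#' deterministic: identical input yields byte-identical files.
#'
#' @param object a `"codon_usage"` fit.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_results <- function(object, dir) {
  stopifnot(inherits(object, "codon_usage"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  write_tsv(object$genes, p("genes.tsv"))
  write_tsv(object$skipped, p("skipped.tsv"))
  write_tsv(object$vs, p("vs.tsv"))
  write_tsv(object$absent_codons, p("absent_codons.tsv"))
  write_tsv(cbind(data.frame(id = rownames(object$rscu),
                             stringsAsFactors = FALSE),
                  as.data.frame(object$rscu)), p("rscu_matrix.tsv"))
  write_tsv(cbind(data.frame(id = rownames(object$aa_freq),
                             stringsAsFactors = FALSE),
                  as.data.frame(object$aa_freq)), p("aa_freq.tsv"))
  write_tsv(object$genes[, c("id", "pr2_at_bias", "pr2_gc_bias")],
            p("pr2.tsv"))
  write_tsv(object$genes[, c("id", "gc3", "enc", "expected_enc",
                             "enc_residual", "significant_bias")],
            p("enc_gc3.tsv"))
  if (!is.null(object$skew_cor)) {
    write_tsv(object$skew_cor, p("skew_correlations.tsv"))
  }
  for (space in c("rscu", "aa")) {
    pc <- object[[paste0("pca_", space)]]
    if (is.null(pc)) next
    write_tsv(cbind(data.frame(id = rownames(pc$coordinates),
                               stringsAsFactors = FALSE),
                    as.data.frame(pc$coordinates)),
              p(sprintf("pca_%s_coords.tsv", space)))
    write_tsv(data.frame(component = seq_along(pc$explained_variance_ratio),
                         explained_variance_ratio =
                           pc$explained_variance_ratio),
              p(sprintf("pca_%s_variance.tsv", space)))
  }
  manifest <- data.frame(
    key = c("package", "version", "n_input", "n_analyzed", "n_skipped",
            "input", "input_md5"),
    value = c(
      "codonbias",
      as.character(utils::packageVersion("codonbias")),
      object$n_input, nrow(object$genes), nrow(object$skipped),
      if (is.na(object$input_path)) "in-memory" else object$input_path,
      if (is.na(object$input_path)) "NA" else
        unname(tools::md5sum(object$input_path))
    ),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, p("manifest.tsv"))
  invisible(dir)
}
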