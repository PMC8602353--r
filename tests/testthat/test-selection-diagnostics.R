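test_that("PR2 coordinates follow the fourfold third-position ratios", {
  # equal counts of all four Ala codons: dead center
  g <- cds_from_codons(c("GCA", "GCT", "GCG", "GCC"))
  p <- pr2_point(g)
  expect_equal(p$at_bias, 0.5)
  expect_equal(p$gc_bias, 0.5)

  # only G-ending fourfold codons: gc_bias 1, at_bias undefined
  p <- pr2_point(cds_from_codons(c("GCG", "GGG", "CCG")))
  expect_equal(p$gc_bias, 1)
  expect_true(is.na(p$at_bias))

  # A3=3, T3=1, G3=1, C3=3
  p <- pr2_point(cds_from_codons(c("GCA", "GGA", "CCA", "ACT",
                                   "GTG", "GCC", "GGC", "CCC")))
  expect_equal(p$at_bias, 0.75)
  expect_equal(p$gc_bias, 0.25)

  # sixfold families contribute nothing: Leu/Ser/Arg codons are ignored
  p0 <- pr2_point(cds_from_codons(c("GCA", "GCT")))
  p1 <- pr2_point(cds_from_codons(c("GCA", "GCT", "CTG", "TCG", "CGG")))
  expect_equal(p0[c("at_bias", "gc_bias")], p1[c("at_bias", "gc_bias")])

  expect_true(is.na(pr2_point(cds_from_codons("ATG"))$at_bias))
})

test_that("PR2 is invariant to codon order and count scaling", {
  set.seed(37)
  g <- random_gene(80)
  perm <- cds_from_codons(sample(g$codons))
  expect_equal(pr2_point(g)[c("at_bias", "gc_bias")],
               pr2_point(perm)[c("at_bias", "gc_bias")])
  counts <- count_codons(g)$counts
  scaled <- counts_as_table(counts * 5L)
  expect_equal(pr2_point(counts_as_table(counts))[c("at_bias", "gc_bias")],
               pr2_point(scaled)[c("at_bias", "gc_bias")])
})

test_that("the ENC-GC3 table carries residuals against the null curve", {
  co <- generate_cohort(cohort_spec(n_species = 4, protein_length = 150,
                                    seed = 41))
  tab <- enc_gc3_table(co$sequences)
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$residual, tab$enc - expected_enc(tab$gc3))
  expect_equal(tab$expected_enc, expected_enc(tab$gc3))
  # arithmetic of the diagnostic: a gene at gc3 0.5 with ENC 55 sits 5.5 low
  expect_equal(55 - expected_enc(0.5), -5.5)
})

test_that("skew correlations match the brute-force Pearson oracle", {
  set.seed(43)
  skews <- lapply(1:30, function(i) skew_profile(random_gene(50)))
  tab <- skew_correlation_table(skews)
  expect_identical(nrow(tab), 18L)
  for (i in seq_len(nrow(tab))) {
    type <- tab$skew_type[i]; pos <- tab$position[i]
    x <- vapply(skews, function(m) m[type, "overall"], numeric(1))
    y <- vapply(skews, function(m) m[type, paste0("pos", pos)], numeric(1))
    ok <- stats::complete.cases(x, y)
    want <- oracle_pearson(x[ok], y[ok])
    expect_equal(tab$r[i], want$r, tolerance = 1e-12)
    expect_equal(tab$p_value[i], want$p, tolerance = 1e-12)
    expect_identical(tab$n[i], sum(ok))
  }
})

test_that("degenerate skew correlation inputs are handled", {
  # positional skew identical to overall: r = 1
  skews <- lapply(1:10, function(i) {
    v <- stats::runif(1, -0.5, 0.5)
    m <- matrix(v, nrow = 6, ncol = 4,
                dimnames = list(names(codonbias:::.skew_pairs),
                                c("overall", "pos1", "pos2", "pos3")))
    m[, "pos2"] <- -v  # mirrored at position 2
    structure(m, class = c("skew_profile", "matrix"))
  })
  tab <- skew_correlation_table(skews)
  expect_equal(tab$r[tab$skew_type == "at" & tab$position == 1], 1)
  expect_equal(tab$r[tab$skew_type == "at" & tab$position == 2], -1)

  # fewer than 3 genes: missing r
  expect_true(all(is.na(skew_correlation_table(skews[1:2])$r)))
})

test_that("null skews give near-nominal type I error rates", {
  set.seed(47)
  # independent overall/positional values: p should be ~uniform
  reps <- 400
  hits <- 0L
  for (i in seq_len(reps)) {
    x <- stats::rnorm(40); y <- stats::rnorm(40)
    p <- oracle_pearson(x, y)$p
    ct <- stats::cor.test(x, y)
    expect_equal(ct$p.value, p, tolerance = 1e-10)
    if (p < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / reps - 0.05), 0.04)
})

test_that("usage PCA is centered, ordered and reconstructs its input", {
  set.seed(53)
  co <- generate_cohort(cohort_spec(n_species = 12, protein_length = 200,
                                    seed = 59))
  fitr <- pca_usage(rscu_matrix(co$sequences), "rscu59")
  expect_true(all(abs(colMeans(fitr$coordinates)) < 1e-10))
  evr <- fitr$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-12)
  expect_identical(ncol(fitr$coordinates), 11L)  # min(genes-1, features)

  # reconstruction through loadings + centers recovers the imputed matrix
  rec <- fitr$coordinates %*% t(fitr$loadings)
  rec <- sweep(rec, 2L, fitr$center, "+")
  expect_equal(unname(rec), unname(fitr$data), tolerance = 1e-8)

  # explained variance matches a direct covariance eigensolve
  expect_equal(evr, oracle_pca_evr(fitr$data)[seq_along(evr)],
               tolerance = 1e-8)
})

test_that("PCA edge geometry behaves as expected", {
  m <- matrix(c(1, 1, 1, 1, 1, 1), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("f", 1:3)))
  m2 <- rbind(m, g3 = c(5, 1, 1))
  fit <- pca_usage(m2, "aa20")
  # two identical genes share coordinates
  expect_equal(fit$coordinates["g1", ], fit$coordinates["g2", ])
  # all variance in one feature: PC1 explains everything
  expect_equal(fit$explained_variance_ratio[1], 1)

  # duplicating every gene leaves the variance ratios unchanged
  set.seed(61)
  m <- matrix(stats::rnorm(60), nrow = 6)
  dup <- m[rep(seq_len(6), each = 2), ]
  e1 <- pca_usage(m, "aa20")$explained_variance_ratio
  e2 <- pca_usage(dup, "aa20")$explained_variance_ratio
  expect_equal(e2[seq_along(e1)], e1, tolerance = 1e-10)

  expect_error(pca_usage(m[1, , drop = FALSE], "aa20"), "at least 2")
})

test_that("undefined RSCU entries are imputed by the codon cohort mean", {
  code <- genetic_code()
  m <- matrix(1, nrow = 4, ncol = 59,
              dimnames = list(paste0("g", 1:4), code$rscu_codons))
  m[, "GCT"] <- c(2, 4, NA, NA)
  fit <- pca_usage(m, "rscu59")
  expect_equal(unname(fit$data[3:4, "GCT"]), c(3, 3))
})
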