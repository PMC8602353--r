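test_that("RSCU matches the family-normalized definition", {
  g <- cds_from_codons(c("GCT", "GCT", "GCC", "GCA", "ATG", "TAA"))
  r <- rscu(g)
  expect_length(r$values, 59L)
  expect_equal(unname(r$values[c("GCT", "GCC", "GCA", "GCG")]),
               c(2, 1, 1, 0))
  expect_true("GCG" %in% r$absent_codons)
  # Cys never used: TGT/TGC undefined, not absent
  expect_true(all(c("TGT", "TGC") %in% r$undefined_codons))
  expect_true(is.na(r$values["TGT"]))
  expect_false("TGT" %in% r$absent_codons)

  # equal use within a family: RSCU 1 for each member
  g <- cds_from_codons(c("GGT", "GGC", "GGA", "GGG"))
  expect_equal(unname(rscu(g)$values[c("GGT", "GGC", "GGA", "GGG")]),
               rep(1, 4))

  expect_error(rscu(cds("TAATAG")), "sense")
})

test_that("RSCU family sums equal degeneracy and scale out of counts", {
  code <- genetic_code()
  set.seed(29)
  for (i in 1:100) {
    counts <- random_counts()
    if (sum(counts[code$sense_codons]) == 0) next
    r <- rscu(counts_as_table(counts))
    for (aa in names(code$families)) {
      fam <- code$families[[aa]]
      if (length(fam) < 2L || sum(counts[fam]) == 0L) next
      expect_equal(sum(r$values[fam]), length(fam))
      expect_equal(mean(r$values[fam]), 1)
    }
    expect_true(all(r$values >= 0, na.rm = TRUE))
    # scale invariance under any positive integer multiple
    k <- sample(2:7, 1)
    r2 <- rscu(counts_as_table(counts * k))
    expect_equal(r2$values, r$values)
  }
})

test_that("RSCU classification uses strict 0.6 / 1.6 thresholds", {
  expect_identical(
    unname(classify_rscu(c(1.7, 0.5, 1.0, 1.6, 0.6, 0, NA))),
    c("overrepresented", "underrepresented", "unbiased", "unbiased",
      "unbiased", "absent", "undefined")
  )
})

test_that("absent-codon report distinguishes avoidance from missing families", {
  # species sp1 lacks CTG but uses other Leu codons; sp2 uses everything;
  # sp3 lacks Cys entirely
  leu_no_ctg <- c("TTA", "TTG", "CTT", "CTC", "CTA")
  sp1 <- rscu(cds_from_codons(c(leu_no_ctg, "TGT", "TGC")))
  sp2 <- rscu(cds_from_codons(c(leu_no_ctg, "CTG", "TGT", "TGC")))
  sp3 <- rscu(cds_from_codons(c(leu_no_ctg, "CTG", "GCA")))
  rep <- absent_codon_report(list(sp1 = sp1, sp2 = sp2, sp3 = sp3))
  expect_identical(rep$species[rep$codon == "CTG"], "sp1")
  # sp3 has no Cys at all: not listed as avoiding TGT/TGC
  expect_false(any(rep$codon %in% c("TGT", "TGC") &
                     grepl("sp3", rep$species)))

  # complete usage everywhere: empty report
  code <- genetic_code()
  full <- rscu(cds_from_codons(code$sense_codons))
  expect_identical(nrow(absent_codon_report(list(a = full, b = full))), 0L)
})

test_that("Vs is the N-1 coefficient of variation over defined entries", {
  code <- genetic_code()
  m <- matrix(NA_real_, nrow = 3, ncol = 59,
              dimnames = list(c("s1", "s2", "s3"), code$rscu_codons))
  m["s1", ] <- 1; m["s2", ] <- 1; m["s3", ] <- 1
  m[, "GCT"] <- c(1, 2, 3)
  m["s3", "GCC"] <- NA  # one undefined entry
  vs <- vs_dispersion(m)
  row <- vs[vs$codon == "GCT", ]
  expect_equal(row$mean_rscu, 2)
  expect_equal(row$sd_rscu, 1)
  expect_equal(row$vs, 0.5)
  expect_identical(row$n_missing, 0L)

  # identical values: Vs = 0
  expect_equal(vs$vs[vs$codon == "GCA"], 0)
  # pairwise deletion recorded
  expect_identical(vs$n_species[vs$codon == "GCC"], 2L)
  expect_identical(vs$n_missing[vs$codon == "GCC"], 1L)

  # single species: Vs undefined
  vs1 <- vs_dispersion(m[1, , drop = FALSE])
  expect_true(all(is.na(vs1$vs)))
})

test_that("GC3 covers only synonymous third positions", {
  expect_equal(gc3(cds_from_codons(c("GCG", "GCC", "CCG"))), 1)
  expect_equal(gc3(cds_from_codons(c("GCA", "GCT", "CCT"))), 0)
  expect_equal(gc3(cds_from_codons(c("GCT", "GCG"))), 0.5)
  # ATG, TGG and stops carry no synonymous third position
  expect_equal(gc3(cds_from_codons(c("ATG", "TGG", "TAG", "GCT"))), 0)
  expect_error(gc3(cds_from_codons(c("ATG", "TGG"))), "undefined")
})

test_that("the expected-ENC null curve has its anchor values and symmetry", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  s <- seq(0, 0.5, by = 0.05)
  expect_equal(expected_enc(0.5 - s) - (0.5 - s),
               expected_enc(0.5 + s) - (0.5 + s))
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
})

test_that("ENC spans 20 to 61 with the < 35 bias rule", {
  code <- genetic_code()
  one_per_aa <- vapply(code$families, `[`, character(1), 1L)
  complete_bias <- cds_from_codons(rep(one_per_aa, each = 100))
  e <- enc(complete_bias)
  expect_equal(e$enc, 20)
  expect_true(e$significant_bias)
  expect_equal(unname(e$class_homozygosities), rep(1, 4))

  uniform <- stats::setNames(rep(0L, 64L), names(code$codon_to_aa))
  uniform[code$sense_codons] <- 1000L
  e <- enc(counts_as_table(uniform))
  expect_equal(e$enc, 61)
  expect_false(e$significant_bias)

  # 2-fold family with counts (3, 1): F = 0.5
  counts <- stats::setNames(rep(0L, 64L), names(code$codon_to_aa))
  counts[c("TTT", "TTC")] <- c(3L, 1L)          # Phe
  counts[c("ATT", "ATC", "ATA")] <- 2L          # Ile
  counts[c("GCT", "GCC", "GCA", "GCG")] <- 2L   # Ala
  counts[code$families$L] <- 2L                 # Leu
  e <- enc(counts_as_table(counts))
  expect_equal(unname(e$class_homozygosities["2"]), 0.5)

  expect_error(enc(counts_as_table(stats::setNames(rep(0L, 64L),
                                                   names(code$codon_to_aa)))),
               "unestimable")
})

test_that("ENC agrees with the brute-force homozygosity oracle", {
  code <- genetic_code()
  # small instances over <= 5 families covering every degeneracy class
  fams <- c("F", "I", "A", "L", "S")
  set.seed(31)
  for (i in 1:200) {
    counts <- stats::setNames(rep(0L, 64L), names(code$codon_to_aa))
    for (aa in fams) {
      fam <- code$families[[aa]]
      counts[fam] <- sample.int(20L, length(fam), replace = TRUE) - 1L
    }
    if (any(vapply(fams, function(aa) {
      sum(counts[code$families[[aa]]]) < 2
    }, logical(1)))) next
    got <- tryCatch(enc(counts_as_table(counts))$enc,
                    error = function(e) NA_real_)
    want <- oracle_enc(counts, code)
    if (!is.na(got)) expect_equal(got, want, tolerance = 1e-12)
  }
  # and on full random tables
  for (i in 1:50) {
    counts <- random_counts()
    got <- tryCatch(enc(counts_as_table(counts))$enc,
                    error = function(e) NA_real_)
    if (!is.na(got)) {
      expect_equal(got, oracle_enc(counts, code), tolerance = 1e-12)
    }
  }
})

test_that("Ile-free genes fall back to the imputed 3-fold homozygosity", {
  code <- genetic_code()
  counts <- stats::setNames(rep(0L, 64L), names(code$codon_to_aa))
  counts[c("TTT", "TTC")] <- c(4L, 2L)
  counts[c("GCT", "GCC", "GCA", "GCG")] <- 3L
  counts[code$families$L] <- 2L
  e <- enc(counts_as_table(counts))
  expect_equal(unname(e$class_homozygosities["3"]),
               mean(e$class_homozygosities[c("2", "4")]))
})
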