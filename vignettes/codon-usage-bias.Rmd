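---
title: "Methods: codon usage bias analysis with codonbias"
author: "codonbias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias analysis with codonbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The problem

Synonymous codons encode the same amino acid but are not used
interchangeably: genomes, and individual genes within them, prefer some
codons over their synonyms. Two forces shape this bias. *Mutation
pressure* — genome-wide nucleotide composition — pushes every position,
including the largely synonymous third codon position, toward the
genome's base mix. *Selection* (most prominently translational
selection, co-evolving with tRNA pools) favors particular codons
independently of composition. Disentangling the two from a cohort of
orthologous coding sequences is a classic exercise in molecular
evolution, and `codonbias` packages the standard toolkit for it: usage
entropies, RSCU and its cross-species dispersion, ENC against the GC3
null curve, PR2 bias coordinates, six nucleotide skews with positional
correlation analysis, and PCA of usage vectors — plus a generator of
synthetic orthologous cohorts with known ground truth, so every stage
can be validated without touching a sequence database.

`codon_usage()` is the single entry point: it takes a FASTA path or an
in-memory cohort and returns a classed object carrying all per-gene and
cohort-level results, with `print`, `summary`, `plot`, and `residuals`
methods and a `write_results()` exporter.

## Statistics computed

### Entropy measures of nucleotide usage

For a gene with base counts $F_A, F_T, F_G, F_C$ (overall or at one
codon position),

$$H = -\sum_i f_i \log_2 f_i, \qquad
  f_i = \frac{F_i}{F_A + F_T + F_G + F_C},$$

in bits, with $0 \log_2 0 := 0$ by continuity. $H = 2$ means uniform
usage of the four bases; lower is more biased. Computed overall and per
codon position (`H_overall`, `H_pos1..3`).

A second, complementary measure asks how evenly one nucleotide $n$ is
spread over the three codon positions:

$$H_n = -\sum_{p=1}^{3} f_p \log_2 f_p, \qquad
  f_p = \frac{F_n(p)}{F_n(1) + F_n(2) + F_n(3)},$$

bounded by $\log_2 3 \approx 1.585$. The denominator is deliberately the
count of *that nucleotide* summed over positions — the only reading
under which $f_p$ is a probability distribution (the alternative, total
positional content, would just reproduce the first measure per
position). A nucleotide absent from a gene yields `NA`, recorded rather
than raised, so cohort summaries can skip it.

### RSCU, classification, and cross-species dispersion

For codon $c$ in a synonymous family of size $k$ with family total $T$,
$\mathrm{RSCU}_c = k\,n_c/T$. The three stop codons and the single-codon
amino acids Met (ATG) and Trp (TGG) admit no synonymous choice, leaving
the canonical 59-dimensional RSCU vector. Values above 1.6 are
*overrepresented*, positive values below 0.6 *underrepresented* — strict
inequalities, so the boundary values themselves are unbiased. A codon
with zero count in a gene that otherwise uses its amino acid is
*absent* (true avoidance); a codon whose whole family is missing is
*undefined* (`NA`), and the two are never conflated: the absent-codon
report lists only the former, and undefined entries are skipped
pairwise (with `n_missing` recorded) in downstream statistics.

Cross-species stability of each codon's usage is summarized by the
coefficient of variation
$V_s = \sigma/\bar{x}$, with $\sigma$ the sample standard deviation
(denominator $N-1$) of the codon's RSCU over the cohort: lower $V_s$,
more conserved usage.

### ENC and the GC3 null curve

The effective number of codons summarizes overall bias on a 20 (one
codon per amino acid) to 61 (all sense codons even) scale, using the
Wright estimator: per amino acid with family total $n \ge 2$ and usage
proportions $p_i$, the homozygosity is $F = (n\sum p_i^2 - 1)/(n-1)$;
class means $\bar F_k$ are taken over amino acids of degeneracy
$k \in \{2, 3, 4, 6\}$ with defined positive $F$, and

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3}
  + \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

When Ile (the only 3-fold family) is unestimable, $\bar F_3$ is imputed
as $(\bar F_2 + \bar F_4)/2$; six-fold amino acids are treated as
single families (consistent with the 20–61 range); finite-sample
estimates above 61 are truncated to 61; ENC below 35 is flagged as
significant bias (strictly below). The composition-only expectation at
third-position GC content $s$ is

$$\mathrm{ENC}_{exp}(s) = 2 + s + \frac{29}{s^2 + (1-s)^2},$$

and `residuals()` returns $\mathrm{ENC} - \mathrm{ENC}_{exp}(GC3)$ per
gene: genes well below zero are more biased than their composition
explains, the signature read as selection. GC3 itself is computed over
sense codons excluding ATG and TGG, whose third position is not
synonymous.

### PR2, skews, and their correlations

PR2 coordinates pool third-position counts over the five strictly
fourfold-degenerate families (Ala, Gly, Pro, Thr, Val) — not the
fourfold subsets of Leu/Ser/Arg, whose usage also reflects the
first-position choice — and plot
$\mathrm{AT bias} = A_3/(A_3+T_3)$ against
$\mathrm{GC bias} = G_3/(G_3+C_3)$. At (0.5, 0.5) mutation and
selection pressures are balanced between complementary bases.

Six skew variants, each overall and per position:
AT $(A-T)/(A+T)$, GC $(G-C)/(G+C)$, purine $(A-G)/(A+G)$, pyrimidine
$(T-C)/(T+C)$, keto $(T-G)/(T+G)$, amino $(A-C)/(A+C)$. A skew with an
empty denominator is `NA`, never 0 — coding it as 0 would bias cohort
correlations toward the null. The correlation table pairs each gene's
overall skew with its positional skew across the cohort (6 types × 3
positions = 18 cells), reporting Pearson $r$ with a two-tailed $t$-test
p-value ($n-2$ df), flagged `***` below 0.001 and `NS` above 0.05. No
multiple-testing correction is applied — a reporting convention for the
18-cell table, not an endorsement. Genes are the statistical unit
throughout (one gene per species in the intended design).

### PCA of usage vectors

PCA of the genes × 59 RSCU matrix and the genes × 20 amino-acid
frequency matrix: column-mean-centered, unscaled (RSCU is already
family-normalized; frequencies live on a common simplex), computed by
singular value decomposition with all components up to
$\min(\text{genes}-1, \text{features})$. Undefined RSCU entries are
imputed by the codon's cohort mean before centering — this preserves
column means and keeps every gene, at the cost of shrinking the
variance of sparsely defined codons slightly toward zero.

## The synthetic cohort generator

`generate_cohort()` emulates a cohort of orthologous CDS sharing a
conserved amino-acid profile but diverging in codon preference. Per
species: draw codon preferences under the bias model, sample the
protein from the amino-acid profile, back-translate by sampling codons
from the preferences, append the stop codon. One cohort seed derives a
sub-seed per species, so per-species output is independent of
generation order, and the whole cohort is byte-reproducible.

Defaults are fixed study conditions, not dials: 226 species (a typical
published eukaryote-wide ortholog cohort) of 500 codons (~1500 nt, the
scale of an ATG13-like protein), with a serine-rich profile (Ser 0.12,
as in intrinsically disordered regulatory proteins; Met 0.025, Trp
0.01; the remaining 17 amino acids uniform) and a TAA stop.

* **mutation_pressure** — codon probability within a family
  $\propto \theta_{b_1}\theta_{b_2}\theta_{b_3}$, renormalized per
  family: composition alone. `gc3_target` calibrates $\theta$ (G = C,
  A = T) by bisection to $10^{-6}$ so the *expected* GC3 under the
  amino-acid profile matches the target; a length-2 range draws a
  per-species target uniformly, producing a compositional gradient.
  The `asymmetry` parameter additionally draws per-species G:C and A:T
  split ratios uniformly in $0.5 \pm a/2$. Real genomes differ in
  strand-compositional skew, and that diversity — not the GC level per
  se — is what makes whole-gene skews track third-position skews; with
  perfectly symmetric $\theta$ (the default, `asymmetry = 0`, which is
  also the PR2 null) positional skews are pure sampling noise and no
  stable correlation ordering exists.
* **selection** — per family of size $k$, preferences drawn from a
  symmetric Dirichlet(`concentration`): small values concentrate usage
  on one codon per family (strong preferred-codon selection), large
  values approach uniform usage.
* **mixed** — per-family log-linear interpolation,
  $p \propto p_{mut}^{1-\lambda} p_{sel}^{\lambda}$.

What the generator does *not* emulate: phylogenetic correlation between
species, within-gene heterogeneity (domains, ramps), intron structure,
dinucleotide constraints (e.g. CpG avoidance), and amino-acid profile
drift across species. Passing recovery tests therefore demonstrates the
estimators' correctness and directional behavior under controlled
composition/selection regimes — not that real cohorts are free of these
confounders.

## Numerical and edge-case conventions

* Uppercasing and U→T precede validation; a trailing partial codon is
  trimmed with a warning (lenient) or an error (strict). Internal stop
  codons are warnings: they occur in database-annotated CDS and still
  carry nucleotide-level signal.
* The terminal stop codon is retained in nucleotide-level statistics
  (composition, entropy, skews) and excluded from all codon-level ones
  (RSCU, ENC, GC3, PR2, amino-acid frequencies), keeping the two layers
  independent.
* An ambiguity character drops one position from nucleotide tallies and
  its whole codon from codon tallies — never the record.
* Undefined quantities (empty skew denominators, absent nucleotides,
  unestimable ENC, undefined RSCU) propagate as `NA` and are written as
  `NA` in every TSV; analyzed + skipped always equals input records.
* Entropies are reported at full precision; TSV output rounds numeric
  columns to 6 decimals.

## Problem sizes used by the test suite

The validation suite exercises the estimators at sizes chosen for
statistical decisiveness at interactive runtimes: analytic invariants
on 1000 random codon tables; oracle cross-checks (brute-force Pearson,
eigendecomposition PCA, first-principles ENC) at $10^{-12}$–$10^{-8}$;
GC3 calibration recovery on 20 × 2000-codon cohorts (tolerance 0.02);
ENC monotonicity across five Dirichlet concentrations (0.02–10) on
12 × 800-codon cohorts; the mutation-vs-selection ENC-curve contrast on
30 × 1200-codon cohorts (mutation cohorts within 3 ENC units of the
curve on average, selection cohorts uniformly below); and the
positional skew-correlation ordering on a 40 × 1000-codon gradient
cohort (GC3 0.25–0.75, asymmetry 0.3).

## Known limitations

* The ENC estimator is the classic degeneracy-class form; genes missing
  an entire estimable class other than Ile (possible in very short
  sequences) are reported unestimable rather than extrapolated.
* Vs for codons defined in only a handful of species is noisy; use the
  reported `n_species`/`n_missing` columns before interpreting.
* PCA mean-imputation slightly compresses variance for codons undefined
  in many genes; with cohorts of mostly complete usage (the intended
  regime) the effect is negligible.
* The pipeline treats each gene independently: no phylogenetic
  correction is applied to correlations, matching standard practice for
  these diagnostics but inviting caution when the cohort has strong
  clade structure.

## A worked example

```{r example}
co <- generate_cohort(cohort_spec(n_species = 12, protein_length = 300,
                                  bias_model = "mixed",
                                  concentration = 0.3, seed = 42))
fit <- codon_usage(co$sequences)
summary(fit)
head(sort(residuals(fit)))
head(fit$vs[order(fit$vs$vs), ], 5)
```

```{r plots, fig.width = 6, fig.height = 6, eval = FALSE}
plot(fit, which = "enc")
plot(fit, which = "pr2")
plot(fit, which = "pca_rscu")
```
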