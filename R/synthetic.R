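#' Default amino-acid profile for synthetic cohorts
#'
#' A serine-rich composition emulating an ATG13-like regulatory protein:
#' Ser at 0.12, Met at 0.025 and Trp at 0.01 (typical start/rare-residue
#' mass), with the remaining 17 amino acids sharing the rest uniformly.
#'
#' @return Named numeric vector of 20 probabilities summing to 1.
#' @export
default_aa_profile <- function() {
  code <- genetic_code()
  p <- stats::setNames(rep(NA_real_, 20L), code$amino_acids)
  p["S"] <- 0.12; p["M"] <- 0.025; p["W"] <- 0.01
  rest <- is.na(p)
  p[rest] <- (1 - sum(p, na.rm = TRUE)) / sum(rest)
  p
}

#' Specification of a synthetic orthologous-CDS cohort
#'
#' Bundles and validates the generative parameters for
#' [generate_cohort()]: cohort size, protein length, amino-acid profile,
#' the codon-bias model and its strength, and the seed. Defaults emulate a
#' 226-species cohort of ~1500 nt serine-rich orthologs.
#'
#' The bias models are:
#' \describe{
#'   \item{mutation_pressure}{codon probabilities within each synonymous
#'     family follow the product of base probabilities `theta`
#'     (renormalized per family); `gc3_target` optionally calibrates
#'     `theta` to a realized GC3 value, or, given a range of length 2,
#'     draws a per-species target uniformly within it.}
#'   \item{selection}{per-species preferred-codon subsets: family codon
#'     probabilities drawn from a symmetric Dirichlet with the given
#'     `concentration`; smaller concentration = stronger preference.}
#'   \item{mixed}{per-family log-linear interpolation between the two,
#'     weight `lambda` on selection.}
#' }
#'
#' @param n_species number of cohort members (default 226).
#' @param protein_length protein length in codons, excluding the appended
#'   stop (default 500).
#' @param aa_profile 20 amino-acid probabilities; see
#'   [default_aa_profile()].
#' @param bias_model `"mutation_pressure"`, `"selection"` or `"mixed"`.
#' @param theta named base probabilities (A, C, G, T) for the mutation
#'   model; ignored when `gc3_target` is given.
#' @param concentration symmetric Dirichlet concentration for the
#'   selection model (default 1; smaller = stronger bias).
#' @param gc3_target optional GC3 fraction in (0, 1), or a length-2 range.
#' @param asymmetry strand-asymmetry width for the mutation model, in
#'   \[0, 1\). When positive, each species draws G:C and A:T split ratios
#'   uniformly from `0.5 +/- asymmetry/2`, emulating the
#'   compositional-skew diversity of real genomes; 0 (default) keeps
#'   theta strand-symmetric (G = C, A = T), the PR2 null.
#' @param lambda selection weight in the mixed model, between 0 and 1.
#' @param stop_codon stop codon appended to every sequence.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_species = 226L, protein_length = 500L,
                        aa_profile = default_aa_profile(),
                        bias_model = c("mutation_pressure", "selection",
                                       "mixed"),
                        theta = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        concentration = 1, gc3_target = NULL,
                        asymmetry = 0, lambda = 0.5, stop_codon = "TAA",
                        seed = 1L) {
  bias_model <- match.arg(bias_model)
  code <- genetic_code()
  stopifnot(
    n_species >= 1L, protein_length >= 1L,
    setequal(names(aa_profile), code$amino_acids),
    all(aa_profile >= 0), abs(sum(aa_profile) - 1) < 1e-8,
    setequal(names(theta), c("A", "C", "G", "T")),
    all(theta >= 0), abs(sum(theta) - 1) < 1e-8,
    concentration > 0, lambda >= 0, lambda <= 1,
    asymmetry >= 0, asymmetry < 1,
    stop_codon %in% code$stop_codons
  )
  if (!is.null(gc3_target)) {
    stopifnot(length(gc3_target) %in% 1:2,
              all(gc3_target > 0), all(gc3_target < 1))
    if (length(gc3_target) == 2L) {
      stopifnot(gc3_target[1] <= gc3_target[2])
    }
  }
  structure(
    list(n_species = as.integer(n_species),
         protein_length = as.integer(protein_length),
         aa_profile = aa_profile[code$amino_acids],
         bias_model = bias_model, theta = theta[c("A", "C", "G", "T")],
         concentration = concentration, gc3_target = gc3_target,
         asymmetry = asymmetry, lambda = lambda, stop_codon = stop_codon,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d species x %d codons, model = %s, seed = %d\n",
    x$n_species, x$protein_length, x$bias_model, x$seed
  ))
  invisible(x)
}

#' Codon probabilities under pure mutation pressure
#'
#' The null model behind the expected-ENC curve: the probability of using
#' codon (b1, b2, b3) within its synonymous family is proportional to
#' `theta[b1] * theta[b2] * theta[b3]`, renormalized within the family --
#' composition alone, no preference among synonymous codons beyond it.
#'
#' @param theta named base probabilities over A, C, G, T.
#' @param code genetic code.
#' @return Named list: amino acid -> named codon probability vector.
#' @export
mutation_pressure_codon_probs <- function(theta, code = genetic_code()) {
  stopifnot(setequal(names(theta), c("A", "C", "G", "T")),
            all(theta >= 0), abs(sum(theta) - 1) < 1e-8)
  lapply(code$families, function(fam) {
    w <- vapply(fam, function(codon) {
      prod(theta[strsplit(codon, "")[[1L]]])
    }, numeric(1))
    if (sum(w) == 0) {
      stop("family with zero total mass under theta: ",
           paste(fam, collapse = ", "))
    }
    w / sum(w)
  })
}

#' Codon probabilities under selection for preferred codons
#'
#' Draws, for each synonymous family of size k, a probability vector from
#' a symmetric Dirichlet(concentration) -- emulating species-specific
#' preferred-codon subsets such as arise from coevolution with tRNA pools.
#' Small concentrations put most mass on one codon per family; large ones
#' approach uniform usage. Uses the current RNG state: seed before calling
#' for reproducibility.
#'
#' @param concentration positive Dirichlet concentration parameter.
#' @param code genetic code.
#' @return Named list: amino acid -> named codon probability vector.
#' @export
selection_codon_probs <- function(concentration, code = genetic_code()) {
  stopifnot(concentration > 0)
  lapply(code$families, function(fam) {
    g <- stats::rgamma(length(fam), shape = concentration, rate = 1)
    # guard against all-zero underflow at tiny concentrations
    if (sum(g) == 0) g[sample.int(length(fam), 1L)] <- 1
    stats::setNames(g / sum(g), fam)
  })
}

# log-linear interpolation between mutation and selection family probs
mix_codon_probs <- function(mut, sel, lambda) {
  out <- mut
  for (aa in names(mut)) {
    w <- mut[[aa]]^(1 - lambda) * sel[[aa]]^lambda
    if (sum(w) == 0) w <- mut[[aa]]
    out[[aa]] <- w / sum(w)
  }
  out
}

# expected GC3 under the mutation model: aa-profile-weighted probability
# that a synonymously-coded codon ends in G or C
expected_gc3_theta <- function(theta, aa_profile, code = genetic_code()) {
  probs <- mutation_pressure_codon_probs(theta, code)
  eligible <- setdiff(names(code$families)[code$degeneracy >= 2L], NULL)
  w <- aa_profile[eligible]
  w <- w / sum(w)
  contrib <- vapply(eligible, function(aa) {
    p <- probs[[aa]]
    third <- substr(names(p), 3L, 3L)
    sum(p[third %in% c("G", "C")])
  }, numeric(1))
  sum(w * contrib)
}

#' Calibrate base probabilities to a target GC3
#'
#' Finds the symmetric composition theta (G = C = g/2, A = T = (1 - g)/2)
#' whose mutation-pressure codon model realizes the requested expected GC3
#' under the given amino-acid profile. Solved by bisection to 1e-6; the
#' genetic code couples positions within codons, so g is not simply the
#' target.
#'
#' @param gc3_target fraction in (0, 1).
#' @param aa_profile amino-acid probabilities (default
#'   [default_aa_profile()]).
#' @param code genetic code.
#' @return Named theta vector over A, C, G, T.
#' @export
gc3_calibrate <- function(gc3_target, aa_profile = default_aa_profile(),
                          code = genetic_code()) {
  stopifnot(gc3_target > 0, gc3_target < 1)
  theta_of <- function(g) c(A = (1 - g) / 2, C = g / 2, G = g / 2,
                            T = (1 - g) / 2)
  f <- function(g) expected_gc3_theta(theta_of(g), aa_profile, code) -
    gc3_target
  lo <- 1e-6; hi <- 1 - 1e-6
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    stop(sprintf(
      "gc3_target %.3f unattainable; attainable range is [%.4f, %.4f]",
      gc3_target, flo + gc3_target, fhi + gc3_target))
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  theta_of((lo + hi) / 2)
}

#' Generate a synthetic orthologous-CDS cohort
#'
#' For each species: draw codon preferences under the spec's bias model,
#' sample a protein of the requested length from the amino-acid profile,
#' back-translate it by sampling codons from the species' preferences, and
#' append the stop codon. A single cohort seed derives one sub-seed per
#' species, so per-species sequences do not depend on generation order.
#' The drawn parameters and realized statistics are returned as ground
#' truth for parameter-recovery testing.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `"synthetic_cohort"`: list with `sequences`
#'   (a `"cds_set"`), `truth` (per-species list: `codon_probs`, `theta`
#'   or `concentration` as applicable, `gc3_target`, `realized_gc3`) and
#'   `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_species = 3, protein_length = 50,
#'                                   seed = 7))
#' co$sequences
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  code <- genetic_code()
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_species)
  base_theta <- if (spec$bias_model != "selection" &&
                    !is.null(spec$gc3_target) &&
                    length(spec$gc3_target) == 1L) {
    gc3_calibrate(spec$gc3_target, spec$aa_profile, code)
  } else {
    spec$theta
  }
  seqs <- vector("list", spec$n_species)
  truth <- vector("list", spec$n_species)
  for (i in seq_len(spec$n_species)) {
    set.seed(sub_seeds[i])
    target_i <- NULL
    theta_i <- base_theta
    if (spec$bias_model != "selection" && !is.null(spec$gc3_target) &&
        length(spec$gc3_target) == 2L) {
      target_i <- stats::runif(1, spec$gc3_target[1], spec$gc3_target[2])
      theta_i <- gc3_calibrate(target_i, spec$aa_profile, code)
    }
    if (spec$bias_model != "selection" && spec$asymmetry > 0) {
      g <- unname(theta_i["G"] + theta_i["C"])
      rho_gc <- stats::runif(1, 0.5 - spec$asymmetry / 2,
                             0.5 + spec$asymmetry / 2)
      rho_at <- stats::runif(1, 0.5 - spec$asymmetry / 2,
                             0.5 + spec$asymmetry / 2)
      theta_i <- c(A = (1 - g) * rho_at, C = g * (1 - rho_gc),
                   G = g * rho_gc, T = (1 - g) * (1 - rho_at))
    }
    probs <- switch(
      spec$bias_model,
      mutation_pressure = mutation_pressure_codon_probs(theta_i, code),
      selection = selection_codon_probs(spec$concentration, code),
      mixed = mix_codon_probs(
        mutation_pressure_codon_probs(theta_i, code),
        selection_codon_probs(spec$concentration, code),
        spec$lambda
      )
    )
    aa_seq <- sample(names(spec$aa_profile), spec$protein_length,
                     replace = TRUE, prob = spec$aa_profile)
    codons <- vapply(aa_seq, function(aa) {
      p <- probs[[aa]]
      if (length(p) == 1L) names(p) else
        sample(names(p), 1L, prob = p)
    }, character(1))
    seq <- paste0(paste(codons, collapse = ""), spec$stop_codon)
    id <- sprintf("synth_%03d", i)
    x <- cds(seq, id = id, species = sprintf("Synthetic species %d", i))
    seqs[[i]] <- x
    truth[[i]] <- list(
      codon_probs = probs,
      theta = if (spec$bias_model == "selection") NULL else theta_i,
      concentration = if (spec$bias_model == "mutation_pressure") NULL
        else spec$concentration,
      gc3_target = if (!is.null(target_i)) target_i else
        if (length(spec$gc3_target) == 1L) spec$gc3_target else NULL,
      realized_gc3 = gc3(x, code)
    )
    names(truth)[i] <- id
  }
  structure(
    list(sequences = structure(seqs, class = "cds_set"),
         truth = truth, spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d species, model = %s, seed = %d\n",
    x$spec$n_species, x$spec$bias_model, x$spec$seed
  ))
  invisible(x)
}

#' Ground-truth summary table of a synthetic cohort
#'
#' @param x a `"synthetic_cohort"`.
#' @return Data frame with one row per species: `id`, `bias_model`,
#'   `gc3_target` (NA when not set), `realized_gc3`, `concentration`
#'   (NA under pure mutation pressure), `theta_gc` (G + C mass of the
#'   species' theta, NA under pure selection).
#' @export
truth_table <- function(x) {
  stopifnot(inherits(x, "synthetic_cohort"))
  rows <- lapply(names(x$truth), function(id) {
    t <- x$truth[[id]]
    data.frame(
      id = id, bias_model = x$spec$bias_model,
      gc3_target = if (is.null(t$gc3_target)) NA_real_ else t$gc3_target,
      realized_gc3 = t$realized_gc3,
      concentration = if (is.null(t$concentration)) NA_real_ else
        t$concentration,
      theta_gc = if (is.null(t$theta)) NA_real_ else
        unname(t$theta["G"] + t$theta["C"]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
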