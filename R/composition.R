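#' Positional nucleotide composition of a coding sequence
#'
#' Tallies A/T/G/C occurrences overall and at each of the three codon
#' positions. Only A, C, G, T characters are counted: an ambiguity
#' character drops that single position from the tallies, not its codon or
#' the record.
#'
#' @param x a [cds()] object.
#' @return An object of class `"nucleotide_composition"`: list with
#'   `counts`, a 4 x 4 integer matrix with rows A, T, G, C and columns
#'   `overall`, `pos1`, `pos2`, `pos3`, and `totals`, the per-column sums.
#' @export
nucleotide_composition <- function(x) {
  stopifnot(inherits(x, "cds"))
  bases <- c("A", "T", "G", "C")
  chars <- strsplit(x$sequence, "")[[1L]]
  pos <- if (length(chars)) (seq_along(chars) - 1L) %% 3L + 1L else integer(0)
  keep <- chars %in% bases
  tab <- table(
    factor(chars[keep], levels = bases),
    factor(pos[keep], levels = 1:3)
  )
  counts <- cbind(overall = rowSums(tab), tab)
  colnames(counts) <- c("overall", "pos1", "pos2", "pos3")
  counts <- matrix(as.integer(counts), nrow = 4L,
                   dimnames = dimnames(counts))
  structure(
    list(counts = counts,
         totals = stats::setNames(as.integer(colSums(counts)),
                                  colnames(counts))),
    class = "nucleotide_composition"
  )
}

#' @export
print.nucleotide_composition <- function(x, ...) {
  cat("<nucleotide_composition>\n")
  print(x$counts)
  invisible(x)
}

#' Shannon entropy of a nucleotide count vector
#'
#' \deqn{H = -\sum_i f_i \log_2 f_i,\qquad f_i = F_i / \sum_j F_j}
#' where \eqn{F_i} are occurrence counts. Zero-count outcomes contribute 0
#' by continuity. With the four nucleotides as outcomes the maximum is
#' 2 bits (uniform usage); lower values indicate more biased usage.
#'
#' @param counts non-negative numeric vector of outcome counts.
#' @return Entropy in bits.
#' @examples
#' nucleotide_entropy(c(1, 1, 1, 1))   # 2
#' nucleotide_entropy(c(2, 1, 1, 0))   # 1.5
#' @export
nucleotide_entropy <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("entropy undefined: all counts are zero")
  f <- counts[counts > 0] / total
  -sum(f * log2(f))
}

#' Positional usage entropy of one nucleotide
#'
#' Quantifies how evenly a given nucleotide is spread across the three
#' codon positions of a gene: a three-outcome Shannon entropy over
#' \eqn{f_p = F_n(p) / (F_n(1) + F_n(2) + F_n(3))}, where \eqn{F_n(p)} is
#' the count of nucleotide `n` at codon position `p`. Maximum is
#' \eqn{\log_2 3 \approx 1.585} bits (even spread); 0 means the nucleotide
#' is confined to one position.
#'
#' @param comp a [nucleotide_composition()] object.
#' @param n one of `"A"`, `"T"`, `"G"`, `"C"`.
#' @return Entropy in bits, or `NA` when the nucleotide is absent from the
#'   gene (recorded, not raised, so cohort summaries can skip it).
#' @export
per_nucleotide_positional_entropy <- function(comp, n) {
  stopifnot(inherits(comp, "nucleotide_composition"),
            n %in% rownames(comp$counts))
  counts <- comp$counts[n, c("pos1", "pos2", "pos3")]
  if (sum(counts) == 0) return(NA_real_)
  nucleotide_entropy(counts)
}

#' Entropy profile of a coding sequence
#'
#' The package's two information-entropy bias measures, per gene: the
#' four-outcome nucleotide usage entropy overall and at each codon
#' position, and the three-outcome positional usage entropy of each
#' nucleotide.
#'
#' @param x a [cds()] or [nucleotide_composition()] object.
#' @return List with `H_overall`, `H_pos1`, `H_pos2`, `H_pos3` (bits, in
#'   \[0, 2\]) and `per_nucleotide`, a named vector over A, T, G, C (bits, in
#'   \[0, log2(3)\], `NA` for absent nucleotides).
#' @export
entropy_profile <- function(x) {
  comp <- if (inherits(x, "nucleotide_composition")) x else
    nucleotide_composition(x)
  scope_h <- function(scope) {
    counts <- comp$counts[, scope]
    if (sum(counts) == 0) NA_real_ else nucleotide_entropy(counts)
  }
  list(
    H_overall = scope_h("overall"),
    H_pos1 = scope_h("pos1"),
    H_pos2 = scope_h("pos2"),
    H_pos3 = scope_h("pos3"),
    per_nucleotide = vapply(
      stats::setNames(nm = rownames(comp$counts)),
      function(n) per_nucleotide_positional_entropy(comp, n), numeric(1)
    )
  )
}

# base pairs defining each skew variant, in (X, Y) order for (X - Y)/(X + Y)
.skew_pairs <- list(
  at = c("A", "T"), gc = c("G", "C"),
  purine = c("A", "G"), pyrimidine = c("T", "C"),
  keto = c("T", "G"), amino = c("A", "C")
)

#' Nucleotide skew profile of a coding sequence
#'
#' Six normalized base-pair asymmetries, each computed overall and at each
#' codon position: AT skew (A-T)/(A+T), GC skew (G-C)/(G+C), purine skew
#' (A-G)/(A+G), pyrimidine skew (T-C)/(T+C), keto skew (T-G)/(T+G) and
#' amino skew (A-C)/(A+C). Positive AT/GC skew means more A than T (G than
#' C). A skew whose denominator is zero is `NA`, never 0, so cohort
#' correlations are not pulled toward the null.
#'
#' @param x a [cds()] or [nucleotide_composition()] object.
#' @return A 6 x 4 numeric matrix of class `"skew_profile"`, rows `at`,
#'   `gc`, `purine`, `pyrimidine`, `keto`, `amino`, columns `overall`,
#'   `pos1`, `pos2`, `pos3`; values in \[-1, 1\] or `NA`.
#' @export
skew_profile <- function(x) {
  comp <- if (inherits(x, "nucleotide_composition")) x else
    nucleotide_composition(x)
  out <- matrix(
    NA_real_, nrow = length(.skew_pairs), ncol = 4L,
    dimnames = list(names(.skew_pairs),
                    c("overall", "pos1", "pos2", "pos3"))
  )
  for (type in names(.skew_pairs)) {
    pair <- .skew_pairs[[type]]
    num <- comp$counts[pair[1L], ] - comp$counts[pair[2L], ]
    den <- comp$counts[pair[1L], ] + comp$counts[pair[2L], ]
    out[type, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  structure(out, class = c("skew_profile", "matrix"))
}

#' @export
print.skew_profile <- function(x, digits = 4, ...) {
  cat("<skew_profile> (X - Y) / (X + Y)\n")
  print(round(unclass(x), digits))
  invisible(x)
}
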