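#' Construct a coding sequence object
#'
#' Normalizes the nucleotide string (uppercase, U mapped to T) and decomposes
#' it into consecutive non-overlapping codons. No validation is performed
#' here; see [validate_cds()].
#'
#' @param sequence nucleotide string (DNA or RNA alphabet; case-insensitive).
#' @param id record identifier.
#' @param species species label; defaults to `id`.
#' @return An object of class `"cds"`: a list with `id`, `species`,
#'   `sequence` (normalized) and `codons` (the sequential triplet
#'   decomposition; a trailing incomplete triplet, if any, is kept out of
#'   `codons` but retained in `sequence`).
#' @export
cds <- function(sequence, id = "cds", species = id) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- unname(chartr("u", "t", sequence))
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  n_codon <- nchar(seq) %/% 3L
  codons <- if (n_codon > 0L) {
    substring(seq, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  } else {
    character(0L)
  }
  structure(
    list(id = id, species = species, sequence = seq, codons = codons),
    class = "cds"
  )
}

#' @export
print.cds <- function(x, ...) {
  cat(sprintf(
    "<cds> %s (%s): %d nt, %d codons\n",
    x$id, x$species, nchar(x$sequence), length(x$codons)
  ))
  invisible(x)
}

#' Validate a coding sequence
#'
#' Checks the structural expectations for an in-frame CDS and reports all
#' findings without raising errors. Issue codes: `EMPTY`,
#' `NOT_MULTIPLE_OF_3`, `NON_ACGT` (all errors) and `INTERNAL_STOP`
#' (a warning: annotated CDS from genome databases occasionally contain
#' in-frame stops, and they still carry nucleotide-level signal).
#'
#' @param x a [cds()] object.
#' @return A list with `ok` (TRUE when no error-level issue is present) and
#'   `issues`, a data frame with columns `code`, `severity`, `message`.
#' @examples
#' validate_cds(cds("ATGTAATAA"))$issues   # internal stop warning
#' @export
validate_cds <- function(x) {
  stopifnot(inherits(x, "cds"))
  issues <- list()
  add <- function(code, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, severity = severity, message = message,
      stringsAsFactors = FALSE
    )
  }
  n <- nchar(x$sequence)
  if (n == 0L) {
    add("EMPTY", "error", "sequence is empty")
  } else {
    if (n %% 3L != 0L) {
      add("NOT_MULTIPLE_OF_3", "error",
          sprintf("length %d is not a multiple of 3", n))
    }
    bad <- gsub("[ACGT]", "", x$sequence)
    if (nchar(bad) > 0L) {
      add("NON_ACGT", "error",
          sprintf("non-ACGT characters present: %s",
                  paste(unique(strsplit(bad, "")[[1L]]), collapse = "")))
    }
    code <- genetic_code()
    nc <- length(x$codons)
    if (nc > 1L) {
      internal <- x$codons[-nc]
      hit <- internal %in% code$stop_codons
      if (any(hit)) {
        add("INTERNAL_STOP", "warning",
            sprintf("internal stop codon(s) at codon position(s) %s",
                    paste(which(hit), collapse = ", ")))
      }
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(0), severity = character(0),
               message = character(0), stringsAsFactors = FALSE)
  list(ok = !any(issues$severity == "error"), issues = issues)
}

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA of CDS, normalizes each record (uppercase,
#' U to T) and validates it. The species label is taken as the header text
#' after the first whitespace when present, otherwise the full identifier --
#' matching NCBI-style deflines without requiring them.
#'
#' In `lenient` mode a trailing incomplete triplet is trimmed with a warning
#' and records with ambiguity characters are kept (ambiguous codons are
#' excluded later at the codon-count layer). In `strict` mode any
#' error-level validation issue aborts with a message naming the record and
#' issue code.
#'
#' @param path FASTA file path.
#' @param strictness `"lenient"` (default) or `"strict"`.
#' @return An object of class `"cds_set"`: a list of [cds()] objects in file
#'   order.
#' @export
read_cds_fasta <- function(path, strictness = c("lenient", "strict")) {
  strictness <- match.arg(strictness)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty cohort: no FASTA records in ", path)
  headers <- names(recs)
  seqs <- as.character(recs)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    species <- if (grepl("\\s", header)) {
      trimws(sub("^\\S+\\s+", "", header))
    } else {
      id
    }
    x <- cds(seqs[i], id = id, species = species)
    rep <- validate_cds(x)
    codes <- rep$issues$code
    if (strictness == "strict") {
      bad <- rep$issues[rep$issues$severity == "error", , drop = FALSE]
      if (nrow(bad) > 0L) {
        stop(sprintf("record '%s' failed validation: %s", id,
                     paste(bad$code, collapse = ", ")))
      }
    } else if ("NOT_MULTIPLE_OF_3" %in% codes) {
      n <- nchar(x$sequence)
      warning(sprintf(
        "record '%s': trimming %d trailing nucleotide(s) (incomplete codon)",
        id, n %% 3L), call. = FALSE)
      x <- cds(substr(x$sequence, 1L, n - n %% 3L), id = id,
               species = species)
    }
    out[[i]] <- x
  }
  structure(out, class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf("<cds_set> %d coding sequence(s)\n", length(x)))
  nt <- vapply(x, function(s) nchar(s$sequence), numeric(1))
  if (length(x)) {
    cat(sprintf("  lengths: %d-%d nt (median %d)\n",
                as.integer(min(nt)), as.integer(max(nt)),
                as.integer(stats::median(nt))))
  }
  invisible(x)
}

#' @export
`[.cds_set` <- function(x, i) {
  structure(unclass(x)[i], class = "cds_set")
}

#' Write coding sequences to a FASTA file
#'
#' Headers are `id` when species equals id, else `id species`, so that
#' [read_cds_fasta()] round-trips both fields.
#'
#' @param x a `"cds_set"` (or list of [cds()] objects).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(x, path) {
  seqs <- vapply(x, function(s) s$sequence, character(1))
  headers <- vapply(x, function(s) {
    if (identical(s$id, s$species)) s$id else paste(s$id, s$species)
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Tabulate codon usage of a coding sequence
#'
#' Counts every complete ACGT codon of the sequence (stop codons included --
#' downstream codon statistics exclude them as needed). Codons containing
#' any non-ACGT character are excluded from the table and tallied
#' separately, so a single ambiguity character drops one codon, never the
#' record.
#'
#' @param x a [cds()] object, or a character vector of codons.
#' @return An object of class `"codon_counts"`: list with `counts` (named
#'   integer vector over all 64 codons), `total` (sum of counts) and
#'   `n_ambiguous` (codons skipped for ambiguity).
#' @export
count_codons <- function(x) {
  codons <- if (inherits(x, "cds")) x$codons else as.character(x)
  code <- genetic_code()
  clean <- grepl("^[ACGT]{3}$", codons)
  counts <- table(factor(codons[clean], levels = names(code$codon_to_aa)))
  counts <- stats::setNames(as.integer(counts), names(code$codon_to_aa))
  structure(
    list(counts = counts, total = sum(counts),
         n_ambiguous = sum(!clean)),
    class = "codon_counts"
  )
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %d codon(s), %d ambiguous skipped\n",
              x$total, x$n_ambiguous))
  invisible(x)
}

as_codon_counts <- function(x) {
  if (inherits(x, "codon_counts")) x else count_codons(x)
}

#' Amino-acid usage frequencies of a coding sequence
#'
#' Relative frequencies of the 20 canonical amino acids encoded by the
#' sense codons of a gene. Stop codons are excluded; amino acids absent from
#' the gene get frequency 0, so the result is always the full
#' 20-dimensional usage vector.
#'
#' @param x a [cds()] object or a `"codon_counts"` table.
#' @param code genetic code, from [genetic_code()].
#' @return Named numeric vector of length 20 summing to 1.
#' @export
amino_acid_frequencies <- function(x, code = genetic_code()) {
  counts <- as_codon_counts(x)$counts
  sense <- counts[code$sense_codons]
  if (sum(sense) == 0L) {
    stop("amino-acid frequencies undefined: no sense codons in sequence")
  }
  aa <- vapply(code$families, function(f) sum(sense[f]), numeric(1))
  out <- stats::setNames(numeric(length(code$amino_acids)),
                         code$amino_acids)
  out[names(aa)] <- aa / sum(aa)
  out
}

#' Per-record validation report for a cohort
#'
#' @param x a `"cds_set"`.
#' @return Data frame with columns `id`, `ok`, `issue_codes`
#'   (comma-separated, empty when clean).
#' @export
validation_report <- function(x) {
  rows <- lapply(x, function(s) {
    rep <- validate_cds(s)
    data.frame(
      id = s$id, ok = rep$ok,
      issue_codes = paste(rep$issues$code, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
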