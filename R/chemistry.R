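# Peptide-level constants: exchangeable hydrogens, elemental composition,
# natural monoisotopic abundance.

# Residue elemental compositions (residue = amino acid minus water).
.residue_formulas <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.package_env <- new.env(parent = emptyenv())

#' Natural abundance of deuterium
#'
#' Fraction of hydrogen atoms that are naturally the heavy isotope (2H).
#' Used as the default `p_h` throughout the package; every function that
#' takes `p_h` accepts an override.
#'
#' @return A single numeric, 0.000115.
#' @export
natural_deuterium_abundance <- function() 0.000115

#' Most-abundant-isotope fractions of the elements of peptides
#'
#' Fractional natural abundance of the lightest (most abundant) isotope for
#' the elements occurring in unmodified peptides. The product of these
#' fractions over a peptide's atoms is its natural monoisotopic relative
#' abundance.
#'
#' @return Named numeric vector with elements `C`, `H`, `N`, `O`, `S`.
#' @export
default_isotope_abundances <- function() {
  c(C = 0.9893, H = 0.999885, N = 0.99636, O = 0.99757, S = 0.9499)
}

#' Construct a residue exchangeable-hydrogen table
#'
#' A residue table maps one-letter amino-acid codes to the number of
#' exchangeable hydrogens (N_EH) each residue contributes during in-vivo
#' deuterium labeling. A peptide's N_EH is the sum of the contributions of
#' its residues.
#'
#' @param values Named numeric vector, names are one-letter residue codes.
#' @return An object of class `residue_exchange_table` (a named numeric
#'   vector).
#' @examples
#' tab <- residue_exchange_table(c(A = 4, G = 2.06))
#' @export
residue_exchange_table <- function(values) {
  if (!is.numeric(values) || is.null(names(values)) || any(names(values) == ""))
    stop("`values` must be a named numeric vector of residue contributions")
  if (anyNA(values) || any(values < 0))
    stop("residue N_EH contributions must be non-negative and non-missing")
  if (any(nchar(names(values)) != 1L))
    stop("residue codes must be single letters")
  if (anyDuplicated(names(values)))
    stop("duplicated residue codes in table")
  structure(as.numeric(values), names = names(values),
            class = "residue_exchange_table")
}

#' Read a residue N_EH table from a file
#'
#' Two-column tabular text (residue, n_eh), whitespace or tab separated,
#' `#` comment lines allowed.
#'
#' @param path Path to the table file.
#' @return A [residue_exchange_table()].
#' @export
read_residue_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("residue", "n_eh"),
                          colClasses = c("character", "numeric"),
                          stringsAsFactors = FALSE)
  residue_exchange_table(stats::setNames(df$n_eh, df$residue))
}

#' Default residue N_EH table
#'
#' The per-residue exchangeable-hydrogen counts shipped with the package
#' (standard heavy-water labeling literature values; see
#' `system.file("extdata", "neh_residues.tsv", package = "deuteRate")`).
#' Covers the 20 standard residues and is overridable everywhere a table is
#' accepted.
#'
#' @return A [residue_exchange_table()].
#' @export
default_residue_table <- function() {
  if (is.null(.package_env$neh_table)) {
    path <- system.file("extdata", "neh_residues.tsv", package = "deuteRate")
    .package_env$neh_table <- read_residue_table(path)
  }
  .package_env$neh_table
}

#' Number of exchangeable hydrogens of a peptide
#'
#' Sums per-residue contributions over a peptide sequence.
#'
#' @param sequence Character vector of peptide sequences (one-letter codes).
#' @param table A [residue_exchange_table()]; defaults to the packaged table.
#' @param nonstandard How to treat residues absent from the table (for the
#'   ambiguity codes B, Z, X, U and similar): `"error"` (default) or
#'   `"zero"`, which counts them as contributing no exchangeable hydrogens
#'   and emits a warning.
#' @return Numeric vector of N_EH values, one per input sequence.
#' @examples
#' compute_neh("AEGLK")
#' @export
compute_neh <- function(sequence, table = default_residue_table(),
                        nonstandard = c("error", "zero")) {
  nonstandard <- match.arg(nonstandard)
  if (!inherits(table, "residue_exchange_table"))
    table <- residue_exchange_table(table)
  if (!is.character(sequence) || any(is.na(sequence)) || any(nchar(sequence) == 0))
    stop("`sequence` must be non-empty, non-missing character strings")
  vapply(sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(res, names(table))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      if (nonstandard == "error")
        stop(sprintf("unknown residue '%s' at position %d of '%s'",
                     res[bad], bad, s))
      warning(sprintf("%d residue(s) without table entries in '%s' counted as 0 N_EH",
                      sum(is.na(idx)), s))
      return(sum(table[idx[!is.na(idx)]]))
    }
    sum(table[idx])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Elemental composition of a peptide
#'
#' Sums residue formulas and adds one water (the peptide termini).
#'
#' @param sequence A single peptide sequence (one-letter codes, standard
#'   residues only).
#' @return Named integer vector of element counts (C, H, N, O, and S when
#'   present).
#' @export
peptide_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(res, names(.residue_formulas))
  if (length(unknown))
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 unknown[1], match(unknown[1], res), sequence))
  counts <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from H2O
  for (r in res) {
    f <- .residue_formulas[[r]]
    counts[names(f)] <- counts[names(f)] + f
  }
  counts[counts > 0]
}

#' Natural monoisotopic abundance from an elemental composition
#'
#' The probability that every atom of the molecule is the most abundant
#' (lightest) isotope: the product over elements of the most-abundant
#' isotope fraction raised to the atom count.
#'
#' @param composition Named numeric vector of element counts (may be empty).
#' @param abundances Named numeric vector of most-abundant-isotope
#'   fractions; defaults to [default_isotope_abundances()]. Hydrogen's
#'   entry is `1 - p_H`.
#' @return A fraction in (0, 1]; 1 for an empty composition.
#' @examples
#' natural_monoisotopic_abundance(c(C = 10, H = 20))
#' @export
natural_monoisotopic_abundance <- function(composition,
                                           abundances = default_isotope_abundances()) {
  if (length(composition) == 0) return(1.0)
  if (is.null(names(composition)) || any(names(composition) == ""))
    stop("`composition` must be a named element -> count vector")
  if (any(composition < 0)) stop("element counts must be non-negative")
  idx <- match(names(composition), names(abundances))
  if (anyNA(idx))
    stop(sprintf("unknown element '%s' (no configured isotope abundance)",
                 names(composition)[which(is.na(idx))[1]]))
  prod(abundances[idx]^composition)
}

#' Read protein sequences from a FASTA file
#'
#' Minimal FASTA reader (wrapped or unwrapped) for optional sequence
#' checks; the first whitespace-delimited token of each header is used as
#' the identifier.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  stats::setNames(unname(seqs), ids)
}
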