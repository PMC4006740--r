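#' Codon number of a coding-sequence position
#'
#' 1-based coding nucleotide positions map to 1-based codon numbers by
#' ceiling(position / 3); coding position 226 falls in codon 76.
#'
#' @param cds_position 1-based coding nucleotide position(s).
#' @return Integer codon number(s).
#' @export
codon_index <- function(cds_position) {
  if (any(cds_position < 1)) stop("cds_position must be >= 1")
  as.integer(ceiling(cds_position / 3))
}

#' Position within the codon
#'
#' @param cds_position 1-based coding nucleotide position(s).
#' @return Offset in {1, 2, 3}.
#' @export
codon_offset <- function(cds_position) {
  if (any(cds_position < 1)) stop("cds_position must be >= 1")
  as.integer((cds_position - 1) %% 3 + 1)
}

# One-letter to three-letter amino-acid code; stop is Ter.
aa3 <- function(aa1) {
  ifelse(aa1 == "*", "Ter", unname(Biostrings::AMINO_ACID_CODE[aa1]))
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Apply a cDNA substitution and classify its protein consequence
#'
#' Mutates the codon containing `cds_position`, translates reference and
#' mutant codons under the standard nuclear genetic code, and classifies
#' the change as missense, nonsense (into a stop), synonymous, or stoploss
#' (away from a stop). The base found at `cds_position` must equal
#' `ref_base`; a mismatch is an error (guarding against off-by-one and
#' transcript-version drift).
#'
#' @param cds Coding sequence: a character string, `DNAString`, or the
#'   first sequence of a `DNAStringSet` (as from
#'   [Biostrings::readDNAStringSet()]).
#' @param cds_position 1-based coding nucleotide position.
#' @param ref_base,alt_base Single bases in A, C, G, T; must differ.
#' @return List of class `protein_change`: residue_index, ref_aa, alt_aa
#'   (3-letter codes), category, and HGVS-style `label` (e.g.
#'   `"p.Asn76Asp"`).
#' @export
apply_substitution <- function(cds, cds_position, ref_base, alt_base) {
  if (inherits(cds, "DNAStringSet")) cds <- cds[[1]]
  cds <- toupper(as.character(cds))
  if (!all(c(ref_base, alt_base) %in% c("A", "C", "G", "T"))) {
    stop("ref and alt must be single bases in A, C, G, T")
  }
  if (ref_base == alt_base) stop("ref and alt bases must differ")
  if (cds_position < 1 || cds_position > nchar(cds)) {
    stop("cds_position ", cds_position, " outside CDS of length ",
         nchar(cds))
  }
  found <- substr(cds, cds_position, cds_position)
  if (found != ref_base) {
    stop("reference base mismatch at cds position ", cds_position,
         ": expected ", ref_base, ", found ", found)
  }
  ci <- codon_index(cds_position)
  off <- codon_offset(cds_position)
  codon_start <- 3 * (ci - 1) + 1
  ref_codon <- substr(cds, codon_start, codon_start + 2)
  if (nchar(ref_codon) < 3) stop("CDS truncated within codon ", ci)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  category <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "nonsense"
  else if (ref_aa == "*") "stoploss"
  else "missense"
  structure(list(
    residue_index = ci,
    ref_aa = aa3(ref_aa),
    alt_aa = aa3(alt_aa),
    category = category,
    label = paste0("p.", aa3(ref_aa), ci, aa3(alt_aa))
  ), class = "protein_change")
}

#' @export
print.protein_change <- function(x, ...) {
  cat(x$label, paste0("(", x$category, ")"), "\n")
  invisible(x)
}

#' Parse an HGVS-style cDNA substitution
#'
#' Accepts the `c.<pos><ref>><alt>` form, e.g. `"c.226A>G"`.
#'
#' @param change Character scalar.
#' @return List with cds_position, ref_base, alt_base.
#' @export
parse_cdna_change <- function(change) {
  m <- regmatches(change,
                  regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", change))[[1]]
  if (length(m) != 4) {
    stop("cannot parse cDNA change (expected e.g. c.226A>G): ", change)
  }
  list(cds_position = as.integer(m[2]), ref_base = m[3], alt_base = m[4])
}

#' Check an annotated candidate's coding consequence
#'
#' Convenience validator: parses an HGVS cDNA substitution and applies it
#' to a CDS read from a FASTA file.
#'
#' @param cds_fasta Path to a FASTA file whose first record is the CDS.
#' @param change HGVS cDNA substitution, e.g. `"c.226A>G"`.
#' @return A `protein_change`.
#' @export
check_consequence <- function(cds_fasta, change) {
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  ch <- parse_cdna_change(change)
  apply_substitution(cds, ch$cds_position, ch$ref_base, ch$alt_base)
}
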