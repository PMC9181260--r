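# Vertebrate mitochondrial genetic code (NCBI translation table 2), embedded
# as an explicit 64-entry table in classic TCAG order. It differs from the
# standard code at four codons: TGA = Trp (not stop), AGA/AGG = stop (not
# Arg), ATA = Met (not Ile).
.mito_code <- local({
  b <- c("T", "C", "A", "G")
  # canonical enumeration: first base slowest, third fastest
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIMMTTTTNNKKSS**",   # ATT..AGG
    "VVVVAAAADDEEGGGG"    # GTT..GGG
  ), "")[[1L]]
  stats::setNames(aa, codons)
})

#' Translate a codon under the vertebrate mitochondrial genetic code
#'
#' Uses the embedded 64-entry vertebrate mitochondrial table (NCBI table 2),
#' not the standard nuclear code: `TGA` is tryptophan, `AGA`/`AGG` are stop
#' codons and `ATA` is methionine. Stops are returned as `"*"`.
#'
#' @param codon character vector of trinucleotides over `A,C,G,T`
#'   (case-insensitive).
#' @return Character vector of single-letter amino acids (`"*"` = stop).
#' @examples
#' translate_mito(c("TGA", "AGA", "ATA", "GTA", "GCA"))
#' @export
translate_mito <- function(codon) {
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad))
    stop("not an unambiguous trinucleotide over {A,C,G,T}: ",
         paste(codon[bad], collapse = ", "), call. = FALSE)
  unname(.mito_code[codon])
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
.comp_base <- function(x) c(A = "T", C = "G", G = "C", T = "A")[[x]]

#' Coding consequence of a point substitution in a mitochondrial gene
#'
#' Locates the substituted position within the coding sequence of `feature`,
#' derives the codon index and within-codon position, and translates the
#' reference and alternate codons under the vertebrate mitochondrial code.
#' With the 0-based within-CDS offset `o` (after strand orientation and
#' `frame_offset`), the codon index is `o %/% 3 + 1` and the codon position
#' `o %% 3 + 1`. Minus-strand genes (e.g. ND6 on the light strand) are
#' processed on the reverse complement, with all coordinates still reported
#' on the plus strand and the alternate base given as observed on the plus
#' strand.
#'
#' @param genome a [mitogenome()].
#' @param feature a one-row feature (list or `data.frame` row with `gene`,
#'   `start`, `end`, `strand`, `frame_offset`; see [read_features()]).
#' @param position 1-based plus-strand position inside the feature span.
#' @param alt alternate base observed on the plus strand; must differ from
#'   the reference base.
#' @return An object of class `coding_consequence`: list with `gene`,
#'   `position`, `codon_index`, `codon_position`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `synonymous`.
#' @export
annotate_consequence <- function(genome, feature, position, alt) {
  feature <- as.list(feature)
  alt <- toupper(alt)
  if (!alt %in% c("A", "C", "G", "T"))
    stop("alt must be one of A, C, G, T", call. = FALSE)
  if (position < feature$start || position > feature$end)
    stop("position ", position, " outside feature ", feature$gene, " (",
         feature$start, "..", feature$end, ")", call. = FALSE)
  ref_plus <- .base_at(genome, position)
  if (ref_plus == alt)
    stop("alt equals the reference base (", alt, ") at position ", position,
         call. = FALSE)
  fo <- if (is.null(feature$frame_offset)) 0L else as.integer(feature$frame_offset)
  if (identical(feature$strand, "-")) {
    offset <- (feature$end - fo) - position
  } else {
    offset <- position - (feature$start + fo)
  }
  if (offset < 0)
    stop("position falls in the frame-offset leader of ", feature$gene,
         call. = FALSE)
  codon_index <- offset %/% 3L + 1L
  codon_position <- offset %% 3L + 1L
  if (identical(feature$strand, "-")) {
    hi <- (feature$end - fo) - 3L * (codon_index - 1L)
    ref_codon <- .revcomp(.seq_extract(genome, hi - 2L, hi))
    alt_within <- .comp_base(alt)
  } else {
    lo <- (feature$start + fo) + 3L * (codon_index - 1L)
    ref_codon <- .seq_extract(genome, lo, lo + 2L)
    alt_within <- alt
  }
  alt_codon <- ref_codon
  substr(alt_codon, codon_position, codon_position) <- alt_within
  ref_aa <- translate_mito(ref_codon)
  alt_aa <- translate_mito(alt_codon)
  structure(list(gene = feature$gene, position = as.integer(position),
                 codon_index = codon_index, codon_position = codon_position,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 synonymous = identical(ref_aa, alt_aa)),
            class = "coding_consequence")
}

#' @export
print.coding_consequence <- function(x, ...) {
  cat(sprintf("%s pos %d: codon %d position %d, %s>%s (%s%d%s)%s\n",
              x$gene, x$position, x$codon_index, x$codon_position,
              x$ref_codon, x$alt_codon, x$ref_aa, x$codon_index, x$alt_aa,
              if (x$synonymous) " synonymous" else ""))
  invisible(x)
}
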