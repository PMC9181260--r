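#' Alignment scoring parameters for mitogenome coordinate mapping
#'
#' Conservative scores for aligning mitogenomes of moderately diverged
#' species (~80% identity): a mismatch is penalised more than a match is
#' rewarded and gap opening is expensive, so the alignment prefers compact,
#' well-anchored homology blocks over speculative gaps.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalties (positive numbers,
#'   subtracted).
#' @return An object of class `aln_params`.
#' @export
aln_params <- function(match = 2, mismatch = -3, gap_open = 8,
                       gap_extend = 1) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "aln_params")
}

# gapped pattern/subject strings of one global alignment
.global_alignment <- function(genome_a, genome_b, params) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(genome_a$seq), Biostrings::DNAString(genome_b$seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Map a position from one mitogenome to another by global alignment
#'
#' Performs one global pairwise alignment (affine gaps) of the two genomes
#' and returns, for each queried position on genome `a`, the genome-`b`
#' coordinate occupying the same alignment column. When the query column
#' holds a gap in `b`, the nearest upstream (smaller-coordinate) non-gap
#' `b` position is returned and the mapping is flagged `"gap_adjacent"`;
#' otherwise the flag is `"aligned"`.
#'
#' This is how a variant position is carried between coordinate systems —
#' e.g. between a bovine mitogenome and the human rCRS, where homologous
#' sites sit at different absolute coordinates because of indels elsewhere
#' in the molecule.
#'
#' @param genome_a,genome_b [mitogenome()] objects.
#' @param pos_a integer vector of 1-based positions on `genome_a`.
#' @param params an [aln_params()] object.
#' @return `data.frame` with columns `pos_a`, `pos_b`, `flag`.
#' @export
map_position <- function(genome_a, genome_b, pos_a, params = aln_params()) {
  pos_a <- as.integer(pos_a)
  if (any(pos_a < 1 | pos_a > genome_a$length))
    stop("pos_a out of range 1..", genome_a$length, call. = FALSE)
  g <- .global_alignment(genome_a, genome_b, params)
  ca <- strsplit(g$a, "")[[1L]]
  cb <- strsplit(g$b, "")[[1L]]
  a_count <- cumsum(ca != "-")
  b_count <- cumsum(cb != "-")
  col_of_a <- match(seq_len(genome_a$length), a_count)
  cols <- col_of_a[pos_a]
  pos_b <- b_count[cols]
  gap <- cb[cols] == "-"
  pos_b[pos_b == 0L] <- NA_integer_  # query before any b base
  data.frame(pos_a = pos_a, pos_b = pos_b,
             flag = ifelse(gap, "gap_adjacent", "aligned"),
             stringsAsFactors = FALSE)
}

#' Compare two mitogenome sequences position by position
#'
#' For equal-length genomes the comparison is direct; for unequal lengths a
#' global alignment is performed first and indel columns are reported
#' separately. Positions can additionally be flagged as heteroplasmic in
#' either genome (e.g. from [classify_site()] calls): a differing or flagged
#' position whose difference is attributable to a flagged heteroplasmy is
#' classified `heteroplasmy_only`, so that two mitogenomes identical up to
#' one within-individual allele mixture show zero substitutions — the
#' situation where two carrier animals plausibly share a single mutation
#' origin.
#'
#' @param a,b [mitogenome()] objects.
#' @param het_a,het_b optional integer vectors of heteroplasmic positions
#'   (coordinates of `a` and `b` respectively; for unequal lengths they are
#'   interpreted on the alignment through each genome's own coordinates).
#' @param params [aln_params()] used only when lengths differ.
#' @return A list with `diffs` (`data.frame`: `pos_a`, `pos_b`, `base_a`,
#'   `base_b`, `class` in `substitution`/`heteroplasmy_only`) and `indels`
#'   (`data.frame` of alignment gap runs; empty for equal lengths).
#' @export
diff_mitogenomes <- function(a, b, het_a = integer(0), het_b = integer(0),
                             params = aln_params()) {
  if (a$length == b$length) {
    ca <- strsplit(a$seq, "")[[1L]]
    cb <- strsplit(b$seq, "")[[1L]]
    pa <- pb <- seq_len(a$length)
    indels <- data.frame(pos_a = integer(0), pos_b = integer(0),
                         gap_in = character(0), stringsAsFactors = FALSE)
  } else {
    g <- .global_alignment(a, b, params)
    ca <- strsplit(g$a, "")[[1L]]
    cb <- strsplit(g$b, "")[[1L]]
    pa <- ifelse(ca != "-", cumsum(ca != "-"), NA_integer_)
    pb <- ifelse(cb != "-", cumsum(cb != "-"), NA_integer_)
    gap <- ca == "-" | cb == "-"
    indels <- data.frame(pos_a = pa[gap], pos_b = pb[gap],
                         gap_in = ifelse(ca[gap] == "-", "a", "b"),
                         stringsAsFactors = FALSE)
    keep <- !gap
    ca <- ca[keep]; cb <- cb[keep]; pa <- pa[keep]; pb <- pb[keep]
  }
  het <- (pa %in% het_a) | (pb %in% het_b)
  hit <- ca != cb | het
  data_class <- ifelse(het[hit], "heteroplasmy_only", "substitution")
  diffs <- data.frame(pos_a = pa[hit], pos_b = pb[hit],
                      base_a = ca[hit], base_b = cb[hit],
                      class = data_class, stringsAsFactors = FALSE)
  # a flagged-het position where the bases agree is still reported: the
  # consensus hides the mixture
  list(diffs = diffs, indels = indels)
}
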