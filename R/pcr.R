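#' Predict PCR products on a mitogenome in silico
#'
#' Searches for the forward primer on the plus strand and the reverse
#' complement of the reverse primer downstream of it (also on the plus
#' strand), each within `max_mismatch` mismatches (no indels). On circular
#' genomes products may span the origin. Amplicon length is measured from
#' the 5' end of the forward primer site through the 5' end of the reverse
#' primer site, inclusive of both primer footprints — the length a band on a
#' gel would show. Primer footprints must not overlap. Multiple compatible
#' site pairs yield multiple products, sorted by length; an absent primer
#' yields an explicit zero-row result, not an error.
#'
#' @param genome a [mitogenome()].
#' @param fwd_primer,rev_primer primer sequences, written 5'->3' as ordered
#'   (the reverse primer anneals to the plus strand).
#' @param max_mismatch allowed mismatches per primer site (default 0).
#' @param max_length ignore candidate products longer than this (default
#'   the genome length).
#' @return `data.frame` of class `amplicons` with columns `fwd_start`,
#'   `rev_end` (1-based plus-strand 5' ends of the two primer sites),
#'   `length`, and `spans_origin`.
#' @export
insilico_pcr <- function(genome, fwd_primer, rev_primer, max_mismatch = 0,
                         max_length = genome$length) {
  stopifnot(nchar(fwd_primer) > 0, nchar(rev_primer) > 0)
  fwd <- toupper(fwd_primer)
  rev_rc <- .revcomp(toupper(rev_primer))
  L <- genome$length
  subject <- if (genome$circular) {
    # doubled sequence exposes origin-spanning sites and products
    Biostrings::DNAString(paste0(genome$seq, genome$seq))
  } else {
    Biostrings::DNAString(genome$seq)
  }
  find_sites <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatch)
    Biostrings::start(m)
  }
  fwd_starts <- find_sites(fwd)
  rev_starts <- find_sites(rev_rc)
  fwd_starts <- fwd_starts[fwd_starts <= L]  # dedupe circular copies
  empty <- data.frame(fwd_start = integer(0), rev_end = integer(0),
                      length = integer(0), spans_origin = logical(0))
  if (length(fwd_starts) == 0 || length(rev_starts) == 0)
    return(structure(empty, class = c("amplicons", "data.frame")))
  prods <- list()
  for (f in fwd_starts) {
    # reverse site must start at or after the forward footprint's end
    cand <- rev_starts[rev_starts >= f + nchar(fwd)]
    for (r in cand) {
      e <- r + nchar(rev_rc) - 1L   # plus-strand 5' end of the reverse primer
      len <- e - f + 1L
      if (len > max_length || len > L) next
      prods[[length(prods) + 1L]] <- data.frame(
        fwd_start = f, rev_end = ((e - 1L) %% L) + 1L, length = len,
        spans_origin = e > L)
    }
  }
  if (length(prods) == 0)
    return(structure(empty, class = c("amplicons", "data.frame")))
  out <- do.call(rbind, prods)
  out <- out[order(out$length, out$fwd_start), , drop = FALSE]
  out <- out[!duplicated(out[, c("fwd_start", "rev_end")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("amplicons", "data.frame"))
}

#' Does an amplicon contain a genome position?
#'
#' @param amplicon one row of an [insilico_pcr()] result.
#' @param position 1-based genome position.
#' @param genome_length genome length (needed for origin-spanning products).
#' @return Logical.
#' @export
amplicon_contains <- function(amplicon, position, genome_length) {
  f <- amplicon$fwd_start
  e <- f + amplicon$length - 1L  # unwrapped end
  p <- position
  if (p < f) p <- p + genome_length
  p >= f && p <= e
}
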