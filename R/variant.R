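#' Thresholds for homoplasmy/heteroplasmy classification
#'
#' Separates genuine intra-individual allele mixtures from sequencing error.
#' A site is called heteroplasmic only when the minor allele clears a
#' fractional threshold *and* an absolute read-count floor at sufficient
#' depth; at lower depth no call is made at all. Defaults (depth >= 50,
#' minor fraction >= 2%, minor count >= 5) sit far below a biologically
#' meaningful mixture such as a ~37% minor allele, yet above the per-base
#' error of modern short-read data.
#'
#' @param min_depth minimum total depth for any call (reads).
#' @param min_minor_fraction minimum minor-allele fraction for a
#'   heteroplasmic call.
#' @param min_minor_count minimum minor-allele read count for a
#'   heteroplasmic call.
#' @return An object of class `het_thresholds`.
#' @export
het_thresholds <- function(min_depth = 50, min_minor_fraction = 0.02,
                           min_minor_count = 5) {
  stopifnot(min_depth >= 1, min_minor_fraction >= 0, min_minor_fraction <= 0.5,
            min_minor_count >= 0)
  structure(list(min_depth = min_depth,
                 min_minor_fraction = min_minor_fraction,
                 min_minor_count = min_minor_count),
            class = "het_thresholds")
}

#' Classify a mitogenome site as homoplasmic or heteroplasmic
#'
#' From per-base read counts at one position: the major allele is the base
#' with the highest count (ties broken lexicographically and flagged), the
#' minor fraction is the second-highest count divided by depth. The site is
#' `heteroplasmic` when the minor allele passes all thresholds,
#' `homoplasmic` when depth suffices but the minor criteria are unmet, and
#' `no_call` below the depth floor (with `zero_depth` flagged for an empty
#' pileup). A homoplasmic site whose major allele differs from the reference
#' is a fixed (homoplasmic) substitution — e.g. every mtDNA copy carrying C
#' where the reference has T.
#'
#' @param pileup a one-row `data.frame` (or list) with elements `position`,
#'   `A`, `C`, `G`, `T` — a row of [read_pileup()] output works directly.
#' @param ref_base reference base at the position (`A`/`C`/`G`/`T`).
#' @param thresholds a [het_thresholds()] object.
#' @return An object of class `variant_call`: list with `position`,
#'   `ref_base`, `major_base`, `minor_base` (`NA` unless heteroplasmic),
#'   `minor_fraction`, `depth`, `status`
#'   (`"homoplasmic"`/`"heteroplasmic"`/`"no_call"`), `is_variant`
#'   (major != ref), `tie` and `zero_depth` flags.
#' @examples
#' pu <- data.frame(position = 11081, A = 2317, C = 0, G = 3970, T = 0)
#' classify_site(pu, ref_base = "G")
#' @export
classify_site <- function(pileup, ref_base, thresholds = het_thresholds()) {
  counts <- c(A = as.numeric(pileup[["A"]]), C = as.numeric(pileup[["C"]]),
              G = as.numeric(pileup[["G"]]), T = as.numeric(pileup[["T"]]))
  if (anyNA(counts) || any(counts < 0))
    stop("pileup counts must be non-negative numbers", call. = FALSE)
  ref_base <- toupper(ref_base)
  if (!ref_base %in% names(counts))
    stop("ref_base must be one of A, C, G, T", call. = FALSE)
  depth <- sum(counts)
  ord <- order(-counts, names(counts))  # count desc, then lexicographic
  major <- names(counts)[ord[1L]]
  second <- names(counts)[ord[2L]]
  tie <- counts[[major]] == counts[[second]] && depth > 0
  minor_count <- counts[[second]]
  minor_fraction <- if (depth > 0) minor_count / depth else 0
  if (depth < thresholds$min_depth) {
    status <- "no_call"
  } else if (minor_fraction >= thresholds$min_minor_fraction &&
             minor_count >= thresholds$min_minor_count) {
    status <- "heteroplasmic"
  } else {
    status <- "homoplasmic"
  }
  structure(list(position = as.integer(pileup[["position"]]),
                 ref_base = ref_base,
                 major_base = if (depth > 0) major else NA_character_,
                 minor_base = if (status == "heteroplasmic") second
                              else NA_character_,
                 minor_fraction = minor_fraction,
                 depth = depth,
                 status = status,
                 is_variant = depth > 0 && major != ref_base,
                 tie = tie,
                 zero_depth = depth == 0),
            class = "variant_call")
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("pos %d  ref %s  major %s  %s", x$position, x$ref_base,
              x$major_base, x$status))
  if (x$status == "heteroplasmic")
    cat(sprintf("  minor %s (%.4f)", x$minor_base, x$minor_fraction))
  cat("  depth", x$depth, "\n")
  invisible(x)
}

#' Classify every site of a pileup table against a reference genome
#'
#' @param pileup table from [read_pileup()].
#' @param genome a [mitogenome()] providing reference bases.
#' @param thresholds a [het_thresholds()].
#' @return `data.frame` with one row per site: position, ref/major/minor
#'   base, minor fraction, depth, status, variant flag.
#' @export
classify_pileup <- function(pileup, genome, thresholds = het_thresholds()) {
  calls <- lapply(seq_len(nrow(pileup)), function(i) {
    row <- pileup[i, ]
    vc <- classify_site(row, .base_at(genome, row$position), thresholds)
    data.frame(position = vc$position, ref_base = vc$ref_base,
               major_base = vc$major_base, minor_base = vc$minor_base,
               minor_fraction = vc$minor_fraction, depth = vc$depth,
               status = vc$status, is_variant = vc$is_variant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}
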