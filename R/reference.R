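#' Construct a mitogenome reference object
#'
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive).
#' @param name sequence name.
#' @param circular is the molecule circular (default `TRUE`, as for
#'   mitochondrial genomes)? Position arithmetic wraps modulo the length on
#'   circular genomes.
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(sequence, name = "mt", circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  structure(list(name = name, seq = sequence, length = nchar(sequence),
                 circular = isTRUE(circular)),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("Mitogenome", x$name, "-", x$length, "bp,",
      if (x$circular) "circular" else "linear", "\n")
  invisible(x)
}

# 1-based inclusive subsequence with circular wrap-around
.seq_extract <- function(genome, start, end) {
  L <- genome$length
  if (start >= 1 && end <= L && start <= end)
    return(substr(genome$seq, start, end))
  if (!genome$circular)
    stop("positions ", start, "..", end, " outside linear genome of length ",
         L, call. = FALSE)
  idx <- ((seq(start, end) - 1L) %% L) + 1L
  paste(strsplit(genome$seq, "")[[1L]][idx], collapse = "")
}

.base_at <- function(genome, pos) .seq_extract(genome, pos, pos)

#' Load a mitogenome reference FASTA with an optional gene feature table
#'
#' The FASTA must contain exactly one record (a single mitochondrial
#' molecule). Feature tables may be BED or GFF3; both are read with
#' `rtracklayer::import()`, so BED's 0-based half-open coordinates are
#' converted to the 1-based inclusive convention used throughout this
#' package. For GFF3 input the phase column (when present) populates
#' `frame_offset`.
#'
#' @param fasta path to a single-record FASTA file.
#' @param features optional path to a BED or GFF3 feature file.
#' @param circular is the genome circular (default `TRUE`)?
#' @return A list with `genome` (a [mitogenome()]) and `features` (a
#'   `data.frame` with columns `gene`, `start`, `end`, `strand`,
#'   `frame_offset`; `NULL` when no feature file is given).
#' @export
load_reference <- function(fasta, features = NULL, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1)
    stop("expected a single-record FASTA, found ", length(seqs), " records",
         call. = FALSE)
  genome <- mitogenome(as.character(seqs[[1L]]),
                       name = sub("\\s.*$", "", names(seqs)[1L]),
                       circular = circular)
  feat <- if (is.null(features)) NULL else read_features(features, genome)
  list(genome = genome, features = feat)
}

#' Read a BED or GFF3 gene feature table
#'
#' @param path feature file; format inferred from the extension
#'   (`.bed` vs `.gff`/`.gff3`).
#' @param genome the [mitogenome()] the features annotate (for range checks).
#' @return `data.frame` with 1-based inclusive `start`/`end`, `strand`
#'   (`"+"`/`"-"`), `gene` and `frame_offset` (0/1/2).
#' @export
read_features <- function(path, genome) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- rtracklayer::import(path, format = fmt)
  md <- as.data.frame(gr)
  gene <- if (fmt == "BED" && "name" %in% names(md)) {
    md$name
  } else if ("gene" %in% names(md)) {
    md$gene
  } else if ("Name" %in% names(md)) {
    md$Name
  } else if ("ID" %in% names(md)) {
    md$ID
  } else {
    paste0("feature", seq_along(gr))
  }
  frame_offset <- if ("phase" %in% names(md) && !all(is.na(md$phase))) {
    ifelse(is.na(md$phase), 0L, as.integer(md$phase))
  } else {
    rep(0L, length(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  feat <- data.frame(gene = as.character(gene),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = strand,
                     frame_offset = frame_offset,
                     stringsAsFactors = FALSE)
  bad <- feat$start < 1 | feat$end > genome$length
  if (any(bad))
    stop("feature(s) out of range for genome of length ", genome$length,
         ": ", paste(feat$gene[bad], collapse = ", "), call. = FALSE)
  feat
}

#' Read a per-site base-count (pileup) table
#'
#' Expects a TSV with header `position A C G T` (any column order, extra
#' columns ignored).
#'
#' @param path pileup TSV path.
#' @return `data.frame` with integer columns `position`, `A`, `C`, `G`, `T`
#'   and a derived `depth` column.
#' @export
read_pileup <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("position", "A", "C", "G", "T")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("pileup table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- tab[, need]
  for (col in need) tab[[col]] <- as.integer(tab[[col]])
  if (any(tab[, c("A", "C", "G", "T")] < 0))
    stop("negative base count in pileup", call. = FALSE)
  tab$depth <- tab$A + tab$C + tab$G + tab$T
  tab
}
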