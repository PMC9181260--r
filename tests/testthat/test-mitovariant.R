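test_that("load_reference validates FASTA and normalises BED coordinates", {
  seq <- rand_dna(100, 1)
  fa <- write_fasta(seq)
  bed <- tempfile(fileext = ".bed")
  writeLines("chrM\t9\t21\tgeneX\t0\t+", bed)
  ref <- load_reference(fa, bed)
  expect_equal(ref$genome$length, 100)
  expect_true(ref$genome$circular)
  # BED half-open 9..21 becomes 1-based inclusive 10..21
  expect_equal(ref$features$start, 10)
  expect_equal(ref$features$end, 21)
  expect_equal(ref$features$gene, "geneX")

  multi <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), multi)
  expect_error(load_reference(multi), "single-record FASTA")

  bed_out <- tempfile(fileext = ".bed")
  writeLines("chrM\t90\t120\tgeneY\t0\t+", bed_out)
  expect_error(load_reference(fa, bed_out, circular = FALSE),
               "out of range")
})

test_that("classify_site reproduces the printed mixed-allele pileup", {
  pu <- data.frame(position = 11081, A = 2317, C = 0, G = 3970, T = 0)
  vc <- classify_site(pu, ref_base = "G")
  expect_equal(vc$status, "heteroplasmic")
  expect_equal(vc$major_base, "G")
  expect_equal(vc$minor_base, "A")
  # direct arithmetic oracle for the minor fraction
  expect_equal(vc$minor_fraction, 2317 / 6287)
  expect_equal(vc$depth, 6287)
})

test_that("classify_site separates fixed substitutions from no-calls", {
  # every read C where the reference has T: a fixed homoplasmic variant
  pure <- data.frame(position = 10432, A = 0, C = 500, G = 0, T = 0)
  vc <- classify_site(pure, ref_base = "T")
  expect_equal(vc$status, "homoplasmic")
  expect_true(vc$is_variant)
  expect_equal(vc$major_base, "C")
  expect_equal(vc$minor_fraction, 0)

  zero <- data.frame(position = 1, A = 0, C = 0, G = 0, T = 0)
  vz <- classify_site(zero, "A")
  expect_equal(vz$status, "no_call")
  expect_true(vz$zero_depth)

  shallow <- data.frame(position = 1, A = 6, C = 4, G = 0, T = 0)
  expect_equal(classify_site(shallow, "A")$status, "no_call")

  tied <- data.frame(position = 1, A = 50, C = 0, G = 50, T = 0)
  vt <- classify_site(tied, "A")
  expect_true(vt$tie)
  expect_equal(vt$major_base, "A")  # lexicographic tie-break
})

test_that("raising thresholds never converts homoplasmic to heteroplasmic", {
  set.seed(7)
  fracs <- seq(0, 0.3, by = 0.02)
  for (i in seq_len(60)) {
    depth <- sample(40:5000, 1)
    minor <- rbinom(1, depth, sample(fracs, 1))
    pu <- data.frame(position = i, A = depth - minor, C = 0, G = minor, T = 0)
    t_lo <- het_thresholds(min_minor_fraction = 0.02)
    t_hi <- het_thresholds(min_minor_fraction = 0.10)
    s_lo <- classify_site(pu, "A", t_lo)$status
    s_hi <- classify_site(pu, "A", t_hi)$status
    if (s_lo == "homoplasmic") expect_false(s_hi == "heteroplasmic")
    if (s_hi == "heteroplasmic") expect_equal(s_lo, "heteroplasmic")
  }
})

test_that("translate_mito applies the vertebrate mitochondrial code", {
  # the defining departures from the standard nuclear code
  expect_equal(translate_mito("TGA"), "W")
  expect_equal(translate_mito("AGA"), "*")
  expect_equal(translate_mito("AGG"), "*")
  expect_equal(translate_mito("ATA"), "M")
  # codons behind a valine-to-alanine change
  expect_equal(translate_mito(c("GTA", "GCA")), c("V", "A"))
  expect_error(translate_mito("GNT"), "unambiguous")
  expect_error(translate_mito("GT"), "trinucleotide")
})

test_that("annotate_consequence does codon arithmetic on both strands", {
  g <- mitogenome("ATGGTACATAAA", circular = FALSE)
  feat <- list(gene = "toy", start = 1, end = 12, strand = "+",
               frame_offset = 0)
  # 9th base of the CDS, T>G: codon 3, position 3, CAT>CAG (His>Gln)
  cons <- annotate_consequence(g, feat, 9, "G")
  expect_equal(cons$codon_index, 3)
  expect_equal(cons$codon_position, 3)
  expect_equal(cons$ref_codon, "CAT")
  expect_equal(cons$alt_codon, "CAG")
  expect_false(cons$synonymous)
  # third-position change preserving the amino acid: GGA>GGG stays glycine
  g2 <- mitogenome("ATGGGACATAAA", circular = FALSE)
  cons2 <- annotate_consequence(g2, feat, 6, "G")
  expect_equal(cons2$codon_position, 3)
  expect_equal(cons2$ref_codon, "GGA")
  expect_equal(cons2$alt_codon, "GGG")
  expect_true(cons2$synonymous)

  # minus strand: CDS is the reverse complement, coordinates stay plus-strand
  # plus: 5'-ATGGTACAT-3' => minus-strand CDS ATGTACCAT read from pos 9 to 1
  gm <- mitogenome("ATGGTACAT", circular = FALSE)
  fm <- list(gene = "toyminus", start = 1, end = 9, strand = "-",
             frame_offset = 0)
  cm <- annotate_consequence(gm, fm, 4, "A")  # plus G>A at pos 4
  expect_equal(cm$codon_index, 2)  # offset (9-4)=5 -> codon 2, position 3
  expect_equal(cm$codon_position, 3)
  expect_equal(cm$ref_codon, "TAC")
  expect_equal(cm$alt_codon, "TAT")  # complement of A is T at codon pos 3
  expect_true(cm$synonymous)        # TAC and TAT are both Tyr

  expect_error(annotate_consequence(g, feat, 20, "A"), "outside feature")
  expect_error(annotate_consequence(g, feat, 9, "T"), "alt equals")
})

test_that("re-annotating the reverse change recovers the original codon", {
  set.seed(11)
  g <- mitogenome(rand_dna(90, 11), circular = FALSE)
  feat <- list(gene = "rt", start = 4, end = 84, strand = "+",
               frame_offset = 0)
  for (pos in sample(4:84, 12)) {
    ref <- substr(g$seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- annotate_consequence(g, feat, pos, alt)
    mutated_seq <- g$seq
    substr(mutated_seq, pos, pos) <- alt
    back <- annotate_consequence(mitogenome(mutated_seq, circular = FALSE),
                                 feat, pos, ref)
    expect_equal(back$alt_codon, fwd$ref_codon)
    expect_equal(back$ref_codon, fwd$alt_codon)
  }
})

test_that("map_position is the identity on identical sequences", {
  for (seed in 1:4) {
    s <- rand_dna(400, seed)
    g <- mitogenome(s, circular = FALSE)
    m <- map_position(g, g, seq_len(400))
    expect_equal(m$pos_b, seq_len(400))
    expect_true(all(m$flag == "aligned"))
  }
})

test_that("map_position tracks indels and flags gap-adjacent queries", {
  s <- rand_dna(300, 5)
  a <- mitogenome(s, circular = FALSE)
  # constructed indel oracle: 3-base insertion before position 100 shifts
  # downstream coordinates by exactly +3
  b <- mitogenome(paste0(substr(s, 1, 99), "TTT", substr(s, 100, 300)),
                  circular = FALSE)
  m <- map_position(a, b, c(50, 150))
  expect_equal(m$pos_b, c(50, 153))
  # deletion in b: positions inside the deleted block map gap-adjacent
  d <- mitogenome(paste0(substr(s, 1, 99), substr(s, 110, 300)),
                  circular = FALSE)
  md <- map_position(a, d, c(50, 105, 200))
  expect_equal(md$pos_b[1], 50)
  expect_equal(md$flag[2], "gap_adjacent")
  expect_equal(md$pos_b[2], 99)   # nearest upstream non-gap coordinate
  expect_equal(md$pos_b[3], 190)
  expect_error(map_position(a, b, 301), "out of range")
})

test_that("insilico_pcr finds products at hand-computed spans", {
  # 60 bp toy genome, forward primer at 5, reverse site ending at 50
  fwd <- "ACGTACGTAC"
  rev_site <- "GGATCCGGAT"            # plus-strand site; primer is its revcomp
  seq <- paste0("TTTT", fwd, strrep("A", 26), rev_site, "CCCCCCCCCC")
  g <- mitogenome(seq, circular = FALSE)
  rev_primer <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev_site)))
  amp <- insilico_pcr(g, fwd, rev_primer)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$fwd_start, 5)
  expect_equal(amp$rev_end, 50)
  expect_equal(amp$length, 50 - 5 + 1)
  expect_true(amplicon_contains(amp[1, ], 30, g$length))
  expect_false(amplicon_contains(amp[1, ], 55, g$length))
  # absent forward primer: explicit empty result, not an error
  none <- insilico_pcr(g, "GGGGGGGGGG", rev_primer)
  expect_s3_class(none, "amplicons")
  expect_equal(nrow(none), 0)
  # one mismatch in the forward site is tolerated within the budget
  fwd_mm <- paste0("T", substr(fwd, 2, 10))
  expect_equal(nrow(insilico_pcr(g, fwd_mm, rev_primer, max_mismatch = 0)), 0)
  expect_equal(insilico_pcr(g, fwd_mm, rev_primer, max_mismatch = 1)$length,
               46)
})

test_that("circular products match the linearization away from the origin", {
  set.seed(21)
  base <- rand_dna(200, 21)
  fwd <- "ACGTACGTACGT"
  rev_site <- "GGATCCGGATCC"
  seq <- paste0(substr(base, 1, 40), fwd, substr(base, 53, 120), rev_site,
                substr(base, 133, 200))
  circ <- insilico_pcr(mitogenome(seq, circular = TRUE), fwd,
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(rev_site))))
  lin <- insilico_pcr(mitogenome(seq, circular = FALSE), fwd,
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(rev_site))))
  expect_equal(as.data.frame(circ), as.data.frame(lin))
  # a product spanning the origin only exists on the circular molecule
  seq2 <- paste0(substr(base, 1, 50), rev_site, substr(base, 63, 150), fwd,
                 substr(base, 163, 200))
  circ2 <- insilico_pcr(mitogenome(seq2, circular = TRUE), fwd,
                        as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(rev_site))))
  lin2 <- insilico_pcr(mitogenome(seq2, circular = FALSE), fwd,
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(rev_site))))
  expect_equal(nrow(lin2), 0)
  expect_equal(nrow(circ2), 1)
  expect_true(circ2$spans_origin)
  # unwrapped span: fwd at 151, rev site ends at 62 on the next turn
  expect_equal(circ2$length, (200 - 151 + 1) + 62)
})

test_that("diff_mitogenomes classifies substitutions vs heteroplasmy", {
  s <- rand_dna(120, 31)
  a <- mitogenome(s, circular = FALSE)
  expect_equal(nrow(diff_mitogenomes(a, a)$diffs), 0)
  s2 <- s
  substr(s2, 81, 81) <- setdiff(c("A", "C", "G", "T"),
                                substr(s, 81, 81))[1]
  d <- diff_mitogenomes(a, mitogenome(s2, circular = FALSE))
  expect_equal(nrow(d$diffs), 1)
  expect_equal(d$diffs$pos_a, 81)
  expect_equal(d$diffs$class, "substitution")
  # consensus-identical genomes, one flagged heteroplasmy: reported as a
  # heteroplasmy-only entry with zero substitutions
  dh <- diff_mitogenomes(a, a, het_a = 45L)
  expect_equal(nrow(dh$diffs), 1)
  expect_equal(dh$diffs$class, "heteroplasmy_only")
  expect_equal(sum(dh$diffs$class == "substitution"), 0)
  # a flagged site that also differs stays heteroplasmy-only
  dboth <- diff_mitogenomes(a, mitogenome(s2, circular = FALSE), het_b = 81L)
  expect_equal(dboth$diffs$class, "heteroplasmy_only")
  # unequal lengths: alignment first, indel columns reported separately
  del <- mitogenome(paste0(substr(s, 1, 60), substr(s, 64, 120)),
                    circular = FALSE)
  du <- diff_mitogenomes(a, del)
  expect_equal(nrow(du$indels), 3)
  expect_true(all(du$indels$gap_in == "b"))
})
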