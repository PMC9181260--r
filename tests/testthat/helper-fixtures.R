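# Fixture builders and independent oracles shared across test files.

# build a pedigree object directly from parallel vectors
make_ped <- function(id, dam = NA, sire = NA, sex = "unknown",
                     birth = NA, cull = NA) {
  n <- length(id)
  df <- data.frame(animal_id = id,
                   sire_id = rep_len(as.character(sire), n),
                   dam_id = rep_len(as.character(dam), n),
                   sex = rep_len(sex, n),
                   birth_date = rep_len(as.Date(birth), n),
                   cull_date = rep_len(as.Date(cull), n),
                   synthesized = FALSE, stringsAsFactors = FALSE)
  ped <- complete_pedigree(df)
  validate_pedigree(ped)
  ped
}

write_ped_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# independent oracle: maternal lineage as brute-force transitive closure of
# dam edges (repeated expansion until fixed point), no package internals
brute_matriline <- function(ped, proband) {
  members <- proband
  repeat {
    dams <- ped$dam_id[match(members, ped$animal_id)]
    kids <- ped$animal_id[!is.na(ped$dam_id) & ped$dam_id %in% members]
    grown <- unique(c(members, dams[!is.na(dams)], kids))
    if (length(grown) == length(members)) return(sort(members))
    members <- grown
  }
}

# independent random pedigree generator (distinct from simulate_pedigree):
# each animal may take a random earlier female as dam and earlier male as sire
random_ped <- function(n, seed) {
  set.seed(seed)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  dam <- sire <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fem <- which(sex[seq_len(i - 1L)] == "female")
    mal <- which(sex[seq_len(i - 1L)] == "male")
    if (length(fem) > 0 && stats::runif(1) < 0.8)
      dam[i] <- sprintf("X%04d", fem[sample.int(length(fem), 1L)])
    if (length(mal) > 0 && stats::runif(1) < 0.6)
      sire[i] <- sprintf("X%04d", mal[sample.int(length(mal), 1L)])
  }
  make_ped(sprintf("X%04d", seq_len(n)), dam = dam, sire = sire, sex = sex,
           birth = as.Date("2000-01-01") + seq_len(n))
}

rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_fasta <- function(seq, path = tempfile(fileext = ".fasta"),
                        name = "mt") {
  writeLines(c(paste0(">", name), seq), path)
  path
}
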