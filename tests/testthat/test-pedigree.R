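test_that("read_pedigree parses a minimal dam chain and resolves links", {
  path <- write_ped_csv(c("animal_id,sire_id,dam_id,sex,birth_date",
                          "calf,0,cow,F,2019-03-01",
                          "cow,0,granddam,F,2010-05-20",
                          "granddam,0,0,F,2002-07-07"))
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(sum(ped$synthesized), 0)
  expect_equal(ped$dam_id[ped$animal_id == "calf"], "cow")
  expect_equal(ped$sex, rep("female", 3))
})

test_that("parents referenced only in a parent column are synthesized", {
  path <- write_ped_csv(c("animal_id,sire_id,dam_id,sex,birth_date",
                          "a1,s9,d9,F,2018-01-01",
                          "a2,s9,d9,M,2019-01-01"))
  ped <- read_pedigree(path)
  # hand count: 2 listed + 2 synthesized parents (s9, d9)
  expect_equal(nrow(ped), 4)
  expect_equal(attr(ped, "n_synthesized"), 2)
  expect_equal(ped$sex[ped$animal_id == "d9"], "female")
  expect_equal(ped$sex[ped$animal_id == "s9"], "male")
})

test_that("row order does not affect the parsed pedigree", {
  rows <- c("calf,0,cow,F,2019-03-01", "cow,0,granddam,F,2010-05-20")
  hdr <- "animal_id,sire_id,dam_id,sex,birth_date"
  p1 <- read_pedigree(write_ped_csv(c(hdr, rows)))
  p2 <- read_pedigree(write_ped_csv(c(hdr, rev(rows))))
  o1 <- p1[order(p1$animal_id), ]
  o2 <- p2[order(p2$animal_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("structural defects are hard errors naming the culprit", {
  hdr <- "animal_id,sire_id,dam_id,sex,birth_date"
  expect_error(read_pedigree(write_ped_csv(
    c(hdr, "dup,0,0,F,2000-01-01", "dup,0,0,F,2001-01-01"))),
    "duplicate animal_id: dup")
  expect_error(read_pedigree(write_ped_csv(
    c(hdr, "a,0,b,F,2000-01-01", "b,0,a,F,2000-01-01"))), "cycle")
  expect_error(read_pedigree(write_ped_csv(
    c(hdr, "a,0,0,F,not-a-date"))), "unparseable birth date at data row 1")
  expect_error(read_pedigree(write_ped_csv(
    c(hdr, "a,0,b,F,2000-01-01", "b,0,0,M,1995-01-01"))),
    "male but referenced as dam: b")
})

test_that("dialects handle unknown codes, day-first dates and TSV", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfather\tmother\tgender\tdob",
               "x1\t.\tNA\tcow\t20-06-2015"), path)
  ped <- read_pedigree(path, pedigree_dialect(
    id = "id", sire = "father", dam = "mother", sex = "gender",
    birth = "dob", date_order = "dmy"))
  expect_true(is.na(ped$dam_id) && is.na(ped$sire_id))
  expect_equal(ped$birth_date, as.Date("2015-06-20"))
  expect_equal(ped$sex, "female")
})

test_that("matriline_founder walks dam links to the unique founder", {
  # 5-generation dam chain G1 (founder) .. G5
  ids <- paste0("G", 1:5)
  ped <- make_ped(ids, dam = c(NA, ids[-5]), sex = "female")
  expect_equal(matriline_founder(ped, "G1"), "G1")  # fixed point
  for (id in ids) expect_equal(matriline_founder(ped, id), "G1")
  # brute-force dam-link walk as oracle
  walk <- function(a) {
    while (!is.na(ped$dam_id[ped$animal_id == a]))
      a <- ped$dam_id[ped$animal_id == a]
    a
  }
  expect_equal(vapply(ids, walk, ""), vapply(ids, function(i)
    matriline_founder(ped, i), ""), ignore_attr = TRUE)
  # disjoint chains have distinct founders
  ped2 <- make_ped(c("u", "v", "p", "q"), dam = c(NA, "u", NA, "p"),
                   sex = "female")
  expect_false(matriline_founder(ped2, "v") == matriline_founder(ped2, "q"))
  expect_error(matriline_founder(ped, "nope"), "not in pedigree")
})

test_that("maternal_lineage equals the dam-edge connected component", {
  # founder dam with 6 maternal descendants + 3 unrelated animals
  ped <- make_ped(
    c("F", "d1", "d2", "g1", "g2", "g3", "s1", "u1", "u2", "u3"),
    dam = c(NA, "F", "F", "d1", "d1", "d2", "d2", NA, "u1", "u1"),
    sex = c("female", "female", "female", "female", "female", "female",
            "male", "female", "female", "male"))
  lin <- maternal_lineage(ped, "g2")
  expect_equal(lin$founder_id, "F")
  expect_equal(length(lin$member_ids), 7)  # males included
  expect_setequal(lin$member_ids, brute_matriline(ped, "g2"))
  # well-definedness: any proband with the same founder, same member set
  expect_setequal(maternal_lineage(ped, "s1")$member_ids, lin$member_ids)
  # a founder with no daughters is a singleton lineage
  ped_single <- make_ped(c("solo", "other"), dam = c(NA, NA), sex = "female")
  expect_equal(maternal_lineage(ped_single, "solo")$member_ids, "solo")
})

test_that("matriline founders partition the pedigree", {
  for (seed in 1:5) {
    ped <- random_ped(80, seed)
    founders <- vapply(ped$animal_id, function(a) matriline_founder(ped, a), "")
    lineages <- lapply(unique(founders), function(f)
      maternal_lineage(ped, f)$member_ids)
    expect_equal(sort(unlist(lineages)), sort(ped$animal_id),
                 ignore_attr = TRUE)
    expect_equal(sum(lengths(lineages)), nrow(ped))  # no overlap
  }
})

test_that("lineage_annual_stats counts cohorts and guards division", {
  ped <- make_ped(c("F", "a", "b", "c", "z1", "z2", "nodate"),
                  dam = c(NA, "F", "F", "a", NA, NA, NA),
                  sex = "female",
                  birth = as.Date(c("2000-05-01", "2001-02-03", "2001-11-30",
                                    "2003-01-01", "2001-07-07", "2003-12-31",
                                    NA)))
  lin <- maternal_lineage(ped, "F")
  st <- lineage_annual_stats(ped, lin, 2000:2003)
  expect_equal(st$year, 2000:2003)
  expect_equal(st$lineage_births, c(1L, 2L, 0L, 1L))
  expect_equal(st$total_births, c(1L, 3L, 0L, 2L))
  expect_equal(st$proportion, c(1, 2 / 3, NA, 0.5))  # zero-birth year is NA
  expect_equal(attr(st, "missing_birth_date"),
               c(lineage = 0L, total = 1L))
  expect_error(lineage_annual_stats(ped, lin, integer(0)), "empty")
  # conservation: in-range lineage births sum to in-range member count
  expect_equal(sum(st$lineage_births), 4L)
})

test_that("maternal_path returns the unique dam chain or NULL", {
  ids <- paste0("G", 1:5)
  ped <- make_ped(c(ids, "other"), dam = c(NA, ids[-5], NA), sex = "female")
  expect_equal(maternal_path(ped, "G3", "G5"), c("G5", "G4", "G3"))
  expect_equal(length(maternal_path(ped, "G1", "G5")), 5)  # five generations
  expect_null(maternal_path(ped, "other", "G5"))
  expect_error(maternal_path(ped, "G1", "ghost"), "not in pedigree")
  # non-NULL path implies shared matriline founder
  for (d in ids) {
    p <- maternal_path(ped, "G1", d)
    if (!is.null(p))
      expect_equal(matriline_founder(ped, d), matriline_founder(ped, "G1"))
  }
})

test_that("infer_carriers labels the maternal closure and flags conflicts", {
  ped <- make_ped(c("F", "d1", "d2", "g1", "g2", "g3", "s1", "u1"),
                  dam = c(NA, "F", "F", "d1", "d1", "d2", "d2", NA),
                  sex = c(rep("female", 6), "male", "female"))
  lin <- maternal_lineage(ped, "F")
  status <- infer_carriers(ped, lin,
                           c(g1 = "mutant", d2 = "mutant"))
  expect_equal(sum(status == "confirmed_carrier"), 2)
  expect_equal(sum(status == "expected_carrier"), 5)
  expect_false("u1" %in% names(status))  # never labels outside the lineage
  # contradiction is surfaced, not overwritten
  status2 <- infer_carriers(ped, lin, c(d1 = "mutant", g1 = "wildtype"))
  expect_equal(unname(status2[["g1"]]), "conflict")
  # wildtype-only genotyping does not spread expectation
  status3 <- infer_carriers(ped, lin, c(g1 = "wildtype"))
  expect_equal(unname(status3[["g1"]]), "confirmed_noncarrier")
  expect_equal(length(status3), 1)
  expect_equal(length(infer_carriers(ped, lin, character(0))), 0)
  expect_error(infer_carriers(ped, lin, c(ghost = "mutant")),
               "not in pedigree")
})

test_that("ages use completed calendar months", {
  # herd-book style: a cow born 2004-04-04 culled 2019-11-20 is 15 y 7 m
  expect_equal(age_months(as.Date("2004-04-04"), as.Date("2019-11-20")), 187L)
  expect_equal(187 %/% 12, 15)
  expect_equal(187 %% 12, 7)
  expect_equal(age_months(as.Date("2010-06-15"), as.Date("2010-06-15")), 0L)
  # day-of-month rule: the month completes only at day >= birth day
  expect_equal(age_months(as.Date("2020-01-31"), as.Date("2020-02-28")), 0L)
  expect_equal(age_months(as.Date("2020-01-15"), as.Date("2020-02-15")), 1L)
})

test_that("age_stats summarises longevity per sex and rejects bad dates", {
  rec <- data.frame(
    animal_id = c("c1", "c2", "b1", "nodates"),
    sex = c("female", "female", "male", "male"),
    birth_date = as.Date(c("2000-01-01", "2004-04-04", "2010-03-01", NA)),
    cull_date = as.Date(c("2006-01-01", "2019-11-20", "2011-10-15", NA)),
    stringsAsFactors = FALSE)
  st <- age_stats(rec)
  expect_equal(nrow(st$per_animal), 3)
  expect_equal(attr(st, "n_excluded"), 1L)
  fem <- st$by_sex[st$by_sex$sex == "female", ]
  expect_equal(fem$n, 2)
  expect_equal(fem$mean_years, mean(c(72, 187) / 12))
  expect_equal(fem$max_years, 187 / 12)
  bad <- rec
  bad$cull_date[1] <- as.Date("1999-01-01")
  expect_error(age_stats(bad), "precedes birth date for animal\\(s\\): c1")
})
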