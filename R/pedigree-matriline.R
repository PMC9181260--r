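#' Matriline founder of an animal
#'
#' Follows dam links upward from `animal_id` until an animal with unknown dam
#' is reached; that animal is the matriline founder. An animal whose own dam
#' is unknown is its own founder. Because each animal has at most one dam,
#' the founder is unique; mtDNA travels along exactly this chain.
#'
#' @param ped a `pedigree` object.
#' @param animal_id animal id present in `ped`.
#' @return The founder's animal id (character scalar).
#' @export
matriline_founder <- function(ped, animal_id) {
  .check_ids(ped, animal_id)
  dam <- ped$dam_id
  names(dam) <- ped$animal_id
  cur <- animal_id
  repeat {
    d <- dam[[cur]]
    if (is.na(d)) return(cur)
    cur <- d
  }
}

# founder of every animal, computed by memoized upward walks
.all_founders <- function(ped) {
  dam <- ped$dam_id
  names(dam) <- ped$animal_id
  founder <- stats::setNames(rep(NA_character_, nrow(ped)), ped$animal_id)
  for (a in ped$animal_id) {
    chain <- character(0)
    cur <- a
    while (is.na(founder[[cur]])) {
      d <- dam[[cur]]
      if (is.na(d)) {
        founder[[cur]] <- cur
        break
      }
      chain <- c(chain, cur)
      cur <- d
    }
    if (length(chain) > 0) founder[chain] <- founder[[cur]]
  }
  founder
}

.check_ids <- function(ped, ids) {
  missing <- setdiff(ids, ped$animal_id)
  if (length(missing) > 0)
    stop("animal id(s) not in pedigree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Maternal lineage of a proband
#'
#' The maternal lineage is the set of all animals sharing the proband's
#' matriline founder — equivalently, the connected component of the
#' dam-edge-only graph containing the proband. Males are members (they carry
#' the lineage's mtDNA but do not transmit it; transmission logic lives in
#' [infer_carriers()]).
#'
#' @param ped a `pedigree` object.
#' @param proband_id animal id present in `ped`.
#' @return An object of class `maternal_lineage`: a list with `founder_id`,
#'   `proband_id` and `member_ids` (character vector, founder included).
#' @export
maternal_lineage <- function(ped, proband_id) {
  .check_ids(ped, proband_id)
  founders <- .all_founders(ped)
  f <- founders[[proband_id]]
  structure(list(founder_id = f, proband_id = proband_id,
                 member_ids = names(founders)[founders == f]),
            class = "maternal_lineage")
}

#' @export
print.maternal_lineage <- function(x, ...) {
  cat("Maternal lineage of", x$proband_id, "- founder", x$founder_id,
      "-", length(x$member_ids), "members\n")
  invisible(x)
}

#' Per-year birth counts for a maternal lineage
#'
#' For each year in `years`, counts births inside the lineage and in the
#' whole pedigree, and the lineage's share of that year's birth cohort.
#' Animals with a missing birth date cannot be assigned to a year and are
#' excluded from both counts; their number is reported in the
#' `missing_birth_date` attribute (named elements `lineage` and `total`)
#' rather than silently dropped.
#'
#' @param ped a `pedigree` object.
#' @param lineage a `maternal_lineage`.
#' @param years integer vector of years; only its range is used (inclusive).
#' @return A `data.frame` with columns `year`, `lineage_births`,
#'   `total_births` and `proportion` (`NA` for years with zero total births —
#'   an undefined share is not reported as 0).
#' @export
lineage_annual_stats <- function(ped, lineage, years) {
  if (length(years) == 0 || anyNA(years))
    stop("empty or invalid year range", call. = FALSE)
  yr_range <- seq(min(years), max(years))
  birth_year <- as.integer(format(ped$birth_date, "%Y"))
  in_lineage <- ped$animal_id %in% lineage$member_ids
  missing <- is.na(birth_year)
  out <- data.frame(
    year = yr_range,
    lineage_births = vapply(yr_range, function(y)
      sum(in_lineage & !missing & birth_year == y), integer(1)),
    total_births = vapply(yr_range, function(y)
      sum(!missing & birth_year == y), integer(1))
  )
  out$proportion <- ifelse(out$total_births > 0,
                           out$lineage_births / out$total_births, NA_real_)
  attr(out, "missing_birth_date") <- c(lineage = sum(in_lineage & missing),
                                       total = sum(missing))
  out
}

#' Dam-link path from a descendant up to an ancestor
#'
#' Walks dam links upward from `descendant_id`; if `ancestor_id` is reached
#' the (unique) maternal path is returned, ordered descendant first. A
#' non-`NULL` result implies the two animals share a matriline founder.
#'
#' @param ped a `pedigree` object.
#' @param ancestor_id,descendant_id animal ids present in `ped`.
#' @return Character vector `descendant_id, ..., ancestor_id`, or `NULL` when
#'   `ancestor_id` is not a maternal ancestor of `descendant_id`.
#' @export
maternal_path <- function(ped, ancestor_id, descendant_id) {
  .check_ids(ped, c(ancestor_id, descendant_id))
  dam <- ped$dam_id
  names(dam) <- ped$animal_id
  path <- descendant_id
  cur <- descendant_id
  while (cur != ancestor_id) {
    cur <- dam[[cur]]
    if (is.na(cur)) return(NULL)
    path <- c(path, cur)
  }
  path
}

#' Infer expected mutation carriers under homoplasmic maternal transmission
#'
#' Given consensus genotypes at the target site for a subset of animals,
#' labels every lineage member. Under strict homoplasmic maternal
#' transmission, one genotyped mutant implies the whole matriline carries the
#' mutation: all maternal descendants of the implicated founder (the entire
#' lineage, founder included) become `expected_carrier` unless genotyped
#' themselves. Genotyped animals are `confirmed_carrier` or, when a wildtype
#' genotype contradicts the expectation, `conflict` — a contradiction is
#' surfaced, never silently overwritten. When no mutant is implicated,
#' genotyped wildtypes are `confirmed_noncarrier` and ungenotyped members stay
#' unlabelled.
#'
#' @param ped a `pedigree` object.
#' @param lineage a `maternal_lineage`.
#' @param genotyped named character vector, names = animal ids (must exist in
#'   the pedigree), values `"mutant"` or `"wildtype"`.
#' @return Named character vector over (a subset of) `lineage$member_ids`
#'   with values `confirmed_carrier`, `expected_carrier`,
#'   `confirmed_noncarrier` or `conflict`. Empty when nothing is genotyped
#'   inside the lineage.
#' @export
infer_carriers <- function(ped, lineage, genotyped) {
  if (length(genotyped) == 0) return(stats::setNames(character(0), character(0)))
  if (is.null(names(genotyped)) || any(names(genotyped) == ""))
    stop("'genotyped' must be a named vector of animal ids", call. = FALSE)
  bad <- setdiff(unique(genotyped), c("mutant", "wildtype"))
  if (length(bad) > 0)
    stop("genotype values must be 'mutant' or 'wildtype', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  .check_ids(ped, names(genotyped))
  members <- lineage$member_ids
  g <- genotyped[names(genotyped) %in% members]
  if (length(g) == 0) return(stats::setNames(character(0), character(0)))
  mutant_present <- any(g == "mutant")
  status <- stats::setNames(rep(NA_character_, length(members)), members)
  if (mutant_present) status[] <- "expected_carrier"
  status[names(g)[g == "mutant"]] <- "confirmed_carrier"
  status[names(g)[g == "wildtype"]] <-
    if (mutant_present) "conflict" else "confirmed_noncarrier"
  status[!is.na(status)]
}

#' Membership table for one or more maternal lineages
#'
#' Convenience tabulation used by the pipeline's TSV output: one row per
#' lineage member with its founder and carrier status (from
#' [infer_carriers()]; unlabelled members get `"unlabelled"`).
#'
#' @param ped a `pedigree` object.
#' @param lineage a `maternal_lineage`.
#' @param genotyped optional named genotype vector (see [infer_carriers()]).
#' @return `data.frame` with columns `animal_id`, `founder_id`,
#'   `carrier_status`.
#' @export
lineage_membership <- function(ped, lineage, genotyped = character(0)) {
  status <- infer_carriers(ped, lineage, genotyped)
  out <- data.frame(animal_id = lineage$member_ids,
                    founder_id = lineage$founder_id,
                    carrier_status = "unlabelled",
                    stringsAsFactors = FALSE)
  hit <- match(names(status), out$animal_id)
  out$carrier_status[hit] <- unname(status)
  out
}
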