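#' Parameters for the synthetic pedigree generator
#'
#' Emulates a small local cattle population recorded over a fixed window:
#' several founder dams establish maternal lineages in the first year, cows
#' produce calves in subsequent years, sires are drawn from contemporaneous
#' males, and every animal inherits its matriline founder's mitochondrial
#' haplotype (strict homoplasmic maternal transmission — no heteroplasmy
#' drift or bottleneck is simulated). One or more founders can be declared
#' mutant, seeding carrier lineages.
#'
#' Defaults give a herd whose recorded window spans 1997-2020 with roughly
#' one calf per cow every third year of her reproductive life (ages
#' `dam_age_min`..`dam_age_max`), a balanced sex ratio, and one mutant
#' founder among ten — a modest, slowly growing multi-matriline population.
#'
#' @param n_founder_dams number of founder dams (each starts a lineage).
#' @param years inclusive year range `c(first, last)`.
#' @param mean_offspring_per_dam_year Poisson mean of calves per cow-year.
#' @param p_female probability a calf is female.
#' @param mutant_founder_ids character ids of mutant founders (founders are
#'   named `F001`, `F002`, ...); default the first founder.
#' @param dam_age_min,dam_age_max reproductive age window in years.
#' @param seed RNG seed.
#' @return An object of class `pedigree_sim_params`.
#' @export
pedigree_sim_params <- function(n_founder_dams = 10,
                                years = c(1997, 2020),
                                mean_offspring_per_dam_year = 0.35,
                                p_female = 0.5,
                                mutant_founder_ids = "F001",
                                dam_age_min = 2, dam_age_max = 12,
                                seed = 1) {
  if (n_founder_dams < 1) stop("need at least one founder dam", call. = FALSE)
  if (length(years) < 1 || min(years) > max(years))
    stop("invalid year range", call. = FALSE)
  if (p_female < 0 || p_female > 1) stop("p_female not in [0,1]", call. = FALSE)
  structure(list(n_founder_dams = as.integer(n_founder_dams),
                 years = c(min(years), max(years)),
                 mean_offspring_per_dam_year = mean_offspring_per_dam_year,
                 p_female = p_female,
                 mutant_founder_ids = mutant_founder_ids,
                 dam_age_min = dam_age_min, dam_age_max = dam_age_max,
                 seed = as.integer(seed)),
            class = "pedigree_sim_params")
}

#' Simulate a multi-matriline pedigree with maternal haplotype transmission
#'
#' Generates founder dams in the first year of the range, then simulates
#' per-year calving: each cow inside her reproductive age window produces a
#' Poisson number of calves, sexes are Bernoulli draws, and sires are chosen
#' among males of reproductive age alive that year (unknown when none
#' exists). Every animal's haplotype equals its dam's, hence its matriline
#' founder's — the generator enforces the faithful homoplasmic transmission
#' the downstream carrier inference assumes. A bookkeeping ledger of births
#' per year and lineage is returned as ground truth for
#' [lineage_annual_stats()].
#'
#' @param params a [pedigree_sim_params()].
#' @return A list with `pedigree` (a validated `pedigree` object),
#'   `haplotypes` (named vector, `"mutant"`/`"wildtype"` per animal),
#'   `ledger` (`data.frame`: `year`, `founder_id`, `births`) and `params`.
#' @export
simulate_pedigree <- function(params = pedigree_sim_params()) {
  set.seed(params$seed)
  y0 <- params$years[1L]
  y1 <- params$years[2L]
  founders <- sprintf("F%03d", seq_len(params$n_founder_dams))
  rec <- data.frame(animal_id = founders, sire_id = NA_character_,
                    dam_id = NA_character_, sex = "female",
                    birth_date = as.Date(sprintf("%d-01-%02d", y0,
                      sample(1:28, params$n_founder_dams, replace = TRUE))),
                    cull_date = as.Date(NA), synthesized = FALSE,
                    stringsAsFactors = FALSE)
  founder_of <- stats::setNames(founders, founders)
  haplo <- stats::setNames(
    ifelse(founders %in% params$mutant_founder_ids, "mutant", "wildtype"),
    founders)
  ledger <- list(data.frame(year = y0, founder_id = founders,
                            births = 1L, stringsAsFactors = FALSE))
  counter <- 0L
  birth_year <- stats::setNames(rep(y0, length(founders)), founders)
  for (yr in seq(y0 + 1L, length.out = max(0L, y1 - y0))) {
    age <- yr - birth_year
    dams <- names(age)[rec$sex[match(names(age), rec$animal_id)] == "female" &
                       age >= params$dam_age_min & age <= params$dam_age_max]
    sires_pool <- names(age)[rec$sex[match(names(age), rec$animal_id)] == "male" &
                             age >= params$dam_age_min]
    if (length(dams) == 0) next
    n_off <- stats::rpois(length(dams), params$mean_offspring_per_dam_year)
    year_births <- character(0)
    for (i in seq_along(dams)) {
      if (n_off[i] == 0) next
      for (j in seq_len(n_off[i])) {
        counter <- counter + 1L
        id <- sprintf("A%05d", counter)
        sex <- if (stats::runif(1) < params$p_female) "female" else "male"
        sire <- if (length(sires_pool) > 0)
          sires_pool[sample.int(length(sires_pool), 1L)] else NA_character_
        rec <- rbind(rec, data.frame(
          animal_id = id, sire_id = sire, dam_id = dams[i], sex = sex,
          birth_date = as.Date(sprintf("%d-%02d-%02d", yr,
            sample(1:12, 1L), sample(1:28, 1L))),
          cull_date = as.Date(NA), synthesized = FALSE,
          stringsAsFactors = FALSE))
        founder_of[id] <- founder_of[[dams[i]]]
        haplo[id] <- haplo[[dams[i]]]
        birth_year[id] <- yr
        year_births <- c(year_births, founder_of[[id]])
      }
    }
    if (length(year_births) > 0) {
      tab <- table(year_births)
      ledger[[length(ledger) + 1L]] <- data.frame(
        year = yr, founder_id = names(tab), births = as.integer(tab),
        stringsAsFactors = FALSE)
    }
  }
  ped <- complete_pedigree(rec)
  validate_pedigree(ped)
  ledger <- do.call(rbind, ledger)
  rownames(ledger) <- NULL
  list(pedigree = ped, haplotypes = haplo, ledger = ledger, params = params)
}

#' Parameters for the pileup simulator
#'
#' @param true_fraction true minor-allele (heteroplasmy) fraction in
#'   `[0, 0.5]`; 0 simulates a homoplasmic site.
#' @param depth total read depth (>= 1).
#' @param error_rate per-base sequencing error rate (< 0.05).
#' @param major_base,minor_base the two alleles of the mixture.
#' @param position genome position recorded in the pileup row.
#' @param seed RNG seed.
#' @return An object of class `pileup_sim_params`.
#' @export
pileup_sim_params <- function(true_fraction, depth, error_rate = 0.001,
                              major_base = "G", minor_base = "A",
                              position = 1L, seed = 1) {
  if (true_fraction < 0 || true_fraction > 0.5)
    stop("true_fraction must be in [0, 0.5]", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.05)
    stop("error_rate must be in [0, 0.05)", call. = FALSE)
  if (major_base == minor_base) stop("alleles must differ", call. = FALSE)
  structure(list(true_fraction = true_fraction, depth = as.integer(depth),
                 error_rate = error_rate, major_base = toupper(major_base),
                 minor_base = toupper(minor_base),
                 position = as.integer(position), seed = as.integer(seed)),
            class = "pileup_sim_params")
}

#' Simulate a per-site base-count pileup
#'
#' Draws the minor-allele read count from a binomial whose success
#' probability is the true heteroplasmy fraction adjusted for sequencing
#' error (a true-minor read miscalled away, a true-major read miscalled into
#' the minor base), assigns the remaining depth to the major allele, and
#' scatters per-base errors from the major reads onto the two off-alleles.
#'
#' @param params a [pileup_sim_params()].
#' @return A one-row `data.frame` with columns `position`, `A`, `C`, `G`,
#'   `T`, `depth`, directly usable by [classify_site()].
#' @export
simulate_pileup <- function(params) {
  set.seed(params$seed)
  f <- params$true_fraction
  e <- params$error_rate
  # minor observed if: truly minor and read correctly, or truly major and
  # miscalled into the minor base (one of three error targets)
  p_minor <- f * (1 - e) + (1 - f) * e / 3
  counts <- stats::setNames(rep(0L, 4L), c("A", "C", "G", "T"))
  n_minor <- stats::rbinom(1L, params$depth, p_minor)
  rest <- params$depth - n_minor
  others <- setdiff(names(counts), c(params$major_base, params$minor_base))
  n_err1 <- stats::rbinom(1L, rest, e / 3)
  n_err2 <- stats::rbinom(1L, rest - n_err1, e / 3)
  counts[params$minor_base] <- n_minor
  counts[others[1L]] <- n_err1
  counts[others[2L]] <- n_err2
  counts[params$major_base] <- rest - n_err1 - n_err2
  data.frame(position = params$position, A = counts[["A"]], C = counts[["C"]],
             G = counts[["G"]], T = counts[["T"]], depth = params$depth)
}

#' Parameters for the breeding-value simulator
#'
#' Group sizes default to the study scale: a carrier group of 44 against a
#' non-carrier population of 3578. Traits are Gaussian on the estimated
#' breeding-value scale (mean 0, unit standard deviation by default);
#' `lineage_shift` adds a per-trait mean shift to the carrier group, in
#' trait standard deviations of 1 by default.
#'
#' @param n_normal,n_mutant group sizes.
#' @param traits `data.frame` with columns `trait`, `mean`, `sd`; default
#'   six conformation-type traits at mean 0, sd 1.
#' @param lineage_shift named numeric vector of per-trait carrier-group mean
#'   shifts (unnamed traits shift by 0).
#' @param seed RNG seed.
#' @return An object of class `bv_sim_params`.
#' @export
bv_sim_params <- function(n_normal = 3578, n_mutant = 44,
                          traits = data.frame(
                            trait = c("withers_height", "muscularity",
                                      "eyes", "head_nobility",
                                      "autochthonous_characteristics",
                                      "body_frame"),
                            mean = 0, sd = 1,
                            stringsAsFactors = FALSE),
                          lineage_shift = numeric(0), seed = 1) {
  if (n_mutant < 1) stop("n_mutant must be >= 1", call. = FALSE)
  if (any(traits$sd <= 0)) stop("trait sd must be > 0", call. = FALSE)
  structure(list(n_normal = as.integer(n_normal),
                 n_mutant = as.integer(n_mutant),
                 traits = traits, lineage_shift = lineage_shift,
                 seed = as.integer(seed)),
            class = "bv_sim_params")
}

#' Simulate breeding-value tables for the carrier and non-carrier groups
#'
#' Non-carrier values are i.i.d. Gaussian per trait; carrier values are
#' Gaussian with the per-trait mean shifted by `lineage_shift`. Deterministic
#' under the seed.
#'
#' @param params a [bv_sim_params()].
#' @return A list with long-format `normal` and `mutant` `data.frame`s
#'   (`animal_id`, `trait`, `value`) and `params`.
#' @export
simulate_bv <- function(params = bv_sim_params()) {
  set.seed(params$seed)
  mk <- function(prefix, n, shift_on) {
    do.call(rbind, lapply(seq_len(nrow(params$traits)), function(i) {
      tr <- params$traits$trait[i]
      shift <- if (shift_on && tr %in% names(params$lineage_shift))
        params$lineage_shift[[tr]] else 0
      data.frame(animal_id = sprintf("%s%05d", prefix, seq_len(n)),
                 trait = tr,
                 value = stats::rnorm(n, params$traits$mean[i] + shift,
                                      params$traits$sd[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(normal = mk("N", params$n_normal, FALSE),
       mutant = mk("M", params$n_mutant, TRUE),
       params = params)
}
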