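#' Age in completed calendar months
#'
#' Ages are measured in completed calendar months, not day counts divided by
#' 365.25: the month is complete once the end date's day-of-month reaches the
#' birth day-of-month. A cow born 2004-04-04 and culled 2019-11-20 is 187
#' completed months old — 15 years and 7 months — which is how herd-book
#' longevity is conventionally quoted.
#'
#' @param birth,end `Date` vectors (recycled to a common length).
#' @return Integer vector of completed months; `NA` where either date is
#'   missing.
#' @export
age_months <- function(birth, end) {
  birth <- as.Date(birth)
  end <- as.Date(end)
  n <- max(length(birth), length(end))
  birth <- rep_len(birth, n)
  end <- rep_len(end, n)
  bl <- as.POSIXlt(birth)
  el <- as.POSIXlt(end)
  months <- 12L * (el$year - bl$year) + (el$mon - bl$mon) -
    as.integer(el$mday < bl$mday)
  months[is.na(birth) | is.na(end)] <- NA_integer_
  months
}

#' Per-animal ages and per-sex longevity summaries
#'
#' Computes each animal's age at culling in completed months (see
#' [age_months()]) and longevity in years (completed months / 12), then
#' summarises mean and maximum longevity per sex. Animals missing either date
#' are excluded and counted in the `n_excluded` attribute. A cull date before
#' birth is a hard error naming the animal.
#'
#' @param records a `data.frame` with columns `animal_id`, `sex`,
#'   `birth_date`, `cull_date` (a `pedigree` object works directly).
#' @return A list with `per_animal` (`animal_id`, `sex`, `age_months`,
#'   `age_years`) and `by_sex` (`sex`, `n`, `mean_years`, `max_years`);
#'   attribute `n_excluded` counts animals lacking a usable date pair.
#' @export
age_stats <- function(records) {
  need <- c("animal_id", "sex", "birth_date", "cull_date")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- !is.na(records$birth_date) & !is.na(records$cull_date)
  r <- records[ok, , drop = FALSE]
  early <- r$cull_date < r$birth_date
  if (any(early))
    stop("cull date precedes birth date for animal(s): ",
         paste(r$animal_id[early], collapse = ", "), call. = FALSE)
  m <- age_months(r$birth_date, r$cull_date)
  per_animal <- data.frame(animal_id = r$animal_id, sex = r$sex,
                           age_months = m, age_years = m / 12,
                           stringsAsFactors = FALSE)
  by_sex <- do.call(rbind, lapply(split(per_animal, per_animal$sex),
    function(d) data.frame(sex = d$sex[1L], n = nrow(d),
                           mean_years = mean(d$age_years),
                           max_years = max(d$age_years),
                           stringsAsFactors = FALSE)))
  rownames(by_sex) <- NULL
  out <- list(per_animal = per_animal, by_sex = by_sex)
  attr(out, "n_excluded") <- sum(!ok)
  out
}
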