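#' Configuration for the resampling-based breeding-value comparison
#'
#' The comparison contrasts the observed mean breeding value of a small
#' carrier ("mutant") group against the distribution of means of repeated
#' random same-size samples drawn from the large non-carrier group. The
#' study-scale defaults are a subset size of 44, 10,000 replicates and a
#' 95% equal-tailed credibility level.
#'
#' @param k subset size per replicate (defaults to the mutant group size in
#'   [compare_trait()]).
#' @param reps number of resampling replicates.
#' @param level credibility level in (0, 1).
#' @param seed RNG seed; identical configuration reproduces results
#'   bit-identically.
#' @param replace sample with replacement within a replicate? Default
#'   `FALSE`: a "sample of k animals" is a subset of distinct animals.
#' @return An object of class `resampling_config`.
#' @export
resampling_config <- function(k = 44, reps = 10000, level = 0.95, seed = 1,
                              replace = FALSE) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  structure(list(k = as.integer(k), reps = as.integer(reps), level = level,
                 seed = as.integer(seed), replace = isTRUE(replace)),
            class = "resampling_config")
}

#' Null distribution of group means by resampling
#'
#' Draws `config$reps` independent samples of `config$k` values (without
#' replacement within a replicate unless `config$replace`) from the
#' non-carrier values and returns each sample's mean. The generator is
#' seeded from `config$seed`, so reruns are bit-identical.
#'
#' @param values_normal numeric vector of non-carrier values (no missing
#'   values; drop and log them upstream).
#' @param config a [resampling_config()].
#' @return Numeric vector of length `config$reps`.
#' @export
resample_null_means <- function(values_normal, config) {
  if (anyNA(values_normal)) stop("missing values in input", call. = FALSE)
  n <- length(values_normal)
  if (!config$replace && config$k > n)
    stop("k (", config$k, ") exceeds the normal group size (", n, ")",
         call. = FALSE)
  set.seed(config$seed)
  vapply(seq_len(config$reps), function(i)
    mean(sample(values_normal, config$k, replace = config$replace)),
    numeric(1))
}

#' Equal-tailed credibility interval of a resampled distribution
#'
#' The `(1-level)/2` and `1-(1-level)/2` empirical quantiles under the
#' linear-interpolation quantile definition (R type 7). Boundaries are
#' inclusive: an observed mean exactly on a bound counts as within the
#' interval.
#'
#' @param null_means non-empty numeric vector of replicate means.
#' @param level credibility level in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' credibility_interval(1:100, 0.95)  # c(3.475, 97.525)
#' @export
credibility_interval <- function(null_means, level) {
  if (length(null_means) == 0) stop("empty null distribution", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  alpha <- (1 - level) / 2
  unname(stats::quantile(null_means, c(alpha, 1 - alpha), type = 7,
                         names = FALSE))
}

#' Compare one trait's carrier mean against the resampled null
#'
#' Computes the observed mean of the carrier group, builds the null
#' distribution by resampling carrier-group-sized subsets of the non-carrier
#' values ([resample_null_means()] with `k = length(bv_mutant)`), and locates
#' the observed mean relative to the equal-tailed credibility interval.
#' `tail_fraction` is the share of null means at or beyond the observed mean
#' on its nearer side, with the `(count + 1)/(reps + 1)` correction that
#' avoids zero estimates; it is descriptive, not a test statistic.
#'
#' @param bv_mutant numeric vector of carrier breeding values (non-empty).
#' @param bv_normal numeric vector of non-carrier breeding values.
#' @param config a [resampling_config()]; its `k` is overridden by
#'   `length(bv_mutant)`.
#' @param trait optional trait name carried into the result.
#' @return An object of class `trait_comparison`: list with `trait`,
#'   `observed_mean`, `null_mean`, `null_sd`, `null_means`, `ci_low`,
#'   `ci_high`, `within_ci`, `tail_side` (`"left"`/`"right"`/`"inside"`),
#'   `tail_fraction`, and the effective `k`, `reps`, `level`, `seed`.
#' @export
compare_trait <- function(bv_mutant, bv_normal, config = resampling_config(),
                          trait = NA_character_) {
  if (length(bv_mutant) == 0) stop("empty mutant group", call. = FALSE)
  if (anyNA(bv_mutant) || anyNA(bv_normal))
    stop("missing values in input", call. = FALSE)
  cfg <- config
  cfg$k <- length(bv_mutant)
  null_means <- resample_null_means(bv_normal, cfg)
  ci <- credibility_interval(null_means, cfg$level)
  obs <- mean(bv_mutant)
  within <- obs >= ci[1L] && obs <= ci[2L]
  tail_side <- if (obs < ci[1L]) "left" else if (obs > ci[2L]) "right"
               else "inside"
  n_left <- sum(null_means <= obs)
  n_right <- sum(null_means >= obs)
  tail_fraction <- (min(n_left, n_right) + 1) / (cfg$reps + 1)
  structure(list(trait = trait, observed_mean = obs,
                 null_mean = mean(null_means), null_sd = stats::sd(null_means),
                 null_means = null_means,
                 ci_low = ci[1L], ci_high = ci[2L], within_ci = within,
                 tail_side = tail_side, tail_fraction = tail_fraction,
                 k = cfg$k, reps = cfg$reps, level = cfg$level,
                 seed = cfg$seed, replace = cfg$replace),
            class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: observed mean %.3f, %.0f%% CI [%.3f, %.3f] -> %s (tail %s, %.4f)\n",
    if (is.na(x$trait)) "trait" else x$trait, x$observed_mean, 100 * x$level,
    x$ci_low, x$ci_high, if (x$within_ci) "within" else "outside",
    x$tail_side, x$tail_fraction))
  invisible(x)
}

#' Read a long-format breeding-value table
#'
#' @param path CSV with header `animal_id,trait,value`.
#' @param traits optional declared trait list; values outside it are an
#'   error.
#' @return `data.frame` with those three columns; duplicate animal-by-trait
#'   entries are an error.
#' @export
read_bv_table <- function(path, traits = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "trait", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("breeding-value table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab <- tab[, need]
  tab$value <- as.numeric(tab$value)
  key <- paste(tab$animal_id, tab$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate animal x trait entries in ", path, call. = FALSE)
  if (!is.null(traits)) {
    bad <- setdiff(unique(tab$trait), traits)
    if (length(bad) > 0)
      stop("undeclared trait(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  tab
}

#' Run the breeding-value comparison for several traits
#'
#' Applies [compare_trait()] to each requested trait, with an independently
#' derived sub-seed per trait spawned deterministically from `config$seed`,
#' so traits are independent yet the whole report is reproducible from one
#' seed. Rows with missing values are dropped per trait and counted.
#'
#' @param table_mutant,table_normal long-format breeding-value tables
#'   (`animal_id`, `trait`, `value`; see [read_bv_table()]).
#' @param traits non-empty character vector of trait names; each must occur
#'   in both tables.
#' @param config a [resampling_config()].
#' @return An object of class `trait_comparison_report`: list with
#'   `comparisons` (named list of `trait_comparison`), `config`,
#'   `sub_seeds`, `n_dropped` (missing-value rows per table).
#' @export
run_all_traits <- function(table_mutant, table_normal, traits,
                           config = resampling_config()) {
  if (length(traits) == 0) stop("empty trait list", call. = FALSE)
  absent <- union(setdiff(traits, unique(table_mutant$trait)),
                  setdiff(traits, unique(table_normal$trait)))
  if (length(absent) > 0)
    stop("trait(s) absent from input: ", paste(absent, collapse = ", "),
         call. = FALSE)
  dropped <- c(mutant = sum(is.na(table_mutant$value)),
               normal = sum(is.na(table_normal$value)))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(traits))
  names(sub_seeds) <- traits
  comparisons <- lapply(traits, function(tr) {
    mut <- table_mutant$value[table_mutant$trait == tr]
    nor <- table_normal$value[table_normal$trait == tr]
    mut <- mut[!is.na(mut)]
    nor <- nor[!is.na(nor)]
    cfg <- config
    cfg$seed <- sub_seeds[[tr]]
    compare_trait(mut, nor, cfg, trait = tr)
  })
  names(comparisons) <- traits
  structure(list(comparisons = comparisons, config = config,
                 sub_seeds = sub_seeds, n_dropped = dropped),
            class = "trait_comparison_report")
}

#' Tabulate a trait-comparison report
#'
#' @param x a `trait_comparison_report`.
#' @param ... unused.
#' @return `data.frame` with one row per trait: observed mean, CI bounds,
#'   within-CI flag, tail side/fraction, and the configuration echo.
#' @method as.data.frame trait_comparison_report
#' @export
as.data.frame.trait_comparison_report <- function(x, ...) {
  do.call(rbind, lapply(x$comparisons, function(cmp)
    data.frame(trait = cmp$trait, observed_mean = cmp$observed_mean,
               ci_low = cmp$ci_low, ci_high = cmp$ci_high,
               within_ci = cmp$within_ci, tail_side = cmp$tail_side,
               tail_fraction = cmp$tail_fraction, k = cmp$k, reps = cmp$reps,
               level = cmp$level, seed = cmp$seed,
               stringsAsFactors = FALSE)))
}

#' @export
print.trait_comparison_report <- function(x, ...) {
  cat("Breeding-value comparison,", length(x$comparisons), "trait(s),",
      x$config$reps, "replicates, level", x$config$level, "\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}
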