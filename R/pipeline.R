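#' Read and validate a pipeline run configuration
#'
#' The whole analysis is reproducible from one declarative YAML file with
#' per-subcommand sections (`pedigree`, `variant`, `pcr`, `map`, `bvtest`,
#' `simulate`), plus top-level `seed` and `out_dir`. Values passed through
#' `overrides` (e.g. from command-line flags) replace file values.
#'
#' @param path YAML config path, or `NULL` to start from defaults.
#' @param overrides named list merged over the file values (nested lists are
#'   merged one level deep).
#' @return A validated named list of class `run_config`, including a `digest`
#'   field (hash of the normalised configuration) echoed into every output.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- suppressWarnings(as.integer(cfg$seed))
  if (is.na(cfg$seed)) stop("config field 'seed' is not an integer",
                            call. = FALSE)
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  for (fld in c("pedigree", "variant", "pcr", "map", "bvtest", "simulate")) {
    if (is.null(cfg[[fld]])) cfg[[fld]] <- list()
  }
  cfg$digest <- .config_digest(cfg)
  structure(cfg, class = "run_config")
}

# order-independent hash of the analytic config payload; out_dir is
# excluded so the same analysis written elsewhere keeps the same digest
.config_digest <- function(cfg) {
  cfg$digest <- NULL
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the serialized text; stable across sessions
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.cfg_path <- function(cfg, section, field, required = TRUE) {
  p <- cfg[[section]][[field]]
  if (is.null(p)) {
    if (required)
      stop("config field '", section, ".", field, "' is missing",
           call. = FALSE)
    return(NULL)
  }
  if (!file.exists(p))
    stop("input path does not exist: ", p, " (config field '", section, ".",
         field, "')", call. = FALSE)
  p
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_json <- function(x, path, cfg) {
  x$config_digest <- cfg$digest
  x$seed <- cfg$seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run one pipeline stage (or the merged report) from a configuration
#'
#' Subcommands:
#' \describe{
#'   \item{`lineage`}{read the pedigree, trace the proband's maternal
#'     lineage, infer carriers, write membership and annual-stats TSVs and a
#'     DOT edge list of the lineage.}
#'   \item{`variant`}{classify a pileup table against the reference genome.}
#'   \item{`consequence`}{annotate the configured substitution's coding
#'     consequence.}
#'   \item{`pcr`}{in-silico PCR of the configured primers on the reference.}
#'   \item{`map`}{map configured positions from genome A to genome B.}
#'   \item{`bvtest`}{the resampling breeding-value comparison.}
#'   \item{`simulate`}{write synthetic pedigree/pileup/breeding-value inputs
#'     plus the generator ledger.}
#'   \item{`report`}{lineage + variant + bvtest merged into one JSON
#'     summary.}
#' }
#' All outputs embed the configuration digest and the seed; identical config
#' and inputs give identical outputs.
#'
#' @param config a [read_run_config()] result, or a path to a YAML config.
#' @param subcommand one of the stage names above.
#' @return Named list of written file paths (and, invisibly, the computed
#'   objects in the `objects` attribute).
#' @export
run_pipeline <- function(config, subcommand = c("report", "lineage",
                                                "variant", "consequence",
                                                "pcr", "map", "bvtest",
                                                "simulate")) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(subcommand,
                lineage = .stage_lineage(cfg),
                variant = .stage_variant(cfg),
                consequence = .stage_consequence(cfg),
                pcr = .stage_pcr(cfg),
                map = .stage_map(cfg),
                bvtest = .stage_bvtest(cfg),
                simulate = .stage_simulate(cfg),
                report = .stage_report(cfg))
  out
}

.stage_lineage <- function(cfg, write = TRUE) {
  pc <- cfg$pedigree
  dialect_args <- pc$dialect
  dialect <- if (is.null(dialect_args)) pedigree_dialect()
             else do.call(pedigree_dialect, dialect_args)
  ped <- read_pedigree(.cfg_path(cfg, "pedigree", "path"), dialect)
  if (is.null(pc$proband))
    stop("config field 'pedigree.proband' is missing", call. = FALSE)
  lin <- maternal_lineage(ped, pc$proband)
  genotyped <- if (is.null(pc$genotyped)) character(0) else unlist(pc$genotyped)
  membership <- lineage_membership(ped, lin, genotyped)
  years <- if (is.null(pc$years)) c(1997, 2020) else unlist(pc$years)
  stats <- lineage_annual_stats(ped, lin, years)
  obj <- list(lineage = lin, membership = membership, annual_stats = stats,
              pedigree = ped)
  if (!write) return(obj)
  files <- list(
    membership = .write_tsv(membership,
                            file.path(cfg$out_dir, "lineage_membership.tsv")),
    annual_stats = .write_tsv(stats,
                              file.path(cfg$out_dir, "lineage_annual_stats.tsv")))
  pedigree_to_dot(ped, lin$member_ids,
                  file.path(cfg$out_dir, "lineage_edges.dot"))
  files$dot <- file.path(cfg$out_dir, "lineage_edges.dot")
  attr(files, "objects") <- obj
  files
}

.stage_variant <- function(cfg, write = TRUE) {
  vc <- cfg$variant
  ref <- load_reference(.cfg_path(cfg, "variant", "fasta"))
  pu <- read_pileup(.cfg_path(cfg, "variant", "pileup"))
  thr <- if (is.null(vc$thresholds)) het_thresholds()
         else do.call(het_thresholds, vc$thresholds)
  calls <- classify_pileup(pu, ref$genome, thr)
  if (!write) return(list(calls = calls, genome = ref$genome))
  files <- list(calls = .write_tsv(calls,
                                   file.path(cfg$out_dir, "variant_calls.tsv")))
  attr(files, "objects") <- list(calls = calls)
  files
}

.stage_consequence <- function(cfg) {
  vc <- cfg$variant
  ref <- load_reference(.cfg_path(cfg, "variant", "fasta"),
                        .cfg_path(cfg, "variant", "features"))
  for (fld in c("gene", "position", "alt"))
    if (is.null(vc[[fld]]))
      stop("config field 'variant.", fld, "' is missing", call. = FALSE)
  feat <- ref$features[ref$features$gene == vc$gene, , drop = FALSE]
  if (nrow(feat) == 0) stop("gene not in feature table: ", vc$gene,
                            call. = FALSE)
  cons <- annotate_consequence(ref$genome, feat[1L, ], vc$position, vc$alt)
  path <- .write_json(unclass(cons),
                      file.path(cfg$out_dir, "consequence.json"), cfg)
  files <- list(consequence = path)
  attr(files, "objects") <- list(consequence = cons)
  files
}

.stage_pcr <- function(cfg) {
  pc <- cfg$pcr
  ref <- load_reference(.cfg_path(cfg, "pcr", "fasta"))
  if (is.null(pc$fwd_primer) || is.null(pc$rev_primer))
    stop("config fields 'pcr.fwd_primer'/'pcr.rev_primer' are missing",
         call. = FALSE)
  mm <- if (is.null(pc$max_mismatch)) 0 else pc$max_mismatch
  amp <- insilico_pcr(ref$genome, pc$fwd_primer, pc$rev_primer, mm)
  path <- .write_json(list(products = as.data.frame(amp)),
                      file.path(cfg$out_dir, "pcr_products.json"), cfg)
  files <- list(pcr = path)
  attr(files, "objects") <- list(amplicons = amp)
  files
}

.stage_map <- function(cfg) {
  mc <- cfg$map
  a <- load_reference(.cfg_path(cfg, "map", "fasta_a"))$genome
  b <- load_reference(.cfg_path(cfg, "map", "fasta_b"))$genome
  if (is.null(mc$positions))
    stop("config field 'map.positions' is missing", call. = FALSE)
  mapped <- map_position(a, b, unlist(mc$positions))
  files <- list(map = .write_tsv(mapped,
                                 file.path(cfg$out_dir, "position_map.tsv")))
  attr(files, "objects") <- list(mapped = mapped)
  files
}

.stage_bvtest <- function(cfg, write = TRUE) {
  bc <- cfg$bvtest
  mut <- read_bv_table(.cfg_path(cfg, "bvtest", "mutant"))
  nor <- read_bv_table(.cfg_path(cfg, "bvtest", "normal"))
  traits <- if (is.null(bc$traits)) sort(unique(mut$trait))
            else unlist(bc$traits)
  config <- resampling_config(
    k = if (is.null(bc$k)) 44 else bc$k,
    reps = if (is.null(bc$reps)) 10000 else bc$reps,
    level = if (is.null(bc$level)) 0.95 else bc$level,
    seed = cfg$seed,
    replace = isTRUE(bc$replace))
  report <- run_all_traits(mut, nor, traits, config)
  if (!write) return(list(report = report))
  tab <- as.data.frame(report)
  files <- list(
    tsv = .write_tsv(tab, file.path(cfg$out_dir, "bv_comparison.tsv")),
    json = .write_json(list(comparisons = tab,
                            config = unclass(report$config),
                            sub_seeds = as.list(report$sub_seeds)),
                       file.path(cfg$out_dir, "bv_comparison.json"), cfg))
  attr(files, "objects") <- list(report = report)
  files
}

.stage_simulate <- function(cfg) {
  sc <- cfg$simulate
  ped_params <- if (is.null(sc$pedigree)) list() else sc$pedigree
  ped_params$seed <- cfg$seed
  sim <- simulate_pedigree(do.call(pedigree_sim_params, ped_params))
  bv_params <- if (is.null(sc$bv)) list() else sc$bv
  bv_params$seed <- cfg$seed + 1L
  bv <- simulate_bv(do.call(bv_sim_params, bv_params))
  pu_params <- if (is.null(sc$pileup))
    list(true_fraction = 0.368, depth = 6287) else sc$pileup
  pu_params$seed <- cfg$seed + 2L
  pu <- simulate_pileup(do.call(pileup_sim_params, pu_params))
  od <- cfg$out_dir
  ped_df <- sim$pedigree
  ped_df$birth_date <- as.character(ped_df$birth_date)
  ped_df$cull_date <- as.character(ped_df$cull_date)
  files <- list(
    pedigree = .write_tsv(ped_df[, c("animal_id", "sire_id", "dam_id", "sex",
                                     "birth_date", "cull_date")],
                          file.path(od, "sim_pedigree.tsv")),
    haplotypes = .write_tsv(
      data.frame(animal_id = names(sim$haplotypes),
                 haplotype = unname(sim$haplotypes)),
      file.path(od, "sim_haplotypes.tsv")),
    pileup = .write_tsv(pu[, c("position", "A", "C", "G", "T")],
                        file.path(od, "sim_pileup.tsv")),
    bv_normal = utils::write.csv(bv$normal,
                                 file.path(od, "sim_bv_normal.csv"),
                                 row.names = FALSE),
    bv_mutant = utils::write.csv(bv$mutant,
                                 file.path(od, "sim_bv_mutant.csv"),
                                 row.names = FALSE),
    ledger = .write_json(list(ledger = sim$ledger),
                         file.path(od, "sim_ledger.json"), cfg))
  files$bv_normal <- file.path(od, "sim_bv_normal.csv")
  files$bv_mutant <- file.path(od, "sim_bv_mutant.csv")
  attr(files, "objects") <- list(sim = sim, bv = bv, pileup = pu)
  files
}

.stage_report <- function(cfg) {
  lin <- .stage_lineage(cfg, write = FALSE)
  var <- .stage_variant(cfg, write = FALSE)
  bvt <- .stage_bvtest(cfg, write = FALSE)
  summary <- list(
    lineage = list(founder = lin$lineage$founder_id,
                   proband = lin$lineage$proband_id,
                   size = length(lin$lineage$member_ids),
                   annual_stats = lin$annual_stats,
                   carrier_status = as.list(table(lin$membership$carrier_status))),
    variant_calls = var$calls,
    bv_comparison = as.data.frame(bvt$report))
  path <- .write_json(summary, file.path(cfg$out_dir, "report.json"), cfg)
  files <- list(report = path)
  attr(files, "objects") <- list(lineage = lin, variant = var, bvtest = bvt)
  files
}
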