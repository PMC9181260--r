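#' Describe the column layout and missing-value codes of a pedigree file
#'
#' Pedigree extracts from herd-book databases come in many dialects: column
#' names differ, unknown parents are coded as `0`, `"NA"`, `"."` or an empty
#' field, and dates may be day-first. A dialect object collects these
#' conventions so [read_pedigree()] can normalise any of them to one internal
#' representation.
#'
#' @param id,sire,dam,sex,birth,cull column names in the input file; `cull`
#'   may name a column that is absent from the file (it is then treated as
#'   all-missing).
#' @param unknown_codes character vector of tokens denoting an unknown parent.
#' @param date_order `"ymd"` for ISO-8601 dates (the default) or `"dmy"` for
#'   day-month-year dates.
#' @param sep field separator; `NULL` (default) infers it from the file
#'   extension (`.tsv`/`.txt` tab, otherwise comma).
#' @return An object of class `pedigree_dialect`.
#' @seealso [read_pedigree()]
#' @export
pedigree_dialect <- function(id = "animal_id", sire = "sire_id",
                             dam = "dam_id", sex = "sex",
                             birth = "birth_date", cull = "cull_date",
                             unknown_codes = c("0", "", "NA", "."),
                             date_order = c("ymd", "dmy"),
                             sep = NULL) {
  date_order <- match.arg(date_order)
  structure(list(id = id, sire = sire, dam = dam, sex = sex,
                 birth = birth, cull = cull,
                 unknown_codes = unknown_codes,
                 date_order = date_order, sep = sep),
            class = "pedigree_dialect")
}

.parse_ped_dates <- function(x, date_order, what) {
  out <- rep(as.Date(NA), length(x))
  present <- !is.na(x) & !(trimws(x) %in% c("", "NA", "."))
  if (!any(present)) return(out)
  fmt <- if (date_order == "dmy") "%d-%m-%Y" else "%Y-%m-%d"
  raw <- gsub("[/.]", "-", trimws(x[present]))
  parsed <- as.Date(raw, format = fmt)
  if (anyNA(parsed)) {
    bad <- which(present)[which(is.na(parsed))[1L]]
    stop("unparseable ", what, " at data row ", bad, ": '", x[bad], "'",
         call. = FALSE)
  }
  out[present] <- parsed
  out
}

.normalize_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[s %in% c("f", "female", "cow", "2")] <- "female"
  out[s %in% c("m", "male", "bull", "1")] <- "male"
  out
}

#' Read and validate a pedigree file
#'
#' Reads a delimited pedigree table (header required), normalises parent
#' codes, sexes and dates, completes the pedigree closure, and validates the
#' result. Parents that are referenced in a sire/dam column but have no row of
#' their own are materialised as records with all fields unknown, so that
#' every parent link resolves; ragged real-world extracts are therefore
#' accepted rather than rejected. Row order never affects the result.
#'
#' Validation is strict where it matters for downstream lineage work:
#' duplicate animal ids, parent-graph cycles (checked over sire and dam edges
#' jointly at load time), unparseable dates, animals used as dams that are
#' recorded as male, and cull dates before birth dates are all hard errors.
#'
#' @param path path to a CSV/TSV pedigree file with a header row.
#' @param dialect a [pedigree_dialect()] describing the file's conventions.
#' @return A `pedigree` object: a `data.frame` with columns `animal_id`,
#'   `sire_id`, `dam_id` (`NA` = unknown parent), `sex`
#'   (`"female"`/`"male"`/`"unknown"`), `birth_date`, `cull_date` (`Date`,
#'   `NA` = missing), and a logical `synthesized` column marking closure
#'   records. The attribute `n_synthesized` counts them.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("animal_id,sire_id,dam_id,sex,birth_date",
#'              "calf,0,cow,F,2019-03-01",
#'              "cow,0,granddam,F,2010-05-20"), tf)
#' ped <- read_pedigree(tf)
#' nrow(ped)  # 3: granddam synthesized
#' @export
read_pedigree <- function(path, dialect = pedigree_dialect()) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  sep <- dialect$sep
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c(dialect$id, dialect$sire, dialect$dam)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("pedigree file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  get_col <- function(nm, default = NA_character_) {
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  id <- trimws(get_col(dialect$id))
  if (any(id == "" | is.na(id)))
    stop("empty animal_id at data row ", which(id == "" | is.na(id))[1L],
         call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate animal_id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)

  clean_parent <- function(x) {
    x <- trimws(x)
    x[is.na(x) | x %in% dialect$unknown_codes] <- NA_character_
    x
  }
  sire <- clean_parent(get_col(dialect$sire))
  dam <- clean_parent(get_col(dialect$dam))
  sex <- .normalize_sex(get_col(dialect$sex, "unknown"))
  birth <- .parse_ped_dates(get_col(dialect$birth), dialect$date_order,
                            "birth date")
  cull <- .parse_ped_dates(get_col(dialect$cull), dialect$date_order,
                           "cull date")

  ped <- data.frame(animal_id = id, sire_id = sire, dam_id = dam, sex = sex,
                    birth_date = birth, cull_date = cull,
                    synthesized = FALSE, stringsAsFactors = FALSE)
  ped <- complete_pedigree(ped)
  validate_pedigree(ped)
  ped
}

#' Complete the pedigree closure
#'
#' Adds a founder record (all fields unknown, flagged `synthesized`) for every
#' parent id that appears in a sire or dam column but has no row of its own.
#' Sires gain sex `"male"` and dams `"female"` unless the same id occurs in
#' both roles (then `"unknown"`; validation will reject it anyway).
#'
#' @param ped a pedigree `data.frame` (see [read_pedigree()]).
#' @return The input with synthesized founder rows appended and the attribute
#'   `n_synthesized` set.
#' @export
complete_pedigree <- function(ped) {
  referenced <- unique(c(ped$sire_id, ped$dam_id))
  referenced <- referenced[!is.na(referenced)]
  missing_ids <- setdiff(referenced, ped$animal_id)
  if (length(missing_ids) > 0) {
    as_sire <- missing_ids %in% ped$sire_id
    as_dam <- missing_ids %in% ped$dam_id
    sex <- ifelse(as_sire & as_dam, "unknown",
                  ifelse(as_dam, "female", "male"))
    add <- data.frame(animal_id = missing_ids, sire_id = NA_character_,
                      dam_id = NA_character_, sex = sex,
                      birth_date = as.Date(NA), cull_date = as.Date(NA),
                      synthesized = TRUE, stringsAsFactors = FALSE)
    ped <- rbind(ped, add)
  }
  rownames(ped) <- NULL
  attr(ped, "n_synthesized") <- sum(ped$synthesized)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Validate pedigree invariants
#'
#' Checks that every parent link resolves, that the joint sire/dam parent
#' graph is acyclic (cycle members are listed in the error), that no animal
#' referenced as a dam is recorded as male, and that cull dates do not precede
#' birth dates. Called by [read_pedigree()]; exported so programmatically
#' built pedigrees can be checked too.
#'
#' @param ped a `pedigree` object.
#' @return `ped`, invisibly, if all checks pass.
#' @export
validate_pedigree <- function(ped) {
  ids <- ped$animal_id
  for (col in c("sire_id", "dam_id")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ids)
    if (any(bad))
      stop("unresolved ", col, ": ", paste(unique(ref[bad]), collapse = ", "),
           call. = FALSE)
  }
  dams <- unique(ped$dam_id[!is.na(ped$dam_id)])
  bad_dam <- dams[ped$sex[match(dams, ids)] == "male"]
  if (length(bad_dam) > 0)
    stop("animal(s) recorded as male but referenced as dam: ",
         paste(bad_dam, collapse = ", "), call. = FALSE)
  both <- !is.na(ped$birth_date) & !is.na(ped$cull_date)
  early <- both & ped$cull_date < ped$birth_date
  if (any(early))
    stop("cull date precedes birth date for animal(s): ",
         paste(ped$animal_id[early], collapse = ", "), call. = FALSE)
  cyc <- .pedigree_cycle(ped)
  if (length(cyc) > 0)
    stop("parent graph contains a cycle involving: ",
         paste(cyc, collapse = ", "), call. = FALSE)
  invisible(ped)
}

# Kahn's algorithm over parent -> child edges; whatever cannot be removed
# lies on (or downstream of a node on) a cycle. Since each animal has at most
# two parents, the residual set is reported as the cycle neighbourhood.
.pedigree_cycle <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal_id
  sire <- unname(idx[ped$sire_id])
  dam <- unname(idx[ped$dam_id])
  indeg <- as.integer(!is.na(sire)) + as.integer(!is.na(dam))
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  removed <- 0L
  while (length(queue) > 0) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (removed == n) character(0) else ped$animal_id[indeg > 0L]
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals (",
      sum(x$synthesized), "synthesized founder records )\n")
  cat(" females:", sum(x$sex == "female"),
      " males:", sum(x$sex == "male"),
      " unknown:", sum(x$sex == "unknown"), "\n")
  invisible(x)
}

#' Emit a DOT-format parent edge list
#'
#' Writes a Graphviz DOT digraph with one edge per known parent link
#' (dam edges solid, sire edges dashed), restricted to `ids` when given.
#' Layout/drawing itself is left to Graphviz.
#'
#' @param ped a `pedigree` object.
#' @param ids optional subset of animal ids (e.g. a reduced carrier pedigree).
#' @param path optional output file; when `NULL` the DOT text is returned.
#' @return The DOT lines, invisibly when written to `path`.
#' @export
pedigree_to_dot <- function(ped, ids = NULL, path = NULL) {
  if (!is.null(ids)) ped <- ped[ped$animal_id %in% ids, , drop = FALSE]
  q <- function(x) paste0('"', x, '"')
  dam_e <- ped[!is.na(ped$dam_id), c("dam_id", "animal_id")]
  sire_e <- ped[!is.na(ped$sire_id), c("sire_id", "animal_id")]
  lines <- c("digraph pedigree {",
             sprintf("  %s -> %s;", q(dam_e$dam_id), q(dam_e$animal_id)),
             sprintf("  %s -> %s [style=dashed];",
                     q(sire_e$sire_id), q(sire_e$animal_id)),
             "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
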