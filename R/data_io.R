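# -- file formats ------------------------------------------------------------
#
# Molecules: SMILES (UTF-8, one "id<TAB>smiles" per line, '#' comments) or
# SDF V2000 (id from the title line or a configurable property tag).
# Pair tables: TSV with columns id_a, id_b, activity; optional header; one
# row per (pair, activity) label. Models: versioned JSON. All writers are
# deterministic (stable orders, fixed number formatting, no timestamps);
# numbers serialize at full (17 significant digit) precision.

#' The seven cytochrome P450 activity labels
#'
#' Default label vocabulary of the interaction model: the CYP isoforms most
#' involved in phase-I drug metabolism.
#' @export
CYP_ACTIVITIES <- c("CYP1A2", "CYP2B6", "CYP2C19", "CYP2C8", "CYP2C9",
                    "CYP2D6", "CYP3A4")

# batch-parse SMILES through one Open Babel call; returns named list of
# graphs plus a diagnostics data frame for records the reader rejected
parse_smiles_batch <- function(smiles, ids, strip_salts = FALSE) {
  stopifnot(length(smiles) == length(ids))
  if (anyDuplicated(ids))
    stop_posmna("duplicate molecule id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "),
                class = "schema")
  if (any(grepl("[\t ]", ids)))
    stop_posmna("molecule ids must not contain whitespace", class = "schema")
  src <- paste0(trimws(smiles), "\t", ids, "\n", collapse = "")
  recs <- split_sdf_records(ob_to_sdf(src, "SMI"))
  titles <- vapply(recs, function(r) trimws(sub("\n.*", "", r)), character(1L))
  out <- list()
  errors <- character()
  for (i in seq_along(ids)) {
    j <- match(ids[[i]], titles)
    if (is.na(j)) {
      errors[[ids[[i]]]] <- paste0("record '", ids[[i]],
                                   "' (line ", i, "): SMILES rejected")
      next
    }
    g <- tryCatch(
      require_single_component(
        parse_molblock(strsplit(recs[[j]], "\n")[[1L]], id = ids[[i]]),
        strip_salts = strip_salts),
      posmna_error = function(e) conditionMessage(e))
    if (is.character(g)) errors[[ids[[i]]]] <- g else out[[ids[[i]]]] <- g
  }
  attr(out, "errors") <- errors
  out
}

#' Read molecules from a SMILES or SDF file
#'
#' @param path file path.
#' @param format `"smiles"`, `"sdf"`, or `"auto"` (by extension:
#'   `.sdf`/`.mol` are SDF, anything else SMILES).
#' @param id_tag for SDF input, the name of a data field (`> <tag>`) to take
#'   molecule ids from instead of the title line.
#' @param strict if `TRUE` (default) any unparseable record aborts the read;
#'   if `FALSE`, failures are collected and returned in the `errors`
#'   attribute (a named character vector of diagnostics).
#' @param strip_salts passed to [require_single_component()].
#' @return named list of [mol_graph()] objects; zero valid records or
#'   duplicate ids are an error.
#' @export
read_molecules <- function(path, format = c("auto", "smiles", "sdf"),
                           id_tag = NULL, strict = TRUE, strip_salts = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_posmna("molecule file not found: ", path, class = "io")
  if (format == "auto")
    format <- if (grepl("\\.(sdf|mol)$", path, ignore.case = TRUE))
      "sdf" else "smiles"
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (!length(lines))
      stop_posmna("no molecule records in ", path, class = "io")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
      stop_posmna("malformed SMILES line(s) (need id<TAB>smiles): line ",
                  paste(bad, collapse = ", "), class = "io")
    ids <- vapply(fields, `[[`, character(1L), 1L)
    smiles <- vapply(fields, `[[`, character(1L), 2L)
    mols <- parse_smiles_batch(smiles, ids, strip_salts = strip_salts)
  } else {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    raw_recs <- split_sdf_records(paste0(text, "\n"))
    ids <- vapply(raw_recs, function(r) {
      lns <- strsplit(r, "\n")[[1L]]
      if (!is.null(id_tag)) {
        hit <- grep(paste0("^>.*<", id_tag, ">"), lns)
        if (length(hit)) return(trimws(lns[[hit[[1L]] + 1L]]))
      }
      trimws(lns[[1L]])
    }, character(1L))
    if (any(!nzchar(ids)))
      stop_posmna("SDF record(s) without an id (empty title line)",
                  class = "io")
    if (anyDuplicated(ids))
      stop_posmna("duplicate molecule id(s): ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", "),
                  class = "schema")
    mols <- list()
    errors <- character()
    for (i in seq_along(raw_recs)) {
      g <- tryCatch(
        parse_structure(paste0(raw_recs[[i]], "$$$$\n"), id = ids[[i]],
                        format = "sdf", strip_salts = strip_salts),
        posmna_error = function(e) conditionMessage(e))
      if (is.character(g)) errors[[ids[[i]]]] <- g else mols[[ids[[i]]]] <- g
    }
    attr(mols, "errors") <- errors
  }
  errs <- attr(mols, "errors")
  if (strict && length(errs))
    stop_posmna("failed to parse ", length(errs), " record(s): ",
                paste(utils::head(errs, 3L), collapse = "; "), class = "io")
  if (!length(mols))
    stop_posmna("no valid molecule records in ", path, class = "io")
  mols
}

#' Write molecules as a SMILES file
#'
#' @param library data frame with columns `id` and `smiles` (e.g. from
#'   [synth_library()]).
#' @param path output path.
#' @param header optional comment line(s) written with a leading `#`.
#' @export
write_smiles <- function(library, path, header = NULL) {
  lines <- c(if (!is.null(header)) paste0("# ", header),
             paste0(library$id, "\t", library$smiles))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled pair table
#'
#' TSV with columns `id_a`, `id_b`, `activity` (header optional, `#` comments
#' allowed). Pair keys are unordered; duplicate (pair, activity) rows are
#' collapsed.
#'
#' @param path file path.
#' @param molecules optional named molecule list; when given, every id must
#'   resolve against it.
#' @param activities allowed label vocabulary (default the seven CYP
#'   isoforms, [CYP_ACTIVITIES]); `NULL` disables the check.
#' @return data frame with columns `id_a`, `id_b`, `activity`, one row per
#'   unique (unordered pair, activity) label.
#' @export
read_pair_table <- function(path, molecules = NULL,
                            activities = CYP_ACTIVITIES) {
  if (!file.exists(path))
    stop_posmna("pair table not found: ", path, class = "io")
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_posmna("no pair rows in ", path, class = "io")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1L]][1:2]), c("id_a", "id_b"))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_posmna("malformed pair row(s) at line ",
                paste(lineno[bad], collapse = ", "), class = "io")
  tab <- data.frame(id_a = vapply(fields, `[[`, character(1L), 1L),
                    id_b = vapply(fields, `[[`, character(1L), 2L),
                    activity = vapply(fields, `[[`, character(1L), 3L),
                    stringsAsFactors = FALSE)
  if (!is.null(activities)) {
    bad <- which(!tab$activity %in% activities)
    if (length(bad))
      stop_posmna("unknown activity label(s) at line ",
                  paste(utils::head(lineno[bad], 5L), collapse = ", "),
                  ": ", paste(unique(tab$activity[bad]), collapse = ", "),
                  class = "schema")
  }
  if (!is.null(molecules)) {
    unknown <- !(tab$id_a %in% names(molecules)) |
               !(tab$id_b %in% names(molecules))
    if (any(unknown))
      stop_posmna("unknown molecule id(s) at line ",
                  paste(utils::head(lineno[unknown], 5L), collapse = ", "),
                  class = "schema")
  }
  key <- paste0(pair_key(tab$id_a, tab$id_b), "\r", tab$activity)
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a labeled pair table
#' @param pairs data frame with columns `id_a`, `id_b`, `activity`.
#' @param path output path.
#' @param header optional `#` comment line(s).
#' @export
write_pair_table <- function(pairs, path, header = NULL) {
  lines <- c(if (!is.null(header)) paste0("# ", header),
             "id_a\tid_b\tactivity",
             paste(pairs$id_a, pairs$id_b, pairs$activity, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Serialize a fitted model to versioned JSON
#'
#' Persists the count statistics and calibration arrays at full numeric
#' precision; a model read back with [read_model()] predicts bit-identically
#' to the in-memory fit.
#'
#' @param m fitted [ddi_fit()] model.
#' @param path output path.
#' @export
write_model <- function(m, path) {
  stopifnot(inherits(m, "posmna_bayes"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    level = m$level, k = m$k,
    activities = m$activities,
    N = m$N, N_a = as.integer(m$N_a),
    descriptors = m$vocab,
    n_d = as.integer(m$n_d),
    n_ad = stats::setNames(
      lapply(seq_along(m$activities), function(a) as.integer(m$n_ad[, a])),
      m$activities),
    calibration = lapply(m$calib, function(cal)
      list(active = cal$active, inactive = cal$inactive)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path path to the model JSON.
#' @return a `posmna_bayes` model (without its training pair sets; prediction
#'   and validation summaries work, [loo_scores()] requires a fresh fit).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop_posmna("model format version mismatch: file has '",
                obj$format_version, "', this package reads '",
                MODEL_FORMAT_VERSION, "'", class = "io")
  acts <- obj$activities
  n_ad <- do.call(cbind, lapply(acts, function(a) as.integer(obj$n_ad[[a]])))
  colnames(n_ad) <- acts
  calib <- lapply(acts, function(a)
    list(active = as.numeric(obj$calibration[[a]]$active),
         inactive = as.numeric(obj$calibration[[a]]$inactive)))
  names(calib) <- acts
  structure(
    list(format_version = obj$format_version, level = as.integer(obj$level),
         k = obj$k, activities = acts, N = as.integer(obj$N),
         N_a = stats::setNames(as.integer(obj$N_a), acts),
         vocab = as.character(obj$descriptors), n_d = as.integer(obj$n_d),
         n_ad = n_ad, calib = calib, loo = NULL, Y = NULL,
         pair_ids = NULL, pair_sets = NULL, call = NULL),
    class = "posmna_bayes")
}

#' Write predictions as TSV
#'
#' Columns `pair_id`, `activity`, `S`, `Pa`, `Pi`, `dP`, `yes_no`; rows per
#' pair sorted by `dP` descending. Numbers carry 17 significant digits.
#'
#' @param prediction a `ddi_prediction` from [predict.posmna_bayes()].
#' @param path output path.
#' @param threshold `dP` threshold for the `yes_no` column (default 0).
#' @param header optional `#` comment line(s).
#' @export
write_predictions <- function(prediction, path, threshold = 0,
                              header = NULL) {
  lines <- c(if (!is.null(header)) paste0("# ", header),
             "pair_id\tactivity\tS\tPa\tPi\tdP\tyes_no",
             paste(prediction$pair_id, prediction$activity,
                   fmt17(prediction$S), fmt17(prediction$Pa),
                   fmt17(prediction$Pi), fmt17(prediction$dP),
                   ifelse(prediction$dP > threshold, "YES", "NO"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a validation report
#'
#' TSV (or JSON) with one row per activity (`activity`, `n_active`,
#' `n_inactive`, `iap`) and a final unweighted `Average` row.
#'
#' @param report a `ddi_validation` from [ddi_validate()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param header optional `#` comment line(s) (TSV only).
#' @export
write_validation_report <- function(report, path, format = c("tsv", "json"),
                                    header = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(activities = as.data.frame(report),
           average = attr(report, "average")),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    lines <- c(if (!is.null(header)) paste0("# ", header),
               "activity\tn_active\tn_inactive\tiap",
               paste(report$activity, report$n_active, report$n_inactive,
                     fmt17(report$iap), sep = "\t"),
               paste("Average", "", "", fmt17(attr(report, "average")),
                     sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}
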