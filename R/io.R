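#' Write a synthetic dataset to disk
#'
#' Writes plain-text files into a directory: `focals.csv`, `roster.csv`,
#' long-form `agonistic.csv` and `grooming.csv` interaction tables, one
#' ESRI ASCII grid per spatial layer, and a `config.json` sidecar recording
#' the generative configuration and seed. [read_dataset()] round-trips the
#' result.
#'
#' @param focals focal-observation table.
#' @param roster group roster.
#' @param agonistic directed interaction count matrix.
#' @param grooming symmetric grooming weight matrix.
#' @param layers named list of [spatial_layer()]s.
#' @param path output directory (created if needed).
#' @param config optional [look_true_config()] to record.
#' @export
write_dataset <- function(focals, roster, agonistic, grooming, layers, path,
                          config = NULL) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2) != 0)
    stop(sprintf("write_dataset: cannot write to '%s'", path))
  utils::write.csv(as.data.frame(focals), file.path(path, "focals.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(roster), file.path(path, "roster.csv"),
                   row.names = FALSE)
  utils::write.csv(matrix_to_long(agonistic),
                   file.path(path, "agonistic.csv"), row.names = FALSE)
  utils::write.csv(matrix_to_long(grooming),
                   file.path(path, "grooming.csv"), row.names = FALSE)
  for (nm in names(layers))
    write_asc(layers[[nm]], file.path(path, paste0(nm, ".asc")))
  meta <- list(layers = as.list(stats::setNames(
    vapply(layers, function(l) l$kind, ""), names(layers))))
  if (!is.null(config)) meta$config <- unclass(config)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(path, "config.json"))
  invisible(path)
}

matrix_to_long <- function(M) {
  idx <- which(M != 0, arr.ind = TRUE)
  data.frame(from = rownames(M)[idx[, 1]], to = colnames(M)[idx[, 2]],
             weight = M[idx], stringsAsFactors = FALSE)
}

long_to_matrix <- function(df, ids) {
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(df)) M[cbind(match(df$from, ids), match(df$to, ids))] <- df$weight
  M
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path dataset directory.
#' @return list with `focals`, `roster`, `agonistic`, `grooming`, `layers`,
#'   `config`.
#' @export
read_dataset <- function(path) {
  focals <- utils::read.csv(file.path(path, "focals.csv"),
                            stringsAsFactors = FALSE)
  if (nrow(focals)) {
    for (cc in grep("_ongoing$|^observer_moved$|^censored$", names(focals)))
      focals[[cc]] <- as.logical(focals[[cc]])
    # an all-NA elapsed column parses as logical; it is numeric minutes
    for (cc in grep("_elapsed$", names(focals)))
      focals[[cc]] <- as.numeric(focals[[cc]])
    if ("neighbour_ids" %in% names(focals))
      focals$neighbour_ids[is.na(focals$neighbour_ids)] <- ""
  }
  class(focals) <- c("look_focals", "data.frame")
  roster <- utils::read.csv(file.path(path, "roster.csv"),
                            stringsAsFactors = FALSE)
  roster$age_sex_class <- factor(roster$age_sex_class, levels = age_sex_levels())
  class(roster) <- c("look_roster", "data.frame")
  meta <- jsonlite::fromJSON(file.path(path, "config.json"),
                             simplifyVector = TRUE)
  layers <- list()
  for (nm in names(meta$layers))
    layers[[nm]] <- read_asc(file.path(path, paste0(nm, ".asc")),
                             kind = meta$layers[[nm]])
  ids <- roster$individual_id
  list(focals = focals, roster = roster,
       agonistic = long_to_matrix(
         utils::read.csv(file.path(path, "agonistic.csv"),
                         stringsAsFactors = FALSE, colClasses = c(
                           from = "character", to = "character")), ids),
       grooming = long_to_matrix(
         utils::read.csv(file.path(path, "grooming.csv"),
                         stringsAsFactors = FALSE, colClasses = c(
                           from = "character", to = "character")), ids),
       layers = layers, config = meta$config)
}

#' Ingest an external focal dataset
#'
#' Reads a focal-observation CSV with the documented schema (or a user
#' schema map translating external column names), validates the record
#' invariants, and rejects violating rows with a line-numbered report.
#' Optional columns that are absent (for example the observer-tolerance
#' score) simply stay absent; models needing them are skipped downstream
#' with a warning.
#'
#' @param path a `focals.csv` file or a dataset directory.
#' @param schema_map optional named character vector mapping canonical
#'   column names to the file's column names, e.g.
#'   `c(in_view_seconds = "exposure_s")`.
#' @return validated `look_focals` table; rejected rows are reported via
#'   warning and attached as attribute `"rejected"`.
#' @export
ingest_dataset <- function(path, schema_map = NULL) {
  file <- if (dir.exists(path)) file.path(path, "focals.csv") else path
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!is.null(schema_map)) {
    for (canon in names(schema_map)) {
      ext <- schema_map[[canon]]
      if (!ext %in% names(tab))
        stop(sprintf("ingest_dataset: mapped column '%s' not found", ext))
      names(tab)[names(tab) == ext] <- canon
    }
  }
  required <- c("individual_id", "date", "time_period", "in_view_seconds")
  absent <- setdiff(required, names(tab))
  if (length(absent))
    stop(sprintf("ingest_dataset: required column(s) missing: %s",
                 paste(absent, collapse = ", ")))
  bad <- rep(FALSE, nrow(tab))
  why <- character(nrow(tab))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    why[cond & !bad] <<- msg
    bad <<- bad | cond
  }
  flag(tab$in_view_seconds <= 0 | tab$in_view_seconds > 30,
       "in_view_seconds outside (0, 30]")
  flag(!tab$time_period %in% 1:4, "time_period outside 1..4")
  if ("total_look_seconds" %in% names(tab)) {
    flag(tab$total_look_seconds > tab$in_view_seconds + 1e-9,
         "total_look_seconds exceeds in_view_seconds")
    if ("censored" %in% names(tab))
      flag(as.logical(tab$censored) &
             abs(tab$total_look_seconds - tab$in_view_seconds) > 1e-9,
           "censored but total_look_seconds != in_view_seconds")
  }
  if ("n_looks" %in% names(tab))
    flag(tab$n_looks < 0 | tab$n_looks != round(tab$n_looks),
         "n_looks not a non-negative integer")
  if (any(bad)) {
    report <- sprintf("row %d: %s", which(bad), why[bad])
    warning(sprintf("ingest_dataset: rejected %d row(s):\n  %s",
                    sum(bad), paste(report, collapse = "\n  ")))
  }
  out <- tab[!bad, , drop = FALSE]
  if ("observer_moved" %in% names(out))
    out$observer_moved <- as.logical(out$observer_moved)
  if ("censored" %in% names(out)) out$censored <- as.logical(out$censored)
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(row = which(bad), reason = why[bad])
  class(out) <- c("look_focals", "data.frame")
  out
}
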