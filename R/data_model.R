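# Shared data model: observations, dose records, study container, CSV I/O.

.obs_cols <- c("animal_id", "group", "analyte", "time", "time_unit",
               "value", "blq", "lloq")
.dose_cols <- c("animal_id", "dose_level_mg_per_kg", "weight_kg")

.groups   <- c("bolus_low", "bolus_mid", "bolus_high", "isl_only", "isl_plus")
.analytes <- c("plasma_parent", "pbmc_triphosphate")
.designs  <- c("sparse_bolus", "serial_implant")

NG_PER_MG     <- 1e6
HOURS_PER_DAY <- 24

#' Assemble a validated pharmacokinetic study dataset
#'
#' Bundles long-format concentration observations with per-animal dose
#' records. One row of `observations` is one measurement of one analyte in
#' one animal at one time; destructive sparse designs therefore contribute a
#' single row per animal and analyte. Below-limit-of-quantification (BLQ)
#' rows are retained with their reported LLOQ so the censoring policy can be
#' changed after the fact; exclusions are only ever flagged, never deleted.
#'
#' @param observations Tibble/data.frame with columns `animal_id`, `group`,
#'   `analyte`, `time`, `time_unit` (`"hours"` or `"days"`), `value`, `blq`
#'   (logical), `lloq`. Optional `excluded` (logical) and `exclude_reason`.
#' @param doses Tibble/data.frame with columns `animal_id`,
#'   `dose_level_mg_per_kg`, `weight_kg` and, for implant studies,
#'   `loaded_dose_mg`. The absolute dose in ng is derived as
#'   `dose_level * weight * 1e6`.
#' @param design `"sparse_bolus"` (time in hours) or `"serial_implant"`
#'   (time in days).
#' @param metadata Optional named list carried along unmodified (simulation
#'   truth, provenance, ...).
#' @return An object of class `pk_study`: a list with elements
#'   `observations`, `doses`, `design`, `metadata`.
#' @export
pk_study <- function(observations, doses, design = c("sparse_bolus", "serial_implant"),
                     metadata = list()) {
  design <- match.arg(design)
  observations <- tibble::as_tibble(observations)
  doses <- tibble::as_tibble(doses)

  missing_obs <- setdiff(.obs_cols, names(observations))
  if (length(missing_obs)) {
    stop("observation table is missing column(s): ",
         paste(missing_obs, collapse = ", "), call. = FALSE)
  }
  missing_dose <- setdiff(.dose_cols, names(doses))
  if (length(missing_dose)) {
    stop("dose table is missing column(s): ",
         paste(missing_dose, collapse = ", "), call. = FALSE)
  }
  if (!"excluded" %in% names(observations)) observations$excluded <- FALSE
  if (!"exclude_reason" %in% names(observations)) observations$exclude_reason <- NA_character_

  bad <- .validate_observations(observations, design)
  if (length(bad)) stop(paste(bad, collapse = "\n"), call. = FALSE)

  if (!"loaded_dose_mg" %in% names(doses)) doses$loaded_dose_mg <- NA_real_
  doses$absolute_dose_ng <- doses$dose_level_mg_per_kg * doses$weight_kg * NG_PER_MG
  if (any(doses$absolute_dose_ng <= 0, na.rm = TRUE)) {
    stop("absolute dose must be positive for every animal", call. = FALSE)
  }
  orphans <- setdiff(unique(observations$animal_id), doses$animal_id)
  if (length(orphans)) {
    stop("observations reference animal(s) without a dose record: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }

  structure(
    list(observations = observations, doses = doses,
         design = design, metadata = metadata),
    class = "pk_study"
  )
}

.validate_observations <- function(obs, design) {
  msgs <- character()
  row_msg <- function(idx, what) {
    sprintf("validation error: %s (row%s %s)", what,
            if (length(idx) > 1) "s" else "",
            paste(utils::head(idx, 10), collapse = ", "))
  }
  if (length(bad <- which(!obs$group %in% .groups))) {
    msgs <- c(msgs, row_msg(bad, "unknown group label"))
  }
  if (length(bad <- which(!obs$analyte %in% .analytes))) {
    msgs <- c(msgs, row_msg(bad, "unknown analyte label"))
  }
  if (length(bad <- which(!is.finite(obs$time) | obs$time < 0))) {
    msgs <- c(msgs, row_msg(bad, "negative or non-finite time"))
  }
  if (length(bad <- which(!is.finite(obs$lloq) | obs$lloq <= 0))) {
    msgs <- c(msgs, row_msg(bad, "nonpositive LLOQ"))
  }
  if (length(bad <- which(!obs$blq & (!is.finite(obs$value) | obs$value <= 0)))) {
    msgs <- c(msgs, row_msg(bad, "nonpositive value on a quantifiable row"))
  }
  expected_unit <- if (design == "sparse_bolus") "hours" else "days"
  if (length(bad <- which(obs$time_unit != expected_unit))) {
    msgs <- c(msgs, row_msg(bad, sprintf("time_unit must be '%s' for design '%s'",
                                         expected_unit, design)))
  }
  msgs
}

# Fill in optional flag columns on bare observation tables.
.ensure_flags <- function(obs) {
  if (!"excluded" %in% names(obs)) obs$excluded <- FALSE
  if (!"exclude_reason" %in% names(obs)) obs$exclude_reason <- NA_character_
  obs
}

#' @export
print.pk_study <- function(x, ...) {
  cat(sprintf("<pk_study> design=%s | %d observations (%d BLQ, %d excluded) | %d animals\n",
              x$design, nrow(x$observations), sum(x$observations$blq),
              sum(x$observations$excluded), nrow(x$doses)))
  invisible(x)
}

#' Read a concentration-time study from CSV files
#'
#' Expects the long (tidy) layout: one observation row per
#' animal/time/analyte, plus a per-animal dose table. Decimal separator is
#' `"."`, files are UTF-8 with a header row. BLQ rows are retained (flagged,
#' not dropped). Malformed rows abort with the offending row numbers.
#'
#' @param obs_path CSV with columns `animal_id, group, analyte, time,
#'   time_unit, value, blq, lloq` (optional `excluded`, `exclude_reason`).
#' @param dose_path CSV with columns `animal_id, dose_level_mg_per_kg,
#'   weight_kg` and optionally `loaded_dose_mg`.
#' @inheritParams pk_study
#' @return A [pk_study()] object.
#' @export
read_study_csv <- function(obs_path, dose_path,
                           design = c("sparse_bolus", "serial_implant")) {
  design <- match.arg(design)
  for (p in c(obs_path, dose_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
  doses <- utils::read.csv(dose_path, stringsAsFactors = FALSE)
  if (nrow(obs) && "blq" %in% names(obs)) obs$blq <- as.logical(obs$blq)
  if ("excluded" %in% names(obs)) obs$excluded <- as.logical(obs$excluded)
  obs$animal_id <- as.character(obs$animal_id)
  doses$animal_id <- as.character(doses$animal_id)
  pk_study(obs, doses, design = design,
           metadata = list(obs_path = obs_path, dose_path = dose_path))
}

#' Write a study or result object to structured text
#'
#' Tables go to CSV, parameter sets to JSON; everything numeric is written
#' with full double precision so that a read-back reproduces values exactly
#' (round-trippable). A `pk_study` writes two files, `<stem>_observations.csv`
#' and `<stem>_doses.csv`.
#'
#' @param x A `pk_study`, any tibble/data.frame result, or a list-like
#'   parameter set (e.g. [uir()], [fit_macro_model()] output).
#' @param path Output path. Extension `.csv` for tables, `.json` for
#'   parameter sets; for `pk_study` give a stem without extension.
#' @return Invisibly, the path(s) written.
#' @export
write_results <- function(x, path) {
  UseMethod("write_results")
}

#' @export
write_results.pk_study <- function(x, path) {
  obs_path <- paste0(path, "_observations.csv")
  dose_path <- paste0(path, "_doses.csv")
  .write_csv_full(x$observations, obs_path)
  dose <- x$doses
  dose$absolute_dose_ng <- NULL  # derived; recomputed on read
  .write_csv_full(dose, dose_path)
  invisible(c(obs_path, dose_path))
}

#' @export
write_results.data.frame <- function(x, path) {
  .write_csv_full(x, path)
  invisible(path)
}

#' @export
write_results.default <- function(x, path) {
  cls <- class(x)[[1L]]
  if (!is.list(x)) stop("don't know how to serialise an object of class ", cls,
                        call. = FALSE)
  payload <- list(class = cls, fields = .strip_functions(unclass(x)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

.strip_functions <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.function, logical(1))]
    lapply(x, .strip_functions)
  } else x
}

.write_csv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
}

#' Read back a result written by [write_results()]
#'
#' @param path A `.csv` or `.json` file produced by [write_results()].
#' @return A tibble (CSV) or the stored field list with a `class` attribute
#'   restored (JSON).
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path)) {
    payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    out <- payload$fields
    class(out) <- payload$class
    out
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
    if ("blq" %in% names(df)) df$blq <- as.logical(df$blq)
    if ("excluded" %in% names(df)) df$excluded <- as.logical(df$excluded)
    tibble::as_tibble(df)
  }
}
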