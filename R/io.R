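MODEL_FORMAT <- "odorblend/mixture-curve"
MODEL_VERSION <- 1L

parse_numeric_column <- function(values, column, path, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(values))
  blank <- is.na(values) | !nzchar(trimws(values))
  bad <- is.na(out) & !blank
  if (allow_na) {
    out[blank] <- NA_real_
  } else {
    bad <- bad | blank
  }
  if (any(bad)) {
    # +1 for the header row
    stop(sprintf("%s: line %d: non-numeric or missing `%s` value \"%s\"",
                 path, which(bad)[1] + 1L, column, values[which(bad)[1]]),
         call. = FALSE)
  }
  out
}

#' Read an odorant threshold table
#'
#' Reads the odorant reference CSV dialect: UTF-8, comma separated, `.`
#' decimal separator, header row with at least `name`, `cas`,
#' `molecular_weight` and `threshold_mg_m3`. Unknown columns are preserved
#' but ignored. Rows with missing or non-positive thresholds are rejected
#' with their line number; `molecular_weight` may be blank (it is needed only
#' for unit conversion).
#'
#' @param path path to the CSV file.
#' @return data.frame of validated odorant records.
#' @seealso [aldehyde_thresholds()], [odorant_from_table()]
#' @export
load_thresholds <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("name", "cas", "molecular_weight", "threshold_mg_m3")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    raw$molecular_weight <- numeric()
    raw$threshold_mg_m3 <- numeric()
    return(raw)
  }
  raw$molecular_weight <- parse_numeric_column(raw$molecular_weight,
                                               "molecular_weight", path,
                                               allow_na = TRUE)
  raw$threshold_mg_m3 <- parse_numeric_column(raw$threshold_mg_m3,
                                              "threshold_mg_m3", path)
  bad <- raw$threshold_mg_m3 <= 0
  if (any(bad)) {
    stop(sprintf("%s: line %d: `threshold_mg_m3` must be strictly positive",
                 path, which(bad)[1] + 1L), call. = FALSE)
  }
  bad_mw <- !is.na(raw$molecular_weight) & raw$molecular_weight <= 0
  if (any(bad_mw)) {
    stop(sprintf("%s: line %d: `molecular_weight` must be strictly positive",
                 path, which(bad_mw)[1] + 1L), call. = FALSE)
  }
  raw
}

#' Packaged aldehyde threshold table
#'
#' The packaged reference table of seven short-chain aldehydes with their
#' panel-measured odor detection thresholds in mg/m3 (with molecular weights
#' for unit conversion).
#'
#' @return data.frame as from [load_thresholds()], plus an `abbrev` column.
#' @examples
#' aldehyde_thresholds()
#' @export
aldehyde_thresholds <- function() {
  load_thresholds(system.file("extdata", "aldehyde_thresholds.csv",
                              package = "odorblend", mustWork = TRUE))
}

#' Look up an odorant in a threshold table
#'
#' @param table data.frame from [load_thresholds()].
#' @param name odorant name, or abbreviation if the table has an `abbrev`
#'   column.
#' @return an [odorant()] object.
#' @examples
#' odorant_from_table(aldehyde_thresholds(), "PA")
#' @export
odorant_from_table <- function(table, name) {
  hit <- table$name == name
  if ("abbrev" %in% names(table)) hit <- hit | table$abbrev == name
  if (sum(hit) != 1L) {
    stop(sprintf("odorant `%s` not found (or ambiguous) in threshold table", name),
         call. = FALSE)
  }
  row <- table[hit, ]
  odorant(row$name, row$threshold_mg_m3, cas = row$cas,
          molecular_weight = row$molecular_weight)
}

#' Packaged binary-mixture validation set
#'
#' The packaged odor-intensity matching validation set for the pooled
#' extended model: 21 binary aldehyde samples (9 from mixtures of the
#' aldehydes the model was pooled over, section A; 12 from mixtures
#' containing other aldehydes, section B), each with the two components'
#' lnOAV values, the panel-measured odor intensity, and the partial
#' intensities and predicted odor intensity as originally reported
#' (`*_pub` columns, at their printed precision).
#'
#' @return data.frame with columns `section`, `odorant_a`, `odorant_b`,
#'   `ln_oav_a`, `ln_oav_b`, `oi_a_m_pub`, `oi_b_m_pub`, `oi_pre_pub`,
#'   `oi_mea`.
#' @examples
#' head(validation_mixtures())
#' @export
validation_mixtures <- function() {
  path <- system.file("extdata", "validation_mixtures.csv",
                      package = "odorblend", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  numeric_cols <- c("ln_oav_a", "ln_oav_b", "oi_a_m_pub", "oi_b_m_pub",
                    "oi_pre_pub", "oi_mea")
  for (col in numeric_cols) out[[col]] <- as.numeric(out[[col]])
  out
}

#' Read a binary-mixture sample table
#'
#' Reads the sample CSV dialect `mixture_id, odorant_a, conc_a_mg_m3,
#' odorant_b, conc_b_mg_m3, measured_oi` (the last column optional for
#' prediction-only runs). Malformed numerics are rejected with line numbers,
#' never coerced. When a threshold table is supplied, `ln_oav_a` and
#' `ln_oav_b` columns are derived from the concentrations.
#'
#' @param path path to the CSV file.
#' @param thresholds optional data.frame from [load_thresholds()].
#' @return data.frame of samples.
#' @export
read_samples <- function(path, thresholds = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("mixture_id", "odorant_a", "conc_a_mg_m3", "odorant_b",
                "conc_b_mg_m3")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) > 0L) {
    raw$conc_a_mg_m3 <- parse_numeric_column(raw$conc_a_mg_m3, "conc_a_mg_m3", path)
    raw$conc_b_mg_m3 <- parse_numeric_column(raw$conc_b_mg_m3, "conc_b_mg_m3", path)
    if ("measured_oi" %in% names(raw)) {
      raw$measured_oi <- parse_numeric_column(raw$measured_oi, "measured_oi",
                                              path, allow_na = TRUE)
    }
  } else {
    raw$conc_a_mg_m3 <- numeric()
    raw$conc_b_mg_m3 <- numeric()
  }
  if (!is.null(thresholds) && nrow(raw) > 0L) {
    raw$ln_oav_a <- vapply(seq_len(nrow(raw)), function(i) {
      compute_ln_oav(raw$conc_a_mg_m3[i],
                     odorant_from_table(thresholds, raw$odorant_a[i]))
    }, numeric(1))
    raw$ln_oav_b <- vapply(seq_len(nrow(raw)), function(i) {
      compute_ln_oav(raw$conc_b_mg_m3[i],
                     odorant_from_table(thresholds, raw$odorant_b[i]))
    }, numeric(1))
  }
  raw
}

#' @rdname read_samples
#' @param samples data.frame of samples to write.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize and restore mixture-curve models
#'
#' Models are stored as JSON with full numeric precision, a format tag and a
#' schema version; `read_model()` refuses files with a different format or
#' version rather than guessing, and reports unparsable files as such. The
#' round trip is lossless for all fields, including the design-matrix
#' summaries the confidence band needs.
#'
#' @param model a `mixture_curve`.
#' @param path path of the JSON file.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored `mixture_curve`.
#' @examples
#' p <- file.path(tempdir(), "model.json")
#' write_model(extended_model(), p)
#' read_model(p)
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mixture_curve"))
  obj <- list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    coefficients = as.list(model$coefficients),
    n_points = model$n_points, residual_sd = model$residual_sd,
    confidence_level = model$confidence_level,
    provenance = model$provenance,
    xtx_inv = model$xtx_inv
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      stop(sprintf("%s: cannot parse model file: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop(sprintf("%s: not a mixture-curve model file", path), call. = FALSE)
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    stop(sprintf("%s: incompatible model version %s (expected %d)", path,
                 obj$version, MODEL_VERSION), call. = FALSE)
  }
  xtx_inv <- obj$xtx_inv
  if (!is.null(xtx_inv)) xtx_inv <- matrix(as.numeric(xtx_inv), nrow = 3, byrow = FALSE)
  new_mixture_curve(
    unlist(obj$coefficients[c("a0", "a1", "a2")]),
    n_points = if (is.null(obj$n_points)) NA_integer_ else obj$n_points,
    residual_sd = if (is.null(obj$residual_sd)) NA_real_ else obj$residual_sd,
    confidence_level = obj$confidence_level,
    xtx_inv = xtx_inv, provenance = obj$provenance
  )
}

#' Write a prediction report
#'
#' Writes predictions in the report CSV dialect `lnoav_a, lnoav_b, oi_a_m,
#' oi_b_m, oi_pre[, oi_mea, ratio]` at report precision: partial intensities
#' at two decimals and odor intensities at one (via [round_oi_report()]);
#' internal full-precision values are unaffected. Column order and formatting
#' are deterministic.
#'
#' @param predictions data.frame from [predict_oi()].
#' @param path output CSV path.
#' @param oi_mea optional vector of measured odor intensities; adds `oi_mea`
#'   and `ratio` columns.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(predictions, path, oi_mea = NULL) {
  stopifnot(is.data.frame(predictions),
            all(c("ln_oav_a", "ln_oav_b", "oi_a_m", "oi_b_m", "oi_pre") %in%
                  names(predictions)))
  out <- data.frame(
    lnoav_a = sprintf("%.2f", round_half_up(predictions$ln_oav_a, 2)),
    lnoav_b = sprintf("%.2f", round_half_up(predictions$ln_oav_b, 2)),
    oi_a_m = sprintf("%.2f", round_half_up(predictions$oi_a_m, 2)),
    oi_b_m = sprintf("%.2f", round_half_up(predictions$oi_b_m, 2)),
    oi_pre = sprintf("%.1f", round_oi_report(predictions$oi_pre))
  )
  if (!is.null(oi_mea)) {
    out$oi_mea <- sprintf("%.1f", round_half_up(oi_mea, 1))
    out$ratio <- sprintf("%.2f",
                         round_half_up(round_oi_report(predictions$oi_pre) / oi_mea, 2))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A manifest records what a command-line run consumed and produced: the
#' command, md5 digests of the input files, the seed, the package version and
#' a timestamp. Reruns with identical manifest inputs produce byte-identical
#' numeric outputs.
#'
#' @param command character, the subcommand that ran.
#' @param inputs character vector of input file paths (digested).
#' @param outputs character vector of output file paths.
#' @param seed integer seed used, or `NULL`.
#' @return `run_manifest()`: a list of manifest fields; `write_manifest()`
#'   writes it as JSON and returns `path` invisibly.
#' @export
run_manifest <- function(command, inputs = character(), outputs = character(),
                         seed = NULL) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character())
  }
  list(
    command = command,
    inputs = digests,
    outputs = as.character(outputs),
    seed = seed,
    package_version = as.character(utils::packageVersion("odorblend")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' @rdname run_manifest
#' @param manifest a manifest list from `run_manifest()`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
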