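#' Write BLI traces to a long-format CSV
#'
#' Columns: `sensor_id, phase, time_s, signal_nm, analyte_nM, is_reference`,
#' one row per time point. Comma-separated, UTF-8, "." decimal.
#'
#' @param traces A [bli_trace()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  if (inherits(traces, "bli_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read BLI traces from a long-format CSV
#'
#' Validates the schema of [write_trace_table()]: required columns, known
#' phase labels, strictly increasing time within each sensor. Malformed
#' content is reported with the offending sensor and line numbers.
#'
#' @param path CSV file path.
#' @return List of [bli_trace()] objects.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sensor_id", "phase", "time_s", "signal_nm", "analyte_nM",
                "is_reference")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_phase <- !df$phase %in% c("baseline", "association", "dissociation")
  if (any(bad_phase)) {
    stop("unknown phase label(s) at line(s) ",
         paste(utils::head(which(bad_phase) + 1L, 5), collapse = ", "),
         ": ", paste(unique(df$phase[bad_phase]), collapse = ", "))
  }
  lapply(split(df, factor(df$sensor_id, levels = unique(df$sensor_id))),
         function(d) {
    bad <- which(diff(d$time_s) <= 0)
    if (length(bad)) {
      stop("time not strictly increasing for sensor '", d$sensor_id[1],
           "' near line ", rownames(d)[bad[1] + 1L])
    }
    bli_trace(d$time_s, d$signal_nm, d$phase, d$analyte_nM[1],
              sensor_id = d$sensor_id[1],
              is_reference = isTRUE(as.logical(d$is_reference[1])))
  })
}

#' Write a steady-state dose-response table to CSV
#'
#' Columns: `conc_nM, replicate, signal_nm`.
#' @param dose_response Data frame as produced by [generate_dose_response()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(dose_response, path) {
  df <- as.data.frame(dose_response)[, c("conc_nM", "replicate", "signal_nm")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a steady-state dose-response table from CSV
#' @param path CSV file path with columns `conc_nM, replicate, signal_nm`.
#' @return Data frame.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("conc_nM", "replicate", "signal_nm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$conc_nM < 0)) stop("negative concentration")
  df
}

#' Write a competition dataset to CSV
#'
#' Columns: `competitor_nM, replicate, value, normalization`.
#' @param dataset A [competition_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_competition_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "competition_dataset"))
  df <- as.data.frame(dataset)
  df$normalization <- attr(dataset, "normalization")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a competition dataset from CSV
#' @param path CSV with columns `competitor_nM, replicate, value,
#'   normalization`.
#' @return A [competition_dataset()].
#' @export
read_competition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("competitor_nM", "replicate", "value", "normalization")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  norm <- unique(df$normalization)
  if (length(norm) != 1L) stop("mixed normalization modes in file")
  competition_dataset(df$competitor_nM, df$value, replicate = df$replicate,
                      normalization = norm)
}

#' Assemble a structured results document
#'
#' A uniform JSON-serializable record of an analysis: what was run, with
#' which inputs and settings, and what came out — every estimate with its
#' units, every stochastic step with its seed.
#'
#' @param analysis Analysis type string (e.g. `"fit_kinetics"`).
#' @param results Named list of estimates (with units in the names).
#' @param input Optional input file path (a SHA-agnostic content digest of
#'   the file is stored).
#' @param filters Optional named list of filters applied (thresholds,
#'   exclusion counts).
#' @param seed Optional seed used for any stochastic step.
#' @param config Optional configuration list echoed into the document.
#' @return List of class `results_document`.
#' @export
results_document <- function(analysis, results, input = NULL, filters = NULL,
                             seed = NULL, config = NULL) {
  digest <- if (!is.null(input) && file.exists(input)) {
    # cheap content fingerprint: size + checksum of the bytes
    bytes <- readBin(input, "raw", file.info(input)$size)
    sprintf("size=%d;sum=%.0f", length(bytes), sum(as.integer(bytes)))
  } else NULL
  structure(
    list(analysis = analysis,
         package = "bindfit",
         version = as.character(utils::packageVersion("bindfit")),
         input = input, input_digest = digest,
         results = results, filters = filters, seed = seed,
         config = config),
    class = "results_document"
  )
}

#' Write a results document (or any list) to JSON
#' @param doc A [results_document()] or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(doc, path) {
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
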