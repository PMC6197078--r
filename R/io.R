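#' Load a virtual-patient cohort
#'
#' Reads a cohort from a JSON or YAML file (a list of records with fields
#' `id`, `rho`, `t_half`, `k_hat`, `gamma_v`), or returns the shipped
#' reference cohort for `source = "reference"`.
#'
#' @param source File path (`.json`, `.yaml`/`.yml`) or the fixture name
#'   `"reference"`.
#' @param relaxed Accept parameters outside the training bounds with a
#'   warning instead of an error.
#' @return A `radfrac_cohort` (list of [patient_parameters()]).
#' @examples
#' length(load_cohort("reference"))  # 7
#' @export
load_cohort <- function(source, relaxed = FALSE) {
  if (identical(source, "reference")) return(reference_cohort())
  if (!file.exists(source)) stop("cohort file not found: ", source,
                                 call. = FALSE)
  records <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
    jsonlite::fromJSON(source, simplifyDataFrame = FALSE)
  } else if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML cohorts",
           call. = FALSE)
    yaml::read_yaml(source)
  } else stop("unsupported cohort format (expected .json or .yaml): ",
              source, call. = FALSE)
  if (length(records) == 0) stop("cohort file is empty: ", source,
                                 call. = FALSE)
  cohort <- lapply(records, function(r) {
    needed <- c("id", "rho", "t_half", "k_hat", "gamma_v")
    if (!all(needed %in% names(r)))
      stop("cohort record is missing fields: ",
           paste(setdiff(needed, names(r)), collapse = ", "), call. = FALSE)
    patient_parameters(r$id, r$rho, r$t_half, r$k_hat, r$gamma_v,
                       relaxed = relaxed)
  })
  names(cohort) <- vapply(cohort, `[[`, "", "id")
  structure(cohort, class = "radfrac_cohort")
}

#' Write a cohort to JSON
#'
#' @param cohort A `radfrac_cohort` or list of [patient_parameters()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  records <- lapply(cohort, function(p)
    list(id = p$id, rho = p$rho, t_half = p$t_half,
         k_hat = p$k_hat, gamma_v = p$gamma_v))
  jsonlite::write_json(unname(records), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @export
as.data.frame.radfrac_cohort <- function(x, ...) {
  do.call(rbind, c(lapply(x, function(p)
    data.frame(id = p$id, rho = p$rho, t_half = p$t_half,
               k_hat = p$k_hat, gamma_v = p$gamma_v)),
    list(make.row.names = FALSE)))
}

#' Write a simulation result (or any tabular result) to disk
#'
#' For a simulated course the daily trajectory is written with the canonical
#' header `day,dose_Gy,V_a,V_n,V_t,PO2,alpha,SF_t,SF_v,k`. JSON output keeps
#' full double precision (read-back equals the written values exactly); CSV
#' keeps 6 significant digits.
#'
#' @param result A `radfrac_sim` or a data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("csv", "json")) {
  if (!is.character(format) || !all(format %in% c("csv", "json")))
    stop("unknown format: ", paste(setdiff(format, c("csv", "json")),
                                   collapse = ", "), call. = FALSE)
  format <- match.arg(format)
  df <- if (inherits(result, "radfrac_sim")) result$trajectory
        else as.data.frame(result)
  ok <- tryCatch({
    if (format == "csv") {
      out <- df
      num <- vapply(out, is.numeric, logical(1))
      out[num] <- lapply(out[num], signif, digits = 6)
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(df, path, dataframe = "columns", digits = I(17))
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write ", format, " result to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a result written by [write_result()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A data frame.
#' @export
read_result <- function(path, format = c("csv", "json")) {
  if (!is.character(format) || !all(format %in% c("csv", "json")))
    stop("unknown format: ", paste(setdiff(format, c("csv", "json")),
                                   collapse = ", "), call. = FALSE)
  format <- match.arg(format)
  if (!file.exists(path)) stop("result file not found: ", path, call. = FALSE)
  if (format == "csv") utils::read.csv(path)
  else as.data.frame(jsonlite::fromJSON(path))
}
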