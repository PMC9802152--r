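#' Write / read an ensemble dataset as plain text
#'
#' An ensemble round-trips to a directory holding `parameters.csv`,
#' `behaviors.csv` and `meta.json` (base point, perturbation fraction,
#' observation times, observable, seed).
#'
#' @param dataset an [ensemble_dataset()].
#' @param dir directory to create/read.
#' @return `write_ensemble` returns `dir` invisibly; `read_ensemble` returns
#'   the reconstructed [ensemble_dataset()].
#' @export
write_ensemble <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ensemble_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dataset$parameters, file.path(dir, "parameters.csv"),
            row.names = FALSE)
  write.csv(dataset$behaviors, file.path(dir, "behaviors.csv"),
            row.names = FALSE)
  meta <- dataset$meta
  meta$residuals <- NULL
  meta$reference <- NULL
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

read_table_checked <- function(path) {
  x <- tryCatch(read.csv(path, check.names = FALSE),
                error = function(e) abort(sprintf("cannot parse %s: %s", path,
                                                  conditionMessage(e))))
  bad <- which(!stats::complete.cases(x))
  if (length(bad) > 0) {
    abort(sprintf("malformed rows in %s (first bad row: %d)", path, bad[1]))
  }
  x
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  pars <- read_table_checked(file.path(dir, "parameters.csv"))
  beh <- read_table_checked(file.path(dir, "behaviors.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  base <- meta$base
  if (!is.null(base)) base <- unlist(base)
  ensemble_dataset(pars, beh, base = base,
                   fraction = if (is.null(meta$fraction)) NA else meta$fraction,
                   times = meta$times, observable = meta$observable,
                   seed = meta$seed)
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory a tibble returned by one of the simulators.
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Write a study report as JSON
#' @param report named list (e.g. from [run_msp_study()]).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
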