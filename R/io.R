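# Tabular I/O: partition datasets and result tables (CSV/JSON, no binary
# formats).

#' Read a partition dataset from CSV
#'
#' Expected header: `solute,smiles,solvent_from,solvent_to,dg_kjmol,source`
#' (`source` optional). Free energies are in kJ/mol.
#'
#' @param path CSV file path.
#' @return A [partition_dataset()].
#' @export
read_partition_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("solute", "smiles", "solvent_from", "solvent_to", "dg_kjmol")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(d$source)) d$source <- "unknown"
  partition_dataset(d$solute, d$smiles, d$solvent_from, d$solvent_to,
                    as.numeric(d$dg_kjmol), d$source)
}

#' Write a partition dataset to CSV
#'
#' @param dataset A [partition_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Collect transfer results into a table
#'
#' @param results A list of `transfer_result` objects (or a single one).
#' @return Data frame with columns `solute`, `solvent_from`, `solvent_to`,
#'   `dg_kjmol`, `logp`.
#' @export
transfer_table <- function(results) {
  if (inherits(results, "transfer_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(solute = r$id, solvent_from = r$solvent_from,
               solvent_to = r$solvent_to, dg_kjmol = r$dg_kjmol,
               logp = r$logp, stringsAsFactors = FALSE)
  }))
}

#' Write a result table to CSV or JSON
#'
#' @param table A data frame (e.g. from [transfer_table()] or
#'   [as.data.frame.ssip_profile()]).
#' @param path Output path; the format is chosen by the `format` argument,
#'   defaulting to the file extension.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("JSON output requires the 'jsonlite' package", call. = FALSE)
    }
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
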