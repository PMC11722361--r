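# Tabular and config I/O shared by the command-line interface and scripts.

#' Read a per-frame pair interaction-energy table
#'
#' CSV with one row per frame; an optional `frame` column is dropped, the
#' remaining columns are per-pair energy series in kJ/mol.
#'
#' @param path CSV file.
#' @return data.frame of per-pair energy columns.
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  tab[, setdiff(names(tab), "frame"), drop = FALSE]
}

#' Read contact criteria from a YAML config
#'
#' Recognized keys match the arguments of [contact_criteria()]; missing keys
#' take the defaults.
#'
#' @param path YAML file.
#' @return a [contact_criteria()].
#' @export
read_contact_criteria <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(contact_criteria)))
  do.call(contact_criteria, cfg[keep])
}

#' Write an analysis result as JSON
#'
#' @param x a list (or S3 analysis object, unclassed).
#' @param path output path.
#' @export
write_results_json <- function(x, path) {
  if (is.object(x)) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
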