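#' Read and write the package's plain-text interchange formats
#'
#' Traces are CSV with columns `time_h,current_A`; metabolite panels are
#' CSV with columns `species,value,unit`; reactor specs are YAML or JSON
#' (by extension); OTU tables are TSV with taxa in rows and samples in
#' columns, first column the taxon identifier; taxonomy maps are TSV with
#' columns `taxon` and `family`; sample metadata are TSV with `sample_id`
#' and `group`; trees are newick.
#'
#' @param path File path.
#' @return `read_trace_csv()`: a trace tibble. `read_panel_csv()`: a named
#'   list suitable for [balance_report()]'s `panel` argument.
#'   `read_reactor_spec()`: a named list for its `spec` argument.
#'   `read_otu_tsv()`: a wide OTU tibble (samples in rows).
#'   `read_taxonomy_tsv()`, `read_metadata_tsv()`: tibbles.
#' @name fermbal_io
NULL

#' @rdname fermbal_io
#' @export
read_trace_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  check_trace(tr)
}

#' @rdname fermbal_io
#' @param trace Trace tibble to write.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(check_trace(trace), path)
  invisible(path)
}

#' @rdname fermbal_io
#' @export
read_panel_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("species", "value", "unit") %in% names(df)))
  as.list(setNames(df$value, df$species))
}

#' @rdname fermbal_io
#' @param panel Named list or one-row data frame of panel entries.
#' @export
write_panel_csv <- function(panel, path) {
  panel <- as.list(panel)
  units <- c(ethanol = "umol/L", acetate = "umol/L", hydrogen = "umol",
             biomass = "umol/L", consumed_fraction = "fraction",
             substrate_final = "g/L")
  keep <- intersect(names(units), names(panel))
  keep <- keep[!vapply(panel[keep], function(v) is.null(v) || is.na(v), logical(1))]
  readr::write_csv(tibble::tibble(
    species = keep,
    value = vapply(panel[keep], as.numeric, numeric(1)),
    unit = unname(units[keep])
  ), path)
  invisible(path)
}

#' @rdname fermbal_io
#' @export
read_reactor_spec <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as.list(spec)
}

#' @rdname fermbal_io
#' @export
read_otu_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  taxa <- df[[1]]
  m <- t(as.matrix(df[-1]))
  colnames(m) <- taxa
  otu_tibble(m)
}

#' @rdname fermbal_io
#' @param table Wide OTU tibble to write (samples in rows).
#' @export
write_otu_tsv <- function(table, path) {
  m <- otu_matrix(table)
  out <- dplyr::bind_cols(tibble::tibble(taxon_id = colnames(m)),
                          tibble::as_tibble(t(m)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname fermbal_io
#' @export
read_taxonomy_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("taxon", "family") %in% names(df)))
  df
}

#' @rdname fermbal_io
#' @export
read_metadata_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  df
}

#' Write a balance or study report as JSON
#'
#' Serialises a report together with provenance: the physical constants and
#' species table in force, the package version, and (for study reports) the
#' seed. Numbers are written at full precision.
#'
#' @param report A `balance_report` or `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  provenance <- list(
    tool = "fermbal",
    version = as.character(utils::packageVersion("fermbal")),
    faraday_C_per_mol_e = faraday_constant(),
    molar_gas_volume_L_per_mol = molar_gas_volume(),
    species_constants = species_constants()
  )
  body <- if (inherits(report, "balance_report")) {
    list(kind = "balance_report",
         summary = glance(report),
         shares = tidy(report),
         yields = report$yields,
         coulombs = report$coulombs)
  } else if (inherits(report, "study_report")) {
    list(kind = "study_report",
         seed = report$seed,
         balance = dplyr::select(report$balance, -"report"),
         rankings = report$rankings,
         permanova = report$community$permanova)
  } else {
    abort("unsupported report type")
  }
  jsonlite::write_json(c(body, list(provenance = provenance)), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
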