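#' Read a protein-group quantification matrix
#'
#' Supports two tab-separated dialects: `"wide-tsv"` (a `ProteinGroup` id
#' column followed by one numeric column per sample) and `"diann-pg"` (a
#' DIA-NN `pg_matrix`-style report: the `Protein.Group` column is the id,
#' annotation columns such as `Protein.Names`, `Genes`, `First.Protein.Description`
#' are dropped, and all remaining columns are samples). With
#' `dialect = "auto"` the dialect is sniffed from the header.
#'
#' DIA outputs conflate zero with not-detected. By default both empty cells
#' and zeros are parsed as missing (`zeros_as_missing = TRUE`); set it to
#' `FALSE` to keep zeros as values.
#'
#' @param path Path to a TSV file.
#' @param dialect `"wide-tsv"`, `"diann-pg"` or `"auto"`.
#' @param zeros_as_missing Logical, default `TRUE`.
#' @return A [quant_matrix()].
#' @export
read_quant_matrix <- function(path, dialect = c("auto", "wide-tsv", "diann-pg"),
                              zeros_as_missing = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "NaN"))
  if (ncol(df) < 2) stop("expected an id column plus at least one sample column")
  hdr <- names(df)
  if (dialect == "auto")
    dialect <- if (hdr[1] %in% c("Protein.Group", "Protein Group")) "diann-pg" else "wide-tsv"
  if (dialect == "diann-pg") {
    anno <- c("Protein.Ids", "Protein.Names", "Genes", "First.Protein.Description",
              "Protein Ids", "Protein Names")
    df <- df[, !(names(df) %in% anno), drop = FALSE]
  } else if (!(hdr[1] %in% c("ProteinGroup", "Protein.Group", "protein_id"))) {
    # transposed-input heuristic: a first column that itself looks numeric
    if (all(!is.na(suppressWarnings(as.numeric(df[[1]])))))
      stop("first column '", hdr[1], "' is numeric; expected a protein id column ",
           "(matrix must be proteins-in-rows; transpose your input)")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], names(vals)[j]))
      v <- conv
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (zeros_as_missing) m[!is.na(m) & m == 0] <- NA_real_
  quant_matrix(m)
}

#' Write a quantification matrix as wide TSV
#'
#' Emits the `wide-tsv` dialect ([read_quant_matrix()] round-trips it,
#' including the missing pattern). Missing values are written as empty cells.
#' If the matrix carries precursor counts they are written alongside as
#' `<path base>_precursors.tsv`.
#'
#' @param m A `quant_matrix` (linear scale).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(m, path) {
  .assert_linear(m, "write_quant_matrix()")
  df <- data.frame(ProteinGroup = protein_ids(m), m$intensity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(m$precursor_counts)) {
    pp <- sub("(\\.[^.]+)?$", "_precursors.tsv", path)
    dfp <- data.frame(ProteinGroup = protein_ids(m), m$precursor_counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dfp, pp, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read/write a sample metadata table
#'
#' TSV with at least a `sample_id` column; conventional columns are
#' `workflow`, `cell_type`, `cell_count` (cells per microlitre), `replicate`
#' and `group`, plus free-form condition fields.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample table must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("cell_count" %in% names(df) && any(df$cell_count < 0, na.rm = TRUE))
    stop("cell_count must be nonnegative")
  df
}

#' @rdname read_sample_table
#' @param tab Data.frame with a `sample_id` column.
#' @export
write_sample_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write marker panel files
#'
#' Panel TSVs carry at least `protein_id`, `cell_type`, `fold_change`, `rank`;
#' panels written by [write_marker_panel()] also keep the mean log10
#' intensity, CV and exclusivity flag of each marker.
#'
#' @param path TSV path.
#' @return A `marker_panel` (see [select_markers()]).
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "cell_type", "fold_change", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("panel file lacks column(s): ", paste(miss, collapse = ", "))
  new_marker_panel(df[order(df$rank), , drop = FALSE],
                   cell_type = df$cell_type[1], criteria = NULL,
                   source = paste0("file:", basename(path)))
}

#' @rdname read_marker_panel
#' @param panel A `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Standard FASTA parsing via Biostrings; the sequence name is the description
#' line truncated at the first whitespace.
#'
#' @param path FASTA path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aas)
  names(seqs) <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Write a QC report to disk
#'
#' Emits a machine-readable pair: `qc_report.json` (full report, versioned
#' schema string, no timestamps, byte-stable across identical inputs) and
#' `qc_samples.tsv` (the per-sample table, stable column order).
#'
#' @param report A `qc_report` from [run_qc()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    schema = "plasmaQC/qc_report/v1",
    parameters = report$parameters,
    per_sample = report$per_sample,
    group_bias = report$group_bias,
    candidate_validation = report$candidate_validation
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                           dataframe = "rows", pretty = TRUE)
  writeLines(json, file.path(dir, "qc_report.json"))
  utils::write.table(report$per_sample, file.path(dir, "qc_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_qc_report
#' @param path Path to a `qc_report.json`.
#' @return `read_qc_report()` returns the parsed report list.
#' @export
read_qc_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!identical(rep$schema, "plasmaQC/qc_report/v1"))
    stop("unrecognized QC report schema: ", rep$schema)
  rep
}
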