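# Derivation of cell-type contamination marker panels from pure-contaminant
# versus pure-plasma measurements: fold-change table, four-criterion filter
# cascade, panel comparison.

#' Default marker filter criteria per cell type
#'
#' The published selection criteria: >1000-fold enrichment for platelets and
#' erythrocytes, >100-fold for PBMCs; a minimum of two precursors per
#' protein; mean contaminant log10 intensity above 7.5 (platelet), 8.2
#' (erythrocyte) or 7.1 (PBMC); replicate CV below 20% (platelet,
#' erythrocyte) or 35% (PBMC); panel truncated to the 30 strongest markers.
#' Proteins detected only in the cellular proteome are aligned at
#' `exclusive_fc_multiplier` times the largest finite fold change.
#'
#' @param cell_type `"platelet"`, `"erythrocyte"` or `"pbmc"`.
#' @param min_fold_change,min_precursors,min_log10_intensity,max_cv,panel_size,exclusive_fc_multiplier
#'   Optional overrides of the per-cell-type defaults.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(cell_type = c("platelet", "erythrocyte", "pbmc"),
                            min_fold_change = NULL, min_precursors = 2,
                            min_log10_intensity = NULL, max_cv = NULL,
                            panel_size = 30, exclusive_fc_multiplier = 1.1) {
  cell_type <- match.arg(cell_type)
  def <- switch(cell_type,
    platelet    = list(fc = 1000, int = 7.5, cv = 0.20),
    erythrocyte = list(fc = 1000, int = 8.2, cv = 0.20),
    pbmc        = list(fc = 100,  int = 7.1, cv = 0.35))
  out <- list(cell_type = cell_type,
              min_fold_change = if (is.null(min_fold_change)) def$fc else min_fold_change,
              min_precursors = min_precursors,
              min_log10_intensity = if (is.null(min_log10_intensity)) def$int else min_log10_intensity,
              max_cv = if (is.null(max_cv)) def$cv else max_cv,
              panel_size = panel_size,
              exclusive_fc_multiplier = exclusive_fc_multiplier)
  if (out$panel_size < 1) stop("panel_size must be >= 1")
  structure(out, class = "filter_criteria")
}

# population-sd coefficient of variation over detected values; NA when
# fewer than 2 detections
.cv_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}

#' Per-protein fold changes between pure contaminant and pure plasma
#'
#' Fold change is the ratio of linear-scale mean intensities over detected
#' replicates. Proteins detected in the contaminant but never in plasma are
#' flagged exclusive and aligned at `exclusive_fc_multiplier` times the
#' largest finite fold change in the table (so they outrank every shared
#' protein); proteins never detected in the contaminant are dropped. The CV
#' is computed from the contaminant replicates on linear intensities
#' (population sd / mean); the precursor count is the maximum across
#' contaminant replicates.
#'
#' @param pure_contaminant,pure_plasma Linear-scale [quant_matrix()]
#'   replicate sets (>= 2 replicates each recommended).
#' @param exclusive_fc_multiplier Alignment multiplier for
#'   contaminant-exclusive proteins (default 1.1).
#' @return Data frame: `protein_id`, `fold_change`, `mean_contaminant`,
#'   `mean_plasma`, `mean_log10_intensity`, `cv`, `precursors`,
#'   `exclusive_flag`.
#' @export
compute_fold_changes <- function(pure_contaminant, pure_plasma,
                                 exclusive_fc_multiplier = 1.1) {
  .assert_linear(pure_contaminant, "compute_fold_changes()")
  .assert_linear(pure_plasma, "compute_fold_changes()")
  universe <- union(protein_ids(pure_contaminant), protein_ids(pure_plasma))
  if (length(intersect(protein_ids(pure_contaminant), protein_ids(pure_plasma))) == 0)
    stop("contaminant and plasma matrices share no proteins")
  if (ncol(pure_contaminant$intensity) < 2)
    warning("single contaminant replicate: CV undefined, CV filter will be disabled")

  row_mean <- function(m, ids) {
    out <- stats::setNames(rep(NA_real_, length(ids)), ids)
    hit <- intersect(ids, rownames(m))
    out[hit] <- rowMeans(m[hit, , drop = FALSE], na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  mc <- row_mean(pure_contaminant$intensity, universe)
  mp <- row_mean(pure_plasma$intensity, universe)
  keep <- !is.na(mc)  # never detected in contaminant -> dropped
  universe <- universe[keep]; mc <- mc[keep]; mp <- mp[keep]

  fc <- mc / mp
  exclusive <- is.na(mp)
  max_finite <- suppressWarnings(max(fc[is.finite(fc)], na.rm = TRUE))
  if (!is.finite(max_finite)) max_finite <- 1
  fc[exclusive] <- exclusive_fc_multiplier * max_finite

  cvs <- apply(pure_contaminant$intensity[
    match(universe, protein_ids(pure_contaminant)), , drop = FALSE], 1, .cv_pop)
  prec <- if (!is.null(pure_contaminant$precursor_counts)) {
    suppressWarnings(apply(pure_contaminant$precursor_counts[
      match(universe, protein_ids(pure_contaminant)), , drop = FALSE],
      1, max, na.rm = TRUE))
  } else rep(NA_real_, length(universe))
  prec[!is.finite(prec)] <- NA_real_

  data.frame(protein_id = universe, fold_change = unname(fc),
             mean_contaminant = unname(mc), mean_plasma = unname(mp),
             mean_log10_intensity = log10(unname(mc)),
             cv = unname(cvs), precursors = unname(prec),
             exclusive_flag = unname(exclusive),
             stringsAsFactors = FALSE, row.names = NULL)
}

new_marker_panel <- function(entries, cell_type, criteria, source) {
  structure(entries, class = c("marker_panel", "data.frame"),
            cell_type = cell_type, criteria = criteria, source = source)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d %s markers (source: %s)\n",
              nrow(x), attr(x, "cell_type"), attr(x, "source")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @rdname select_markers
#' @param panel A `marker_panel`.
#' @export
panel_proteins <- function(panel) as.data.frame(panel)$protein_id

#' Select contamination markers by the four-criterion filter cascade
#'
#' Keeps proteins with fold change above `min_fold_change` AND precursors at
#' least `min_precursors` AND mean contaminant log10 intensity above
#' `min_log10_intensity` AND CV below `max_cv` (a pure conjunction, so the
#' filter order is irrelevant), ranks survivors by fold change descending
#' (ties broken by protein id ascending) and truncates to `panel_size`. If
#' CVs or precursor counts are entirely unavailable the corresponding filter
#' is disabled with a warning. A panel shorter than `panel_size` is emitted
#' short with a warning, never padded.
#'
#' @param fc_table Output of [compute_fold_changes()].
#' @param criteria A [filter_criteria()] (or a cell-type string to use that
#'   type's defaults).
#' @return A `marker_panel`: data frame of `protein_id`, `fold_change`,
#'   `mean_log10_intensity`, `cv`, `exclusive_flag`, `rank`, `cell_type`,
#'   with the criteria attached as an attribute.
#' @export
select_markers <- function(fc_table, criteria = "platelet") {
  if (is.character(criteria)) criteria <- filter_criteria(criteria)
  stopifnot(inherits(criteria, "filter_criteria"))
  tab <- fc_table
  keep <- tab$fold_change > criteria$min_fold_change &
    tab$mean_log10_intensity > criteria$min_log10_intensity
  if (all(is.na(tab$cv))) {
    warning("no CV available (single replicate?): CV filter disabled")
  } else keep <- keep & !is.na(tab$cv) & tab$cv < criteria$max_cv
  if (all(is.na(tab$precursors))) {
    warning("no precursor counts available: precursor filter disabled")
  } else keep <- keep & !is.na(tab$precursors) & tab$precursors >= criteria$min_precursors
  keep[is.na(keep)] <- FALSE
  surv <- tab[keep, , drop = FALSE]
  ord <- order(-surv$fold_change, surv$protein_id)
  surv <- surv[ord, , drop = FALSE]
  if (nrow(surv) < criteria$panel_size)
    warning(sprintf("only %d proteins satisfy all criteria (panel_size %d): emitting short panel",
                    nrow(surv), criteria$panel_size))
  surv <- utils::head(surv, criteria$panel_size)
  entries <- data.frame(protein_id = surv$protein_id,
                        cell_type = rep(criteria$cell_type, nrow(surv)),
                        fold_change = surv$fold_change,
                        rank = seq_len(nrow(surv)),
                        mean_log10_intensity = surv$mean_log10_intensity,
                        cv = surv$cv, exclusive_flag = surv$exclusive_flag,
                        stringsAsFactors = FALSE, row.names = NULL)
  new_marker_panel(entries, cell_type = criteria$cell_type,
                   criteria = criteria, source = "select_markers")
}

#' Compare two marker panels
#'
#' Overlap of the top-`depth` entries of each panel: shared count, Jaccard
#' index, and Spearman rank correlation of the shared proteins' within-panel
#' ranks. Symmetric in its arguments.
#'
#' @param a,b `marker_panel`s of the same cell type.
#' @param depth Comparison depth (default 30); if it exceeds a panel length
#'   the comparison is made at the shorter length, with a note.
#' @return List: `depth_used`, `overlap`, `jaccard`, `rank_correlation`,
#'   `note`.
#' @export
compare_panels <- function(a, b, depth = 30) {
  stopifnot(inherits(a, "marker_panel"), inherits(b, "marker_panel"))
  if (!identical(attr(a, "cell_type"), attr(b, "cell_type")))
    stop("panels are for different cell types")
  note <- NULL
  d <- min(depth, nrow(a), nrow(b))
  if (d < depth) note <- sprintf("depth truncated to %d (shorter panel)", d)
  ta <- utils::head(panel_proteins(a), d)
  tb <- utils::head(panel_proteins(b), d)
  shared <- intersect(ta, tb)
  jac <- if (length(union(ta, tb)) == 0) NA_real_ else
    length(shared) / length(union(ta, tb))
  rc <- if (length(shared) >= 3)
    stats::cor(match(shared, ta), match(shared, tb), method = "spearman")
  else NA_real_
  list(depth_used = d, overlap = length(shared), jaccard = jac,
       rank_correlation = rc, note = note)
}

#' Build a marker panel from a plain id list
#'
#' Wraps an ordered vector of protein ids (e.g. a published panel or a
#' simulator ground-truth marker set) as a `marker_panel` usable by the
#' scoring functions; fold changes are unknown (`NA`).
#'
#' @param ids Ordered character vector of protein ids (strongest first).
#' @param cell_type Cell type label.
#' @param source Provenance string.
#' @return A `marker_panel`.
#' @export
as_marker_panel <- function(ids, cell_type, source = "user") {
  if (anyDuplicated(ids)) stop("panel ids must be unique")
  entries <- data.frame(protein_id = as.character(ids),
                        cell_type = rep(cell_type, length(ids)),
                        fold_change = NA_real_, rank = seq_along(ids),
                        mean_log10_intensity = NA_real_, cv = NA_real_,
                        exclusive_flag = NA, stringsAsFactors = FALSE)
  new_marker_panel(entries, cell_type = cell_type, criteria = NULL, source = source)
}

#' Published top-5 contamination marker gene symbols
#'
#' The study's published top-5 markers per cell type, shipped as reference
#' panels for string matching against gene-symbol-keyed user data.
#'
#' @return Named list of character vectors
#'   (`platelet`, `erythrocyte`, `pbmc`).
#' @export
reference_marker_panels <- function() {
  list(platelet    = c("ACTB", "PFN1", "THBS1", "TPM4", "TLN1"),
       erythrocyte = c("HBB", "HBA1", "HBD", "HBG2", "CA1"),
       pbmc        = c("H4C1", "H2AZ1", "H2BC3", "H2BC14", "RAP1B"))
}
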