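# Per-sample contamination statistics: contamination index, cellular
# enrichment score, contaminant enrichment factor, Z-scored panel summaries.
# All summed-intensity statistics operate on the linear scale and refuse
# log10 views; undefined conditions surface as explicit flags, never as
# NaN/Inf.

#' Contamination index
#'
#' For each sample, the summed linear MS intensity of the panel's marker
#' proteins detected in the sample divided by the summed intensity of all
#' other detected proteins in that sample. Missing values contribute zero to
#' both sums. Markers absent from the matrix's protein universe are ignored
#' (their number is reported). When a sample contains only marker proteins
#' the denominator is zero and the index is flagged undefined rather than
#' returned as infinity.
#'
#' @param m Linear-scale [quant_matrix()].
#' @param panel A `marker_panel` (or character vector of marker ids).
#' @return Data frame: `sample_id`, `cell_type`, `contamination_index`,
#'   `marker_sum`, `other_sum`, `n_markers_detected`, `n_markers_missing_from_matrix`,
#'   `undefined` (logical).
#' @export
contamination_index <- function(m, panel) {
  .assert_linear(m, "contamination_index()")
  ids <- if (inherits(panel, "marker_panel")) panel_proteins(panel) else panel
  if (length(ids) == 0) stop("panel is empty")
  cell_type <- if (inherits(panel, "marker_panel")) attr(panel, "cell_type") else NA_character_
  in_matrix <- ids[ids %in% protein_ids(m)]
  n_absent <- length(ids) - length(in_matrix)
  is_marker <- protein_ids(m) %in% in_matrix
  x <- m$intensity
  marker_sum <- colSums(x[is_marker, , drop = FALSE], na.rm = TRUE)
  other_sum <- colSums(x[!is_marker, , drop = FALSE], na.rm = TRUE)
  n_det <- colSums(!is.na(x[is_marker, , drop = FALSE]))
  undef <- other_sum == 0
  ci <- ifelse(undef, NA_real_, marker_sum / other_sum)
  data.frame(sample_id = sample_ids(m), cell_type = cell_type,
             contamination_index = ci, marker_sum = marker_sum,
             other_sum = other_sum, n_markers_detected = n_det,
             n_markers_missing_from_matrix = n_absent,
             undefined = undef, stringsAsFactors = FALSE, row.names = NULL)
}

#' Top plasma proteins from a reference sample set
#'
#' Ranks proteins of a designated reference (pure plasma) sample set by mean
#' linear intensity, excludes marker proteins, and returns the top `n` ids --
#' the denominator set of the cellular enrichment score.
#'
#' @param reference Linear-scale [quant_matrix()] of reference plasma
#'   samples.
#' @param n Number of proteins (default 30).
#' @param exclude Protein ids (or a `marker_panel`) to exclude.
#' @return Character vector of protein ids, most abundant first.
#' @export
top_plasma_proteins <- function(reference, n = 30, exclude = NULL) {
  .assert_linear(reference, "top_plasma_proteins()")
  if (inherits(exclude, "marker_panel")) exclude <- panel_proteins(exclude)
  mu <- rowMeans(reference$intensity, na.rm = TRUE)
  mu <- mu[!is.nan(mu)]
  mu <- mu[!(names(mu) %in% exclude)]
  names(utils::head(sort(mu, decreasing = TRUE), n))
}

#' Cellular enrichment score
#'
#' Ratio of the summed intensity of the (up to 30) cell-specific marker
#' proteins to the summed intensity of the top-30 most abundant plasma
#' proteins, evaluated within each sample. A sample in which none of the
#' plasma top-30 is detected gets an undefined flag.
#'
#' @param m Linear-scale [quant_matrix()].
#' @param panel `marker_panel` (its top 30 entries are used).
#' @param plasma_top30 Character vector from [top_plasma_proteins()].
#' @return Data frame: `sample_id`, `cell_type`, `enrichment_score`,
#'   `marker_sum`, `plasma_sum`, `undefined`.
#' @export
enrichment_score <- function(m, panel, plasma_top30) {
  .assert_linear(m, "enrichment_score()")
  ids <- if (inherits(panel, "marker_panel")) utils::head(panel_proteins(panel), 30) else panel
  cell_type <- if (inherits(panel, "marker_panel")) attr(panel, "cell_type") else NA_character_
  x <- m$intensity
  msum <- colSums(x[rownames(x) %in% ids, , drop = FALSE], na.rm = TRUE)
  psum <- colSums(x[rownames(x) %in% plasma_top30, , drop = FALSE], na.rm = TRUE)
  undef <- psum == 0
  es <- ifelse(undef, NA_real_, msum / psum)
  data.frame(sample_id = sample_ids(m), cell_type = cell_type,
             enrichment_score = es, marker_sum = msum, plasma_sum = psum,
             undefined = undef, stringsAsFactors = FALSE, row.names = NULL)
}

#' Contaminant enrichment factor
#'
#' Ratio of a sample's contamination index to that of a matched pure-plasma
#' reference measured under the same workflow. With `method = "es"` the
#' enrichment-score ratio is used instead. A zero or undefined reference
#' index yields an undefined flag rather than infinity.
#'
#' @param m Linear-scale [quant_matrix()] containing both samples.
#' @param panel `marker_panel`.
#' @param sample,reference_sample Sample ids.
#' @param method `"ci"` (default) or `"es"`.
#' @param plasma_top30 Required for `method = "es"`.
#' @return List: `factor`, `sample_value`, `reference_value`, `method`,
#'   `undefined`.
#' @export
contaminant_enrichment_factor <- function(m, panel, sample, reference_sample,
                                          method = c("ci", "es"),
                                          plasma_top30 = NULL) {
  method <- match.arg(method)
  sub <- subset_quant(m, samples = unique(c(sample, reference_sample)))
  v <- if (method == "ci") {
    contamination_index(sub, panel)$contamination_index
  } else {
    if (is.null(plasma_top30)) stop("method='es' needs plasma_top30")
    enrichment_score(sub, panel, plasma_top30)$enrichment_score
  }
  vals <- v[match(c(sample, reference_sample), sample_ids(sub))]
  undef <- is.na(vals[2]) || vals[2] == 0 || is.na(vals[1])
  list(factor = if (undef) NA_real_ else vals[1] / vals[2],
       sample_value = vals[1], reference_value = vals[2],
       method = method, undefined = undef)
}

#' Z-scored marker panel intensities
#'
#' Z-scores each of the top `top_n` panel proteins across all samples of a
#' log10-scale matrix (population sd over detected values; a protein with
#' zero sd gets z = 0 wherever detected) and summarizes each sample as the
#' mean z over its detected panel proteins. Proteins detected in fewer than
#' two samples are excluded from the summary with an undefined z.
#'
#' @param m Log10-scale [quant_matrix()] (see [log10_transform()]).
#' @param panel `marker_panel` (or character vector of ids).
#' @param top_n Number of top panel proteins to use (default: all).
#' @return List: `z` (proteins x samples matrix), `sample_mean_z` (named
#'   vector), `proteins_used`, `proteins_excluded`.
#' @export
zscore_panel <- function(m, panel, top_n = NULL) {
  .assert_log(m, "zscore_panel()")
  ids <- if (inherits(panel, "marker_panel")) panel_proteins(panel) else panel
  if (!is.null(top_n)) {
    if (top_n > length(ids)) stop("top_n exceeds panel length")
    ids <- utils::head(ids, top_n)
  }
  ids <- ids[ids %in% protein_ids(m)]
  x <- m$intensity[ids, , drop = FALSE]
  n_det <- rowSums(!is.na(x))
  excluded <- rownames(x)[n_det < 2]
  z <- x * NA_real_
  for (i in which(n_det >= 2)) {
    v <- x[i, ]
    det <- !is.na(v)
    mu <- mean(v[det])
    sd_pop <- sqrt(mean((v[det] - mu)^2))
    z[i, det] <- if (sd_pop == 0) 0 else (v[det] - mu) / sd_pop
  }
  zs <- z[n_det >= 2, , drop = FALSE]
  mean_z <- apply(zs, 2, function(col) {
    det <- !is.na(col)
    if (!any(det)) NA_real_ else mean(col[det])
  })
  list(z = z, sample_mean_z = mean_z,
       proteins_used = rownames(x)[n_det >= 2], proteins_excluded = excluded)
}
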