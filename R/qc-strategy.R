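# The three-step contamination-control strategy for biomarker studies:
# (1) per-sample contamination assessment against a study-specific baseline
#     with robust outlier flagging,
# (2) group-bias detection with nonparametric tests,
# (3) candidate-biomarker validation by correlation against the marker
#     panels and the per-sample contamination index.

#' Step 1: flag contamination outliers against a study baseline
#'
#' The study baseline is the median of `log10(CI + epsilon)` per cell type;
#' a sample is flagged when its value exceeds `median + k * MAD` (MAD with
#' the usual 1.4826 normal-consistency constant; one-sided, since only high
#' contamination is pathological). With fewer than `min_samples` samples the
#' baseline is not meaningful and every flag is `"undefined"`, with a
#' warning. Flags are tri-state: `"pass"`, `"flag"`, `"undefined"`.
#'
#' @param scores Output of [contamination_index()] (one row per sample, one
#'   cell type).
#' @param k MAD multiplier (default 3).
#' @param epsilon Offset guarding `log10(0)` (default 1e-6).
#' @param min_samples Minimum study size for a baseline (default 5).
#' @return List: `per_sample` (data frame with `flag` column), `baseline`
#'   (`median`, `mad`, `threshold` on the log10 scale), `parameters`.
#' @export
assess_samples <- function(scores, k = 3, epsilon = 1e-6, min_samples = 5) {
  ci <- scores$contamination_index
  if (all(is.na(ci))) stop("all contamination indices are undefined")
  lx <- log10(ci + epsilon)
  out <- data.frame(sample_id = scores$sample_id,
                    cell_type = scores$cell_type,
                    contamination_index = ci,
                    log10_ci = lx, stringsAsFactors = FALSE)
  n_ok <- sum(!is.na(ci))
  if (n_ok < min_samples) {
    warning(sprintf("only %d samples with a defined CI (< %d): flags undefined",
                    n_ok, min_samples))
    out$flag <- "undefined"
    baseline <- list(median = NA_real_, mad = NA_real_, threshold = NA_real_)
  } else {
    med <- stats::median(lx, na.rm = TRUE)
    md <- stats::mad(lx, na.rm = TRUE)  # 1.4826 * median abs deviation
    thr <- med + k * md
    out$flag <- ifelse(is.na(lx), "undefined",
                       ifelse(lx > thr, "flag", "pass"))
    baseline <- list(median = med, mad = md, threshold = thr)
  }
  list(per_sample = out, baseline = baseline,
       parameters = list(k = k, epsilon = epsilon, min_samples = min_samples))
}

#' Step 2: detect contamination bias between study groups
#'
#' Two groups: two-sided Mann-Whitney U on the contamination index; more
#' than two: Kruskal-Wallis. Contamination indices are heavy-tailed by
#' nature, hence rank tests. Groups below `min_group_size` make the result
#' undefined with a note. Constant data across all samples yields p = 1 by
#' convention (flagged).
#'
#' @param scores Output of [contamination_index()].
#' @param groups Group label per row of `scores`.
#' @param alpha Flagging level (default 0.05).
#' @param min_group_size Default 3.
#' @return List: `test`, `statistic`, `p_value`, `bias_flag`,
#'   `group_medians`, `direction` (two-group case: the higher-median group),
#'   `note`.
#' @export
detect_group_bias <- function(scores, groups, alpha = 0.05, min_group_size = 3) {
  ci <- scores$contamination_index
  ok <- !is.na(ci) & !is.na(groups)
  ci <- ci[ok]; g <- factor(groups[ok])
  sizes <- table(g)
  if (nlevels(g) < 2 || any(sizes < min_group_size))
    return(list(test = NA_character_, statistic = NA_real_, p_value = NA_real_,
                bias_flag = "undefined", group_medians = tapply(ci, g, stats::median),
                direction = NA_character_,
                note = sprintf("need >= 2 groups with >= %d samples each", min_group_size)))
  meds <- tapply(ci, g, stats::median)
  if (length(unique(ci)) == 1) {
    return(list(test = if (nlevels(g) == 2) "mann-whitney" else "kruskal-wallis",
                statistic = 0, p_value = 1, bias_flag = "pass",
                group_medians = meds, direction = NA_character_,
                note = "constant contamination index: p = 1 by convention"))
  }
  if (nlevels(g) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(ci ~ g, exact = FALSE, correct = TRUE))
    res <- list(test = "mann-whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value)
    res$direction <- names(meds)[which.max(meds)]
  } else {
    kt <- stats::kruskal.test(ci, g)
    res <- list(test = "kruskal-wallis", statistic = unname(kt$statistic),
                p_value = kt$p.value)
    res$direction <- names(meds)[which.max(meds)]
  }
  res$bias_flag <- if (res$p_value < alpha) "flag" else "pass"
  res$group_medians <- meds
  res$note <- NULL
  res[c("test", "statistic", "p_value", "bias_flag", "group_medians",
        "direction", "note")]
}

#' Step 3: correlate candidate biomarkers with contamination markers
#'
#' Spearman correlation (pairwise-complete, at least `min_pairs` paired
#' detections) between each candidate protein and every panel protein across
#' samples, plus the correlation against the per-sample contamination index
#' when supplied. A candidate is flagged as a potential contamination
#' artifact when its maximum absolute correlation against any panel protein,
#' or against the contamination index, reaches `r_threshold`. The full
#' candidate x marker map is retained for reporting. Spearman is the
#' default because monotone association suffices to implicate contamination;
#' `method = "pearson"` is available.
#'
#' @param m Log10-scale [quant_matrix()].
#' @param candidates Character vector of candidate protein ids (must be in
#'   the matrix).
#' @param panels A `marker_panel` or list of panels.
#' @param r_threshold Flagging threshold on |rho| (default 0.7).
#' @param ci Optional per-sample contamination index vector aligned with the
#'   matrix samples (or the data frame from [contamination_index()]).
#' @param min_pairs Minimum paired detections per correlation (default 6).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List: `per_candidate` (data frame with `max_abs_r`, `top_marker`,
#'   `r_vs_ci`, `artifact_flag`), `map` (candidates x markers correlation
#'   matrix), `parameters`.
#' @export
candidate_correlation_map <- function(m, candidates, panels, r_threshold = 0.7,
                                      ci = NULL, min_pairs = 6,
                                      method = c("spearman", "pearson")) {
  .assert_log(m, "candidate_correlation_map()")
  method <- match.arg(method)
  if (inherits(panels, "marker_panel")) panels <- list(panels)
  marker_ids <- unique(unlist(lapply(panels, function(p)
    if (inherits(p, "marker_panel")) panel_proteins(p) else p)))
  marker_ids <- marker_ids[marker_ids %in% protein_ids(m)]
  missing_cand <- setdiff(candidates, protein_ids(m))
  if (length(missing_cand) > 0)
    stop("candidate(s) not in matrix: ", paste(missing_cand, collapse = ", "))
  x <- t(m$intensity[candidates, , drop = FALSE])
  y <- t(m$intensity[marker_ids, , drop = FALSE])

  pair_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_pairs) return(NA_real_)
    suppressWarnings(stats::cor(a[ok], b[ok], method = method))
  }
  map <- matrix(NA_real_, length(candidates), length(marker_ids),
                dimnames = list(candidates, marker_ids))
  for (i in seq_along(candidates))
    for (j in seq_along(marker_ids))
      map[i, j] <- pair_cor(x[, i], y[, j])

  civ <- NULL
  if (!is.null(ci)) {
    civ <- if (is.data.frame(ci)) ci$contamination_index[match(sample_ids(m), ci$sample_id)] else ci
    if (length(civ) != ncol(m$intensity))
      stop("'ci' must provide one value per sample of the matrix")
  }
  per <- data.frame(candidate = candidates,
                    max_abs_r = NA_real_, top_marker = NA_character_,
                    r_vs_ci = NA_real_, artifact_flag = "undefined",
                    stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    row <- map[i, ]
    if (any(!is.na(row))) {
      per$max_abs_r[i] <- max(abs(row), na.rm = TRUE)
      per$top_marker[i] <- marker_ids[which.max(abs(row))]
    }
    if (!is.null(civ)) per$r_vs_ci[i] <- pair_cor(x[, i], civ)
    crit <- c(per$max_abs_r[i], abs(per$r_vs_ci[i]))
    if (any(!is.na(crit)))
      per$artifact_flag[i] <- if (any(crit >= r_threshold, na.rm = TRUE)) "flag" else "pass"
  }
  list(per_candidate = per, map = map,
       parameters = list(r_threshold = r_threshold, min_pairs = min_pairs,
                         method = method))
}

#' Run the full three-step contamination-control strategy
#'
#' Computes per-cell-type contamination indices, flags per-sample outliers
#' (step 1), tests for group bias when a `group` column is present (step 2),
#' and screens candidate biomarkers against the panels (step 3).
#'
#' @param m Linear-scale [quant_matrix()].
#' @param samples Sample metadata (`sample_id`, optional `group`).
#' @param panels Named list of `marker_panel`s (one per cell type).
#' @param candidates Optional candidate protein ids for step 3.
#' @param k MAD multiplier for step 1.
#' @param alpha Significance level for step 2.
#' @param r_threshold Correlation threshold for step 3.
#' @return A `qc_report`: `per_sample`, `group_bias`, `candidate_validation`,
#'   `scores`, `parameters`.
#' @export
run_qc <- function(m, samples, panels, candidates = NULL,
                   k = 3, alpha = 0.05, r_threshold = 0.7) {
  .assert_linear(m, "run_qc()")
  if (inherits(panels, "marker_panel")) panels <- list(panels)
  if (is.null(names(panels)) || any(names(panels) == ""))
    names(panels) <- vapply(panels, function(p) attr(p, "cell_type"), character(1))
  idx <- match(sample_ids(m), samples$sample_id)
  if (anyNA(idx)) stop("matrix contains samples absent from the metadata")
  samples <- samples[idx, , drop = FALSE]

  per_sample <- data.frame(sample_id = sample_ids(m), stringsAsFactors = FALSE)
  scores <- list(); group_bias <- list()
  has_groups <- "group" %in% names(samples) && length(unique(samples$group)) >= 2
  for (ct in names(panels)) {
    sc <- contamination_index(m, panels[[ct]])
    scores[[ct]] <- sc
    asmt <- assess_samples(sc, k = k)
    per_sample[[paste0("ci_", ct)]] <- sc$contamination_index
    per_sample[[paste0("flag_", ct)]] <- asmt$per_sample$flag
    if (has_groups)
      group_bias[[ct]] <- detect_group_bias(sc, samples$group, alpha = alpha)
  }
  candidate_validation <- NULL
  if (!is.null(candidates)) {
    ml <- log10_transform(m)
    ci_first <- scores[[1]]
    candidate_validation <- candidate_correlation_map(
      ml, candidates, panels, r_threshold = r_threshold, ci = ci_first)
  }
  structure(list(per_sample = per_sample, group_bias = group_bias,
                 candidate_validation = candidate_validation, scores = scores,
                 parameters = list(k = k, alpha = alpha, r_threshold = r_threshold,
                                   cell_types = names(panels))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, panels: %s\n", nrow(x$per_sample),
              paste(x$parameters$cell_types, collapse = ", ")))
  for (ct in names(x$group_bias)) {
    gb <- x$group_bias[[ct]]
    cat(sprintf("  group bias [%s]: %s p = %.3g (%s)\n", ct, gb$test,
                gb$p_value, gb$bias_flag))
  }
  if (!is.null(x$candidate_validation)) {
    pc <- x$candidate_validation$per_candidate
    cat(sprintf("  candidates flagged: %d / %d\n",
                sum(pc$artifact_flag == "flag"), nrow(pc)))
  }
  invisible(x)
}
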