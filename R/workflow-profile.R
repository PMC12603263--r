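# Characterization of how a workflow reshapes the plasma proteome relative
# to a neat baseline: rank-abundance shift profiles, enrichment/depletion
# classification, replicate CV distributions, and PCA with KNN imputation.

.mean_profile <- function(m, samples = NULL) {
  if (inherits(m, "quant_matrix")) {
    .assert_linear(m, "rank_shift_profile()")
    x <- if (is.null(samples)) m$intensity else m$intensity[, samples, drop = FALSE]
    mu <- rowMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    mu
  } else m  # already a named mean vector
}

#' Rank-abundance shift profile of a workflow versus the neat baseline
#'
#' Ranks all proteins detected in the neat baseline by mean abundance
#' (descending, ties broken by protein id) and tracks how each protein's
#' signal changes in the alternative workflow: `log10_ratio =
#' log10(other / neat)` where both are detected; proteins detected in only
#' one workflow are classed `neat_only` / `other_only`.
#'
#' @param neat,other Linear-scale [quant_matrix()]s (replicates are averaged)
#'   or named mean-intensity vectors.
#' @param neat_samples,other_samples Optional sample subsets.
#' @return A `shift_profile` data frame: `protein_id`, `neat_rank`,
#'   `neat_intensity`, `other_intensity`, `ratio`, `log10_ratio`, `class`.
#' @export
rank_shift_profile <- function(neat, other, neat_samples = NULL, other_samples = NULL) {
  mn <- .mean_profile(neat, neat_samples)
  mo <- .mean_profile(other, other_samples)
  mn <- mn[!is.na(mn)]; mo <- mo[!is.na(mo)]
  if (length(mn) == 0) stop("neat baseline is empty")
  universe <- union(names(mn), names(mo))
  if (length(intersect(names(mn), names(mo))) == 0)
    warning("neat and other share no detected proteins: only *_only classes")
  ord <- order(-mn, names(mn))
  rank_neat <- stats::setNames(rep(NA_integer_, length(universe)), universe)
  rank_neat[names(mn)[ord]] <- seq_along(mn)
  ni <- stats::setNames(rep(NA_real_, length(universe)), universe)
  ni[names(mn)] <- mn
  oi <- stats::setNames(rep(NA_real_, length(universe)), universe)
  oi[names(mo)] <- mo
  ratio <- oi / ni
  cls <- ifelse(is.na(ni), "other_only", ifelse(is.na(oi), "neat_only", "neither"))
  out <- data.frame(protein_id = universe, neat_rank = unname(rank_neat),
                    neat_intensity = unname(ni), other_intensity = unname(oi),
                    ratio = unname(ratio), log10_ratio = log10(unname(ratio)),
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$neat_rank, out$protein_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shift_profile", "data.frame")
  out
}

#' Classify strongly enriched and depleted proteins
#'
#' A protein differing by at least `threshold_fraction` (default 80%) from
#' the neat baseline is classed `enriched` (ratio >= 1 + threshold, i.e.
#' >= 1.8) or `depleted` (ratio <= 1 - threshold, i.e. <= 0.2); otherwise
#' `neither`. The literal percent-difference reading; an absolute log2
#' fold-change cutoff is available via `mode = "log2"` (enriched if
#' |log2 ratio| >= `log2_cutoff` on the up side, etc.).
#'
#' @param profile A `shift_profile`.
#' @param threshold_fraction Fraction in (0, 1), default 0.8.
#' @param mode `"ratio"` (default, the percent reading) or `"log2"`.
#' @param log2_cutoff Cutoff for `mode = "log2"` (default 1).
#' @return The profile with its `class` column updated for proteins
#'   quantified in both workflows (`*_only` classes are preserved).
#' @export
classify_enriched_depleted <- function(profile, threshold_fraction = 0.8,
                                       mode = c("ratio", "log2"), log2_cutoff = 1) {
  mode <- match.arg(mode)
  if (mode == "ratio" && !(threshold_fraction > 0 && threshold_fraction < 1))
    stop("threshold_fraction must be in (0, 1)")
  both <- !is.na(profile$ratio)
  r <- profile$ratio[both]
  cls <- if (mode == "ratio") {
    # small tolerance keeps boundary ratios (e.g. exactly 1.8 / 0.2) inside
    # their classes despite floating-point representation of the thresholds
    eps <- 1e-9
    ifelse(r >= 1 + threshold_fraction - eps, "enriched",
           ifelse(r <= 1 - threshold_fraction + eps, "depleted", "neither"))
  } else {
    l2 <- log2(r)
    ifelse(l2 >= log2_cutoff, "enriched", ifelse(l2 <= -log2_cutoff, "depleted", "neither"))
  }
  profile$class[both] <- cls
  profile
}

#' Compare physicochemical properties of enriched versus depleted proteins
#'
#' Welch two-sided t-test per property (molecular weight, length,
#' isoelectric point, GRAVY, aromaticity, instability index), returning the
#' t statistic, p value, `-log10 p` and the direction of the mean
#' difference -- the heatmap-ready per-workflow row. Properties with fewer
#' than `min_n` proteins on either side are undefined. Zero variance on both
#' sides with equal means yields p = 1 by convention (flagged).
#'
#' @param enriched,depleted Data frames of [sequence_properties()] rows (or
#'   any data frame sharing the property columns).
#' @param properties Property columns to test.
#' @param min_n Minimum set size per side (default 3).
#' @return Data frame: `property`, `t`, `p`, `neg_log10_p`,
#'   `mean_enriched`, `mean_depleted`, `direction`, `note`.
#' @export
property_enrichment_tests <- function(enriched, depleted,
                                      properties = c("molecular_weight", "length",
                                                     "isoelectric_point", "gravy",
                                                     "aromaticity", "instability_index"),
                                      min_n = 3) {
  res <- lapply(properties, function(p) {
    a <- enriched[[p]]; b <- depleted[[p]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    row <- data.frame(property = p, t = NA_real_, p = NA_real_,
                      neg_log10_p = NA_real_,
                      mean_enriched = if (length(a)) mean(a) else NA_real_,
                      mean_depleted = if (length(b)) mean(b) else NA_real_,
                      direction = NA_character_, note = NA_character_,
                      stringsAsFactors = FALSE)
    if (length(a) < min_n || length(b) < min_n) {
      row$note <- sprintf("undefined: need >= %d proteins per side", min_n)
      return(row)
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) {
        row$t <- 0; row$p <- 1; row$neg_log10_p <- 0
        row$direction <- "none"
        row$note <- "zero variance both sides, equal means: p = 1 by convention"
      } else {
        row$t <- sign(mean(a) - mean(b)) * Inf; row$p <- 0; row$neg_log10_p <- Inf
        row$direction <- if (mean(a) > mean(b)) "higher_in_enriched" else "lower_in_enriched"
        row$note <- "zero variance both sides, unequal means"
      }
      return(row)
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    row$t <- unname(tt$statistic); row$p <- tt$p.value
    row$neg_log10_p <- -log10(tt$p.value)
    row$direction <- if (mean(a) > mean(b)) "higher_in_enriched" else
      if (mean(a) < mean(b)) "lower_in_enriched" else "none"
    row
  })
  do.call(rbind, res)
}

#' Per-protein replicate coefficients of variation
#'
#' CV = population sd / mean on linear intensities over detected replicates;
#' proteins detected in fewer than two replicates of a group are excluded
#' from that group. Summaries report the median and quartiles per group.
#'
#' @param m Linear-scale [quant_matrix()].
#' @param replicate_groups Named list mapping group label to sample ids (or
#'   a factor/vector aligned with the samples).
#' @return List: `cv` (data frame protein x group, long format), `summary`
#'   (per-group median and quartiles).
#' @export
replicate_cv <- function(m, replicate_groups) {
  .assert_linear(m, "replicate_cv()")
  if (!is.list(replicate_groups)) {
    if (length(replicate_groups) != ncol(m$intensity))
      stop("grouping vector must align with samples")
    replicate_groups <- split(sample_ids(m), replicate_groups)
  }
  if (any(lengths(replicate_groups) < 2)) stop("every group needs >= 2 replicates")
  rows <- list(); summ <- list()
  for (g in names(replicate_groups)) {
    x <- m$intensity[, replicate_groups[[g]], drop = FALSE]
    cvs <- apply(x, 1, .cv_pop)
    cvs <- cvs[!is.na(cvs)]
    if (length(cvs) == 0) next
    rows[[g]] <- data.frame(group = g, protein_id = names(cvs), cv = unname(cvs),
                            stringsAsFactors = FALSE)
    qs <- stats::quantile(cvs, c(0.25, 0.5, 0.75), names = FALSE)
    summ[[g]] <- data.frame(group = g, n_proteins = length(cvs),
                            q1 = qs[1], median_cv = qs[2], q3 = qs[3],
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no group has proteins detected in >= 2 replicates")
  list(cv = do.call(rbind, c(rows, make.row.names = FALSE)),
       summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

# impute one sample's missing proteins from its k nearest samples (Euclidean
# distance over mutually detected proteins, scaled to a common dimension)
.knn_impute <- function(x, k) {
  ns <- ncol(x)
  if (k >= ns) stop("k must be smaller than the number of samples")
  d <- matrix(Inf, ns, ns)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    if (any(ok))
      d[i, j] <- d[j, i] <- sqrt(mean((x[ok, i] - x[ok, j])^2))
  }
  out <- x
  for (j in seq_len(ns)) {
    miss <- which(is.na(x[, j]))
    if (length(miss) == 0) next
    ord <- order(d[, j])
    ord <- ord[ord != j]
    for (i in miss) {
      donors <- ord[!is.na(x[i, ord])]
      use <- utils::head(donors, k)
      out[i, j] <- if (length(use) > 0) mean(x[i, use])
      else mean(x[i, ], na.rm = TRUE)  # protein mean fallback
    }
  }
  out
}

#' PCA with K-nearest-neighbour imputation
#'
#' Completes the matrix by KNN imputation in sample space (a sample's
#' missing protein is the mean of that protein in the `k` nearest samples by
#' Euclidean distance over mutually detected proteins; default k = 3),
#' drops proteins detected in fewer than two samples beforehand, then runs
#' column-centred PCA via SVD on the samples x proteins matrix. On a
#' complete matrix the imputation is the identity.
#'
#' @param m Log10-scale [quant_matrix()].
#' @param k_neighbors Number of neighbours (default 3; must be < n samples).
#' @return List: `scores` (samples x PC), `loadings` (proteins x PC),
#'   `variance_fraction` (per component), `imputed` (the completed
#'   log10-scale [quant_matrix()]).
#' @export
pca_with_imputation <- function(m, k_neighbors = 3) {
  .assert_log(m, "pca_with_imputation()")
  ns <- ncol(m$intensity)
  if (ns < 3) stop("need >= 3 samples")
  if (k_neighbors >= ns) stop("k_neighbors must be smaller than the number of samples")
  keep <- rowSums(!is.na(m$intensity)) >= 2
  x <- m$intensity[keep, , drop = FALSE]
  xi <- .knn_impute(x, k_neighbors)
  if (anyNA(xi)) stop("imputation left missing values (a protein with no donors)")
  sm <- t(xi)                       # samples x proteins
  sm <- scale(sm, center = TRUE, scale = FALSE)
  sv <- svd(sm)
  ncomp <- sum(sv$d > sv$d[1] * 1e-12)
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(sv$d[seq_len(ncomp)], ncomp)
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  dimnames(loadings) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  varfrac <- sv$d[seq_len(ncomp)]^2 / sum(sv$d^2)
  list(scores = scores, loadings = loadings, variance_fraction = varfrac,
       imputed = quant_matrix(xi, log_scale = TRUE))
}
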