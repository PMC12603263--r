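# Dose-response modelling of contamination index versus spiked cell count:
# ordinary least squares on the raw scale (linear model) and on the log-log
# scale (power law), with raw-scale model comparison.

new_dose_response_fit <- function(model, params, r2, n_points, pearson_r = NA_real_,
                                  n_dropped = 0L, flags = character(0)) {
  structure(list(model = model, params = params, r2 = r2, n_points = n_points,
                 pearson_r = pearson_r, n_dropped = n_dropped, flags = flags),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  p <- paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)), collapse = ", ")
  cat(sprintf("dose_response_fit [%s]: %s; r2 = %.4f (n = %d)\n",
              x$model, p, x$r2, x$n_points))
  invisible(x)
}

.finite_pairs <- function(counts, cis) {
  ok <- is.finite(counts) & is.finite(cis)
  list(x = counts[ok], y = cis[ok], dropped = sum(!ok))
}

#' Fit a linear contamination dose-response model
#'
#' Ordinary least squares `CI = m * count + c`. Reports the slope, intercept,
#' raw-scale r-squared and the Pearson correlation. With zero variance in CI
#' the slope is 0 and r2 is reported as 0 with a `"zero_variance_response"`
#' flag (r-squared is undefined when total variance is zero).
#'
#' @param counts Spiked cell counts (cells per uL).
#' @param cis Contamination indices (same length).
#' @return A `dose_response_fit` with `params$m`, `params$c`.
#' @export
fit_linear <- function(counts, cis) {
  p <- .finite_pairs(counts, cis)
  if (length(p$x) < 3) stop("need >= 3 finite (count, CI) pairs")
  if (stats::var(p$x) == 0) stop("zero variance in counts: slope undefined")
  fit <- stats::lm.fit(cbind(intercept = 1, count = p$x), p$y)
  m <- unname(fit$coefficients["count"])
  c0 <- unname(fit$coefficients["intercept"])
  ss_tot <- sum((p$y - mean(p$y))^2)
  flags <- character(0)
  if (ss_tot == 0) {
    r2 <- 0
    flags <- "zero_variance_response"
    pr <- NA_real_
  } else {
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    pr <- stats::cor(p$x, p$y)
  }
  new_dose_response_fit("linear", list(m = m, c = c0), r2, length(p$x),
                        pearson_r = pr, n_dropped = p$dropped, flags = flags)
}

#' Fit a power-law contamination dose-response model
#'
#' Least squares on `log10 CI = log10 a + b * log10 count`, back-transforming
#' the prefactor. Pairs with nonpositive count or CI cannot enter a log-log
#' fit and are dropped (their number is reported). The r-squared is on the
#' log-log fitting scale; the Pearson correlation is reported on that scale
#' too.
#'
#' @inheritParams fit_linear
#' @return A `dose_response_fit` with `params$a` (prefactor) and `params$b`
#'   (exponent).
#' @export
fit_power_law <- function(counts, cis) {
  p <- .finite_pairs(counts, cis)
  pos <- p$x > 0 & p$y > 0
  dropped <- p$dropped + sum(!pos)
  x <- log10(p$x[pos]); y <- log10(p$y[pos])
  if (length(x) < 3) stop("need >= 3 strictly positive (count, CI) pairs for a power-law fit")
  if (stats::var(x) == 0) stop("zero variance in counts: exponent undefined")
  fit <- stats::lm.fit(cbind(intercept = 1, logc = x), y)
  b <- unname(fit$coefficients["logc"])
  a <- 10^unname(fit$coefficients["intercept"])
  ss_tot <- sum((y - mean(y))^2)
  flags <- character(0)
  if (ss_tot == 0) { r2 <- 0; flags <- "zero_variance_response"; pr <- NA_real_ }
  else { r2 <- 1 - sum(fit$residuals^2) / ss_tot; pr <- stats::cor(x, y) }
  new_dose_response_fit("power", list(a = a, b = b), r2, length(x),
                        pearson_r = pr, n_dropped = dropped, flags = flags)
}

# Gaussian small-sample AIC from a residual sum of squares; k counts the
# mean-model parameters plus one for sigma
.aicc <- function(rss, n, k) {
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' Compare linear and power-law dose-response models
#'
#' Fits both models to the shared subset of strictly positive pairs (the
#' only points a power law can describe) and compares them on identical
#' points under the multiplicative-error model that governs replicate noise
#' in MS intensities: residual sums of squares of `log10(observed) -
#' log10(predicted)`, with small-sample AIC (AICc) as the reported criterion
#' and tie-break. A linear fit that predicts a nonpositive index at an
#' observed positive point cannot generate the data under multiplicative
#' error and loses the comparison outright. Raw-scale RSS values are also
#' reported for reference. If one fit fails the comparison degrades to the
#' surviving model with a warning.
#'
#' @inheritParams fit_linear
#' @return List: `preferred` (`"linear"` or `"power"`), `linear`, `power`
#'   (the two fits), `rss_linear`, `rss_power` (log-scale comparison RSS),
#'   `raw_rss_linear`, `raw_rss_power`, `aicc_linear`, `aicc_power`,
#'   `margin` (AICc difference in favour of the preferred model),
#'   `n_points`.
#' @export
compare_models <- function(counts, cis) {
  p <- .finite_pairs(counts, cis)
  pos <- p$x > 0 & p$y > 0
  x <- p$x[pos]; y <- p$y[pos]
  lin <- tryCatch(fit_linear(x, y), error = function(e) e)
  pow <- tryCatch(fit_power_law(x, y), error = function(e) e)
  if (inherits(lin, "error") && inherits(pow, "error"))
    stop("both fits failed: ", conditionMessage(lin))
  if (inherits(lin, "error") || inherits(pow, "error")) {
    surv <- if (inherits(lin, "error")) pow else lin
    warning("one model fit failed; comparison degrades to the ", surv$model, " model")
    return(list(preferred = surv$model,
                linear = if (inherits(lin, "error")) NULL else lin,
                power = if (inherits(pow, "error")) NULL else pow,
                rss_linear = NA_real_, rss_power = NA_real_,
                aicc_linear = NA_real_, aicc_power = NA_real_,
                margin = NA_real_, n_points = length(x)))
  }
  n <- length(x)
  pred_lin <- lin$params$m * x + lin$params$c
  pred_pow <- lin_pow_pred(pow, x)
  raw_rss_lin <- sum((y - pred_lin)^2)
  raw_rss_pow <- sum((y - pred_pow)^2)
  rss_lin <- if (any(pred_lin <= 0)) Inf else sum((log10(y) - log10(pred_lin))^2)
  rss_pow <- sum((log10(y) - log10(pred_pow))^2)
  aicc_lin <- if (is.finite(rss_lin)) .aicc(max(rss_lin, 1e-300), n, 3) else Inf
  aicc_pow <- .aicc(max(rss_pow, 1e-300), n, 3)
  preferred <- if (rss_lin < rss_pow) "linear"
  else if (rss_pow < rss_lin) "power"
  else if (aicc_lin <= aicc_pow) "linear" else "power"
  list(preferred = preferred, linear = lin, power = pow,
       rss_linear = rss_lin, rss_power = rss_pow,
       raw_rss_linear = raw_rss_lin, raw_rss_power = raw_rss_pow,
       aicc_linear = aicc_lin, aicc_power = aicc_pow,
       margin = abs(aicc_lin - aicc_pow), n_points = n)
}

lin_pow_pred <- function(fit, counts) fit$params$a * counts ^ fit$params$b

#' Fit dose-response models to a scored dilution series
#'
#' Joins per-sample contamination indices to their spiked cell counts and
#' fits the requested model(s). Quadruplicates enter as individual points by
#' default; `aggregate_replicates = "mean"` averages the CI over replicates
#' of the same count first.
#'
#' @param scores Output of [contamination_index()].
#' @param samples Sample metadata with `sample_id` and `cell_count`.
#' @param model `"both"` (default), `"linear"` or `"power"`.
#' @param aggregate_replicates `"none"` or `"mean"`.
#' @return For `"both"`, the [compare_models()] result; otherwise the single
#'   fit.
#' @export
fit_dose_response <- function(scores, samples, model = c("both", "linear", "power"),
                              aggregate_replicates = c("none", "mean")) {
  model <- match.arg(model)
  aggregate_replicates <- match.arg(aggregate_replicates)
  idx <- match(scores$sample_id, samples$sample_id)
  if (anyNA(idx)) stop("scores contain sample ids absent from the metadata")
  counts <- samples$cell_count[idx]
  cis <- scores$contamination_index
  if (aggregate_replicates == "mean") {
    agg <- tapply(cis, counts, mean, na.rm = TRUE)
    counts <- as.numeric(names(agg)); cis <- as.numeric(agg)
  }
  switch(model,
         both = compare_models(counts, cis),
         linear = fit_linear(counts, cis),
         power = fit_power_law(counts, cis))
}
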