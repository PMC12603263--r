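#' Protein-group quantification matrix
#'
#' The universal currency of the pipeline: a proteins x samples table of
#' linear-scale MS intensities with an explicit missing marker (`NA`), plus
#' optional per-protein-per-sample precursor counts. Intensities are always
#' stored on the linear scale; [log10_transform()] returns a view that is
#' explicitly tagged as log-scale so that sum-based metrics can refuse it.
#'
#' @param intensity Numeric matrix (proteins in rows, samples in columns) with
#'   unique row and column names. `NA` marks missing; present values must be
#'   nonnegative (linear scale).
#' @param precursor_counts Optional integer matrix of the same shape (or a
#'   per-protein vector) of precursor counts supporting each quantification.
#' @param log_scale Logical; `TRUE` only for views produced by
#'   [log10_transform()]. User code should not set this.
#'
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(intensity, precursor_counts = NULL, log_scale = FALSE) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("'intensity' must be a numeric matrix (proteins x samples)")
  pid <- rownames(intensity)
  sid <- colnames(intensity)
  if (is.null(pid) || is.null(sid))
    stop("'intensity' must carry protein ids as rownames and sample ids as colnames")
  if (anyDuplicated(pid))
    stop("duplicate protein ids: ", paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!log_scale && any(intensity < 0, na.rm = TRUE))
    stop("negative intensities are not allowed on the linear scale")
  if (!is.null(precursor_counts)) {
    if (is.vector(precursor_counts)) {
      if (length(precursor_counts) != nrow(intensity))
        stop("per-protein 'precursor_counts' must have one entry per protein")
      precursor_counts <- matrix(precursor_counts, nrow = nrow(intensity),
                                 ncol = ncol(intensity),
                                 dimnames = dimnames(intensity))
    }
    if (!all(dim(precursor_counts) == dim(intensity)))
      stop("'precursor_counts' must match the intensity matrix shape")
    dimnames(precursor_counts) <- dimnames(intensity)
  }
  structure(list(intensity = intensity, precursor_counts = precursor_counts,
                 log_scale = isTRUE(log_scale)),
            class = "quant_matrix")
}

#' @export
dim.quant_matrix <- function(x) dim(x$intensity)

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteins x %d samples (%s scale, %.1f%% missing)\n",
              nrow(x$intensity), ncol(x$intensity),
              if (x$log_scale) "log10" else "linear",
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @rdname quant_matrix
#' @param x A `quant_matrix`.
#' @export
protein_ids <- function(x) rownames(x$intensity)

#' @rdname quant_matrix
#' @export
sample_ids <- function(x) colnames(x$intensity)

#' @rdname quant_matrix
#' @export
intensities <- function(x) x$intensity

#' @rdname quant_matrix
#' @export
is_log_scale <- function(x) isTRUE(x$log_scale)

# guard used by every sum-based metric: summed MS intensity is a linear-scale
# quantity, so log-scale views are rejected loudly rather than silently summed
.assert_linear <- function(x, what) {
  if (!inherits(x, "quant_matrix")) stop(what, " requires a quant_matrix")
  if (is_log_scale(x))
    stop(what, " operates on linear-scale intensities; got a log10-scale view. ",
         "Pass the matrix before log10_transform().")
  invisible(TRUE)
}

.assert_log <- function(x, what) {
  if (!inherits(x, "quant_matrix")) stop(what, " requires a quant_matrix")
  if (!is_log_scale(x))
    stop(what, " requires a log10-scale view; apply log10_transform() first.")
  invisible(TRUE)
}

#' Log10-transform a quantification matrix
#'
#' Returns an explicitly log-scale view. Missing values stay missing. Present
#' zero or negative values are an error: DIA software conflates zeros with
#' missingness, so zeros must be mapped to `NA` at read time (the default of
#' [read_quant_matrix()]) before transforming.
#'
#' @param m A linear-scale `quant_matrix`.
#' @return A `quant_matrix` with `log_scale = TRUE`.
#' @export
log10_transform <- function(m) {
  .assert_linear(m, "log10_transform()")
  bad <- which(!is.na(m$intensity) & m$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive present value at protein '%s', sample '%s'; treat zeros as missing first",
                 rownames(m$intensity)[bad[1, 1]], colnames(m$intensity)[bad[1, 2]]))
  out <- m
  out$intensity <- log10(m$intensity)
  out$log_scale <- TRUE
  out
}

#' Subset a quant_matrix by proteins and/or samples
#'
#' @param x A `quant_matrix`.
#' @param proteins,samples Character vectors of ids (or logical/integer
#'   indices); `NULL` keeps everything.
#' @return A `quant_matrix`.
#' @export
subset_quant <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "quant_matrix"))
  pi <- if (is.null(proteins)) seq_len(nrow(x$intensity)) else proteins
  si <- if (is.null(samples)) seq_len(ncol(x$intensity)) else samples
  quant_matrix(x$intensity[pi, si, drop = FALSE],
               precursor_counts = if (!is.null(x$precursor_counts))
                 x$precursor_counts[pi, si, drop = FALSE],
               log_scale = x$log_scale)
}
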