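# Synthetic plasma + cellular spike-in generator.
#
# The generator states a world calibrated to well-established facts about
# blood: ~70 ug total protein per uL of plasma, the 20 most abundant plasma
# proteins carrying ~99% of protein mass, and per-cell protein mass
# proportional to cell volume (platelet ~10 fL, erythrocyte ~90 fL,
# PBMC ~250 fL). All randomness is driven by one explicit integer seed per
# call; the caller's RNG state is preserved.

.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# flatten a positive shape vector v (order-preserving power transform v^t,
# t in (0,1]) until max(v)/sum(v) <= target_max_share; used to bound the
# brightest protein of a block without disturbing its total mass
.flatten_to_max_share <- function(v, target_max_share) {
  share <- function(t) { w <- v^t; max(w) / sum(w) }
  if (share(1) <= target_max_share) return(v / sum(v))
  if (1 / length(v) > target_max_share)
    stop("unattainable shape: even a flat block exceeds the requested max share")
  t <- stats::uniroot(function(t) share(t) - target_max_share,
                      lower = 0, upper = 1, tol = 1e-12)$root
  w <- v^t
  w / sum(w)
}

#' Generate a synthetic plasma proteome
#'
#' Per-protein relative mass is drawn log-normally (log10 sd `sd_log10`),
#' sorted descending, and the 20-protein head block is deterministically
#' rescaled so it carries exactly `top20_mass_target` of the total mass -- the
#' defining dynamic-range feature of plasma. Protein ids are `PLS00001...`
#' in descending abundance order.
#'
#' @param n_proteins Number of protein groups (>= 30).
#' @param top20_mass_target Mass fraction carried by the 20 most abundant
#'   proteins (default 0.99).
#' @param seed Integer seed.
#' @param sd_log10 Log10-scale sd of the rank-abundance law (default 1.5).
#' @param mass_per_uL Total plasma protein mass per microlitre, in picograms
#'   (default 7e7 pg = 70 ug, the physiological plasma protein concentration).
#' @return A `plasma_model`: list with `abundance` (named, sums to 1),
#'   `n_proteins`, `rank_shape`, `mass_per_uL`, `seed`.
#' @export
generate_plasma_proteome <- function(n_proteins = 1000, top20_mass_target = 0.99,
                                     seed = 1, sd_log10 = 1.5, mass_per_uL = 7e7) {
  if (n_proteins < 30) stop("n_proteins must be >= 30")
  if (!(top20_mass_target > 0 && top20_mass_target < 1))
    stop("unattainable top20_mass_target: must be strictly inside (0, 1)")
  ab <- .with_seed(seed, {
    v <- sort(10^stats::rnorm(n_proteins, 0, sd_log10), decreasing = TRUE)
    head20 <- v[1:20] / sum(v[1:20]) * top20_mass_target
    tail <- v[-(1:20)] / sum(v[-(1:20)]) * (1 - top20_mass_target)
    # keep the head/tail boundary monotone in the head-dominant regime by
    # bounding the brightest tail protein below the dimmest head protein
    if (max(tail) >= min(head20) && top20_mass_target >= 20 / n_proteins) {
      target <- 0.99 * min(head20) / (1 - top20_mass_target)
      if (target >= 1 / length(tail))
        tail <- .flatten_to_max_share(tail, target) * (1 - top20_mass_target)
    }
    c(head20, tail)
  })
  ab <- ab / sum(ab)
  names(ab) <- sprintf("PLS%05d", seq_len(n_proteins))
  structure(list(n_proteins = n_proteins, abundance = ab,
                 rank_shape = list(mean_log10 = 0, sd_log10 = sd_log10,
                                   top20_mass_target = top20_mass_target),
                 mass_per_uL = mass_per_uL, seed = seed),
            class = "plasma_model")
}

.cell_defaults <- list(
  platelet    = list(prefix = "PLT", volume_fL = 10,  marker_mass_fraction = 0.5),
  erythrocyte = list(prefix = "ERY", volume_fL = 90,  marker_mass_fraction = 0.9),
  pbmc        = list(prefix = "PBM", volume_fL = 250, marker_mass_fraction = 0.5)
)

#' Generate a synthetic contaminant cell proteome
#'
#' Builds a blood-cell proteome with three compartments: `n_markers`
#' designated cell-exclusive marker proteins (the most abundant cellular
#' proteins, carrying `marker_mass_fraction` of cell protein mass and
#' separated from the rest by an abundance gap), exclusive non-marker
#' proteins, and -- when a `plasma` model is supplied -- a shared compartment
#' of low-abundance plasma proteins that the cell also expresses (the trace
#' cellular leakage present in real plasma, which is what gives realistic
#' finite fold changes in marker derivation). The erythrocyte model
#' additionally concentrates `top5_mass_fraction` of total mass in its 5
#' dominant proteins, mimicking the hemoglobins.
#'
#' @param cell_type One of `"platelet"`, `"erythrocyte"`, `"pbmc"`.
#' @param n_proteins Total protein groups in the cell proteome.
#' @param n_markers Number of designated exclusive markers (default 50).
#' @param per_cell_protein_mass Protein mass per cell in pg; default
#'   0.25 pg/fL times the cell volume (10/90/250 fL), i.e. 2.5/22.5/62.5 pg.
#' @param seed Integer seed.
#' @param plasma Optional `plasma_model` supplying the shared compartment.
#' @param marker_mass_fraction Mass share of the marker block (default 0.5;
#'   0.9 for erythrocytes so the hemoglobin-like head fits inside it).
#' @param marker_sd,tail_sd Log10 sd of abundance within the marker block and
#'   the non-marker tail.
#' @param gap Minimum abundance ratio between the dimmest marker and the
#'   brightest non-marker protein (default 10).
#' @param top5_mass_fraction Erythrocytes only: mass share of the 5 dominant
#'   proteins (default 0.8).
#' @param shared_fraction Fraction of non-marker proteins shared with plasma
#'   when `plasma` is given (default 0.3).
#' @return A `cell_proteome_model`.
#' @export
generate_cell_proteome <- function(cell_type, n_proteins = 6000, n_markers = 50,
                                   per_cell_protein_mass = NULL, seed = 1,
                                   plasma = NULL, marker_mass_fraction = NULL,
                                   marker_sd = 0.25, tail_sd = 1.2, gap = 10,
                                   top5_mass_fraction = 0.8, shared_fraction = 0.3) {
  if (!cell_type %in% names(.cell_defaults))
    stop("unknown cell_type '", cell_type, "'; must be one of ",
         paste(names(.cell_defaults), collapse = ", "))
  if (n_markers > n_proteins) stop("n_markers must be <= n_proteins")
  def <- .cell_defaults[[cell_type]]
  if (is.null(per_cell_protein_mass)) per_cell_protein_mass <- 0.25 * def$volume_fL
  if (per_cell_protein_mass <= 0) stop("per_cell_protein_mass must be > 0")
  if (is.null(marker_mass_fraction)) marker_mass_fraction <- def$marker_mass_fraction

  out <- .with_seed(seed, {
    u <- sort(10^stats::rnorm(n_markers, 0, marker_sd), decreasing = TRUE)
    u <- u / sum(u)
    if (cell_type == "erythrocyte" && n_markers > 5) {
      # concentrate hemoglobin-like mass in the 5 dominant markers
      t5 <- min(top5_mass_fraction / marker_mass_fraction, 0.98)
      u <- c(u[1:5] / sum(u[1:5]) * t5, u[-(1:5)] / sum(u[-(1:5)]) * (1 - t5))
    }
    n_tail <- n_proteins - n_markers
    w <- if (n_tail > 0) {
      w0 <- sort(10^stats::rnorm(n_tail, 0, tail_sd), decreasing = TRUE)
      w0 <- w0 / sum(w0)
      # enforce the marker/non-marker abundance gap without moving block masses
      cap <- marker_mass_fraction * min(u) / (gap * (1 - marker_mass_fraction))
      cap <- max(cap, 1 / n_tail)  # a flat tail is the best achievable
      if (max(w0) > cap) w0 <- .flatten_to_max_share(w0, cap)
      w0
    } else numeric(0)
    ab <- c(marker_mass_fraction * u,
            if (n_tail > 0) (1 - marker_mass_fraction) * w else numeric(0))
    ab <- ab / sum(ab)

    marker_ids <- sprintf("%s.M%03d", def$prefix, seq_len(n_markers))
    tail_ids <- if (n_tail > 0) sprintf("%s.P%05d", def$prefix, seq_len(n_tail)) else character(0)
    shared_ids <- character(0)
    if (!is.null(plasma) && n_tail > 0 && shared_fraction > 0) {
      # shared compartment: the cell also expresses some of the dim half of
      # the plasma proteome (trace leakage proteins)
      dim_half <- names(plasma$abundance)[(plasma$n_proteins %/% 2 + 1):plasma$n_proteins]
      n_shared <- min(round(shared_fraction * n_tail), length(dim_half))
      shared_ids <- sort(sample(dim_half, n_shared))
      tail_ids[seq_len(n_shared)] <- shared_ids  # brightest tail slots
    }
    names(ab) <- c(marker_ids, tail_ids)
    list(abundance = ab, marker_ids = marker_ids, shared_ids = shared_ids)
  })
  structure(list(cell_type = cell_type, n_proteins = n_proteins,
                 abundance = out$abundance, per_cell_protein_mass = per_cell_protein_mass,
                 marker_ids = out$marker_ids, shared_ids = out$shared_ids,
                 seed = seed),
            class = "cell_proteome_model")
}

#' Simulate a spike-in series
#'
#' Mixes defined cell counts into plasma: the true per-protein mass of a
#' sample is `plasma_mass_per_uL * plasma abundance` plus, for each spiked
#' cell type, `count * per_cell_protein_mass * cell abundance`. Supports
#' multi-cell-type mixtures.
#'
#' @param plasma A `plasma_model`.
#' @param cells A list of `cell_proteome_model`s (distinct cell types).
#' @param design Data frame with a `sample_id` column and one nonnegative
#'   count column (cells per uL) per cell type in `cells`.
#' @param plasma_mass_per_uL Plasma protein mass per uL in pg; defaults to
#'   `plasma$mass_per_uL`.
#' @return A `spikein_truth`: true mixture matrix (proteins x samples, pg),
#'   per-component masses, the design, the true marker sets and the models.
#' @export
simulate_spikein_series <- function(plasma, cells, design,
                                    plasma_mass_per_uL = plasma$mass_per_uL) {
  stopifnot(inherits(plasma, "plasma_model"))
  if (inherits(cells, "cell_proteome_model")) cells <- list(cells)
  types <- vapply(cells, `[[`, character(1), "cell_type")
  if (anyDuplicated(types)) stop("cell types in 'cells' must be distinct")
  names(cells) <- types
  if (!"sample_id" %in% names(design)) stop("design needs a 'sample_id' column")
  missing_cols <- setdiff(types, names(design))
  if (length(missing_cols) > 0)
    stop("design lacks count column(s): ", paste(missing_cols, collapse = ", "))
  for (ct in types) if (any(design[[ct]] < 0, na.rm = TRUE))
    stop("negative cell count for ", ct)

  universe <- names(plasma$abundance)
  for (cm in cells) universe <- union(universe, names(cm$abundance))
  n <- length(universe)
  ns <- nrow(design)
  plasma_mass <- stats::setNames(numeric(n), universe)
  plasma_mass[names(plasma$abundance)] <- plasma_mass_per_uL * plasma$abundance

  true_mix <- matrix(plasma_mass, nrow = n, ncol = ns,
                     dimnames = list(universe, design$sample_id))
  cell_contrib <- list()
  for (ct in types) {
    cm <- cells[[ct]]
    per_unit <- stats::setNames(numeric(n), universe)
    per_unit[names(cm$abundance)] <- cm$per_cell_protein_mass * cm$abundance
    contrib <- outer(per_unit, design[[ct]])
    dimnames(contrib) <- dimnames(true_mix)
    cell_contrib[[ct]] <- contrib
    true_mix <- true_mix + contrib
  }
  structure(list(design = design, true_mixture = true_mix,
                 plasma_mass = plasma_mass, cell_contrib = cell_contrib,
                 true_markers = lapply(cells, `[[`, "marker_ids"),
                 plasma = plasma, cells = cells,
                 plasma_mass_per_uL = plasma_mass_per_uL),
            class = "spikein_truth")
}

#' Workflow transformation model
#'
#' A workflow reshapes the true protein mass vector before measurement:
#' `captured_i = affinity_i * true_i ^ compression_exponent`, then -- for
#' finite `binding_capacity` -- each sample column is globally rescaled so
#' total captured signal never exceeds the capacity (bead saturation).
#' `intensity_per_mass` converts captured signal to MS intensity units at
#' measurement time; `lod`, `cv` and `dropout_steepness` control the noise
#' and missingness model of [corrupt_measurements()].
#'
#' @param name Workflow label.
#' @param compression_exponent Power in (0, 1] applied to true mass;
#'   values < 1 compress the dynamic range (bead corona effect).
#' @param binding_capacity Total capturable signal per sample in captured
#'   units; `Inf` for workflows without beads.
#' @param affinity Optional named per-protein capture weight multipliers
#'   (default 1 for every protein).
#' @param lod Detection limit on measured intensity (0 disables missingness).
#' @param cv Replicate coefficient of variation of the multiplicative noise.
#' @param dropout_steepness Slope (per log10 intensity) of the sigmoidal
#'   abundance-dependent missingness curve centred at the lod.
#' @param intensity_per_mass Intensity units per captured unit (default 1,
#'   i.e. measured intensity equals captured signal).
#' @return A `workflow_model`.
#' @export
workflow_model <- function(name = "custom", compression_exponent = 1,
                           binding_capacity = Inf, affinity = NULL,
                           lod = 0, cv = 0.1, dropout_steepness = 3,
                           intensity_per_mass = 1) {
  if (!(compression_exponent > 0 && compression_exponent <= 1))
    stop("compression_exponent must be in (0, 1]")
  if (!(binding_capacity > 0)) stop("binding_capacity must be > 0 (or Inf)")
  if (cv < 0) stop("cv must be >= 0")
  if (lod < 0) stop("lod must be >= 0")
  structure(list(name = name, compression_exponent = compression_exponent,
                 binding_capacity = binding_capacity, affinity = affinity,
                 lod = lod, cv = cv, dropout_steepness = dropout_steepness,
                 intensity_per_mass = intensity_per_mass),
            class = "workflow_model")
}

#' Workflow presets
#'
#' The five workflow archetypes of the study, parameterized as a stated
#' world: `neat` (identity capture), `pca-n` (perchloric-acid precipitation:
#' mild compression, no bead capacity), and three bead workflows (`sax`,
#' `serasil`, `nonmagnetic`) with strong dynamic-range compression and finite
#' binding capacity. Capacities and intensity scales are calibrated once
#' against the canonical 70 ug/uL plasma input so that pure plasma sits below
#' bead saturation, heavy spike-ins saturate, and every workflow reports
#' ~7e11 total intensity for pure plasma (the instrument-loading
#' normalization all workflows share in practice). Replicate CVs follow the
#' observed ordering (neat most precise, precipitation and non-magnetic
#' beads noisiest).
#'
#' @param name One of `"neat"`, `"pca-n"`, `"sax"`, `"serasil"`,
#'   `"nonmagnetic"`.
#' @return A `workflow_model`.
#' @export
workflow_preset <- function(name = c("neat", "pca-n", "sax", "serasil", "nonmagnetic")) {
  name <- match.arg(name)
  p <- switch(name,
    "neat"        = list(gamma = 1.00, cap = Inf,   cv = 0.10, scale = 1.0e4),
    "pca-n"       = list(gamma = 0.85, cap = Inf,   cv = 0.15, scale = 1.25e5),
    "sax"         = list(gamma = 0.65, cap = 3.2e5, cv = 0.12, scale = 2.85e6),
    "serasil"     = list(gamma = 0.70, cap = 6.7e5, cv = 0.12, scale = 1.35e6),
    "nonmagnetic" = list(gamma = 0.55, cap = 8.1e4, cv = 0.15, scale = 1.13e7))
  workflow_model(name = name, compression_exponent = p$gamma,
                 binding_capacity = p$cap, lod = 1e3, cv = p$cv,
                 dropout_steepness = 3, intensity_per_mass = p$scale)
}

#' Apply a workflow transformation to true protein masses
#'
#' @param truth A `spikein_truth`, or a plain nonnegative matrix/vector of
#'   true per-protein masses (proteins x samples).
#' @param wf A `workflow_model`.
#' @return Captured-signal matrix (proteins x samples), same dimnames.
#' @export
apply_workflow <- function(truth, wf) {
  stopifnot(inherits(wf, "workflow_model"))
  m <- if (inherits(truth, "spikein_truth")) truth$true_mixture else truth
  if (is.vector(m)) m <- matrix(m, ncol = 1, dimnames = list(names(m), "S1"))
  if (any(m < 0, na.rm = TRUE)) stop("true masses must be nonnegative")
  cap <- m ^ wf$compression_exponent
  if (!is.null(wf$affinity)) {
    a <- rep(1, nrow(m))
    names(a) <- rownames(m)
    hit <- intersect(names(wf$affinity), rownames(m))
    a[hit] <- wf$affinity[hit]
    cap <- cap * a
  }
  if (is.finite(wf$binding_capacity)) {
    tot <- colSums(cap)
    scale <- pmin(1, wf$binding_capacity / pmax(tot, .Machine$double.xmin))
    cap <- sweep(cap, 2, scale, `*`)
  }
  cap
}

#' Corrupt captured signal into a measured quantification matrix
#'
#' Converts captured signal to intensity (`intensity_per_mass`), applies
#' multiplicative log-normal noise with exact target CV (`sigma^2 =
#' log(1 + cv^2)`, mean-preserving), sets values below the lod missing, adds
#' sigmoidal abundance-dependent dropout centred at the lod, and emits
#' simulated per-protein precursor counts
#' `max(1, round(2 * (log10 intensity - log10 lod)))` (a monotone proxy
#' supporting the minimum-precursor marker filter).
#'
#' @param captured Captured-signal matrix from [apply_workflow()].
#' @param wf The `workflow_model` (noise/lod parameters).
#' @param n_replicates Replicates per sample column (>= 1).
#' @param seed Integer seed.
#' @return A [quant_matrix()] with `n_replicates` columns per input sample
#'   (sample ids suffixed `_r1`, `_r2`, ...), including precursor counts.
#' @export
corrupt_measurements <- function(captured, wf, n_replicates = 4, seed = 1) {
  stopifnot(inherits(wf, "workflow_model"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (wf$cv < 0) stop("cv must be >= 0")
  base <- captured * wf$intensity_per_mass
  n <- nrow(base); ns <- ncol(base)
  rep_idx <- rep(seq_len(ns), each = n_replicates)
  out <- base[, rep_idx, drop = FALSE]
  colnames(out) <- paste0(colnames(base)[rep_idx], "_r",
                          rep(seq_len(n_replicates), times = ns))
  out <- .with_seed(seed, {
    if (wf$cv > 0) {
      sigma <- sqrt(log(1 + wf$cv^2))
      noise <- exp(matrix(stats::rnorm(length(out), -sigma^2 / 2, sigma), nrow = n))
      out <- out * noise
    }
    if (wf$lod > 0) {
      miss <- out < wf$lod
      l10 <- suppressWarnings(log10(pmax(out, .Machine$double.xmin)))
      p_miss <- stats::plogis(-wf$dropout_steepness * (l10 - log10(wf$lod)))
      miss <- miss | (matrix(stats::runif(length(out)), nrow = n) < p_miss)
      out[miss] <- NA_real_
    }
    out
  })
  if (all(is.na(out)))
    warning("lod exceeds every simulated intensity: matrix is fully missing")
  lod_ref <- if (wf$lod > 0) log10(wf$lod) else 0
  prec <- pmax(round(2 * (log10(pmax(base[, rep_idx, drop = FALSE],
                                     .Machine$double.xmin)) - lod_ref)), 1)
  dimnames(prec) <- dimnames(out)
  quant_matrix(out, precursor_counts = prec)
}

#' Simulate a contamination-rescue experiment
#'
#' Removes a fraction of each cell type's contribution from the true mixture
#' (modelling post-thaw centrifugation that pellets residual cells), leaves
#' plasma-derived mass untouched, and re-applies the workflow and noise
#' model. With the same seed, `removal_fraction = 0` reproduces the
#' unrescued simulation bit-for-bit.
#'
#' @param truth A `spikein_truth`.
#' @param wf A `workflow_model`.
#' @param removal_fraction Scalar in \[0, 1\], or a named vector per cell type.
#' @param n_replicates Replicates per sample.
#' @param seed Integer seed.
#' @return A list: `matrix` (the rescued [quant_matrix()]) and `truth` (the
#'   rescued `spikein_truth`).
#' @export
simulate_rescue <- function(truth, wf, removal_fraction, n_replicates = 4, seed = 1) {
  stopifnot(inherits(truth, "spikein_truth"))
  types <- names(truth$cell_contrib)
  f <- if (length(removal_fraction) == 1 && is.null(names(removal_fraction)))
    stats::setNames(rep(removal_fraction, length(types)), types)
  else removal_fraction
  if (!all(types %in% names(f))) stop("removal_fraction must cover every cell type")
  if (any(f < 0 | f > 1)) stop("removal_fraction must be within [0, 1]")
  new_truth <- truth
  mix <- truth$true_mixture
  for (ct in types) {
    mix <- mix - f[[ct]] * truth$cell_contrib[[ct]]
    new_truth$cell_contrib[[ct]] <- (1 - f[[ct]]) * truth$cell_contrib[[ct]]
  }
  mix[mix < 0] <- 0  # guard against floating-point dust
  new_truth$true_mixture <- mix
  list(matrix = corrupt_measurements(apply_workflow(new_truth, wf), wf,
                                     n_replicates = n_replicates, seed = seed),
       truth = new_truth)
}

#' Spike-in count series used in the study design
#'
#' Platelets and erythrocytes: 1 to 2e6 cells/uL; PBMCs: 1 to 1.4e4 cells/uL
#' (log-spaced, plus a pure-plasma zero point).
#'
#' @param cell_type Cell type label.
#' @param include_zero Include the pure-plasma point (default `TRUE`).
#' @return Numeric vector of cells per uL.
#' @export
spikein_counts <- function(cell_type, include_zero = TRUE) {
  counts <- switch(cell_type,
    platelet    = c(1, 10, 100, 1e3, 1e4, 1e5, 1e6, 2e6),
    erythrocyte = c(1, 10, 100, 1e3, 1e4, 1e5, 1e6, 2e6),
    pbmc        = c(1, 14, 140, 1.4e3, 1.4e4),
    stop("unknown cell_type '", cell_type, "'"))
  if (include_zero) c(0, counts) else counts
}

#' Simulate a complete dilution-series experiment
#'
#' Convenience wrapper: builds plasma + one contaminant proteome, spikes the
#' study's count series, applies a workflow, corrupts measurements in
#' quadruplicate and returns matrix, metadata and ground truth.
#'
#' @param cell_type Contaminant cell type.
#' @param workflow A `workflow_model` or preset name.
#' @param seed Integer seed.
#' @param counts Cells/uL per sample (default [spikein_counts()]).
#' @param n_replicates Replicates per count (default 4, as in the study).
#' @param n_proteins_plasma,n_proteins_cell Generator sizes.
#' @param plasma,cell Optional pre-built models (override the generators).
#' @return List: `matrix` ([quant_matrix()]), `samples` (metadata
#'   data.frame), `truth` (`spikein_truth`), `workflow`.
#' @export
simulate_dilution_series <- function(cell_type = "platelet", workflow = "neat",
                                     seed = 1, counts = NULL, n_replicates = 4,
                                     n_proteins_plasma = 1000,
                                     n_proteins_cell = 3000,
                                     plasma = NULL, cell = NULL) {
  wf <- if (inherits(workflow, "workflow_model")) workflow else workflow_preset(workflow)
  if (is.null(counts)) counts <- spikein_counts(cell_type)
  if (is.null(plasma))
    plasma <- generate_plasma_proteome(n_proteins_plasma, seed = seed)
  if (is.null(cell))
    cell <- generate_cell_proteome(cell_type, n_proteins = n_proteins_cell,
                                   seed = seed + 1000L, plasma = plasma)
  design <- data.frame(sample_id = sprintf("%s_c%02d", cell_type, seq_along(counts)))
  design[[cell_type]] <- counts
  truth <- simulate_spikein_series(plasma, list(cell), design)
  mat <- corrupt_measurements(apply_workflow(truth, wf), wf,
                              n_replicates = n_replicates, seed = seed + 2000L)
  samples <- data.frame(
    sample_id = sample_ids(mat),
    base_sample = rep(design$sample_id, each = n_replicates),
    workflow = wf$name, cell_type = cell_type,
    cell_count = rep(counts, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(counts)),
    stringsAsFactors = FALSE)
  list(matrix = mat, samples = samples, truth = truth, workflow = wf)
}

#' Simulate a two-group biomarker study with a contamination artifact
#'
#' The headline QC scenario: cases and controls (n per group) where cases
#' carry `contamination_ratio`-fold higher platelet contamination. The study
#' contains a "false biomarker" -- a platelet-derived protein outside the
#' top-30 QC panel whose apparent group difference is induced solely by the
#' differential contamination -- and a genuine biomarker, a mid-abundance
#' plasma protein with a real `biomarker_fold` group effect and equal
#' contamination across groups. Per-sample platelet counts jitter
#' log-normally (`count_sd_log10`) around the group level, as contamination
#' does across a real study.
#'
#' @param n_per_group Samples per group (default 20).
#' @param contamination_ratio Case/control platelet-count ratio (default 5).
#' @param base_count Geometric-mean control platelet count per uL
#'   (default 2e4, a realistic residual contamination level).
#' @param count_sd_log10 Log10 sd of per-sample platelet counts (default 0.4).
#' @param biomarker_fold True fold change of the genuine biomarker
#'   (default 2).
#' @param workflow Workflow preset name or model (default `"sax"`).
#' @param seed Integer seed.
#' @param n_proteins_plasma,n_proteins_cell Generator sizes.
#' @return List: `matrix`, `samples` (with `group`), `truth`,
#'   `true_biomarker`, `false_biomarker`, `workflow`, plus the generating
#'   models.
#' @export
simulate_two_group_study <- function(n_per_group = 20, contamination_ratio = 5,
                                     base_count = 2e4, count_sd_log10 = 0.4,
                                     biomarker_fold = 2, workflow = "sax",
                                     seed = 1, n_proteins_plasma = 1000,
                                     n_proteins_cell = 3000) {
  wf <- if (inherits(workflow, "workflow_model")) workflow else workflow_preset(workflow)
  plasma <- generate_plasma_proteome(n_proteins_plasma, seed = seed)
  cell <- generate_cell_proteome("platelet", n_proteins = n_proteins_cell,
                                 seed = seed + 1000L, plasma = plasma)
  n <- 2 * n_per_group
  group <- rep(c("control", "case"), each = n_per_group)
  counts <- .with_seed(seed + 3000L, {
    jitter <- 10^stats::rnorm(n, 0, count_sd_log10)
    base_count * jitter * ifelse(group == "case", contamination_ratio, 1)
  })
  design <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), platelet = counts)
  truth <- simulate_spikein_series(plasma, list(cell), design)

  # genuine biomarker: plasma protein ~rank 100, real fold change in cases
  true_bm <- names(plasma$abundance)[100]
  truth$true_mixture[true_bm, group == "case"] <-
    truth$true_mixture[true_bm, group == "case"] * biomarker_fold
  # false biomarker: a bright platelet marker protein that is NOT in the
  # top-30 QC panel (panels keep the 30 strongest of 50 designed markers)
  false_bm <- cell$marker_ids[40]

  mat <- corrupt_measurements(apply_workflow(truth, wf), wf,
                              n_replicates = 1, seed = seed + 2000L)
  colnames(mat$intensity) <- design$sample_id
  if (!is.null(mat$precursor_counts)) colnames(mat$precursor_counts) <- design$sample_id
  samples <- data.frame(sample_id = design$sample_id, group = group,
                        workflow = wf$name, cell_type = "platelet",
                        cell_count = counts, replicate = 1L,
                        stringsAsFactors = FALSE)
  list(matrix = mat, samples = samples, truth = truth,
       true_biomarker = true_bm, false_biomarker = false_bm,
       workflow = wf, plasma = plasma, cell = cell)
}

#' Simulate the marker-derivation experiment
#'
#' Produces the two measurement sets marker derivation needs: pure-plasma
#' replicates and "pure contamination" replicates (the contaminant cell type
#' spiked at the top of its count series into plasma), both under the same
#' workflow.
#'
#' @param cell A `cell_proteome_model`.
#' @param plasma A `plasma_model`.
#' @param workflow Workflow preset name or model (default `"neat"`).
#' @param count Spike level for the contaminant samples (default: the top of
#'   the study's series for that cell type).
#' @param n_replicates Replicates per side (default 4).
#' @param seed Integer seed.
#' @return List: `contaminant` and `plasma` ([quant_matrix()]s), `truth`.
#' @export
simulate_contaminant_experiment <- function(cell, plasma, workflow = "neat",
                                            count = NULL, n_replicates = 4,
                                            seed = 1) {
  wf <- if (inherits(workflow, "workflow_model")) workflow else workflow_preset(workflow)
  if (is.null(count)) count <- max(spikein_counts(cell$cell_type))
  design <- data.frame(sample_id = c("pure_plasma", "pure_contaminant"))
  design[[cell$cell_type]] <- c(0, count)
  truth <- simulate_spikein_series(plasma, list(cell), design)
  mat <- corrupt_measurements(apply_workflow(truth, wf), wf,
                              n_replicates = n_replicates, seed = seed)
  reps <- function(base) grep(paste0("^", base, "_r"), sample_ids(mat), value = TRUE)
  list(contaminant = subset_quant(mat, samples = reps("pure_contaminant")),
       plasma = subset_quant(mat, samples = reps("pure_plasma")),
       truth = truth)
}
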