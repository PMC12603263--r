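# Shared fixtures, built in code once per test run.

# small quant_matrix from a plain matrix-like spec
qm <- function(..., proteins = NULL, samples = NULL, precursors = NULL) {
  m <- rbind(...)
  if (is.null(proteins)) proteins <- sprintf("P%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(m)))
  dimnames(m) <- list(proteins, samples)
  quant_matrix(m, precursor_counts = precursors)
}

# one modest world shared by many tests (kept small for speed)
.world <- new.env()
test_world <- function() {
  if (is.null(.world$plasma)) {
    .world$plasma <- generate_plasma_proteome(500, seed = 42)
    .world$cell <- generate_cell_proteome("platelet", n_proteins = 1500,
                                          seed = 43, plasma = .world$plasma)
    .world$panel <- as_marker_panel(.world$cell$marker_ids[1:30], "platelet",
                                    source = "truth")
  }
  as.list(.world)
}

# a model's abundance vector expanded into a protein universe (0 elsewhere)
ab_in <- function(model, universe) {
  v <- stats::setNames(numeric(length(universe)), universe)
  v[names(model$abundance)] <- model$abundance
  v
}

# noiseless identity workflow (measured intensity == true mass)
wf_identity <- function(scale = 1) {
  workflow_model("identity", compression_exponent = 1, binding_capacity = Inf,
                 lod = 0, cv = 0, intensity_per_mass = scale)
}

# simulate a simple pure-vs-contaminated study (for PCA / rescue tests)
sim_pure_vs_contaminated <- function(n_each = 8, count = 1e5, workflow = "sax",
                                     seed = 1, world = test_world()) {
  wf <- if (inherits(workflow, "workflow_model")) workflow else workflow_preset(workflow)
  des <- data.frame(sample_id = sprintf("S%02d", seq_len(2 * n_each)),
                    platelet = rep(c(0, count), each = n_each))
  tr <- simulate_spikein_series(world$plasma, list(world$cell), des)
  m <- corrupt_measurements(apply_workflow(tr, wf), wf, n_replicates = 1,
                            seed = seed + 77L)
  colnames(m$intensity) <- des$sample_id
  if (!is.null(m$precursor_counts)) colnames(m$precursor_counts) <- des$sample_id
  list(matrix = m, status = rep(c("pure", "contaminated"), each = n_each),
       truth = tr, workflow = wf)
}

# contamination-outlier study: bounded baseline contamination band plus
# discrete 10x handling failures (5% of samples)
sim_outlier_study <- function(seed, n = 40, base_count = 2e4, halfwidth = 0.15,
                              failure_factor = 10, world = test_world()) {
  wf <- workflow_preset("neat")
  set.seed(seed)
  counts <- base_count * 10^stats::runif(n, -halfwidth, halfwidth)
  spiked <- sample(n, round(0.05 * n))
  counts[spiked] <- counts[spiked] * failure_factor
  des <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), platelet = counts)
  tr <- simulate_spikein_series(world$plasma, list(world$cell), des)
  m <- corrupt_measurements(apply_workflow(tr, wf), wf, n_replicates = 1,
                            seed = seed + 500L)
  colnames(m$intensity) <- des$sample_id
  list(matrix = m, spiked = spiked, design = des)
}
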