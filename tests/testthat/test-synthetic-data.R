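test_that("plasma proteome hits the top-20 mass target and is deterministic", {
  pl <- generate_plasma_proteome(1000, top20_mass_target = 0.99, seed = 1)
  ab <- pl$abundance
  expect_true(all(ab > 0))
  expect_equal(sum(ab), 1, tolerance = 1e-9)
  frac <- sum(ab[1:20])
  expect_gte(frac, 0.985); expect_lte(frac, 0.995)
  expect_false(is.unsorted(rev(ab)))  # descending in the head-dominant regime

  pl2 <- generate_plasma_proteome(1000, top20_mass_target = 0.99, seed = 1)
  expect_identical(pl$abundance, pl2$abundance)

  # low-target regime: normalization still exact
  pl3 <- generate_plasma_proteome(30, top20_mass_target = 0.5, seed = 7)
  expect_equal(sum(pl3$abundance), 1, tolerance = 1e-9)

  expect_error(generate_plasma_proteome(20), "n_proteins")
  expect_error(generate_plasma_proteome(100, top20_mass_target = 1), "unattainable")
  expect_error(generate_plasma_proteome(100, top20_mass_target = 0), "unattainable")
})

test_that("cell proteomes respect marker design, namespaces and determinism", {
  pl <- generate_plasma_proteome(500, seed = 2)
  ery <- generate_cell_proteome("erythrocyte", n_proteins = 3000, n_markers = 50,
                                seed = 9, plasma = pl)
  # hemoglobin-like head: top-5 mass fraction near the 0.8 default
  expect_gte(sum(sort(ery$abundance, decreasing = TRUE)[1:5]), 0.75)
  expect_equal(sum(ery$abundance), 1, tolerance = 1e-12)
  expect_length(ery$marker_ids, 50)
  # markers are namespaced out of the plasma universe
  expect_length(intersect(ery$marker_ids, names(pl$abundance)), 0)
  # shared ids live in the plasma universe
  expect_true(all(ery$shared_ids %in% names(pl$abundance)))
  # the designed abundance gap separates markers from everything else
  nonmark <- setdiff(names(ery$abundance), ery$marker_ids)
  expect_gte(min(ery$abundance[ery$marker_ids]) / max(ery$abundance[nonmark]), 10 - 1e-9)

  p1 <- generate_cell_proteome("platelet", n_proteins = 2000, seed = 3)
  p2 <- generate_cell_proteome("platelet", n_proteins = 2000, seed = 3)
  expect_identical(p1$abundance, p2$abundance)
  expect_error(generate_cell_proteome("neuron", 100), "unknown cell_type")
  # volume-proportional per-cell mass ordering: pbmc > erythrocyte > platelet
  masses <- vapply(c("platelet", "erythrocyte", "pbmc"), function(ct)
    generate_cell_proteome(ct, n_proteins = 100, n_markers = 10, seed = 1)$per_cell_protein_mass,
    numeric(1))
  expect_true(masses[["pbmc"]] > masses[["erythrocyte"]] &&
              masses[["erythrocyte"]] > masses[["platelet"]])
})

test_that("spike-in mixing is linear and conserves mass", {
  w <- test_world()
  ery <- generate_cell_proteome("erythrocyte", n_proteins = 800, seed = 5,
                                plasma = w$plasma)
  pbm <- generate_cell_proteome("pbmc", n_proteins = 900, seed = 6,
                                plasma = w$plasma)
  des <- data.frame(sample_id = c("zero", "single", "double", "combined"),
                    platelet = c(0, 5e4, 1e5, 5e4),
                    erythrocyte = c(0, 0, 0, 5e5),
                    pbmc = c(0, 0, 0, 500))
  tr <- simulate_spikein_series(w$plasma, list(w$cell, ery, pbm), des)

  # zero spike-in equals pure plasma exactly
  pure <- tr$plasma_mass
  expect_identical(unname(tr$true_mixture[, "zero"]), unname(pure))
  # doubling one count doubles that cell's contribution everywhere
  expect_equal(tr$true_mixture[, "double"] - pure,
               2 * (tr$true_mixture[, "single"] - pure), tolerance = 1e-12)
  # combined contamination = sum of single-type contributions (oracle:
  # independent per-type summation)
  manual <- pure +
    5e4 * w$cell$per_cell_protein_mass * ab_in(w$cell, rownames(tr$true_mixture)) +
    5e5 * ery$per_cell_protein_mass * ab_in(ery, rownames(tr$true_mixture)) +
    500 * pbm$per_cell_protein_mass * ab_in(pbm, rownames(tr$true_mixture))
  expect_equal(unname(tr$true_mixture[, "combined"]), unname(manual), tolerance = 1e-9)
  # mass conservation, relative
  tot <- sum(tr$true_mixture[, "combined"])
  expected <- w$plasma$mass_per_uL + 5e4 * w$cell$per_cell_protein_mass +
    5e5 * ery$per_cell_protein_mass + 500 * pbm$per_cell_protein_mass
  expect_equal(tot, expected, tolerance = 1e-9)

  des_bad <- des; des_bad$platelet[1] <- -5
  expect_error(simulate_spikein_series(w$plasma, list(w$cell, ery, pbm), des_bad),
               "negative cell count")
})

test_that("workflow transform: identity, saturation limit, compression algebra", {
  x <- matrix(c(1, 10, 100, 1000), 4, 1,
              dimnames = list(paste0("p", 1:4), "s"))
  # identity workflow: captured equals truth exactly
  expect_identical(apply_workflow(x, wf_identity()), x)
  # saturation: captured total never exceeds capacity; equality above onset
  wf_cap <- workflow_model("cap", binding_capacity = 100)
  expect_equal(sum(apply_workflow(x, wf_cap)), 100)
  small <- x / 1000
  expect_equal(sum(apply_workflow(small, wf_cap)), sum(small))  # below capacity
  # exponent 0.5 halves the log10 dynamic range
  wf_c <- workflow_model("compress", compression_exponent = 0.5)
  capt <- apply_workflow(x, wf_c)
  expect_equal(log10(max(capt) / min(capt)), 0.5 * log10(max(x) / min(x)),
               tolerance = 1e-12)
  # monotone in true mass
  expect_false(is.unsorted(capt[, 1]))
})

test_that("measurement corruption: noiseless limit, CV calibration, lod", {
  x <- matrix(10^runif(200, 4, 9), 100, 2,
              dimnames = list(sprintf("p%03d", 1:100), c("a", "b")))
  m0 <- corrupt_measurements(x, wf_identity(), n_replicates = 3, seed = 1)
  expect_equal(unname(m0$intensity[, "a_r1"]), unname(x[, "a"]))
  expect_equal(unname(m0$intensity[, "a_r3"]), unname(x[, "a"]))

  # empirical CV matches the target
  wfn <- workflow_model("noisy", cv = 0.2, lod = 0)
  xx <- matrix(1e6, 2000, 1, dimnames = list(sprintf("p%04d", 1:2000), "s"))
  mn <- corrupt_measurements(xx, wfn, n_replicates = 4, seed = 11)
  cvs <- apply(mn$intensity, 1, function(v) sd(v) / mean(v))
  expect_lt(abs(median(cvs) - 0.2), 0.03)

  # lod above everything: fully missing, with warning
  wfl <- workflow_model("blind", cv = 0, lod = 1e12)
  expect_warning(mfull <- corrupt_measurements(x, wfl, n_replicates = 1, seed = 2),
                 "fully missing")
  expect_true(all(is.na(mfull$intensity)))

  # determinism and precursor counts
  m1 <- corrupt_measurements(x, wfn, n_replicates = 2, seed = 5)
  m2 <- corrupt_measurements(x, wfn, n_replicates = 2, seed = 5)
  expect_identical(m1$intensity, m2$intensity)
  wfp <- workflow_model("prec", cv = 0, lod = 1e3)
  mp <- suppressWarnings(corrupt_measurements(
    matrix(c(1e3, 1e5, 1e9), 3, 1, dimnames = list(c("a", "b", "c"), "s")),
    wfp, n_replicates = 1, seed = 1))
  expect_equal(unname(mp$precursor_counts[, 1]), c(1, 4, 12))
  expect_error(workflow_model("bad", cv = -1), "cv")
})

test_that("rescue removes contaminant mass and only that", {
  w <- test_world()
  des <- data.frame(sample_id = c("pure", "cont"), platelet = c(0, 1e5))
  tr <- simulate_spikein_series(w$plasma, list(w$cell), des)
  wf <- wf_identity(1e4)
  m0 <- corrupt_measurements(apply_workflow(tr, wf), wf, n_replicates = 1, seed = 7)

  # removal 0 with the same seed is bit-identical
  r0 <- simulate_rescue(tr, wf, 0, n_replicates = 1, seed = 7)
  expect_identical(r0$matrix$intensity, m0$intensity)

  # removal 0.9 cuts marker summed intensity by exactly 10x (noiseless linear)
  r9 <- simulate_rescue(tr, wf, 0.9, n_replicates = 1, seed = 7)
  mk <- panel_proteins(w$panel)
  expect_equal(sum(m0$intensity[mk, "cont_r1"]) / sum(r9$matrix$intensity[mk, "cont_r1"]),
               10, tolerance = 1e-9)

  # complete removal reproduces the pure-plasma contamination index
  r1 <- simulate_rescue(tr, wf, 1, n_replicates = 1, seed = 7)
  ci <- contamination_index(r1$matrix, w$panel)
  expect_equal(ci$contamination_index[ci$sample_id == "cont_r1"],
               ci$contamination_index[ci$sample_id == "pure_r1"])
  expect_error(simulate_rescue(tr, wf, 1.2), "within")
})
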