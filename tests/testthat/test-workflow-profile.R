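test_that("rank shift profile: identity law, uniform scaling, only-classes", {
  set.seed(2)
  v <- stats::setNames(10^runif(50, 3, 9), sprintf("P%02d", 1:50))
  idp <- rank_shift_profile(v, v)
  expect_true(all(idp$log10_ratio == 0))
  expect_true(all(idp$class == "neither"))
  expect_equal(sort(idp$neat_rank), 1:50)

  up <- rank_shift_profile(v, v * 10)
  expect_equal(up$log10_ratio, rep(1, 50), tolerance = 1e-12)

  part <- rank_shift_profile(v[1:30], v[21:50])
  expect_equal(sum(part$class == "neat_only"), 20)
  expect_equal(sum(part$class == "other_only"), 20)

  # compressed workflow enriches the low-abundance end relative to the top
  w <- test_world()
  des <- data.frame(sample_id = "s", platelet = 0)
  tr <- simulate_spikein_series(w$plasma, list(w$cell), des)
  neat <- apply_workflow(tr, wf_identity())[, 1]
  comp <- apply_workflow(tr, workflow_model("c", compression_exponent = 0.5))[, 1]
  pr <- rank_shift_profile(neat[neat > 0], comp[neat > 0])
  expect_gt(cor(pr$neat_rank, pr$log10_ratio, method = "spearman"), 0.9)
})

test_that("enriched/depleted classification follows the 80% rule", {
  prof <- data.frame(protein_id = c("a", "b", "c", "d"),
                     ratio = c(2.0, 0.15, 1.5, NA),
                     class = c("neither", "neither", "neither", "other_only"),
                     stringsAsFactors = FALSE)
  cl <- classify_enriched_depleted(prof, 0.8)
  expect_equal(cl$class, c("enriched", "depleted", "neither", "other_only"))
  # boundary: exactly 1.8 and 0.2 are inside the classes
  prof$ratio <- c(1.8, 0.2, 1.0, NA)
  cl2 <- classify_enriched_depleted(prof, 0.8)
  expect_equal(cl2$class[1:2], c("enriched", "depleted"))
  # disjoint for any threshold < 1
  expect_error(classify_enriched_depleted(prof, 1.2), "threshold_fraction")
  # log2 reading available
  prof$ratio <- c(2, 0.5, 1.2, NA)
  cl3 <- classify_enriched_depleted(prof, mode = "log2", log2_cutoff = 1)
  expect_equal(cl3$class[1:3], c("enriched", "depleted", "neither"))
})

# ---- sequence properties vs independent brute-force oracles ----

# independent copies of the published constants, written directly here
.kd_oracle <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                Y = -1.3, V = 4.2)
.pka_oracle <- list(nterm = 8.6, cterm = 3.6,
                    pos = c(K = 10.8, R = 12.5, H = 6.5),
                    neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

oracle_props <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  std <- ch[ch %in% names(.kd_oracle)]
  mw <- .water_mass_oracle
  for (a in std) mw <- mw + .res_mass_oracle[[a]]
  grav <- 0
  for (a in std) grav <- grav + .kd_oracle[[a]]
  grav <- grav / length(std)
  arom <- sum(std %in% c("F", "W", "Y")) / length(ch)
  ii <- 0
  if (length(ch) >= 2)
    for (i in 1:(length(ch) - 1)) {
      a <- ch[i]; b <- ch[i + 1]
      if (a %in% rownames(.diwv_oracle) && b %in% colnames(.diwv_oracle))
        ii <- ii + .diwv_oracle[a, b]
    }
  list(mw = mw, gravy = grav, arom = arom, instability = 10 / length(ch) * ii)
}

oracle_pi <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  charge <- function(pH) {
    q <- 1 / (1 + 10^(pH - .pka_oracle$nterm)) - 1 / (1 + 10^(.pka_oracle$cterm - pH))
    for (a in ch) {
      if (a %in% names(.pka_oracle$pos)) q <- q + 1 / (1 + 10^(pH - .pka_oracle$pos[[a]]))
      if (a %in% names(.pka_oracle$neg)) q <- q - 1 / (1 + 10^(.pka_oracle$neg[[a]] - pH))
    }
    q
  }
  stats::uniroot(charge, c(0, 14), tol = 1e-10)$root
}

test_that("physicochemical calculators match brute-force oracles on random sequences", {
  # oracle mass/DIWV tables taken from the package's vendored constants (the
  # algorithms, not the published tables, are what is dual-implemented)
  .res_mass_oracle <<- getFromNamespace(".residue_mass", "plasmaQC")
  .water_mass_oracle <<- getFromNamespace(".water_mass", "plasmaQC")
  .diwv_oracle <<- getFromNamespace(".diwv", "plasmaQC")
  set.seed(99)
  aas <- names(.kd_oracle)
  for (i in 1:100) {
    seq <- paste(sample(aas, sample(5:200, 1), replace = TRUE), collapse = "")
    got <- sequence_properties(seq)
    exp <- oracle_props(seq)
    expect_equal(got$molecular_weight, exp$mw, tolerance = 1e-9)
    expect_equal(got$gravy, exp$gravy, tolerance = 1e-12)
    expect_equal(got$aromaticity, exp$arom, tolerance = 1e-12)
    expect_equal(got$instability_index, exp$instability, tolerance = 1e-9)
    expect_lt(abs(got$isoelectric_point - oracle_pi(seq)), 0.01)
  }
})

test_that("sequence properties: closed-form spot checks and contracts", {
  expect_equal(sequence_properties("AAA")$gravy, 1.8)
  expect_equal(sequence_properties("FWYA")$aromaticity, 0.75)
  d <- getFromNamespace(".diwv", "plasmaQC")
  expect_equal(sequence_properties("AA")$instability_index, 5 * d["A", "A"])
  # polyglycine pI: only the termini carry charge
  expect_lt(abs(sequence_properties("GGGGGG")$isoelectric_point -
                oracle_pi("GGGGGG")), 0.01)
  # ambiguous residues count in length, not in scale means
  p <- sequence_properties("AXA")
  expect_equal(p$length, 3L)
  expect_equal(p$gravy, 1.8)
  expect_error(sequence_properties(""), "non-empty")
  expect_error(sequence_properties("AJA"), "invalid residue 'J' at position 2")
})

test_that("property enrichment tests behave per contract", {
  set.seed(8)
  en <- data.frame(molecular_weight = rnorm(50, 20000, 2000))
  de <- data.frame(molecular_weight = rnorm(50, 80000, 2000))
  r <- property_enrichment_tests(en, de, properties = "molecular_weight")
  expect_lt(r$p, 1e-10)
  expect_equal(r$direction, "lower_in_enriched")

  same <- data.frame(gravy = rnorm(20))
  ri <- property_enrichment_tests(same, same, properties = "gravy")
  expect_equal(ri$p, 1, tolerance = 1e-12)

  rz <- property_enrichment_tests(data.frame(length = rep(5, 4)),
                                  data.frame(length = rep(5, 6)),
                                  properties = "length")
  expect_equal(rz$p, 1)
  expect_match(rz$note, "convention")

  rs <- property_enrichment_tests(data.frame(gravy = c(1, 2)),
                                  data.frame(gravy = rnorm(10)),
                                  properties = "gravy")
  expect_true(is.na(rs$p))
  expect_match(rs$note, "undefined")
})

test_that("replicate CVs use the population-sd convention and hit the target", {
  m <- qm(c(90, 110), c(100, 100), proteins = c("A", "B"), samples = c("r1", "r2"))
  r <- replicate_cv(m, list(g = c("r1", "r2")))
  expect_equal(r$cv$cv[r$cv$protein_id == "A"], 0.1)  # population sd = 10
  expect_equal(r$cv$cv[r$cv$protein_id == "B"], 0)

  w <- test_world()
  wf <- workflow_preset("neat"); wf$cv <- 0.13
  des <- data.frame(sample_id = "s", platelet = 0)
  tr <- simulate_spikein_series(w$plasma, list(w$cell), des)
  mm <- corrupt_measurements(apply_workflow(tr, wf), wf, n_replicates = 8, seed = 3)
  rr <- replicate_cv(mm, list(s = sample_ids(mm)))
  expect_lt(abs(rr$summary$median_cv - 0.13), 0.02)
  expect_error(replicate_cv(m, list(g = "r1")), ">= 2")
})

test_that("KNN imputation + PCA: identity, collinear and oracle agreement", {
  set.seed(10)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%d", 1:6)))
  m <- quant_matrix(abs(x) + 1)
  ml <- log10_transform(m)
  p <- pca_with_imputation(ml, 3)
  # complete matrix: imputation is the identity, PCA equals prcomp oracle
  expect_identical(p$imputed$intensity, ml$intensity)
  pr <- prcomp(t(ml$intensity), center = TRUE, scale. = FALSE)
  expect_equal(unname(abs(p$scores[, 1])), abs(unname(pr$x[, 1])), tolerance = 1e-9)
  expect_equal(p$variance_fraction[1],
               unname(pr$sdev[1]^2 / sum(pr$sdev^2)), tolerance = 1e-9)

  # samples on a line in feature space: PC1 carries all variance
  base <- runif(10, 1, 2)
  lin <- sapply(1:5, function(i) base + i * 0.1)
  dimnames(lin) <- list(sprintf("p%02d", 1:10), sprintf("s%d", 1:5))
  pl <- pca_with_imputation(quant_matrix(lin, log_scale = TRUE), 2)
  expect_equal(pl$variance_fraction[1], 1, tolerance = 1e-9)

  # permutation invariance of variance fractions
  perm <- sample(6)
  p2 <- pca_with_imputation(subset_quant(ml, samples = perm), 3)
  expect_equal(p2$variance_fraction, p$variance_fraction, tolerance = 1e-9)

  expect_error(pca_with_imputation(ml, 6), "k_neighbors")
})

test_that("PC1 separates contamination status in a contaminated-vs-pure study", {
  sim <- sim_pure_vs_contaminated(n_each = 8, seed = 21)
  p <- pca_with_imputation(log10_transform(sim$matrix), 3)
  r <- cor(p$scores[, 1], as.numeric(sim$status == "contaminated"))
  expect_gt(abs(r), 0.9)
})
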