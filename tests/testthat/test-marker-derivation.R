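test_that("fold changes: ratios, exclusive alignment, identity case", {
  cont <- qm(c(1e8, 1e8), c(5e6, 5e6), c(2e5, 2e5),
             proteins = c("A", "B", "C"), samples = c("c1", "c2"))
  plas <- qm(c(1e4, 1e4), c(NA, NA), c(4e5, 4e5),
             proteins = c("A", "B", "C"), samples = c("p1", "p2"))
  fc <- compute_fold_changes(cont, plas)
  # plain ratio of linear means
  expect_equal(fc$fold_change[fc$protein_id == "A"], 1e4)
  expect_equal(fc$fold_change[fc$protein_id == "C"], 0.5)
  # exclusive protein aligned at 1.1 x max finite FC
  expect_true(fc$exclusive_flag[fc$protein_id == "B"])
  expect_equal(fc$fold_change[fc$protein_id == "B"], 1.1 * 1e4)

  # identical matrices on both sides: all fold changes are 1
  same <- qm(c(10, 12), c(7, 9), proteins = c("A", "B"), samples = c("r1", "r2"))
  same2 <- qm(c(10, 12), c(7, 9), proteins = c("A", "B"), samples = c("q1", "q2"))
  fc1 <- compute_fold_changes(same, same2)
  expect_equal(fc1$fold_change, c(1, 1))

  # proteins never detected in the contaminant are dropped
  contNA <- qm(c(NA, NA), c(5, 5), proteins = c("A", "B"), samples = c("c1", "c2"))
  fc2 <- compute_fold_changes(contNA, same2)
  expect_equal(fc2$protein_id, "B")

  expect_error(compute_fold_changes(
    qm(1, proteins = "X", samples = "c1"),
    qm(1, proteins = "Y", samples = "p1")), "no proteins")
})

# independent brute-force filter oracle: per-protein loop, conjunction of
# the four published criteria, sorted by FC desc then id
brute_force_panel <- function(tab, crit) {
  keep <- character(0)
  for (i in seq_len(nrow(tab))) {
    ok <- TRUE
    if (!(tab$fold_change[i] > crit$min_fold_change)) ok <- FALSE
    if (!(isTRUE(tab$precursors[i] >= crit$min_precursors))) ok <- FALSE
    if (!(tab$mean_log10_intensity[i] > crit$min_log10_intensity)) ok <- FALSE
    if (!(isTRUE(tab$cv[i] < crit$max_cv))) ok <- FALSE
    if (ok) keep <- c(keep, tab$protein_id[i])
  }
  sub <- tab[tab$protein_id %in% keep, ]
  sub <- sub[order(-sub$fold_change, sub$protein_id), ]
  head(sub$protein_id, crit$panel_size)
}

rand_fc_table <- function(n, seed) {
  set.seed(seed)
  data.frame(protein_id = sprintf("PR%03d", sample(1:999, n)),
             fold_change = 10^runif(n, 0, 5),
             mean_contaminant = 10^runif(n, 4, 10),
             mean_plasma = 10^runif(n, 3, 8),
             mean_log10_intensity = runif(n, 5, 10),
             cv = ifelse(runif(n) < 0.1, NA, runif(n, 0, 0.6)),
             precursors = ifelse(runif(n) < 0.1, NA, sample(1:20, n, TRUE)),
             exclusive_flag = FALSE, stringsAsFactors = FALSE)
}

test_that("select_markers equals the brute-force filter oracle exactly", {
  for (s in 1:20) {
    n <- sample(10:100, 1)
    tab <- rand_fc_table(n, seed = 1000 + s)
    crit <- filter_criteria(sample(c("platelet", "erythrocyte", "pbmc"), 1),
                            min_fold_change = 10^runif(1, 0, 4),
                            min_log10_intensity = runif(1, 5, 9),
                            max_cv = runif(1, 0.05, 0.5),
                            panel_size = sample(1:40, 1))
    got <- suppressWarnings(select_markers(tab, crit))
    expect_identical(panel_proteins(got), brute_force_panel(tab, crit),
                     info = paste("seed", s))
  }
})

test_that("vacuous thresholds keep the top panel_size by fold change", {
  tab <- rand_fc_table(50, seed = 7)
  tab$cv[is.na(tab$cv)] <- 0.1
  tab$precursors[is.na(tab$precursors)] <- 5
  crit <- filter_criteria("platelet", min_fold_change = 0, min_precursors = 0,
                          min_log10_intensity = -Inf, max_cv = Inf,
                          panel_size = 30)
  pan <- select_markers(tab, crit)
  ord <- tab[order(-tab$fold_change, tab$protein_id), ]
  expect_identical(panel_proteins(pan), head(ord$protein_id, 30))
})

test_that("raising any threshold never adds a protein (monotonicity)", {
  tab <- rand_fc_table(80, seed = 21)
  base <- filter_criteria("platelet", min_fold_change = 100,
                          min_log10_intensity = 6, max_cv = 0.4, panel_size = 80)
  p0 <- suppressWarnings(panel_proteins(select_markers(tab, base)))
  tighter <- list(
    filter_criteria("platelet", min_fold_change = 1000, min_log10_intensity = 6,
                    max_cv = 0.4, panel_size = 80),
    filter_criteria("platelet", min_fold_change = 100, min_log10_intensity = 7.5,
                    max_cv = 0.4, panel_size = 80),
    filter_criteria("platelet", min_fold_change = 100, min_log10_intensity = 6,
                    max_cv = 0.2, panel_size = 80),
    filter_criteria("platelet", min_fold_change = 100, min_log10_intensity = 6,
                    max_cv = 0.4, min_precursors = 8, panel_size = 80))
  for (cr in tighter)
    expect_true(all(suppressWarnings(panel_proteins(select_markers(tab, cr))) %in% p0))
})

test_that("markers derived from simulation recover the designed set", {
  w <- test_world()
  ex <- simulate_contaminant_experiment(w$cell, w$plasma, workflow = "neat", seed = 5)
  fc <- compute_fold_changes(ex$contaminant, ex$plasma)
  pan <- suppressWarnings(select_markers(fc, "platelet"))
  expect_true(all(panel_proteins(pan) %in% w$cell$marker_ids))
  expect_length(intersect(panel_proteins(pan), names(w$plasma$abundance)), 0)
  # noiseless panel is a subset of the true exclusive marker set
  wf0 <- wf_identity(1e4)
  ex0 <- simulate_contaminant_experiment(w$cell, w$plasma, workflow = wf0, seed = 6)
  fc0 <- compute_fold_changes(ex0$contaminant, ex0$plasma)
  pan0 <- suppressWarnings(select_markers(
    fc0, filter_criteria("platelet", max_cv = Inf, min_precursors = 0)))
  expect_true(all(panel_proteins(pan0) %in% w$cell$marker_ids))
})

test_that("panel comparison: identity, disjoint, and stability under noise", {
  w <- test_world()
  self <- compare_panels(w$panel, w$panel, depth = 30)
  expect_equal(self$overlap, 30); expect_equal(self$jaccard, 1)
  other <- as_marker_panel(paste0("X", 1:30), "platelet")
  expect_equal(compare_panels(w$panel, other, depth = 30)$overlap, 0)
  expect_error(compare_panels(w$panel, as_marker_panel("A", "pbmc")), "different cell types")
  # depth beyond panel length: truncation note
  short <- as_marker_panel(panel_proteins(w$panel)[1:5], "platelet")
  cmp <- compare_panels(w$panel, short, depth = 30)
  expect_equal(cmp$depth_used, 5)
  expect_match(cmp$note, "truncated")

  # two independent-noise derivations of the same truth stay concordant
  pans <- lapply(c(1, 2), function(s) {
    ex <- simulate_contaminant_experiment(w$cell, w$plasma, workflow = "neat", seed = s)
    suppressWarnings(select_markers(compute_fold_changes(ex$contaminant, ex$plasma),
                                    "platelet"))
  })
  stab <- compare_panels(pans[[1]], pans[[2]], depth = 30)
  expect_gte(stab$overlap, 25)
})

test_that("published reference panels carry the expected gene symbols", {
  ref <- reference_marker_panels()
  expect_equal(ref$platelet[1], "ACTB")
  expect_equal(ref$erythrocyte[1], "HBB")
  expect_length(ref$pbmc, 5)
})
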