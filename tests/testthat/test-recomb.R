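test_that("divergence filtering drops outliers and enforces the minimum set", {
  fam <- simulate_clonal_family(4, 400, 0.05, seed = 3)
  kept <- prepare_alignment(fam, 0.5)
  expect_equal(nrow(kept), 4L)
  expect_length(attr(kept, "dropped"), 0L)
  ## an unrelated sequence (~25% identity to the family) is dropped
  out <- rbind(fam, outlier = strsplit(random_dna_str(400, seed = 9),
                                       "")[[1]])
  kept2 <- prepare_alignment(out, 0.5)
  expect_equal(attr(kept2, "dropped"), "outlier")
  expect_error(prepare_alignment(fam[1:2, ]), "at least 3")
  expect_error(prepare_alignment(rbind(t1 = strsplit("AAAA", "")[[1]],
                                       t2 = strsplit("TTTT", "")[[1]],
                                       t3 = strsplit("GGGG", "")[[1]]),
                                 min_mean_identity = 0.9), "fewer than 3")
})

test_that("MaxChi detects planted mosaics with accurate breakpoints", {
  pp <- recomb_params(n_permutations = 200)
  for (sd in 1:5) {
    tri <- simulate_mosaic_triplet(800, 0.10, seed = sd)
    e <- maxchi_scan(tri$aln, c("rec", "pA", "pB"), pp, seed = sd)
    expect_equal(nrow(e), 1L)
    expect_lte(e$maxchi_p, 0.01)
    ## breakpoint within 10 variable sites of the planted position
    varsites <- which(tri$aln["pA", ] != tri$aln["pB", ])
    truth_site <- sum(varsites <= tri$breakpoint)
    expect_lte(abs(e$breakpoint_site - truth_site), 10L)
  }
  ## identical parents: no informative sites, no test
  aln <- simulate_clonal_family(2, 500, 0.05, seed = 4)
  aln <- rbind(aln, pB = aln["t2", ])
  expect_equal(nrow(maxchi_scan(aln, c("t1", "t2", "pB"), pp, seed = 1)), 0L)
})

test_that("MaxChi is deterministic under a fixed seed and calm on clonal data", {
  pp <- recomb_params(n_permutations = 150)
  fam <- simulate_clonal_family(3, 700, 0.08, seed = 21)
  e1 <- maxchi_scan(fam, c("t1", "t2", "t3"), pp, seed = 77)
  e2 <- maxchi_scan(fam, c("t1", "t2", "t3"), pp, seed = 77)
  expect_identical(e1, e2)
  hits <- 0L
  for (sd in 1:20) {
    fam <- simulate_clonal_family(3, 700, 0.08, seed = 100 + sd)
    e <- maxchi_scan(fam, c("t1", "t2", "t3"), pp, seed = sd)
    if (nrow(e) && e$significant) hits <- hits + 1L
  }
  expect_lte(hits, 3L)   # ~binomial(20, 0.05) upper tail
})

test_that("the window distance scan finds a single switch near the breakpoint", {
  pp <- recomb_params()
  tri <- simulate_mosaic_triplet(900, 0.10, breakpoint = 450L, seed = 8)
  e <- window_distance_scan(tri$aln, c("rec", "pA", "pB"), pp)
  expect_equal(nrow(e), 1L)
  expect_true(e$significant)
  expect_lte(abs(e$breakpoint_col - 450L), 120L)
  ## candidate equidistant from identical parents: no informative windows
  fam <- simulate_clonal_family(2, 600, 0.05, seed = 5)
  aln <- rbind(cand = fam["t1", ], pA = fam["t2", ], pB = fam["t2", ])
  expect_equal(nrow(window_distance_scan(aln, c("cand", "pA", "pB"), pp)), 0L)
  ## degenerate: step larger than the alignment gives a single window
  pp2 <- recomb_params(window_cols = 2000L, step_cols = 3000L)
  expect_equal(nrow(window_distance_scan(tri$aln, c("rec", "pA", "pB"),
                                         pp2)), 0L)
})

test_that("the consensus rule excludes only doubly flagged recombinants", {
  aln <- simulate_clonal_family(4, 300, 0.05, seed = 6)
  e_mx <- data.frame(recombinant_id = c("t1", "t2"),
                     parentA_id = "t3", parentB_id = "t4",
                     breakpoint_col = c(150L, 160L),
                     maxchi_chi2 = c(12, 11), maxchi_p = c(0.01, 0.02),
                     significant = c(TRUE, TRUE), stringsAsFactors = FALSE)
  e_ws <- data.frame(recombinant_id = "t1", parentA_id = "t3",
                     parentB_id = "t4", breakpoint_col = 155L,
                     winscan_support = 0.95, significant = TRUE,
                     stringsAsFactors = FALSE)
  res <- consensus_and_exclude(e_mx, e_ws, aln)
  ev <- res$events
  expect_true(ev$consensus[ev$recombinant_id == "t1"])
  expect_false(ev$consensus[ev$recombinant_id == "t2"])  # MaxChi only
  expect_setequal(rownames(res$pruned), c("t2", "t3", "t4"))
  ## no events at all: pruned alignment equals the input
  res0 <- consensus_and_exclude(e_mx[0, ], e_ws[0, ], aln)
  expect_identical(res0$pruned, mhciscan:::.aln_matrix(aln))
})

test_that("the full screen flags a planted mosaic among clonal background", {
  pp <- recomb_params(n_permutations = 150)
  tri <- simulate_mosaic_triplet(800, 0.10, seed = 12)
  fam <- simulate_clonal_family(5, 800, 0.08, seed = 12)
  aln <- rbind(tri$aln, fam)
  res <- scan_recombination(aln, pp, seed = 12)
  expect_true("rec" %in% res$events$recombinant_id[res$events$consensus])
  expect_false("rec" %in% rownames(res$pruned))
  ## determinism
  res2 <- scan_recombination(aln, pp, seed = 12)
  expect_identical(res$events, res2$events)
})
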