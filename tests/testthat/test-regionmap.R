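test_that("framework markers are located at their planted positions", {
  sim <- default_sim()
  ml <- locate_markers(sim$assembly, sim$panel$markers)
  expect_setequal(ml$marker, sim$marker_truth$marker)
  for (i in seq_len(nrow(sim$marker_truth))) {
    tr <- sim$marker_truth[i, ]
    got <- ml[ml$marker == tr$marker, ]
    expect_equal(nrow(got), 1L)
    expect_equal(got$scaffold_id, tr$scaffold_id)
    expect_lte(abs(got$g_start - tr$start), 50L)
    expect_lte(abs(got$g_end - tr$end), 50L)
    expect_false(got$ambiguous)
  }
})

test_that("blocks are defined between their bounding markers in order", {
  sim <- default_sim()
  ml <- locate_markers(sim$assembly, sim$panel$markers)
  bl <- define_blocks(ml)
  expect_true(all(bl$defined))
  g <- function(b) bl[bl$block == b, ]
  ## alpha, kappa, beta disjoint and ordered on the region scaffold
  expect_lt(g("alpha")$g_end, g("kappa")$g_start)
  expect_lt(g("kappa")$g_end, g("beta")$g_start)
  expect_lt(g("extendedI")$g_end, g("alpha")$g_start)
})

test_that("blocks are undefined across scaffolds and ambiguous markers error", {
  ml <- data.frame(
    marker = c("TRIM26", "ABCF1", "MOG", "RNF39"),
    scaffold_id = c("s1", "s2", "s1", "s1"),
    g_start = c(100L, 100L, 5000L, 9000L),
    g_end = c(700L, 700L, 5600L, 9600L),
    strand = "+", best_evalue = 1e-40, ambiguous = FALSE,
    stringsAsFactors = FALSE)
  bl <- define_blocks(ml)
  expect_false(bl$defined[bl$block == "kappa"])
  expect_true(bl$defined[bl$block == "alpha"])
  ml2 <- rbind(ml, data.frame(marker = "TRIM26", scaffold_id = "s3",
                              g_start = 1L, g_end = 600L, strand = "+",
                              best_evalue = 1e-30, ambiguous = TRUE,
                              stringsAsFactors = FALSE))
  ml2$ambiguous[ml2$marker == "TRIM26"] <- TRUE
  expect_error(define_blocks(ml2), "ambiguous")
})

test_that("genes are assigned by midpoint and default to outside", {
  blocks <- data.frame(block = c("alpha", "kappa", "beta", "extendedI"),
                       scaffold_id = c("s1", "s1", "s1", NA),
                       g_start = c(1000L, 5000L, 9000L, NA),
                       g_end = c(4000L, 8000L, 12000L, NA),
                       defined = c(TRUE, TRUE, TRUE, FALSE),
                       stringsAsFactors = FALSE)
  models <- data.frame(locus_id = c("a", "b", "c", "d"),
                       scaffold_id = c("s1", "s1", "s2", "s1"),
                       g_start = c(5500L, 950L, 100L, 8500L),
                       g_end = c(6500L, 1500L, 1100L, 9500L),
                       stringsAsFactors = FALSE)
  out <- assign_genes(models, blocks)
  expect_equal(out$assignment, c("kappa", "alpha", "outside", "beta"))
  ## b: midpoint 1225 inside alpha; d: midpoint 9000 at beta start (closed
  ## left edge)
})

test_that("splits are reported above the gap threshold only", {
  ml <- data.frame(marker = c("TRIM26", "ABCF1"), scaffold_id = "s1",
                   g_start = c(0L, 4000000L), g_end = c(600L, 4000600L),
                   strand = "+", best_evalue = 1e-40, ambiguous = FALSE,
                   stringsAsFactors = FALSE)
  bl <- define_blocks(ml)
  models <- data.frame(locus_id = c("g1", "g2"), scaffold_id = "s1",
                       g_start = c(1000000L, 3200000L),
                       g_end = c(1002000L, 3202000L),
                       assignment = "kappa", stringsAsFactors = FALSE)
  sp <- detect_splits(ml, bl, models, gap_threshold_bp = 1e6)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$gap_bp, 3200000 - 1002000)
  expect_equal(sp$left_feature, "g1")
  expect_equal(sp$right_feature, "g2")
  ## raising the threshold above the planted gap removes it
  expect_equal(nrow(detect_splits(ml, bl, models, gap_threshold_bp = 3e6)),
               0L)
  ## compact block: no splits
  models2 <- models; models2$g_start <- c(1000000L, 1010000L)
  models2$g_end <- c(1002000L, 1012000L)
  expect_gte(nrow(detect_splits(ml, bl, models2, 1e6)), 1L) # marker gaps
  ml3 <- ml; ml3$g_start <- c(0L, 30000L); ml3$g_end <- c(600L, 30600L)
  bl3 <- define_blocks(ml3)
  models3 <- data.frame(locus_id = "g1", scaffold_id = "s1",
                        g_start = 10000L, g_end = 12000L,
                        assignment = "kappa", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_splits(ml3, bl3, models3, 1e6)), 0L)
})

test_that("block assignment matches planted truth and is orientation invariant", {
  run <- default_run()
  sim <- default_sim()
  mm <- match_truth(run$gene_models$models, sim$truth)
  expect_equal(mean(mm$assignment == mm$block_label), 1)
  ## reverse-complement the whole assembly: assignments must not change
  rc <- Biostrings::reverseComplement(sim$assembly)
  ml <- locate_markers(rc, sim$panel$markers)
  bl <- define_blocks(ml)
  L <- setNames(Biostrings::width(sim$assembly), names(sim$assembly))
  flipped <- run$gene_models$models
  gs <- flipped$g_start
  flipped$g_start <- L[flipped$scaffold_id] - flipped$g_end
  flipped$g_end <- L[flipped$scaffold_id] - gs
  out <- assign_genes(flipped, bl)
  expect_equal(out$assignment, run$gene_models$models$assignment)
})
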