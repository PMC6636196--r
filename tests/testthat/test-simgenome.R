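test_that("configuration invariants are enforced", {
  expect_error(sim_config(exon_lengths = c(73, 270, 276, 276, 117, 150)),
               "multiple of 3")
  expect_error(sim_config(exon_lengths = c(72, 270, 276)), "six")
  expect_error(sim_config(divergence = 0.8), "divergence")
  expect_error(sim_config(insertion_alleles = c(2L)), "subset")
  expect_error(sim_config(intergenic_gc = 1.2), "\\[0, 1\\]")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(sum(cfg$exon_lengths) %% 3L, 0L)
})

test_that("simulated coding sequences are valid ORFs with annotated domains", {
  cfg <- sim_config(seed = 9)
  base <- simulate_mhci_cds(cfg)
  expect_equal(substr(base$cds, 1, 3), "ATG")
  expect_true(substr(base$cds, nchar(base$cds) - 2, nchar(base$cds)) %in%
                c("TAA", "TAG", "TGA"))
  expect_equal(nchar(base$cds), sum(cfg$exon_lengths))
  expect_false(grepl("*", base$protein, fixed = TRUE))
  expect_equal(nrow(base$domains), 6L)
  expect_equal(base$domains$nt_end[6], nchar(base$cds))
  ## 3-codon insertion allele: +9 nt, frame preserved, still stop-free
  ins3 <- simulate_mhci_cds(cfg, list(name = "x", insertion_codons = 3L,
                                      divergence = 0))
  expect_equal(nchar(ins3$cds), sum(cfg$exon_lengths) + 9L)
  expect_false(grepl("*", ins3$protein, fixed = TRUE))
  expect_equal(nchar(ins3$protein), nchar(base$protein) + 3L)
  ## determinism
  again <- simulate_mhci_cds(cfg, list(name = "x", insertion_codons = 3L,
                                       divergence = 0))
  expect_identical(ins3$cds, again$cds)
  ## divergence stays ORF-preserving
  div <- simulate_mhci_cds(cfg, list(name = "y", insertion_codons = 0L,
                                     divergence = 0.05))
  expect_false(grepl("*", div$protein, fixed = TRUE))
  expect_equal(substr(div$cds, 1, 3), "ATG")
})

test_that("pseudogenization modes plant the intended lesions", {
  cfg <- sim_config(seed = 10)
  cds <- simulate_mhci_cds(cfg)$cds
  ps <- pseudogenize(cds, "premature_stop", seed = 3)
  aa <- Biostrings::translate(Biostrings::DNAString(ps$cds))
  inner <- substr(as.character(aa), 2, nchar(cds) / 3 - 1)
  expect_true(grepl("*", inner, fixed = TRUE))
  fs <- pseudogenize(cds, "frameshift", seed = 3, k = 1)
  expect_true(abs(nchar(fs$cds) - nchar(cds)) %% 3L != 0L)
  expect_error(pseudogenize(cds, "frameshift", seed = 3, k = 3),
               "multiple of three")
  ls_ <- pseudogenize(cds, "lost_start", seed = 3)
  expect_false(substr(ls_$cds, 1, 3) == "ATG")
  expect_equal(substr(ls_$cds, 4, nchar(cds)), substr(cds, 4, nchar(cds)))
  lst <- pseudogenize(cds, "lost_stop", seed = 3)
  n <- nchar(lst$cds)
  expect_false(substr(lst$cds, n - 2, n) %in% c("TAA", "TAG", "TGA"))
  expect_error(pseudogenize(cds, "nonsense_mode"), "unknown")
})

test_that("mosaic recombinants follow the breakpoint structure exactly", {
  a <- strrep("A", 100); b <- strrep("G", 100)
  expect_equal(simulate_recombinant(a, b)$seq, a)
  half <- simulate_recombinant(a, b, 50)
  expect_equal(half$seq, paste0(strrep("A", 50), strrep("G", 50)))
  ## two breakpoints: positionwise oracle against a hand-rolled mosaic
  pa <- random_dna_str(90, seed = 31); pb <- random_dna_str(90, seed = 32)
  mos <- simulate_recombinant(pa, pb, c(30, 60))
  expected <- paste0(substr(pa, 1, 30), substr(pb, 31, 60),
                     substr(pa, 61, 90))
  expect_equal(mos$seq, expected)
  expect_equal(unname(table(mos$origin)["B"]), 30L)
  expect_error(simulate_recombinant(pa, pb, c(60, 30)), "sorted")
  expect_error(simulate_recombinant(pa, pb, 90), "range")
  expect_error(simulate_recombinant(pa, substr(pb, 1, 50)), "equal length")
})

test_that("planted assemblies satisfy the truth round-trip byte for byte", {
  sim <- default_sim()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    slice <- as.character(Biostrings::subseq(sim$assembly[[tr$scaffold_id]],
                                             tr$start + 1L, tr$end))
    expect_identical(slice, as.character(sim$gene_seqs[[tr$locus_id]]))
  }
})

test_that("truth accounting closes and block placement matches the marker map", {
  sim <- default_sim()
  tr <- sim$truth
  expect_equal(sum(tr$planted_completeness == "intact") +
                 sum(tr$planted_completeness == "partial"), nrow(tr))
  expect_equal(sum(tr$planted_class == "PFG") +
                 sum(tr$planted_class == "pseudogene"), nrow(tr))
  ## kappa genes lie between the planted TRIM26 and ABCF1 markers
  mk <- sim$marker_truth
  t26 <- mk[mk$marker == "TRIM26", ]; ab <- mk[mk$marker == "ABCF1", ]
  kap <- tr[tr$block_label == "kappa", ]
  expect_gt(nrow(kap), 0)
  expect_true(all(kap$start > t26$end & kap$end < ab$start))
  ## partial genes carry an adjacent N-run
  par <- tr[tr$planted_completeness == "partial", ]
  for (i in seq_len(nrow(par))) {
    sc <- as.character(sim$assembly[[par$scaffold_id[i]]])
    win <- substr(sc, max(1, par$start[i] - 500), par$end[i] + 500)
    expect_true(grepl("N{10,}", win))
  }
  ## every recombinant records an interior breakpoint
  rec <- tr[tr$breakpoints != "", ]
  expect_gte(nrow(rec), 1L)
  bp <- as.integer(rec$breakpoints[1])
  expect_gt(bp, 0); expect_lt(bp, rec$end[1] - rec$start[1])
})

test_that("identical seeds give byte-identical assemblies and truth", {
  s1 <- plant_scaffolds(sim_config(seed = 77,
                                   scaffold_length = c(120000L, 40000L,
                                                       40000L)))
  s2 <- plant_scaffolds(sim_config(seed = 77,
                                   scaffold_length = c(120000L, 40000L,
                                                       40000L)))
  expect_identical(as.character(s1$assembly), as.character(s2$assembly))
  expect_identical(s1$truth, s2$truth)
})

test_that("features that overflow a scaffold raise an error naming it", {
  expect_error(plant_scaffolds(sim_config(scaffold_length = c(5000L, 45000L,
                                                              45000L))),
               "scaffold_1")
})

test_that("simulation output round-trips through the written files", {
  dir <- withr::local_tempdir()
  sim <- default_sim()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths["assembly"])
  expect_identical(as.character(fa), as.character(sim$assembly))
  gff <- read_gff3(paths["truth_gff"])
  expect_equal(nrow(gff), nrow(sim$truth))
  expect_equal(gff$start, sim$truth$start + 1L)   # GFF3 is 1-based closed
  tsv <- read_tsv(paths["truth_tsv"])
  expect_equal(tsv$locus_id, sim$truth$locus_id)
  ## FASTA wrapped at 60 columns
  lines <- readLines(paths["assembly"], n = 5)
  expect_equal(nchar(lines[2]), 60L)
})
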