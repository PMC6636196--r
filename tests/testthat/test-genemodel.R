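test_that("the PFG/pseudogene decision table is reproduced exactly", {
  ## exhaustive over the rule inputs
  grid <- expand.grid(intact = c(TRUE, FALSE), has_start = c(TRUE, FALSE),
                      has_terminal_stop = c(TRUE, FALSE),
                      frameshift_events = c(0L, 1L),
                      premature_stops = c(0L, 2L),
                      flanking_N = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    out <- classify(as.list(g))
    clean <- g$frameshift_events == 0 && g$premature_stops == 0
    if (g$intact) {
      expect_equal(out$completeness, "intact")
      expected <- clean && g$has_start && g$has_terminal_stop
    } else {
      expect_equal(out$completeness, "partial")
      expected <- clean && g$flanking_N
    }
    expect_equal(out$functional_class == "PFG", expected,
                 info = paste(capture.output(print(g)), collapse = " "))
  }
  ## in-frame indels never pseudogenize: the rule has no indel input other
  ## than frameshift events
  m <- list(intact = TRUE, has_start = TRUE, has_terminal_stop = TRUE,
            frameshift_events = 0L, premature_stops = 0L, flanking_N = FALSE,
            net_indel_codons = 5L)
  expect_equal(classify(m)$functional_class, "PFG")
})

test_that("similarity confirmation applies a strict greater-than threshold", {
  base <- random_dna_str(300, seed = 41)
  mutate_n <- function(dna, n) {
    x <- strsplit(dna, "")[[1]]
    set.seed(99)
    idx <- sample(10:(length(x) - 10), n)   # keep ends intact so the
                                            # overlap alignment is gapless
    for (i in idx) x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
    paste(x, collapse = "")
  }
  panel <- Biostrings::DNAStringSet(c(ref = base))
  ## exactly 30/300 mismatches -> identity 0.90 -> dropped
  at90 <- similarity_confirmation(mutate_n(base, 30), panel, threshold = 0.90)
  expect_equal(at90$identity, 0.90, tolerance = 1e-9)
  expect_false(at90$keep)
  ## 27/300 -> 0.91 -> kept
  at91 <- similarity_confirmation(mutate_n(base, 27), panel, threshold = 0.90)
  expect_equal(at91$identity, 0.91, tolerance = 1e-9)
  expect_true(at91$keep)
  expect_error(similarity_confirmation(base, Biostrings::DNAStringSet()),
               "empty")
})

test_that("domain presence follows reference-column coverage", {
  prot <- random_protein(120, seed = 42)
  cds <- backtranslate_simple(prot)
  dt <- data.frame(exon = 1:6,
                   domain = c("leader", "alpha1", "alpha2", "alpha3",
                              "intercellular", "cytoplasmic"),
                   aa_start = c(1, 21, 41, 61, 81, 101),
                   aa_end = c(20, 40, 60, 80, 100, 120))
  full <- frame_aware_align(cds, prot)
  expect_true(all(infer_domains(full, dt)))
  ## truncation before the last domain loses only the cytoplasmic tail
  part <- frame_aware_align(substr(cds, 1, 300), prot)
  pres <- infer_domains(part, dt)
  expect_false(pres["cytoplasmic"])
  expect_true(all(pres[1:5]))
  expect_false(any(infer_domains(NULL, dt)))
})

test_that("recovered gene models match planted classes on the default scenario", {
  run <- default_run()
  sim <- default_sim()
  mm <- match_truth(run$gene_models$models, sim$truth)
  expect_equal(nrow(mm), nrow(sim$truth))     # every planted locus recovered
  acc <- mean(mm$completeness == mm$planted_completeness &
                mm$functional_class == mm$planted_class)
  expect_gte(acc, 0.95)
  expect_true(all(mm$confirmed))
  ## adding a premature stop flips any PFG to pseudogene and back (rule
  ## monotonicity)
  one <- as.list(mm[mm$functional_class == "PFG" &
                      mm$completeness == "intact", ][1, ])
  one$intact <- TRUE
  expect_equal(classify(one)$functional_class, "PFG")
  one$premature_stops <- 1L
  expect_equal(classify(one)$functional_class, "pseudogene")
  one$premature_stops <- 0L
  expect_equal(classify(one)$functional_class, "PFG")
})

test_that("repertoire accounting closes and formats the scaffold multiset", {
  expect_equal(repertoire_table(NULL)$gene, 0L)
  m <- data.frame(scaffold_id = c("s1", "s2", "s3"),
                  functional_class = c("PFG", "PFG", "pseudogene"),
                  completeness = c("intact", "partial", "intact"),
                  stringsAsFactors = FALSE)
  tab <- repertoire_table(m)
  expect_equal(tab$gene, 3L)
  expect_equal(tab$pfg + tab$pseudogene, tab$gene)
  expect_equal(tab$full_length + tab$partial, tab$gene)
  expect_equal(tab$gene_scaffold, "1^3")
  m2 <- data.frame(scaffold_id = c("s1", "s1", "s2"),
                   functional_class = "PFG", completeness = "intact",
                   stringsAsFactors = FALSE)
  expect_equal(repertoire_table(m2)$gene_scaffold, "2^1;1^1")
  ## the default run's table closes against its own models
  run <- default_run()
  tab <- run$repertoire
  mdl <- run$gene_models$models
  expect_equal(tab$gene, nrow(mdl))
  expect_equal(tab$pfg, sum(mdl$functional_class == "PFG"))
  expect_equal(tab$full_length, sum(mdl$completeness == "intact"))
})
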