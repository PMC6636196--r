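test_that("six-frame translation produces the expected frames and errors on empty input", {
  fr <- six_frame_translate("ATGGCC")
  plus1 <- Filter(function(f) f$strand == "+" && f$frame == 0, fr)[[1]]
  expect_equal(plus1$aa, "MA")
  fr2 <- six_frame_translate("ATGTAA")
  plus1b <- Filter(function(f) f$strand == "+" && f$frame == 0, fr2)[[1]]
  expect_equal(plus1b$aa, "M*")
  expect_length(fr, 6L)
  expect_error(six_frame_translate(""), "empty")
})

test_that("a reverse-complemented CDS appears in exactly one minus-strand frame", {
  prot <- random_protein(60, seed = 11)
  cds <- backtranslate_simple(prot)
  dna <- paste0(random_dna_str(101, seed = 2),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(cds))),
                random_dna_str(50, seed = 3))
  fr <- six_frame_translate(dna)
  hits <- vapply(fr, function(f)
    f$strand == "-" && grepl(prot, f$aa, fixed = TRUE), logical(1))
  expect_equal(sum(hits), 1L)
})

test_that("amino-acid coordinates map back to the correct genomic interval", {
  prot <- random_protein(40, seed = 12)
  cds <- backtranslate_simple(prot)
  lead <- 7L
  dna <- paste0(random_dna_str(lead, seed = 4), cds,
                random_dna_str(30, seed = 5))
  fr <- six_frame_translate(dna)
  for (f in fr) {
    at <- regexpr(prot, f$aa, fixed = TRUE)
    if (at > 0) {
      g <- aa_to_genomic(f, at, at + nchar(prot) - 1L)
      expect_equal(substr(dna, g[1] + 1L, g[2]), cds)
    }
  }
})

test_that("Karlin-Altschul E-values follow the closed form and its identities", {
  p <- search_params(lambda_ka = 0.3176, k_ka = 0.134)
  ## S chosen so lambda*S = ln(K m n) gives E = 1
  m <- 200; n <- 1e6
  S <- log(p$k_ka * m * n) / p$lambda_ka
  expect_equal(evalue(S, m, n, p), 1, tolerance = 1e-12)
  ## linear in database size
  expect_equal(evalue(120, m, 2 * n, p), 2 * evalue(120, m, n, p))
  ## direct closed-form evaluation
  expect_equal(evalue(120, 200, 1e6, p),
               0.134 * 200 * 1e6 * exp(-0.3176 * 120))
  expect_error(evalue(100, 0, 1e6, p), "positive")
})

test_that("a planted back-translated CDS is recovered as one near-full-length hit", {
  prot <- random_protein(300, seed = 13)
  cds <- backtranslate_simple(prot)
  dna <- paste0(random_dna_str(3000, seed = 6), cds,
                random_dna_str(3000, seed = 7))
  hits <- seed_and_extend(prot, dna, search_params())
  hits <- hits[hits$evalue <= 1e-10, ]
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$raw_score), ]
  expect_equal(best$strand, "+")
  expect_gte((best$q_end - best$q_start + 1) / nchar(prot), 0.95)
  ## mapped genomic interval translates back to the aligned query segment
  seg <- substr(dna, best$g_start + 1L, best$g_end)
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(seg))),
               substr(prot, best$q_start, best$q_end))
  ## minus-strand recovery
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  hits_rc <- seed_and_extend(prot, rc, search_params())
  hits_rc <- hits_rc[hits_rc$evalue <= 1e-10, ]
  expect_equal(hits_rc$strand[which.max(hits_rc$raw_score)], "-")
})

test_that("an unrelated query finds nothing significant in a random scaffold", {
  dna <- random_dna_str(100000, seed = 8)
  prot <- random_protein(250, seed = 14)
  hits <- seed_and_extend(prot, dna, search_params())
  expect_equal(sum(hits$evalue <= 1e-10), 0L)
})

test_that("queries shorter than the seed length are rejected", {
  expect_error(seed_and_extend("MKL", random_dna_str(1000, seed = 9),
                               search_params(seed_k = 4)), "seed_k")
})

test_that("best hit score matches full Smith-Waterman whenever a seed lies in the optimum", {
  mat <- score_matrix("BLOSUM62")
  p <- search_params()
  for (sd in 1:5) {
    prot <- random_protein(120, seed = 20 + sd)
    cds <- backtranslate_simple(prot)
    set.seed(sd)
    ## substitution-diverged copy (~5% nt) inside a short scaffold
    x <- strsplit(cds, "")[[1]]
    mut <- which(runif(length(x)) < 0.05)
    for (i in mut) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    dna <- paste0(random_dna_str(800, seed = sd + 40),
                  paste(x, collapse = ""), random_dna_str(800, seed = sd + 50))
    hits <- seed_and_extend(prot, dna, p)
    expect_gte(nrow(hits), 1L)
    f <- six_frame_translate(dna)
    sw_best <- max(vapply(f, function(fi) {
      if (nchar(fi$aa) < 10) return(0)
      Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::AAString(prot), Biostrings::AAString(fi$aa),
        type = "local", substitutionMatrix = mat,
        gapOpening = p$gap_open, gapExtension = p$gap_extend))
    }, 0))
    expect_equal(max(hits$raw_score), sw_best)
  }
})

test_that("redundant hits merge into loci with strand separation and best E-value", {
  h <- data.frame(
    query_id = c("q1", "q2", "q3", "q1", "q1"),
    scaffold_id = "s1",
    g_start = c(1000L, 1000L, 1000L, 2200L, 5000L),
    g_end = c(1900L, 1900L, 1900L, 3100L, 5900L),
    strand = c("+", "+", "+", "+", "-"),
    frame = 0L, q_start = 1L, q_end = 300L, s_start = 1L, s_end = 300L,
    raw_score = 500, bit_score = 200,
    evalue = c(1e-50, 1e-60, 1e-40, 1e-45, 1e-30),
    stringsAsFactors = FALSE)
  ## gap 1900 -> 2200 is 300 <= 1000: merged; the minus-strand hit is separate
  ls <- merge_redundant_hits(h, max_locus_gap = 1000L)
  expect_equal(nrow(ls$loci), 2L)
  plus <- ls$loci[ls$loci$strand == "+", ]
  expect_equal(plus$n_hits, 4L)
  expect_equal(plus$best_evalue, 1e-60)   # identical-interval hits keep best
  expect_equal(plus$g_start, 1000L)
  expect_equal(plus$g_end, 3100L)
  ## same coordinates on opposite strands stay two loci
  h2 <- h[c(1, 5), ]
  h2$g_start <- 1000L; h2$g_end <- 1900L
  expect_equal(nrow(merge_redundant_hits(h2, 1000L)$loci), 2L)
})

test_that("the 400-nt length filter is strict on 'shorter than'", {
  mk <- function(span) {
    h <- data.frame(query_id = "q", scaffold_id = "s", g_start = 0L,
                    g_end = span, strand = "+", frame = 0L, q_start = 1L,
                    q_end = 10L, s_start = 1L, s_end = 10L, raw_score = 100,
                    bit_score = 40, evalue = 1e-20, stringsAsFactors = FALSE)
    merge_redundant_hits(h, 1000L)
  }
  expect_equal(nrow(length_filter(mk(399L), min_nt = 400L)$loci), 0L)
  expect_equal(nrow(length_filter(mk(400L), min_nt = 400L)$loci), 1L)
  empty <- merge_redundant_hits(mk(400L)$hits[0, ], 1000L)
  expect_equal(nrow(length_filter(empty, 400L)$loci), 0L)
})
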