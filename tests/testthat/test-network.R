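test_that("Jukes-Cantor distances follow the closed form with pairwise deletion", {
  a <- strrep("ACGT", 25)
  m <- rbind(s1 = strsplit(a, "")[[1]], s2 = strsplit(a, "")[[1]])
  expect_equal(unname(jc_distance(m)["s1", "s2"]), 0)
  ## p = 0.3 exactly: change 30 of 100 positions
  x <- strsplit(a, "")[[1]]
  y <- x
  for (i in 1:30) y[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
  m2 <- rbind(s1 = x, s2 = y)
  expect_equal(unname(jc_distance(m2)["s1", "s2"]), -0.75 * log(1 - 0.4),
               tolerance = 1e-12)
  ## saturation errors per pair, or caps on request
  z <- x
  for (i in 1:80) z[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
  m3 <- rbind(s1 = x, s2 = z)
  expect_error(jc_distance(m3), "saturation")
  capped <- jc_distance(m3, on_saturation = "cap")
  expect_length(attr(capped, "saturated"), 1L)
  ## gaps are excluded pairwise
  g <- y; g[31:40] <- "-"
  m4 <- rbind(s1 = x, s2 = g)
  p <- 30 / 90
  expect_equal(unname(jc_distance(m4)["s1", "s2"]),
               -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
})

test_that("jc_distance agrees with the ape JC69 oracle", {
  skip_if_not_installed("ape")
  fam <- simulate_clonal_family(6, 500, 0.08, seed = 31)
  D <- jc_distance(fam)
  bin <- ape::as.DNAbin(tolower(fam))
  Dape <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(D[rownames(Dape), colnames(Dape)]), unname(Dape),
               tolerance = 1e-10)
})

test_that("NeighborNet ordering is circular-consistent with additive trees", {
  ## all tree splits must be contiguous arcs of the circular ordering
  is_arc <- function(members, ordering) {
    pos <- sort(match(members, ordering))
    n <- length(ordering)
    contiguous <- function(p) all(diff(p) == 1)
    contiguous(pos) ||
      contiguous(sort(match(setdiff(ordering, members), ordering)))
  }
  for (sd in 1:6) {
    tm <- simulate_additive_metric(6 + sd %% 3, seed = sd)
    ord <- neighbornet_ordering(tm$D)
    for (s in tm$splits)
      expect_true(is_arc(s, ord), info = paste("seed", sd))
  }
  expect_equal(neighbornet_ordering(matrix(1, 3, 3,
                                           dimnames = list(letters[1:3],
                                                           letters[1:3]))),
               c("a", "b", "c"))
  bad <- matrix(runif(16), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  diag(bad) <- 0
  expect_error(neighbornet_ordering(bad), "symmetric")
})

test_that("relabelling leaves the circular ordering unchanged up to rotation", {
  tm <- simulate_additive_metric(7, seed = 11)
  ord1 <- neighbornet_ordering(tm$D)
  set.seed(2)
  perm <- sample(7)
  ord2 <- neighbornet_ordering(tm$D[perm, perm])
  expect_setequal(ord1, ord2)
  expect_identical(ord1, ord2)   # canonical rotation/reflection fixes both
})

test_that("split weights are exact on tree metrics and non-negative always", {
  for (sd in 1:4) {
    tm <- simulate_additive_metric(8, seed = 40 + sd)
    ord <- neighbornet_ordering(tm$D)
    sp <- fit_split_weights(tm$D, ord)
    expect_true(all(sp$weight >= 0))
    got <- setNames(sp$weight, sp$key)
    expect_setequal(names(got), names(tm$weights))
    expect_equal(got[names(tm$weights)], tm$weights, tolerance = 1e-6)
    ## split-implied distances reproduce the metric
    rec <- matrix(0, 8, 8, dimnames = dimnames(tm$D))
    for (k in seq_len(nrow(sp))) {
      side <- strsplit(sp$side[k], "|", fixed = TRUE)[[1]]
      other <- setdiff(rownames(rec), side)
      rec[side, other] <- rec[side, other] + sp$weight[k]
      rec[other, side] <- rec[other, side] + sp$weight[k]
    }
    expect_equal(rec, tm$D, tolerance = 1e-6)
  }
  ## equidistant quartet: fully symmetric trivial splits
  D <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  spq <- fit_split_weights(D, neighbornet_ordering(D))
  triv <- spq[spq$size == 1 | spq$size == 3, ]
  expect_equal(length(unique(round(triv$weight, 9))), 1L)
})

test_that("every emitted split is an interval of the circular ordering", {
  fam <- simulate_clonal_family(8, 400, 0.08, seed = 51)
  net <- neighbornet(fam)
  pos <- setNames(seq_along(net$taxa), net$taxa)
  for (k in seq_len(nrow(net$splits))) {
    side <- strsplit(net$splits$side[k], "|", fixed = TRUE)[[1]]
    p <- sort(pos[side])
    q <- sort(pos[setdiff(net$taxa, side)])
    expect_true(all(diff(p) == 1) || all(diff(q) == 1))
  }
  expect_true(all(net$splits$weight >= 0))
})

test_that("bootstrap support is deterministic and finds well-supported splits", {
  ## two clearly separated clades: one family plus a clade-defining block
  ## of shared substitutions in the second half of the taxa
  aln <- simulate_clonal_family(6, 600, 0.04, seed = 61)
  rownames(aln) <- c(paste0("a", 1:3), paste0("b", 1:3))
  aln[4:6, 1:80] <- chartr("ACGT", "GTAC", aln[4:6, 1:80])
  net <- neighbornet(aln)
  bs1 <- bootstrap_support(aln, net, B = 100, seed = 9)
  bs2 <- bootstrap_support(aln, net, B = 100, seed = 9)
  expect_identical(bs1$splits$support, bs2$splits$support)
  key_ab <- split_key(paste0("a", 1:3), net$taxa)
  expect_true(key_ab %in% bs1$splits$key)
  expect_gt(bs1$splits$support[bs1$splits$key == key_ab], 70)
  expect_true(bs1$splits$strong[bs1$splits$key == key_ab])
})

test_that("the NEXUS export carries taxa, distances and cyclic splits", {
  fam <- simulate_clonal_family(5, 300, 0.05, seed = 71)
  net <- neighbornet(fam)
  path <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(net, path)
  txt <- readLines(path)
  expect_equal(txt[1], "#nexus")
  expect_true(any(grepl("BEGIN Taxa;", txt)))
  expect_true(any(grepl("BEGIN Distances;", txt)))
  expect_true(any(grepl("BEGIN Splits;", txt)))
  expect_true(any(grepl("CYCLE", txt)))
  expect_true(any(grepl(sprintf("nsplits=%d", nrow(net$splits)), txt)))
})
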