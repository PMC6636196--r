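## Recombination screening on aligned class I sequences (exon 2-5 region):
## a MaxChi sliding-window chi-square scan with a permutation test, a
## window distance (parent-affinity) scan, and a consensus rule that excludes
## sequences flagged by both statistics from network building.

#' Recombination-screen parameters
#'
#' @param window_sites MaxChi window width in variable sites (even).
#' @param n_permutations permutations for the MaxChi null (>= 100).
#' @param alpha per-candidate significance level.
#' @param n_parents candidate parents preselected per sequence (the
#'   `n_parents` nearest neighbours; all pairs among them are tested and the
#'   best p-value is Bonferroni-adjusted for the number of pairs).
#' @param window_cols,step_cols window/step (alignment columns) of the
#'   distance scan.
#' @param min_run minimum consecutive windows favoring one parent on each
#'   side of a switch.
#' @param min_support minimum fraction of informative windows consistent
#'   with a single-switch mosaic.
#' @param min_mean_identity sequences whose mean pairwise identity falls
#'   below this are dropped before scanning.
#' @return a `recomb_params` list.
#' @export
recomb_params <- function(window_sites = 40L, n_permutations = 200L,
                          alpha = 0.05, n_parents = 3L,
                          window_cols = 100L, step_cols = 20L,
                          min_run = 3L, min_support = 0.8,
                          min_mean_identity = 0.5) {
  stopifnot(window_sites %% 2L == 0L, n_permutations >= 100L,
            window_cols >= 50L)
  structure(as.list(environment()), class = "recomb_params")
}

## Coerce aligned input (character matrix, named character vector or
## XStringSet) to an upper-case character matrix.
.aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    dn <- dimnames(seqs)
    m <- toupper(seqs)
    dimnames(m) <- dn
  } else {
    nm <- names(seqs)
    v <- toupper(as.character(seqs))
    if (length(unique(nchar(v))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(v, ""))
    rownames(m) <- nm
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

## Pairwise identity over columns where both sequences have A/C/G/T.
.pairwise_identity <- function(m) {
  n <- nrow(m)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  id <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- ok[i, ] & ok[j, ]
    id[i, j] <- id[j, i] <- if (!any(v)) NA else mean(m[i, v] == m[j, v])
  }
  id
}

#' Drop over-divergent sequences from an alignment
#'
#' Sequences whose mean pairwise identity to the others falls below
#' `min_mean_identity` are removed before recombination scanning (the most
#' divergent sequences destabilize triplet-based statistics).
#'
#' @param seqs aligned sequences (character matrix, named vector or
#'   XStringSet); at least 3.
#' @param min_mean_identity threshold in `[0, 1]`.
#' @return character matrix of retained sequences;
#'   `attr(, "dropped")` holds removed names.
#' @export
prepare_alignment <- function(seqs, min_mean_identity = 0.5) {
  m <- .aln_matrix(seqs)
  if (nrow(m) < 3L) stop("need at least 3 sequences")
  id <- .pairwise_identity(m)
  diag(id) <- NA
  mean_id <- rowMeans(id, na.rm = TRUE)
  keep <- mean_id >= min_mean_identity
  if (sum(keep) < 3L)
    stop("fewer than 3 sequences remain after divergence filtering")
  out <- m[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(m)[!keep]
  out
}

## 2x2 chi-square over window halves at every breakpoint, vectorized.
.maxchi_stat <- function(y, h) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  centers <- (h + 1L):(n - h + 1L)
  a <- cs[centers] - cs[centers - h]          # matches-to-A, left half
  cc <- cs[centers + h] - cs[centers]         # matches-to-A, right half
  b <- h - a; d <- h - cc
  num <- 2 * h * (a * d - b * cc)^2
  den <- h * h * (a + cc) * (b + d)
  chi <- ifelse(den > 0, num / den, 0)
  list(chi = chi, centers = centers)
}

#' MaxChi recombination scan for one triplet
#'
#' For candidate vs. parent pair, the informative sites are those where the
#' parents differ and the candidate matches exactly one of them. A window of
#' `window_sites` informative sites slides across them; at each possible
#' breakpoint the two window halves are compared with a 2x2 chi-square of
#' (matches parent A / matches parent B). Significance of the maximum
#' chi-square is assessed by permuting the order of informative sites.
#'
#' @param aln aligned sequences (see [prepare_alignment()]).
#' @param triplet character vector `c(candidate, parentA, parentB)` of row
#'   names.
#' @param params a [recomb_params()].
#' @param seed integer seed for the permutation null.
#' @return data.frame with 0 or 1 row: `recombinant_id`, `parentA_id`,
#'   `parentB_id`, `breakpoint_col` (alignment column of the maximizing
#'   breakpoint), `breakpoint_site` (index among informative sites),
#'   `n_informative`, `maxchi_chi2`, `maxchi_p`, `significant`.
#' @export
maxchi_scan <- function(aln, triplet, params = recomb_params(), seed = 1L) {
  m <- .aln_matrix(aln)
  stopifnot(length(triplet) == 3L, all(triplet %in% rownames(m)))
  cand <- m[triplet[1L], ]; pa <- m[triplet[2L], ]; pb <- m[triplet[3L], ]
  base <- c("A", "C", "G", "T")
  inf <- which(pa != pb & pa %in% base & pb %in% base & cand %in% base &
                 (cand == pa | cand == pb))
  empty <- data.frame(recombinant_id = character(), parentA_id = character(),
                      parentB_id = character(), breakpoint_col = integer(),
                      breakpoint_site = integer(), n_informative = integer(),
                      maxchi_chi2 = numeric(), maxchi_p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  h <- params$window_sites %/% 2L
  if (length(inf) < max(2L, 2L * h)) return(empty)   # too few variable sites
  y <- as.integer(cand[inf] == pa[inf])
  obs <- .maxchi_stat(y, h)
  stat <- max(obs$chi)
  best <- obs$centers[which.max(obs$chi)]
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(params$n_permutations), function(i) {
      max(.maxchi_stat(y[sample.int(length(y))], h)$chi)
    }, 0) >= stat)
  })
  p <- (1 + exceed) / (1 + params$n_permutations)
  data.frame(recombinant_id = triplet[1L], parentA_id = triplet[2L],
             parentB_id = triplet[3L],
             breakpoint_col = inf[best],
             breakpoint_site = best, n_informative = length(inf),
             maxchi_chi2 = stat, maxchi_p = p,
             significant = p <= params$alpha, stringsAsFactors = FALSE)
}

#' Window distance (parent-affinity) scan for one triplet
#'
#' The candidate's p-distance to each parent is computed in sliding windows;
#' a mosaic signal is a single switch of the nearer parent between two runs
#' of at least `min_run` informative windows, with at least `min_support` of
#' all informative windows consistent with the two-segment model.
#'
#' @inheritParams maxchi_scan
#' @return data.frame with 0 or 1 row: ids, `breakpoint_col`,
#'   `winscan_support`, `significant`, plus the per-window affinity profile
#'   in `attr(, "profile")`.
#' @export
window_distance_scan <- function(aln, triplet, params = recomb_params()) {
  m <- .aln_matrix(aln)
  stopifnot(length(triplet) == 3L, all(triplet %in% rownames(m)))
  cand <- m[triplet[1L], ]; pa <- m[triplet[2L], ]; pb <- m[triplet[3L], ]
  base <- c("A", "C", "G", "T")
  L <- ncol(m)
  starts <- seq(1L, max(1L, L - params$window_cols + 1L),
                by = params$step_cols)
  prof <- data.frame(start = starts,
                     mid = pmin(starts + params$window_cols %/% 2L, L),
                     dA = NA_real_, dB = NA_real_)
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(L, starts[k] + params$window_cols - 1L)
    okA <- cand[idx] %in% base & pa[idx] %in% base
    okB <- cand[idx] %in% base & pb[idx] %in% base
    if (any(okA)) prof$dA[k] <- mean(cand[idx][okA] != pa[idx][okA])
    if (any(okB)) prof$dB[k] <- mean(cand[idx][okB] != pb[idx][okB])
  }
  sgn <- sign(prof$dB - prof$dA)    # +1: closer to A, -1: closer to B
  informative <- which(!is.na(sgn) & sgn != 0)
  empty <- data.frame(recombinant_id = character(), parentA_id = character(),
                      parentB_id = character(), breakpoint_col = integer(),
                      winscan_support = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (length(informative) < 2L * params$min_run) {
    attr(empty, "profile") <- prof
    return(empty)
  }
  s <- sgn[informative]
  best_support <- -Inf; best_split <- NA_integer_
  for (k in seq(params$min_run, length(s) - params$min_run)) {
    left <- s[seq_len(k)]; right <- s[(k + 1L):length(s)]
    dl <- sign(sum(left)); dr <- sign(sum(right))
    if (dl == 0 || dr == 0 || dl == dr) next
    support <- (sum(left == dl) + sum(right == dr)) / length(s)
    if (support > best_support) { best_support <- support; best_split <- k }
  }
  if (!is.finite(best_support)) {
    attr(empty, "profile") <- prof
    return(empty)
  }
  bp <- (prof$mid[informative[best_split]] +
           prof$mid[informative[best_split + 1L]]) %/% 2L
  out <- data.frame(recombinant_id = triplet[1L], parentA_id = triplet[2L],
                    parentB_id = triplet[3L], breakpoint_col = bp,
                    winscan_support = best_support,
                    significant = best_support >= params$min_support,
                    stringsAsFactors = FALSE)
  attr(out, "profile") <- prof
  out
}

#' Consensus rule and exclusion list
#'
#' A sequence is a significant recombinant iff flagged by both statistics
#' (the all-methods-agree analog of multi-method consensus screening); the
#' pruned alignment removes significant recombinants.
#'
#' @param events_maxchi,events_winscan event tables from the two scans.
#' @param aln alignment matrix.
#' @return list with `events` (per-candidate merged table incl. `consensus`)
#'   and `pruned` (alignment without significant recombinants).
#' @export
consensus_and_exclude <- function(events_maxchi, events_winscan, aln) {
  m <- .aln_matrix(aln)
  sig1 <- unique(events_maxchi$recombinant_id[events_maxchi$significant])
  sig2 <- unique(events_winscan$recombinant_id[events_winscan$significant])
  both <- intersect(sig1, sig2)
  cands <- union(unique(events_maxchi$recombinant_id),
                 unique(events_winscan$recombinant_id))
  events <- lapply(cands, function(id) {
    e1 <- events_maxchi[events_maxchi$recombinant_id == id, , drop = FALSE]
    e1 <- e1[order(e1$maxchi_p), , drop = FALSE]
    e2 <- events_winscan[events_winscan$recombinant_id == id, , drop = FALSE]
    e2 <- e2[order(-e2$winscan_support), , drop = FALSE]
    data.frame(
      recombinant_id = id,
      parentA_id = if (nrow(e1)) e1$parentA_id[1L] else NA_character_,
      parentB_id = if (nrow(e1)) e1$parentB_id[1L] else NA_character_,
      breakpoint_col = if (nrow(e1)) e1$breakpoint_col[1L]
                       else if (nrow(e2)) e2$breakpoint_col[1L]
                       else NA_integer_,
      maxchi_chi2 = if (nrow(e1)) e1$maxchi_chi2[1L] else NA_real_,
      maxchi_p = if (nrow(e1)) e1$maxchi_p[1L] else NA_real_,
      winscan_support = if (nrow(e2)) e2$winscan_support[1L] else NA_real_,
      maxchi_significant = id %in% sig1,
      winscan_significant = id %in% sig2,
      consensus = id %in% both, stringsAsFactors = FALSE)
  })
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(recombinant_id = character(),
                            consensus = logical())
  list(events = events, pruned = m[!rownames(m) %in% both, , drop = FALSE])
}

#' Full recombination screen of an alignment
#'
#' For every sequence, the `n_parents` nearest neighbours are preselected as
#' candidate parents; every parent pair is tested with MaxChi (best pair
#' kept, Bonferroni-adjusted) and with the window distance scan, and the
#' two-statistic consensus is applied.
#'
#' @param aln aligned sequences.
#' @param params a [recomb_params()].
#' @param seed integer seed (fans out per candidate).
#' @return list as in [consensus_and_exclude()] plus `dropped` (sequences
#'   removed by the divergence filter).
#' @export
scan_recombination <- function(aln, params = recomb_params(), seed = 1L) {
  m <- prepare_alignment(aln, params$min_mean_identity)
  ids <- rownames(m)
  idm <- .pairwise_identity(m)
  ev1 <- list(); ev2 <- list()
  for (cand in ids) {
    others <- setdiff(ids, cand)
    near <- others[order(-idm[cand, others])]
    near <- near[seq_len(min(params$n_parents, length(near)))]
    if (length(near) < 2L) next
    pairs <- utils::combn(near, 2L, simplify = FALSE)
    best <- NULL
    for (pp in pairs) {
      e <- maxchi_scan(m, c(cand, pp), params,
                       seed = derive_seed(seed, paste0("maxchi:", cand)))
      if (nrow(e) && (is.null(best) || e$maxchi_p < best$maxchi_p)) best <- e
    }
    if (!is.null(best)) {
      best$maxchi_p <- min(1, best$maxchi_p * length(pairs))
      best$significant <- best$maxchi_p <= params$alpha
      ev1[[cand]] <- best
      e2 <- window_distance_scan(m, c(cand, best$parentA_id,
                                      best$parentB_id), params)
      if (nrow(e2)) ev2[[cand]] <- e2
    }
  }
  ev1 <- if (length(ev1)) do.call(rbind, ev1) else
    data.frame(recombinant_id = character(), significant = logical(),
               maxchi_p = numeric(), breakpoint_col = integer(),
               parentA_id = character(), parentB_id = character(),
               maxchi_chi2 = numeric())
  ev2 <- if (length(ev2)) do.call(rbind, ev2) else
    data.frame(recombinant_id = character(), significant = logical(),
               winscan_support = numeric(), breakpoint_col = integer())
  res <- consensus_and_exclude(ev1, ev2, m)
  res$dropped <- attr(m, "dropped")
  res
}
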