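## Gene-model curation: reconstruct a spliced candidate coding sequence from
## the translated-search segments of each locus, re-align it codon-aware
## against the best reference protein, infer the six-domain structure, apply
## the functional/pseudogene decision rules, and confirm identity against a
## reference panel.

#' Gene-model parameters
#'
#' @param frameshift_penalty cost of a 1-2 nt frameshift in
#'   [frame_aware_align()].
#' @param gap_codon cost per whole-codon indel.
#' @param coverage_min fraction of a domain's reference columns that must be
#'   aligned for the domain to count as present.
#' @param similarity_threshold strict lower bound on nucleotide identity to
#'   the reference panel ("greater than" semantics: equality is dropped).
#' @param min_query_cov minimum fraction of the locus CDS that must be
#'   aligned for the identity to count.
#' @param exon_join_gap bp; search segments this close are one exon cluster
#'   (must be well below the intron length).
#' @param fill_max_aa extend the terminal exon clusters along their diagonal
#'   by at most this many codons to reach the reference ends (start codon /
#'   terminal stop); larger shortfalls are treated as genuinely missing
#'   sequence.
#' @param flank_window bp scanned beyond each locus end for assembly-gap
#'   N-runs.
#' @param n_run_min minimum N-run length that counts as an assembly gap.
#' @return a `genemodel_params` list.
#' @export
genemodel_params <- function(frameshift_penalty = 30, gap_codon = 12,
                             coverage_min = 0.8, similarity_threshold = 0.90,
                             min_query_cov = 0.6, exon_join_gap = 120L,
                             fill_max_aa = 12L, flank_window = 500L,
                             n_run_min = 10L) {
  structure(as.list(environment()), class = "genemodel_params")
}

## Cluster the genomic intervals of a locus's hits into exon clusters and
## splice a candidate CDS in gene orientation. Terminal clusters are extended
## along the best hit's reading-frame diagonal to reach reference position 1
## and reference end + stop codon, when the shortfall is small.
.extract_cds <- function(locus, hits, scaffold_seq, query, params) {
  query_len <- nchar(query)
  h <- hits[hits$locus_id == locus$locus_id & hits$strand == locus$strand, ,
            drop = FALSE]
  h <- h[order(h$g_start), ]
  ## union adjacent intervals into exon clusters
  ir <- IRanges::IRanges(h$g_start + 1L, h$g_end)
  red <- IRanges::reduce(ir, min.gapwidth = params$exon_join_gap + 1L)
  cl_start <- IRanges::start(red) - 1L
  cl_end <- IRanges::end(red)
  ncl <- length(red)
  ov <- IRanges::findOverlaps(ir, red)
  member <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))

  minus <- locus$strand == "-"
  bq <- locus$best_query
  L <- nchar(scaffold_seq)
  ## gene-order index of clusters (first = exon 1 side)
  ord <- if (minus) rev(seq_len(ncl)) else seq_len(ncl)

  best_in <- function(k) {
    mem <- member[[as.character(k)]]
    hh <- h[mem, , drop = FALSE]
    pref <- hh[hh$query_id == bq, , drop = FALSE]
    if (nrow(pref)) pref[which.max(pref$raw_score), ]
    else hh[which.max(hh$raw_score), ]
  }

  ## leading fill: reach reference column 1 along the anchor hit's diagonal
  k1 <- ord[1L]
  b1 <- best_in(k1)
  gap1 <- b1$q_start - 1L
  if (gap1 > 0L && gap1 <= params$fill_max_aa) {
    if (!minus) cl_start[k1] <- max(0L, b1$g_start - 3L * gap1)
    else cl_end[k1] <- min(L, b1$g_end + 3L * gap1)
  }
  ## trailing fill: reach reference end plus the terminal stop codon
  k2 <- ord[ncl]
  b2 <- best_in(k2)
  gap2 <- query_len - b2$q_end
  if (gap2 <= params$fill_max_aa) {
    ext <- 3L * gap2 + 3L
    if (!minus) cl_end[k2] <- min(L, b2$g_end + ext)
    else cl_start[k2] <- max(0L, b2$g_start - ext)
  }

  q_lo <- vapply(ord, function(k) min(h$q_start[member[[as.character(k)]]]),
                 0L)
  q_hi <- vapply(ord, function(k) max(h$q_end[member[[as.character(k)]]]),
                 0L)
  ## polish internal junctions: reclaim in-frame stub codons that the
  ## peak-trimmed segments left inside the junction gap
  if (ncl > 1L) {
    for (j in seq_len(ncl - 1L)) {
      A <- ord[j]; B <- ord[j + 1L]
      m <- q_lo[j + 1L] - q_hi[j] - 1L
      if (m < 1L || m > 40L) next
      gap <- if (minus) {
        if (cl_start[A] - cl_end[B] < 3L) next
        revcomp(substr(scaffold_seq, cl_end[B] + 1L, cl_start[A]))
      } else {
        if (cl_start[B] - cl_end[A] < 3L) next
        substr(scaffold_seq, cl_end[A] + 1L, cl_start[B])
      }
      missing <- substr(query, q_hi[j] + 1L, q_lo[j + 1L] - 1L)
      kk <- .polish_junction(gap, missing)
      if (kk[1L] > 0L) {
        if (minus) cl_start[A] <- cl_start[A] - 3L * kk[1L]
        else cl_end[A] <- cl_end[A] + 3L * kk[1L]
        q_hi[j] <- q_hi[j] + kk[1L]
      }
      if (kk[2L] > 0L) {
        if (minus) cl_end[B] <- cl_end[B] + 3L * kk[2L]
        else cl_start[B] <- cl_start[B] - 3L * kk[2L]
        q_lo[j + 1L] <- q_lo[j + 1L] - kk[2L]
      }
    }
  }
  pieces <- vapply(ord, function(k)
    substr(scaffold_seq, cl_start[k] + 1L, cl_end[k]), "")
  if (minus) pieces <- vapply(pieces, revcomp, "")
  widths <- nchar(pieces)
  list(cds = paste(pieces, collapse = ""),
       exons = data.frame(g_start = cl_start, g_end = cl_end),
       gene_order = data.frame(g_start = cl_start[ord], g_end = cl_end[ord],
                               cds_end = cumsum(widths),
                               q_lo = q_lo, q_hi = q_hi),
       strand = locus$strand,
       g_start = min(cl_start), g_end = max(cl_end))
}

## Frameshifts whose shifted-frame remainder was too short to produce its
## own search segment leave a gap of missing reference residues at an
## inter-cluster junction, with the skipped nucleotides absent from the
## spliced CDS. Recover them by translating the skipped genomic gap at all
## frame offsets from either end: if the missing residues reappear in a
## shifted frame (but not in frame 0), the junction hides a frameshift.
.rescue_junction_frameshifts <- function(ex, fal, scaffold_seq, query,
                                         min_missing = 3L, min_ident = 0.6,
                                         max_gap_nt = 1000L) {
  go <- ex$gene_order
  ncl <- nrow(go)
  if (ncl < 2L || !nrow(fal$pairs)) return(0L)
  minus <- ex$strand == "-"
  n_fs <- 0L
  for (j in seq_len(ncl - 1L)) {
    ## reference residues between the ungapped cores of adjacent clusters
    m <- go$q_lo[j + 1L] - go$q_hi[j] - 1L
    if (m < min_missing) next
    missing <- substr(query, go$q_hi[j] + 1L, go$q_lo[j + 1L] - 1L)
    gap <- if (minus) {
      if (go$g_start[j] - go$g_end[j + 1L] < 1L) next
      revcomp(substr(scaffold_seq, go$g_end[j + 1L] + 1L, go$g_start[j]))
    } else {
      if (go$g_start[j + 1L] - go$g_end[j] < 1L) next
      substr(scaffold_seq, go$g_end[j] + 1L, go$g_start[j + 1L])
    }
    if (nchar(gap) < 3L * m || nchar(gap) > max_gap_nt) next
    sc <- .two_piece_identity(gap, missing)
    ## evidence scales with the run: three missing residues must all match
    ## in the shifted frame, longer runs need at least four matches
    need <- if (m == 3L) 3L else 4L
    if (sc$shifted >= min_ident && round(sc$shifted * m) >= need &&
        sc$inframe < sc$shifted - 0.2)
      n_fs <- n_fs + 1L
  }
  n_fs
}

## How many missing residues can be reclaimed, in frame, from the two ends
## of a junction gap: `k_head` codons continuing the upstream cluster and
## `k_tail` codons preceding the downstream cluster. A piece is reclaimed
## only while its identity to the corresponding reference residues stays
## >= 0.6 (random intron translation almost never qualifies).
.polish_junction <- function(gap, missing) {
  m <- nchar(missing); G <- nchar(gap)
  mis <- chars(missing)
  ## a premature stop codon inside an otherwise-matching stub counts toward
  ## the reclaim (the codon aligner will then flag it), but the reclaimed
  ## piece must terminate on a true residue match at its open end so that
  ## intron stop codons beyond the exon boundary are never absorbed
  ok <- function(aa, ref, open_end) {
    a <- chars(aa)
    k <- length(a)
    true_m <- sum(a == ref)
    eff <- true_m + sum(a == "*")
    anchored <- if (open_end == "last") a[k] == ref[k] else a[1L] == ref[1L]
    eff / k >= 0.6 && true_m >= 1L && anchored
  }
  k_head <- 0L
  for (k in seq_len(m)) {
    if (3L * k > G) break
    aa <- translate_str(substr(gap, 1L, 3L * k))
    if (nchar(aa) < k) break
    if (ok(aa, mis[seq_len(k)], "last")) k_head <- k
  }
  k_tail <- 0L
  for (k in seq_len(m - k_head)) {
    if (3L * (k_head + k) > G) break
    aa <- translate_str(substr(gap, G - 3L * k + 1L, G))
    if (nchar(aa) < k) break
    if (ok(aa, mis[(m - k + 1L):m], "first")) k_tail <- k
  }
  c(k_head, k_tail)
}

## Best identity between `missing` residues and translations of `gap`
## reassembled as an in-frame piece plus a 1-2 nt shifted piece (the
## signature of a skipped frameshift), anchored at either end of the gap.
## `inframe` is the best single-frame (no shift) identity for comparison.
.two_piece_identity <- function(gap, missing) {
  m <- nchar(missing)
  G <- nchar(gap)
  mis <- chars(missing)
  n_match <- function(aa_str, ref_chars) {
    if (!nchar(aa_str)) return(0L)
    a <- chars(aa_str)
    sum(a == ref_chars[seq_along(a)])
  }
  ## in-frame anchored pieces: prefix of k residues at the gap head,
  ## suffix of k residues at the gap tail
  pre_h <- integer(m + 1L); suf_t <- integer(m + 1L)
  for (k in 0:m) {
    pre_h[k + 1L] <- if (k > 0L)
      n_match(translate_str(substr(gap, 1L, 3L * k)), mis) else 0L
    suf_t[k + 1L] <- if (k > 0L)
      n_match(translate_str(substr(gap, G - 3L * k + 1L, G)),
              mis[(m - k + 1L):m]) else 0L
  }
  ## baseline: an ordinary junction (intron between two undershoot stubs)
  ## explains the missing residues with in-frame pieces at both gap ends
  best_inframe <- 0
  for (k in 0:m)
    best_inframe <- max(best_inframe, (pre_h[k + 1L] + suf_t[m - k + 1L]) / m)
  ## frameshift signature: an anchored in-frame piece plus the remaining
  ## residues in a 1-2 nt shifted frame adjacent to it
  best_shift <- 0
  for (k in 0:(m - 1L)) {
    for (delta in c(-2L, -1L, 1L, 2L)) {
      ## head-anchored: shifted suffix right after the in-frame prefix
      s0 <- 3L * k + delta + 1L
      if (s0 >= 1L && s0 + 3L * (m - k) - 1L <= G) {
        suf <- n_match(translate_str(substr(gap, s0,
                                            s0 + 3L * (m - k) - 1L)),
                       mis[(k + 1L):m])
        best_shift <- max(best_shift, (pre_h[k + 1L] + suf) / m)
      }
      ## tail-anchored: shifted prefix right before the in-frame suffix
      p1 <- G - 3L * k - delta - 3L * (m - k) + 1L
      if (p1 >= 1L && p1 + 3L * (m - k) - 1L <= G) {
        pre2 <- n_match(translate_str(substr(gap, p1,
                                             p1 + 3L * (m - k) - 1L)),
                        mis)
        best_shift <- max(best_shift, (pre2 + suf_t[k + 1L]) / m)
      }
    }
  }
  list(shifted = best_shift, inframe = best_inframe)
}

#' Domain presence from a frame-aware alignment
#'
#' A domain is present when at least `coverage_min` of its reference columns
#' are aligned to locus codons.
#'
#' @param fal a `frame_alignment` (or `NULL`).
#' @param domain_tab reference domain table with `domain`, `aa_start`,
#'   `aa_end`.
#' @param coverage_min fraction in (0, 1].
#' @return named logical vector over the six domains.
#' @export
infer_domains <- function(fal, domain_tab, coverage_min = 0.8) {
  pres <- setNames(rep(FALSE, nrow(domain_tab)), domain_tab$domain)
  if (is.null(fal) || !nrow(fal$pairs)) return(pres)
  cols <- fal$pairs$ref_col
  for (i in seq_len(nrow(domain_tab))) {
    rng <- domain_tab$aa_start[i]:domain_tab$aa_end[i]
    pres[i] <- mean(rng %in% cols) >= coverage_min
  }
  pres
}

#' Confirm a locus against a reference panel by nucleotide identity
#'
#' Identity is computed over aligned columns (matches / (matches +
#' mismatches)) of a free-end-gap pairwise alignment of the locus CDS to
#' each panel sequence; the locus is kept iff the best identity is strictly
#' greater than the threshold and the alignment covers at least
#' `min_query_cov` of the CDS.
#'
#' @param cds locus coding sequence (character).
#' @param panel_cds named [Biostrings::DNAStringSet] of reference coding
#'   sequences.
#' @param threshold strict identity cutoff (default 0.90).
#' @param min_query_cov minimum aligned fraction of the CDS.
#' @return list with `keep`, `identity`, `best_ref`.
#' @export
similarity_confirmation <- function(cds, panel_cds, threshold = 0.90,
                                    min_query_cov = 0.6) {
  if (length(panel_cds) == 0L) stop("reference panel is empty")
  best <- -1; best_ref <- NA_character_; best_cov <- 0
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (nm in names(panel_cds)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(cds), panel_cds[[nm]], type = "overlap",
      substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
    nm_ <- Biostrings::nmatch(pa); nx <- Biostrings::nmismatch(pa)
    if (nm_ + nx == 0L) next
    ident <- nm_ / (nm_ + nx)
    if (ident > best) {
      best <- ident; best_ref <- nm; best_cov <- (nm_ + nx) / nchar(cds)
    }
  }
  keep <- best > threshold && best_cov >= min_query_cov
  list(keep = keep, identity = best, best_ref = best_ref)
}

#' Completeness and functional classification of a gene model
#'
#' Decision rules: an intact model (all six domains present) is a putatively
#' functional gene (PFG) iff it has a start codon at the beginning of exon 1,
#' a stop codon at the end of exon 6, no frameshifts and no premature stop
#' codons; indels of multiples of three nucleotides never pseudogenize. A
#' partial model is a PFG iff its present exons are free of frameshifts and
#' premature stops and the flanking region contains an assembly-gap N-run;
#' otherwise it is a pseudogene.
#'
#' @param model a list or one-row data.frame with logical `intact`,
#'   `has_start`, `has_terminal_stop`, `flanking_N` and counts
#'   `frameshift_events`, `premature_stops`.
#' @return list with `completeness` (`"intact"`/`"partial"`) and
#'   `functional_class` (`"PFG"`/`"pseudogene"`).
#' @export
classify <- function(model) {
  clean <- model$frameshift_events == 0L && model$premature_stops == 0L
  if (isTRUE(model$intact)) {
    ok <- clean && isTRUE(model$has_start) && isTRUE(model$has_terminal_stop)
    list(completeness = "intact",
         functional_class = if (ok) "PFG" else "pseudogene")
  } else {
    ok <- clean && isTRUE(model$flanking_N)
    list(completeness = "partial",
         functional_class = if (ok) "PFG" else "pseudogene")
  }
}

## N-run within `window` bp beyond either locus end?
.flanking_N <- function(scaffold_seq, g_start, g_end, window, n_run_min) {
  L <- nchar(scaffold_seq)
  left <- substr(scaffold_seq, max(1L, g_start - window + 1L), g_start)
  right <- substr(scaffold_seq, g_end + 1L, min(L, g_end + window))
  nrow(n_runs(left, n_run_min)) > 0L || nrow(n_runs(right, n_run_min)) > 0L
}

#' Build curated gene models for a set of candidate loci
#'
#' For each locus: splice a candidate CDS from its search segments, align it
#' codon-aware to the best-matching query protein, infer domain presence,
#' check start/stop codons, frameshifts and premature stops, scan the flanks
#' for assembly-gap N-runs, confirm identity against the reference panel,
#' and classify.
#'
#' @param locus_set a `locus_set` from [merge_redundant_hits()] /
#'   [length_filter()].
#' @param assembly named [Biostrings::DNAStringSet].
#' @param queries named [Biostrings::AAStringSet] used in the search.
#' @param domain_tab reference domain table (`domain`, `aa_start`, `aa_end`),
#'   e.g. the simulator's `$domains`.
#' @param panel_cds reference panel for [similarity_confirmation()].
#' @param params a [genemodel_params()].
#' @return list of class `gene_models`: `models` (data.frame with the
#'   GeneModel fields incl. `confirmed`) and `details` (per-locus list with
#'   `cds`, `alignment`, `exons`, `domain_presence`).
#' @export
build_gene_models <- function(locus_set, assembly, queries, domain_tab,
                              panel_cds, params = genemodel_params()) {
  loci <- locus_set$loci
  hits <- locus_set$hits
  scaffolds <- setNames(as.character(assembly), names(assembly))
  qs <- setNames(as.character(queries), names(queries))
  models <- list(); details <- list()
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    sc <- scaffolds[[lc$scaffold_id]]
    ex <- .extract_cds(lc, hits, sc, qs[[lc$best_query]], params)
    fal <- frame_aware_align(ex$cds, qs[[lc$best_query]],
                             frameshift_penalty = params$frameshift_penalty,
                             gap_codon = params$gap_codon)
    if (is.null(fal)) next   # unalignable: not a credible class I locus
    pres <- infer_domains(fal, domain_tab, params$coverage_min)
    fs_rescued <- .rescue_junction_frameshifts(ex, fal, sc,
                                               qs[[lc$best_query]])
    n3 <- substr(ex$cds, nchar(ex$cds) - 2L, nchar(ex$cds))
    conf <- similarity_confirmation(ex$cds, panel_cds,
                                    params$similarity_threshold,
                                    params$min_query_cov)
    md <- data.frame(
      locus_id = lc$locus_id, scaffold_id = lc$scaffold_id,
      g_start = ex$g_start, g_end = ex$g_end, strand = lc$strand,
      intact = all(pres),
      has_start = substr(ex$cds, 1L, 3L) == "ATG",
      has_terminal_stop = n3 %in% stop_codons,
      frameshift_events = nrow(fal$frameshifts) + fs_rescued,
      premature_stops = nrow(fal$stops),
      net_indel_codons = fal$n_ins_codons - fal$n_del_codons,
      flanking_N = .flanking_N(sc, ex$g_start, ex$g_end,
                               params$flank_window, params$n_run_min),
      best_panel_identity = conf$identity,
      confirmed = conf$keep,
      best_query = lc$best_query,
      stringsAsFactors = FALSE)
    cl <- classify(md)
    md$completeness <- cl$completeness
    md$functional_class <- cl$functional_class
    models[[lc$locus_id]] <- md
    details[[lc$locus_id]] <- list(cds = ex$cds, alignment = fal,
                                   exons = ex$exons,
                                   domain_presence = pres)
  }
  models <- do.call(rbind, models)
  rownames(models) <- NULL
  structure(list(models = models, details = details,
                 domain_tab = domain_tab), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  m <- x$models
  cat("gene_models:", nrow(m), "loci |", sum(m$functional_class == "PFG"),
      "PFG /", sum(m$functional_class == "pseudogene"), "pseudogene |",
      sum(m$completeness == "intact"), "intact /",
      sum(m$completeness == "partial"), "partial\n")
  invisible(x)
}

#' Repertoire accounting table
#'
#' Per-group counts of total genes, putatively functional genes,
#' pseudogenes, full-length (intact) and partial genes, plus the
#' genes-per-scaffold multiset formatted like `"2^1;1^3"` (one scaffold with
#' two genes, three scaffolds with one gene each).
#'
#' @param models the `models` data.frame of a `gene_models` object (or the
#'   object itself).
#' @param by optional column to group by (e.g. a species tag); default one
#'   row for the whole set.
#' @return data.frame with columns `group`, `gene`, `pfg`, `pseudogene`,
#'   `full_length`, `partial`, `gene_scaffold`.
#' @export
repertoire_table <- function(models, by = NULL) {
  if (inherits(models, "gene_models")) models <- models$models
  if (is.null(models) || !nrow(models)) {
    return(data.frame(group = "all", gene = 0L, pfg = 0L, pseudogene = 0L,
                      full_length = 0L, partial = 0L, gene_scaffold = "",
                      stringsAsFactors = FALSE))
  }
  groups <- if (is.null(by)) list(all = models)
            else split(models, models[[by]])
  out <- lapply(names(groups), function(g) {
    m <- groups[[g]]
    per_scaf <- table(m$scaffold_id)
    multiset <- table(factor(per_scaf))
    counts <- sort(as.integer(names(multiset)), decreasing = TRUE)
    gs <- paste(vapply(counts, function(k)
      sprintf("%d^%d", k, multiset[[as.character(k)]]), ""), collapse = ";")
    data.frame(group = g, gene = nrow(m),
               pfg = sum(m$functional_class == "PFG"),
               pseudogene = sum(m$functional_class == "pseudogene"),
               full_length = sum(m$completeness == "intact"),
               partial = sum(m$completeness == "partial"),
               gene_scaffold = gs, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
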