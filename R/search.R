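## Six-frame translated homology search: exact amino-acid seed matching on
## each frame, ungapped x-drop extension along the diagonal, then gapped
## refinement with the affine Smith-Waterman kernel in a window around each
## surviving segment. E-values follow Karlin-Altschul statistics with
## ungapped BLOSUM62 constants by default.

#' Translated-search parameters
#'
#' @param seed_k amino-acid word length for exact seeding (>= 3).
#' @param score_matrix substitution matrix name.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param x_drop ungapped extension cutoff, matrix units.
#' @param evalue_max locus-level E-value cutoff (the reported repertoire
#'   keeps loci whose best segment reaches this).
#' @param hsp_evalue_max segment-level retention threshold; individual exon
#'   segments of a multi-exon gene are kept at this looser level and the
#'   strict cutoff is applied to the merged locus, playing the role of
#'   BLAST's sum statistics for linked segments.
#' @param ungapped_floor minimum raw score of an ungapped extension to enter
#'   gapped refinement.
#' @param refine_pad_aa window padding (aa) around an ungapped segment for
#'   gapped refinement; kept below the intron width in frame units so
#'   segments do not bridge introns.
#' @param lambda_ka,k_ka Karlin-Altschul constants (ungapped BLOSUM62
#'   defaults).
#' @return a `search_params` list.
#' @export
search_params <- function(seed_k = 4L, score_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1, x_drop = 20,
                          evalue_max = 1e-10, hsp_evalue_max = 1e-3,
                          ungapped_floor = 50, refine_pad_aa = 25L,
                          lambda_ka = 0.3176, k_ka = 0.134) {
  stopifnot(seed_k >= 3L, gap_open > 0, gap_extend > 0, x_drop > 0,
            evalue_max > 0, hsp_evalue_max > 0, lambda_ka > 0, k_ka > 0)
  structure(list(seed_k = as.integer(seed_k), score_matrix = score_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 x_drop = x_drop, evalue_max = evalue_max,
                 hsp_evalue_max = hsp_evalue_max,
                 ungapped_floor = ungapped_floor,
                 refine_pad_aa = as.integer(refine_pad_aa),
                 lambda_ka = lambda_ka, k_ka = k_ka),
            class = "search_params")
}

#' Six-frame translation with coordinate maps
#'
#' @param dna a DNA string over `A,C,G,T,N` (N translates to X).
#' @return list of six frames, each a list with `strand` (`"+"`/`"-"`),
#'   `frame` (0, 1, 2 = offset within the strand), `aa` (translated string)
#'   and the source length `dna_len`. Use [aa_to_genomic()] to map amino-acid
#'   positions back to forward-strand genomic intervals.
#' @export
six_frame_translate <- function(dna) {
  if (!nzchar(dna)) stop("empty sequence")
  dna <- toupper(dna)
  L <- nchar(dna)
  rc <- revcomp(dna)
  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") dna else rc
    for (off in 0:2) {
      aa <- if (L - off >= 3L) translate_str(substr(src, off + 1L, L)) else ""
      out[[length(out) + 1L]] <- list(strand = strand, frame = off,
                                      aa = aa, dna_len = L)
    }
  }
  out
}

#' Map an amino-acid interval of a translation frame to genomic coordinates
#'
#' @param frame one element of [six_frame_translate()] output.
#' @param aa_start,aa_end 1-based inclusive positions in the frame.
#' @return integer `c(g_start, g_end)`, 0-based half-open on the forward
#'   strand.
#' @export
aa_to_genomic <- function(frame, aa_start, aa_end) {
  off <- frame$frame; L <- frame$dna_len
  if (frame$strand == "+")
    c(off + 3L * (aa_start - 1L), off + 3L * aa_end)
  else
    c(L - (off + 3L * aa_end), L - (off + 3L * (aa_start - 1L)))
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m`
#' and searched (translated) database length `n`, both in amino acids.
#'
#' @param raw_score raw alignment score, matrix units.
#' @param query_len_aa,db_len_aa positive lengths.
#' @param params a [search_params()].
#' @return the expectation value.
#' @export
evalue <- function(raw_score, query_len_aa, db_len_aa, params = search_params()) {
  if (any(query_len_aa <= 0) || any(db_len_aa <= 0))
    stop("lengths must be positive")
  params$k_ka * query_len_aa * db_len_aa *
    exp(-params$lambda_ka * raw_score)
}

## Translate a scaffold in six frames and index each frame's k-mers; built
## once per scaffold and shared by all queries.
scaffold_index <- function(scaffold, params = search_params(),
                           mat = score_matrix(params$score_matrix)) {
  k <- params$seed_k
  frames <- six_frame_translate(as.character(scaffold))
  lapply(frames, function(f) {
    ns <- nchar(f$aa)
    if (ns >= k) {
      sk <- substring(f$aa, 1:(ns - k + 1L), k:ns)
      keep <- !grepl("[X*]", sk)
      f$kmer_index <- split(which(keep), sk[keep])
      f$si <- .mat_index(chars(f$aa), mat)
    } else {
      f$kmer_index <- list()
      f$si <- integer()
    }
    f
  })
}

## All (query_pos, subject_pos) exact k-mer seed matches against an indexed
## frame.
.find_seeds <- function(query, frame_idx, k) {
  nq <- nchar(query)
  if (nq < k || !length(frame_idx$kmer_index)) return(NULL)
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  idx <- frame_idx$kmer_index
  hit_q <- integer(); hit_s <- integer()
  uq <- unique(qk)
  uq <- uq[uq %in% names(idx)]
  for (w in uq) {
    qs <- which(qk == w)
    ss <- idx[[w]]
    hit_q <- c(hit_q, rep(qs, each = length(ss)))
    hit_s <- c(hit_s, rep(ss, times = length(qs)))
  }
  if (!length(hit_q)) return(NULL)
  data.frame(q = hit_q, s = hit_s, diag = hit_s - hit_q)
}

## Trim an ungapped segment to its outermost runs of `run` consecutive
## exact residue matches: random (e.g. intronic) translation almost never
## contains such a run, while genuinely homologous sequence is full of
## them, so this removes neutral-drift overshoot beyond exon boundaries.
.trim_to_match_core <- function(match, run = 3L) {
  n <- length(match)
  if (n < run) return(NULL)
  ok <- match
  for (r in seq_len(run - 1L))
    ok <- ok & c(match[-seq_len(r)], rep(FALSE, r))
  w <- which(ok)            # start positions of full runs
  if (!length(w)) return(NULL)
  c(w[1L], w[length(w)] + run - 1L)
}

## Ungapped x-drop extension of one seed along its diagonal.
.xdrop_ungapped <- function(qi, si, qpos, spos, k, mat, x_drop) {
  nq <- length(qi); ns <- length(si)
  d <- spos - qpos
  lo <- max(1L, 1L + d)            # subject pos when query pos = 1
  hi <- min(ns, nq + d)
  svec <- mat[cbind(qi[(lo - d):(hi - d)], si[lo:hi])]
  a <- spos - lo + 1L              # seed start within the diagonal slice
  ## right extension from the seed start
  right <- cumsum(svec[a:length(svec)])
  stop_r <- which(cummax(right) - right > x_drop)
  rmax_at <- if (length(stop_r)) which.max(right[seq_len(stop_r[1L] - 1L)])
             else which.max(right)
  ## left extension
  if (a > 1L) {
    left <- cumsum(rev(svec[seq_len(a - 1L)]))
    stop_l <- which(cummax(left) - left > x_drop)
    lbest <- if (length(stop_l)) {
      w <- left[seq_len(stop_l[1L] - 1L)]
      if (max(w) > 0) which.max(w) else 0L
    } else if (max(left) > 0) which.max(left) else 0L
  } else lbest <- 0L
  s_start <- spos - lbest
  s_end <- spos + rmax_at - 1L
  ## trim drift beyond the homologous core
  core <- .trim_to_match_core(qi[(s_start - d):(s_end - d)] ==
                                si[s_start:s_end])
  if (is.null(core)) return(list(s_start = spos, s_end = spos - 1L,
                                 q_start = qpos, q_end = qpos - 1L,
                                 score = -Inf))
  s_start2 <- s_start + core[1L] - 1L
  s_end2 <- s_start + core[2L] - 1L
  score <- sum(svec[(s_start2 - lo + 1L):(s_end2 - lo + 1L)])
  list(s_start = s_start2, s_end = s_end2,
       q_start = s_start2 - d, q_end = s_end2 - d, score = score)
}

#' Seed-and-extend translated search of one protein against one scaffold
#'
#' Exact `seed_k`-mer seeds on each of the six frames are extended without
#' gaps under an x-drop rule, surviving segments are re-aligned with the
#' affine-gap local kernel in a padded window, and segments are reported with
#' Karlin-Altschul E-values. Deterministic for fixed inputs.
#'
#' @param query_protein amino-acid string (length >= `seed_k`).
#' @param scaffold DNA string.
#' @param params a [search_params()].
#' @param query_id,scaffold_id identifiers copied into the hit table.
#' @param index optional precomputed [scaffold_index()] (recomputed when
#'   `NULL`); pass it when searching many queries against one scaffold.
#' @return data.frame of hits: `query_id`, `scaffold_id`, `g_start`, `g_end`
#'   (0-based half-open, forward strand), `strand`, `frame`, `q_start`,
#'   `q_end` (aa, 1-based), `raw_score`, `bit_score`, `evalue`; sorted by
#'   `(scaffold_id, g_start)`.
#' @export
seed_and_extend <- function(query_protein, scaffold, params = search_params(),
                            query_id = "query", scaffold_id = "scaffold",
                            index = NULL) {
  query <- as.character(query_protein)
  if (nchar(query) < params$seed_k)
    stop("query shorter than seed_k")
  mat <- score_matrix(params$score_matrix)
  qi <- .mat_index(chars(query), mat)
  frames <- index %||% scaffold_index(scaffold, params, mat)
  db_len <- sum(vapply(frames, function(f) nchar(f$aa), 0L))
  m <- nchar(query)
  rows <- list()
  for (f in frames) {
    if (nchar(f$aa) < params$seed_k) next
    seeds <- .find_seeds(query, f, params$seed_k)
    if (is.null(seeds)) next
    seeds <- seeds[order(seeds$diag, seeds$s), ]
    si <- f$si
    covered <- list()   # per-diagonal coverage end
    segs <- list()
    for (r in seq_len(nrow(seeds))) {
      dg <- as.character(seeds$diag[r])
      if (!is.null(covered[[dg]]) && seeds$s[r] <= covered[[dg]]) next
      ext <- .xdrop_ungapped(qi, si, seeds$q[r], seeds$s[r], params$seed_k,
                             mat, params$x_drop)
      covered[[dg]] <- ext$s_end
      if (ext$score >= params$ungapped_floor)
        segs[[length(segs) + 1L]] <- ext
    }
    if (!length(segs)) next
    ## gapped re-scoring in a padded window around each segment. The
    ## reported coordinates stay those of the ungapped core segment (which
    ## stops at its score peak, i.e. at exon boundaries); the raw score is
    ## the gapped local-alignment score of the surrounding window, which
    ## equals the full Smith-Waterman score whenever the optimum lies within
    ## the window.
    pad <- params$refine_pad_aa
    seen <- character()
    for (sg in segs) {
      key <- paste(f$strand, f$frame, sg$q_start, sg$q_end, sg$s_start,
                   sg$s_end)
      if (key %in% seen) next
      seen <- c(seen, key)
      w1 <- max(1L, sg$s_start - pad)
      w2 <- min(nchar(f$aa), sg$s_end + pad)
      win <- substr(f$aa, w1, w2)
      qw <- substr(query, max(1L, sg$q_start - pad),
                   min(m, sg$q_end + pad))
      al <- sw_align(qw, win, mat, params$gap_open, params$gap_extend)
      raw <- max(al$score, sg$score)
      ev <- evalue(raw, m, db_len, params)
      if (ev > params$hsp_evalue_max) next
      g <- aa_to_genomic(f, sg$s_start, sg$s_end)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query_id, scaffold_id = scaffold_id,
        g_start = g[1L], g_end = g[2L], strand = f$strand, frame = f$frame,
        q_start = sg$q_start, q_end = sg$q_end,
        s_start = sg$s_start, s_end = sg$s_end,
        raw_score = raw,
        bit_score = (params$lambda_ka * raw - log(params$k_ka)) / log(2),
        evalue = ev, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_hits())
  out <- do.call(rbind, rows)
  out[order(out$scaffold_id, out$g_start, out$evalue), , drop = FALSE]
}

.empty_hits <- function() {
  data.frame(query_id = character(), scaffold_id = character(),
             g_start = integer(), g_end = integer(), strand = character(),
             frame = integer(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             raw_score = numeric(), bit_score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Search a set of protein queries against an assembly
#'
#' @param queries a named [Biostrings::AAStringSet] (or named character).
#' @param assembly a named [Biostrings::DNAStringSet].
#' @param params a [search_params()].
#' @param verbose log progress to stderr.
#' @return combined hit table (see [seed_and_extend()]).
#' @export
search_assembly <- function(queries, assembly, params = search_params(),
                            verbose = FALSE) {
  qs <- setNames(as.character(queries), names(queries))
  ss <- setNames(as.character(assembly), names(assembly))
  mat <- score_matrix(params$score_matrix)
  out <- list()
  for (sn in names(ss)) {
    idx <- scaffold_index(ss[[sn]], params, mat)
    for (qn in names(qs)) {
      log_msg("search: ", qn, " vs ", sn, verbose = verbose)
      out[[length(out) + 1L]] <-
        seed_and_extend(qs[[qn]], ss[[sn]], params, qn, sn, index = idx)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(.empty_hits())
  out[order(out$scaffold_id, out$g_start, out$evalue), , drop = FALSE]
}

#' Merge redundant hits into candidate loci
#'
#' Hits on the same scaffold and strand whose genomic intervals overlap or
#' lie within `max_locus_gap` bp are merged into one locus; the locus records
#' the union interval and the best (lowest) E-value. Ties are broken by
#' lowest E-value, then leftmost start.
#'
#' @param hits hit table from [search_assembly()].
#' @param max_locus_gap bp; segments this close (e.g. exons of one gene) are
#'   one locus.
#' @return a `locus_set`: list with `loci` (data.frame `locus_id`,
#'   `scaffold_id`, `strand`, `g_start`, `g_end`, `span`, `best_evalue`,
#'   `best_query`, `n_hits`) and `hits` (input with a `locus_id` column).
#' @export
merge_redundant_hits <- function(hits, max_locus_gap = 1000L) {
  if (!nrow(hits)) {
    return(structure(list(loci = data.frame(), hits = hits),
                     class = "locus_set"))
  }
  hits$locus_id <- NA_character_
  loci <- list()
  n_loc <- 0L
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$scaffold_id, hits$strand))) {
    h <- hits[grp, ]
    ir <- IRanges::IRanges(start = h$g_start + 1L, end = h$g_end)
    red <- IRanges::reduce(ir, min.gapwidth = max_locus_gap + 1L)
    ov <- IRanges::findOverlaps(ir, red)
    for (k in seq_along(red)) {
      members <- grp[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]]
      n_loc <- n_loc + 1L
      id <- sprintf("locus_%03d", n_loc)
      hits$locus_id[members] <- id
      best <- members[order(hits$evalue[members], hits$g_start[members])][1L]
      loci[[id]] <- data.frame(
        locus_id = id,
        scaffold_id = hits$scaffold_id[best],
        strand = hits$strand[best],
        g_start = IRanges::start(red)[k] - 1L,
        g_end = IRanges::end(red)[k],
        span = IRanges::width(red)[k],
        best_evalue = hits$evalue[best],
        best_query = hits$query_id[best],
        n_hits = length(members), stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, loci)
  loci <- loci[order(loci$scaffold_id, loci$g_start), , drop = FALSE]
  ## stable ids in coordinate order
  remap <- setNames(sprintf("locus_%03d", seq_len(nrow(loci))), loci$locus_id)
  loci$locus_id <- unname(remap[loci$locus_id])
  hits$locus_id <- unname(remap[hits$locus_id])
  rownames(loci) <- NULL
  structure(list(loci = loci, hits = hits), class = "locus_set")
}

#' Filter loci by genomic span
#'
#' Loci spanning fewer than `min_nt` nucleotides are removed ("shorter than"
#' is strict: a span of exactly `min_nt` is retained).
#'
#' @param locus_set output of [merge_redundant_hits()].
#' @param min_nt minimum genomic span in bp.
#' @param evalue_max locus-level E-value cutoff applied alongside the span
#'   filter (`NULL` to skip).
#' @return a filtered `locus_set`.
#' @export
length_filter <- function(locus_set, min_nt = 400L, evalue_max = NULL) {
  loci <- locus_set$loci
  if (!nrow(loci)) return(locus_set)
  keep <- loci$span >= min_nt
  if (!is.null(evalue_max)) keep <- keep & loci$best_evalue <= evalue_max
  kept <- loci[keep, , drop = FALSE]
  hits <- locus_set$hits
  hits <- hits[hits$locus_id %in% kept$locus_id, , drop = FALSE]
  structure(list(loci = kept, hits = hits), class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", nrow(x$loci), "loci from", nrow(x$hits), "hits\n")
  invisible(x)
}
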