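## Alignment kernels: an affine-gap local (Smith-Waterman) protein aligner used
## by the translated search, and a frameshift-aware DNA-vs-protein codon
## aligner used for gene-model curation. Both are row-vectorized dynamic
## programs; the within-row gap recurrence is solved with a running-maximum
## transformation so no scalar inner loop is needed.

#' Fetch a protein substitution matrix by name
#'
#' @param name matrix name; one of the matrices shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @return a numeric substitution matrix with amino-acid row/column names.
#' @export
score_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name)
  get(name, envir = e)
}

## Map characters onto the matrix alphabet; anything unknown scores as X.
.mat_index <- function(x, mat) {
  i <- match(x, rownames(mat))
  i[is.na(i)] <- match("X", rownames(mat))
  i
}

## Core forward pass of affine-gap local alignment. Returns the best score and
## its (query, subject) end coordinates. Gap of length L costs
## gap_open + L * gap_extend (same convention as Biostrings).
.sw_forward <- function(qi, si, mat, gap_open, gap_extend) {
  n <- length(qi); m <- length(si)
  Hprev <- numeric(m + 1L)
  Fprev <- rep(-Inf, m + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    srow <- mat[qi[i], si]
    diagv <- Hprev[jj] + srow
    Fv <- pmax(Fprev[jj + 1L], Hprev[jj + 1L] - gap_open) - gap_extend
    G <- pmax(0, diagv, Fv)
    ## within-row (subject) gaps: E[j] = max_{k<j} G[k] - open - (j-k)*ext
    Tk <- G + jj * gap_extend
    E <- c(-Inf, cummax(Tk)[-m]) - gap_open - jj * gap_extend
    H <- pmax(G, E)
    w <- which.max(H)
    if (H[w] > best) { best <- H[w]; bi <- i; bj <- w }
    Hprev <- c(0, H)
    Fprev <- c(-Inf, Fv)
  }
  list(score = best, q_end = bi, s_end = bj)
}

#' Local protein alignment with affine gaps
#'
#' Smith-Waterman alignment of two amino-acid strings. Endpoints are obtained
#' by a second pass on the reversed prefixes, so no traceback matrices are
#' kept.
#'
#' @param query,subject amino-acid strings.
#' @param mat substitution matrix (see [score_matrix()]).
#' @param gap_open,gap_extend positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return a list with `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based, inclusive; zeros if no positive-scoring alignment exists).
#' @export
sw_align <- function(query, subject, mat = score_matrix(), gap_open = 11,
                     gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend > 0)
  qc <- chars(query); sc <- chars(subject)
  qi <- .mat_index(qc, mat); si <- .mat_index(sc, mat)
  fwd <- .sw_forward(qi, si, mat, gap_open, gap_extend)
  if (fwd$score <= 0)
    return(list(score = 0, q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L))
  rqi <- rev(qi[seq_len(fwd$q_end)])
  rsi <- rev(si[seq_len(fwd$s_end)])
  bwd <- .sw_forward(rqi, rsi, mat, gap_open, gap_extend)
  list(score = fwd$score,
       q_start = fwd$q_end - bwd$q_end + 1L, q_end = fwd$q_end,
       s_start = fwd$s_end - bwd$s_end + 1L, s_end = fwd$s_end)
}

## Amino acid of the codon ending at each DNA position (NA for i < 3).
.codon_aa_ends <- function(dna) {
  L <- nchar(dna)
  aa <- rep(NA_character_, L)
  for (off in 0:2) {
    tr <- translate_str(substr(dna, off + 1L, L))
    if (nchar(tr) == 0L) next
    ends <- off + 3L * seq_len(nchar(tr))
    aa[ends] <- chars(tr)
  }
  aa
}

#' Frameshift-aware alignment of a nucleotide sequence to a reference protein
#'
#' Aligns DNA to a protein reading the DNA in codons, allowing explicit 1- or
#' 2-nucleotide frameshift events (penalized) as well as whole-codon
#' insertions and deletions, in the spirit of codon-aware aligners used to
#' separate functional genes from pseudogenes. End gaps are free on both
#' sequences, so leading/trailing unaligned DNA (e.g. a terminal stop codon)
#' or missing reference domains are not penalized. Internal stop codons are
#' reported with their positions.
#'
#' @param locus_dna nucleotide string (length >= 30).
#' @param ref_protein amino-acid string.
#' @param frameshift_penalty cost of each 1- or 2-nt frameshift event
#'   (matrix units).
#' @param gap_codon cost per whole-codon insertion or deletion.
#' @param mat substitution matrix.
#' @param score_floor alignments scoring below this return `NULL`
#'   ("unalignable").
#' @return `NULL` if unalignable, otherwise a `frame_alignment` list:
#'   `score`; `pairs` (data.frame `dna_end`, `ref_col`, `codon_aa`, `ref_aa`);
#'   `frameshifts` (data.frame `dna_pos`, `ref_col`, `kind`);
#'   `stops` (data.frame `dna_pos`, `ref_col`, internal stop codons);
#'   `n_ins_codons`/`n_del_codons` (whole-codon indels, DNA-relative);
#'   `dna_range`, `ref_range` (aligned spans, 1-based inclusive).
#' @export
frame_aware_align <- function(locus_dna, ref_protein, frameshift_penalty = 30,
                              gap_codon = 12, mat = score_matrix(),
                              score_floor = 20) {
  stopifnot(nchar(locus_dna) >= 30L, nchar(ref_protein) >= 1L)
  dna <- toupper(locus_dna)
  L <- nchar(dna); P <- nchar(ref_protein)
  pc <- chars(ref_protein)
  pidx <- .mat_index(pc, mat)
  aa_end <- .codon_aa_ends(dna)
  aa_idx <- .mat_index(aa_end, mat)          # '*' maps to the stop row
  fs <- frameshift_penalty; gc3 <- gap_codon
  jj <- seq_len(P)

  H <- matrix(-Inf, nrow = L + 1L, ncol = P + 1L)
  H[, 1L] <- 0; H[1L, ] <- 0                  # free leading gaps
  for (i in seq_len(L)) {
    r <- i + 1L
    cand <- rep(-Inf, P)
    if (i >= 3L) {
      cand <- H[r - 3L, jj] + mat[aa_idx[i], pidx]                        # codon vs residue
      cand <- pmax(cand, H[r - 3L, jj + 1L] - gc3)       # extra codon in DNA
    }
    cand <- pmax(cand,
                 H[r - 1L, jj] - fs,                     # 1-nt "codon" (fs)
                 H[r - 1L, jj + 1L] - fs)                # 1-nt skipped (fs)
    if (i >= 2L)
      cand <- pmax(cand,
                   H[r - 2L, jj] - fs,                   # 2-nt "codon" (fs)
                   H[r - 2L, jj + 1L] - fs)              # 2-nt skipped
    ## within-row: reference residues deleted from the DNA (whole codons)
    Tk <- c(0, cand + jj * gc3)
    E <- cummax(Tk)[jj] - jj * gc3
    H[r, jj + 1L] <- pmax(cand, E)
  }

  lastrow <- H[L + 1L, ]; lastcol <- H[, P + 1L]
  if (max(lastrow) >= max(lastcol)) {
    j <- which.max(lastrow) - 1L; i <- L
  } else {
    i <- which.max(lastcol) - 1L; j <- P
  }
  score <- H[i + 1L, j + 1L]
  if (!is.finite(score) || score < score_floor) return(NULL)

  ## traceback by move re-testing (priority: codon > frameshifts > indels)
  pairs_dna <- integer(); pairs_ref <- integer(); pairs_aa <- character()
  fsh_pos <- integer(); fsh_ref <- integer(); fsh_kind <- character()
  n_ins <- 0L; n_del <- 0L
  eps <- 1e-9
  while (i > 0L && j > 0L) {
    r <- i + 1L; cell <- H[r, j + 1L]
    if (i >= 3L && abs(H[r - 3L, j] + mat[aa_idx[i], pidx[j]] - cell) < eps) {
      pairs_dna <- c(pairs_dna, i); pairs_ref <- c(pairs_ref, j)
      pairs_aa <- c(pairs_aa, aa_end[i])
      i <- i - 3L; j <- j - 1L
    } else if (i >= 2L && abs(H[r - 2L, j] - fs - cell) < eps) {
      fsh_pos <- c(fsh_pos, i); fsh_ref <- c(fsh_ref, j)
      fsh_kind <- c(fsh_kind, "2nt_codon")
      i <- i - 2L; j <- j - 1L
    } else if (abs(H[r - 1L, j] - fs - cell) < eps) {
      fsh_pos <- c(fsh_pos, i); fsh_ref <- c(fsh_ref, j)
      fsh_kind <- c(fsh_kind, "1nt_codon")
      i <- i - 1L; j <- j - 1L
    } else if (i >= 3L && abs(H[r - 3L, j + 1L] - gc3 - cell) < eps) {
      n_ins <- n_ins + 1L
      i <- i - 3L
    } else if (i >= 2L && abs(H[r - 2L, j + 1L] - fs - cell) < eps) {
      fsh_pos <- c(fsh_pos, i); fsh_ref <- c(fsh_ref, j)
      fsh_kind <- c(fsh_kind, "2nt_skip")
      i <- i - 2L
    } else if (abs(H[r - 1L, j + 1L] - fs - cell) < eps) {
      fsh_pos <- c(fsh_pos, i); fsh_ref <- c(fsh_ref, j)
      fsh_kind <- c(fsh_kind, "1nt_skip")
      i <- i - 1L
    } else if (abs(H[r, j] - gc3 - cell) < eps) {
      n_del <- n_del + 1L
      j <- j - 1L
    } else {
      break   # numerically degenerate; should not happen
    }
  }

  ord <- order(pairs_ref)
  pairs <- data.frame(dna_end = pairs_dna[ord], ref_col = pairs_ref[ord],
                      codon_aa = pairs_aa[ord],
                      ref_aa = pc[pairs_ref[ord]],
                      stringsAsFactors = FALSE)
  is_stop <- pairs$codon_aa == "*"
  stops <- pairs[is_stop, c("dna_end", "ref_col")]
  names(stops) <- c("dna_pos", "ref_col")
  fo <- order(fsh_pos)
  structure(list(
    score = score,
    pairs = pairs,
    frameshifts = data.frame(dna_pos = fsh_pos[fo], ref_col = fsh_ref[fo],
                             kind = fsh_kind[fo], stringsAsFactors = FALSE),
    stops = stops,
    n_ins_codons = n_ins, n_del_codons = n_del,
    dna_range = if (nrow(pairs)) c(min(pairs$dna_end) - 2L, max(pairs$dna_end))
                else c(NA_integer_, NA_integer_),
    ref_range = if (nrow(pairs)) range(pairs$ref_col)
                else c(NA_integer_, NA_integer_),
    dna_len = L, ref_len = P), class = "frame_alignment")
}

#' @export
print.frame_alignment <- function(x, ...) {
  cat("frame_alignment: score", x$score, "|", nrow(x$pairs), "codons aligned |",
      nrow(x$frameshifts), "frameshift(s) |", nrow(x$stops),
      "internal stop(s)\n")
  invisible(x)
}
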