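## Lineage-specific alpha-1 (exon 2) insertion calling: extract the alpha-1
## peptide of each gene model, align focal and reference peptides, and call
## contiguous alignment blocks where the focal lineage has residues while
## every reference sequence has a gap.

#' Extract alpha-1 domain peptides from gene models
#'
#' The alpha-1 peptide is the translation of the locus nucleotides spanning
#' the codons aligned to the reference alpha-1 columns (inserted codons
#' between them included). Loci without an alpha-1 domain are skipped with a
#' logged reason.
#'
#' @param gene_models a `gene_models` object from [build_gene_models()].
#' @param min_coverage minimum fraction of alpha-1 reference columns that
#'   must be aligned.
#' @return a named [Biostrings::AAStringSet]; skipped loci are recorded in
#'   `attr(, "skipped")` (named character of reasons).
#' @export
extract_alpha1 <- function(gene_models, min_coverage = 0.8) {
  dt <- gene_models$domain_tab
  a1 <- dt[dt$domain == "alpha1", ]
  rng <- a1$aa_start:a1$aa_end
  out <- character(); skipped <- character()
  for (id in names(gene_models$details)) {
    d <- gene_models$details[[id]]
    fal <- d$alignment
    pr <- fal$pairs[fal$pairs$ref_col %in% rng, , drop = FALSE]
    if (nrow(pr) / length(rng) < min_coverage) {
      skipped[id] <- "alpha1 domain absent or too fragmentary"
      next
    }
    nt <- substr(d$cds, min(pr$dna_end) - 2L, max(pr$dna_end))
    pep <- translate_str(nt)
    if (grepl("*", pep, fixed = TRUE)) {
      skipped[id] <- "internal stop within alpha1"
      next
    }
    out[id] <- pep
  }
  res <- Biostrings::AAStringSet(out)
  attr(res, "skipped") <- skipped
  res
}

#' Profile alignment of alpha-1 peptides against a reference set
#'
#' Aligns focal and reference alpha-1 peptides into one multiple alignment
#' (via MAFFT); the reference (non-focal) columns define the coordinate
#' system used by [call_insertions()]. Sequences are sorted by name before
#' alignment so the result does not depend on input order.
#'
#' @param seqs named [Biostrings::AAStringSet] of focal peptides.
#' @param reference_set named [Biostrings::AAStringSet] of non-focal
#'   (reference) peptides; at least one required.
#' @return an `alpha1_msa`: list with `aln` (character matrix, rows =
#'   sequences, columns = alignment columns) and `focal` (logical per row).
#' @export
profile_align_alpha1 <- function(seqs, reference_set) {
  if (length(reference_set) < 1L) stop("need at least one reference sequence")
  if (length(seqs) < 1L) stop("no focal sequences to align")
  all <- c(Biostrings::AAStringSet(seqs),
           Biostrings::AAStringSet(reference_set))
  if (anyDuplicated(names(all)))
    stop("duplicate sequence names across focal and reference sets")
  focal_names <- names(seqs)
  all <- all[order(names(all))]
  aln <- run_mafft(all)
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  structure(list(aln = m, focal = rownames(m) %in% focal_names),
            class = "alpha1_msa")
}

## Thin MAFFT wrapper (deterministic; input written sorted by name).
run_mafft <- function(seqs, args = c("--auto", "--quiet")) {
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft))
    stop("mafft not found on PATH; it is required for profile alignment")
  tmp_in <- tempfile(fileext = ".faa"); tmp_out <- tempfile(fileext = ".afa")
  on.exit(unlink(c(tmp_in, tmp_out)))
  Biostrings::writeXStringSet(seqs, tmp_in)
  status <- system2(mafft, c(args, shQuote(tmp_in)), stdout = tmp_out,
                    stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  Biostrings::readAAStringSet(tmp_out)
}

#' Call lineage-specific insertions from an alpha-1 alignment
#'
#' A candidate column is one where every reference (non-focal) sequence has
#' a gap; maximal runs of candidate columns form blocks. A block is called
#' lineage-specific when at least `min_focal_frac` of the focal sequences
#' have at least one residue in it. One call is emitted per focal locus per
#' called block, with the locus's own residue count in the block (so mixed
#' 3- and 5-residue alleles sharing one anchor are reported per locus).
#' Ragged alignment ends (first and last `edge_exclude` columns) are not
#' called.
#'
#' @param msa an `alpha1_msa` from [profile_align_alpha1()].
#' @param min_focal_frac fraction of focal sequences that must carry the
#'   insertion (default 0.9).
#' @param edge_exclude columns excluded at each alignment end.
#' @return data.frame: `locus_id`, `insertion_length_aa`, `alignment_column`
#'   (preceding reference column, in reference coordinates), `in_frame`
#'   (always TRUE at the peptide level: length is in whole residues),
#'   `block_id`.
#' @export
call_insertions <- function(msa, min_focal_frac = 0.9, edge_exclude = 5L) {
  m <- msa$aln
  nc <- ncol(m)
  refs <- m[!msa$focal, , drop = FALSE]
  foc <- m[msa$focal, , drop = FALSE]
  empty <- data.frame(locus_id = character(),
                      insertion_length_aa = integer(),
                      alignment_column = integer(), in_frame = logical(),
                      block_id = integer(), stringsAsFactors = FALSE)
  if (!nrow(foc) || !nrow(refs) || nc == 0L) return(empty)
  ref_gap <- apply(refs == "-", 2L, all)
  inner <- seq_len(nc) > edge_exclude & seq_len(nc) <= nc - edge_exclude
  cand <- ref_gap & inner
  if (!any(cand)) return(empty)
  ## maximal runs of candidate columns
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- which(r$values)
  ## reference coordinate of each alignment column (non-gap ref columns)
  ref_col <- cumsum(!ref_gap)
  out <- list(); bid <- 0L
  for (b in blocks) {
    cols <- starts[b]:ends[b]
    has <- apply(foc[, cols, drop = FALSE] != "-", 1L, any)
    if (mean(has) < min_focal_frac) next
    bid <- bid + 1L
    len <- apply(foc[, cols, drop = FALSE] != "-", 1L, sum)
    anchor <- if (starts[b] > 1L) ref_col[starts[b] - 1L] else 0L
    out[[bid]] <- data.frame(
      locus_id = rownames(foc)[has], insertion_length_aa = len[has],
      alignment_column = anchor, in_frame = TRUE, block_id = bid,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
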