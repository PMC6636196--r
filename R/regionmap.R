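## Canonical class I region mapping: locate the framework marker genes,
## define the alpha/kappa/beta duplication blocks and the extended class I
## interval from the marker pairs, assign every class I gene to a region by
## its midpoint, and report large gaps (splits) inside defined blocks.

BLOCK_BOUNDS <- list(alpha = c("MOG", "RNF39"),
                     kappa = c("TRIM26", "ABCF1"),
                     beta = c("TCF19", "MICB_BAT1"),
                     extendedI = c("HIST1H2AA", "MOG"))

#' Locate framework marker genes in an assembly
#'
#' Runs the translated search with the marker proteins as queries and keeps
#' the best-scoring locus per marker per scaffold. Absence of a marker is
#' data, not an error; a marker found on several scaffolds is flagged
#' ambiguous.
#'
#' @param assembly named [Biostrings::DNAStringSet].
#' @param marker_proteins named [Biostrings::AAStringSet]; names are marker
#'   names (see [marker_panel()]).
#' @param params a [search_params()].
#' @param max_locus_gap bp used to merge a marker's split segments.
#' @return data.frame: `marker`, `scaffold_id`, `g_start`, `g_end`, `strand`,
#'   `best_evalue`, `ambiguous`.
#' @export
locate_markers <- function(assembly, marker_proteins,
                           params = search_params(),
                           max_locus_gap = 1000L) {
  hits <- search_assembly(marker_proteins, assembly, params)
  if (!nrow(hits)) {
    return(data.frame(marker = character(), scaffold_id = character(),
                      g_start = integer(), g_end = integer(),
                      strand = character(), best_evalue = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  }
  hits <- hits[hits$evalue <= params$evalue_max, , drop = FALSE]
  out <- list()
  for (mk in unique(hits$query_id)) {
    hmk <- hits[hits$query_id == mk, , drop = FALSE]
    per_scaf <- list()
    for (sn in unique(hmk$scaffold_id)) {
      h <- hmk[hmk$scaffold_id == sn, , drop = FALSE]
      ls <- merge_redundant_hits(h, max_locus_gap)$loci
      best <- ls[order(ls$best_evalue, ls$g_start), ][1L, ]
      per_scaf[[sn]] <- data.frame(
        marker = mk, scaffold_id = sn, g_start = best$g_start,
        g_end = best$g_end, strand = best$strand,
        best_evalue = best$best_evalue, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, per_scaf)
    df$ambiguous <- nrow(df) > 1L
    out[[mk]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$marker, out$scaffold_id), , drop = FALSE]
}

## Composite MICB/BAT1 marker: either protein name satisfies it.
.canonical_marker <- function(x) ifelse(x %in% c("MICB", "BAT1"),
                                        "MICB_BAT1", x)

#' Define duplication-block intervals from located markers
#'
#' The alpha block is the open interval between MOG and RNF39, kappa between
#' TRIM26 and ABCF1, beta between TCF19 and MICB/BAT1, and the extended
#' class I interval between HIST1H2AA and MOG. A block is defined only when
#' both bounding markers lie on one scaffold; orientation of the scaffold is
#' irrelevant (the interval between the two marker loci is used whichever is
#' leftmost).
#'
#' @param marker_loci output of [locate_markers()].
#' @return data.frame: `block`, `scaffold_id`, `g_start`, `g_end` (0-based
#'   half-open; the open interval between the inner marker edges), `defined`.
#' @export
define_blocks <- function(marker_loci) {
  ml <- marker_loci
  if (nrow(ml)) ml$marker <- .canonical_marker(ml$marker)
  amb <- unique(ml$marker[ml$ambiguous])
  out <- list()
  for (b in names(BLOCK_BOUNDS)) {
    pair <- BLOCK_BOUNDS[[b]]
    if (any(pair %in% amb)) {
      cand <- ml[ml$marker %in% intersect(pair, amb), ]
      stop("ambiguous duplicate marker(s) for block ", b, ": ",
           paste(sprintf("%s@%s", cand$marker, cand$scaffold_id),
                 collapse = ", "))
    }
    a <- ml[ml$marker == pair[1L], ]
    z <- ml[ml$marker == pair[2L], ]
    if (nrow(a) == 1L && nrow(z) == 1L &&
        a$scaffold_id == z$scaffold_id) {
      lo <- min(a$g_end, z$g_end); hi <- max(a$g_start, z$g_start)
      out[[b]] <- data.frame(block = b, scaffold_id = a$scaffold_id,
                             g_start = lo, g_end = hi, defined = TRUE,
                             stringsAsFactors = FALSE)
    } else {
      out[[b]] <- data.frame(block = b, scaffold_id = NA_character_,
                             g_start = NA_integer_, g_end = NA_integer_,
                             defined = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign gene models to duplication blocks
#'
#' A gene belongs to the unique defined block whose interval contains its
#' midpoint; the extended class I interval is checked after the three
#' blocks. Genes on scaffolds without any defined block, or outside every
#' defined interval, are `"outside"`.
#'
#' @param models gene-model data.frame (needs `locus_id`, `scaffold_id`,
#'   `g_start`, `g_end`).
#' @param blocks output of [define_blocks()].
#' @return the models with an `assignment` column.
#' @export
assign_genes <- function(models, blocks) {
  assignment <- rep("outside", nrow(models))
  mid <- (models$g_start + models$g_end) / 2
  for (b in c("alpha", "kappa", "beta", "extendedI")) {
    bi <- blocks[blocks$block == b, ]
    if (!nrow(bi) || !bi$defined) next
    inb <- models$scaffold_id == bi$scaffold_id &
      mid >= bi$g_start & mid < bi$g_end & assignment == "outside"
    assignment[inb] <- b
  }
  models$assignment <- assignment
  models
}

#' Detect splits (large insertions) inside defined blocks
#'
#' Within each defined block, the anchored features (bounding markers plus
#' assigned genes) are ordered by position; any gap between consecutive
#' features exceeding `gap_threshold_bp` is reported as a split.
#'
#' @param marker_loci output of [locate_markers()].
#' @param blocks output of [define_blocks()].
#' @param models assigned gene models (from [assign_genes()]).
#' @param gap_threshold_bp report gaps larger than this (default 1 Mbp).
#' @return data.frame: `block`, `gap_bp`, `g_start`, `g_end`,
#'   `left_feature`, `right_feature`.
#' @export
detect_splits <- function(marker_loci, blocks, models,
                          gap_threshold_bp = 1e6) {
  ml <- marker_loci
  if (nrow(ml)) ml$marker <- .canonical_marker(ml$marker)
  out <- list()
  for (b in c("alpha", "kappa", "beta", "extendedI")) {
    bi <- blocks[blocks$block == b, ]
    if (!nrow(bi) || !bi$defined) next
    pair <- BLOCK_BOUNDS[[b]]
    anchors <- rbind(
      data.frame(name = ml$marker[ml$marker %in% pair &
                                    ml$scaffold_id == bi$scaffold_id],
                 g_start = ml$g_start[ml$marker %in% pair &
                                        ml$scaffold_id == bi$scaffold_id],
                 g_end = ml$g_end[ml$marker %in% pair &
                                    ml$scaffold_id == bi$scaffold_id],
                 stringsAsFactors = FALSE),
      if (nrow(models)) {
        inb <- models$assignment == b
        data.frame(name = models$locus_id[inb],
                   g_start = models$g_start[inb],
                   g_end = models$g_end[inb], stringsAsFactors = FALSE)
      })
    anchors <- anchors[order(anchors$g_start), ]
    if (nrow(anchors) < 2L) next
    for (i in seq_len(nrow(anchors) - 1L)) {
      gap <- anchors$g_start[i + 1L] - anchors$g_end[i]
      if (gap > gap_threshold_bp) {
        out[[length(out) + 1L]] <- data.frame(
          block = b, gap_bp = gap,
          g_start = anchors$g_end[i], g_end = anchors$g_start[i + 1L],
          left_feature = anchors$name[i],
          right_feature = anchors$name[i + 1L], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(block = character(), gap_bp = numeric(),
                      g_start = integer(), g_end = integer(),
                      left_feature = character(),
                      right_feature = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map the canonical class I region and assign genes
#'
#' Convenience wrapper: locate markers, define blocks, assign the given gene
#' models and detect splits.
#'
#' @inheritParams locate_markers
#' @param models gene-model data.frame.
#' @param gap_threshold_bp split-detection threshold.
#' @return list of class `region_map` with `marker_loci`, `blocks`,
#'   `models` (with `assignment`), `splits`.
#' @export
map_region <- function(assembly, marker_proteins, models,
                       params = search_params(), gap_threshold_bp = 1e6) {
  ml <- locate_markers(assembly, marker_proteins, params)
  bl <- define_blocks(ml)
  mo <- assign_genes(models, bl)
  sp <- detect_splits(ml, bl, mo, gap_threshold_bp)
  structure(list(marker_loci = ml, blocks = bl, models = mo, splits = sp),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map:", nrow(x$marker_loci), "marker loci;",
      sum(x$blocks$defined), "of", nrow(x$blocks), "blocks defined;",
      nrow(x$splits), "split(s)\n")
  if (nrow(x$models))
    print(table(x$models$assignment))
  invisible(x)
}
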