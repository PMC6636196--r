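## Synthetic genome simulator: plants MHC class I-like genes (functional,
## pseudogenized, partial), the six framework marker genes that demarcate the
## alpha/kappa/beta duplication blocks, alpha-1 insertion alleles, and mosaic
## recombinants into multi-scaffold assemblies, together with a truth set for
## recovery testing.

MARKER_NAMES <- c("HIST1H2AA", "MOG", "RNF39", "TRIM26", "ABCF1", "TCF19",
                  "MICB_BAT1")

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic assembly: a scaffold holding
#' the canonical class I region (extended class I, alpha, kappa and beta
#' blocks bounded by the framework markers in their conserved order), plus
#' additional scaffolds holding class I genes outside the region.
#'
#' @param seed integer RNG seed; all randomness derives from it.
#' @param n_scaffolds number of scaffolds (scaffold 1 carries the region).
#' @param scaffold_length bp per scaffold (recycled to `n_scaffolds`).
#' @param exon_lengths six coding exon lengths in bp; must sum to a multiple
#'   of 3. Exon 6 includes the terminal stop codon.
#' @param intron_bp intron length between coding exons.
#' @param intergenic_bp spacing between planted features.
#' @param intergenic_gc GC fraction of intergenic sequence.
#' @param n_functional,n_pseudogene,n_partial named counts per compartment
#'   (`alpha`, `kappa`, `beta`, `extendedI`, `outside`).
#' @param pseudogene_modes modes cycled over planted pseudogenes.
#' @param insertion_alleles codon insertion alleles (subset of 0/3/5) cycled
#'   over planted functional genes; the alpha-1 anchor is fixed.
#' @param insertion_anchor codon within exon 2 after which alleles insert.
#' @param divergence expected substitutions/site among paralogs (each locus
#'   diverges at half this rate from the common ancestor); in `[0, 0.75)`.
#' @param n_recombinants mosaic loci planted outside the region, built from
#'   two equal-allele functional parents with one interior breakpoint.
#' @param n_run_bp length of the N-run flanking each partial gene.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 3L,
                       scaffold_length = c(150000L, 45000L, 45000L),
                       exon_lengths = c(72L, 270L, 276L, 276L, 117L, 150L),
                       intron_bp = 200L,
                       intergenic_bp = 3000L,
                       intergenic_gc = 0.41,
                       n_functional = c(alpha = 2L, kappa = 4L, beta = 3L,
                                        extendedI = 2L, outside = 5L),
                       n_pseudogene = c(alpha = 1L, kappa = 1L, beta = 1L,
                                        extendedI = 0L, outside = 2L),
                       n_partial = c(alpha = 0L, kappa = 1L, beta = 0L,
                                     extendedI = 0L, outside = 3L),
                       pseudogene_modes = c("premature_stop", "frameshift",
                                            "lost_start", "lost_stop"),
                       insertion_alleles = c(3L, 5L),
                       insertion_anchor = 50L,
                       divergence = 0.10,
                       n_recombinants = 1L,
                       n_run_bp = 300L) {
  comp <- c("alpha", "kappa", "beta", "extendedI", "outside")
  fix <- function(x) {
    out <- setNames(rep(0L, 5L), comp)
    out[names(x)] <- as.integer(x)
    out
  }
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = rep_len(as.integer(scaffold_length),
                                        n_scaffolds),
              exon_lengths = as.integer(exon_lengths),
              intron_bp = as.integer(intron_bp),
              intergenic_bp = as.integer(intergenic_bp),
              intergenic_gc = intergenic_gc,
              n_functional = fix(n_functional),
              n_pseudogene = fix(n_pseudogene),
              n_partial = fix(n_partial),
              pseudogene_modes = match.arg(pseudogene_modes,
                c("premature_stop", "frameshift", "lost_start", "lost_stop"),
                several.ok = TRUE),
              insertion_alleles = as.integer(insertion_alleles),
              insertion_anchor = as.integer(insertion_anchor),
              divergence = divergence,
              n_recombinants = as.integer(n_recombinants),
              n_run_bp = as.integer(n_run_bp))
  if (length(cfg$exon_lengths) != 6L)
    stop("exon_lengths must have six entries")
  if (sum(cfg$exon_lengths) %% 3L != 0L)
    stop("sum of exon_lengths must be a multiple of 3")
  if (cfg$divergence < 0 || cfg$divergence >= 0.75)
    stop("divergence must be in [0, 0.75)")
  if (!all(cfg$insertion_alleles %in% c(0L, 3L, 5L)))
    stop("insertion_alleles must be a subset of {0, 3, 5}")
  if (cfg$intergenic_gc < 0 || cfg$intergenic_gc > 1)
    stop("intergenic_gc must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

## i.i.d. nucleotides at a given GC fraction (uses current RNG stream)
.random_dna <- function(n, gc = 0.41) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Random coding sequence: residues drawn uniformly over the 20 amino
## acids, then a synonymous codon uniformly per residue (drawing codons
## directly would skew the residue composition toward L/S/R and distort
## alignment score statistics relative to real proteins).
CODONS_BY_AA <- local({
  aa <- vapply(SENSE_CODONS, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)), "")
  split(SENSE_CODONS, aa)
})

.random_cds <- function(n_codons) {
  res <- sample(names(CODONS_BY_AA), n_codons, replace = TRUE)
  paste(vapply(res, function(a) {
    cds <- CODONS_BY_AA[[a]]
    cds[sample.int(length(cds), 1L)]
  }, ""), collapse = "")
}

## Jukes-Cantor substitution of a DNA string at expected `d` subs/site.
## Positions listed in `frozen` are never touched; codons that would become
## stops are reverted.
.jc_mutate <- function(dna, d, frozen = integer()) {
  if (d <= 0) return(dna)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  x <- chars(dna)
  hit <- which(runif(length(x)) < p)
  hit <- setdiff(hit, frozen)
  if (!length(hit)) return(dna)
  b <- c("A", "C", "G", "T")
  for (i in hit) x[i] <- sample(setdiff(b, x[i]), 1L)
  out <- x
  ## revert codons that mutated into stops (ORF-preserving divergence)
  nc <- length(out) %/% 3L
  if (nc > 1L) {
    orig <- chars(dna)
    for (k in seq_len(nc - 1L)) {
      idx <- (3L * k - 2L):(3L * k)
      if (paste(out[idx], collapse = "") %in% stop_codons)
        out[idx] <- orig[idx]
    }
  }
  paste(out, collapse = "")
}

#' Simulate an MHC class I-like coding sequence
#'
#' Builds the six-exon coding sequence of one lineage from the configured
#' ancestor: an open reading frame starting with ATG and ending with a stop
#' codon, with annotated boundaries for the six domains (leader, alpha-1,
#' alpha-2, alpha-3, intercellular, cytoplasmic). A lineage may carry an
#' in-frame 3- or 5-codon insertion in exon 2 at the fixed anchor column.
#'
#' @param config a [sim_config()].
#' @param lineage list with `name`, `insertion_codons` (0, 3 or 5) and
#'   `divergence` (expected substitutions/site from the ancestor).
#' @return list with `cds`, `protein` (no terminal stop), `domains`
#'   (data.frame of exon/domain boundaries in nt and aa, 1-based closed),
#'   and `insertion_codons`.
#' @export
simulate_mhci_cds <- function(config,
                              lineage = list(name = "anc",
                                             insertion_codons = 0L,
                                             divergence = 0)) {
  stopifnot(inherits(config, "sim_config"))
  ins <- as.integer(lineage$insertion_codons %||% 0L)
  div <- lineage$divergence %||% 0
  if (!ins %in% c(0L, 3L, 5L)) stop("insertion_codons must be 0, 3 or 5")

  anc <- with_seed(config$seed, {
    n_codons <- sum(config$exon_lengths) / 3L
    body <- .random_cds(n_codons - 2L)
    paste0("ATG", body, "TAA")
  })
  ins_seq <- with_seed(config$seed + 7L,
                       .random_cds(5L))           # shared derived allele
  exl <- config$exon_lengths
  cds <- anc
  if (ins > 0L) {
    at <- exl[1L] + 3L * config$insertion_anchor  # nt offset inside exon 2
    cds <- paste0(substr(cds, 1L, at), substr(ins_seq, 1L, 3L * ins),
                  substr(cds, at + 1L, nchar(cds)))
    exl[2L] <- exl[2L] + 3L * ins
  }
  if (div > 0) {
    seed_l <- derive_seed(config$seed, paste0("lineage:",
                                              lineage$name %||% "anon"))
    frozen <- c(1:3, (nchar(cds) - 2L):nchar(cds))
    cds <- with_seed(seed_l, .jc_mutate(cds, div, frozen))
  }
  ends <- cumsum(exl)
  starts <- c(1L, head(ends, -1L) + 1L)
  domains <- data.frame(
    exon = 1:6,
    domain = c("leader", "alpha1", "alpha2", "alpha3", "intercellular",
               "cytoplasmic"),
    nt_start = starts, nt_end = ends,
    aa_start = (starts + 2L) %/% 3L, aa_end = ends %/% 3L,
    stringsAsFactors = FALSE)
  ## exon 6 carries the terminal stop; the protein excludes it
  domains$aa_end[6L] <- domains$aa_end[6L] - 1L
  prot <- translate_str(substr(cds, 1L, nchar(cds) - 3L))
  if (grepl("*", prot, fixed = TRUE))
    stop("internal error: simulated ORF contains a stop")   # nocov
  list(cds = cds, protein = prot, domains = domains, insertion_codons = ins)
}

#' Pseudogenize a coding sequence
#'
#' Introduces one inactivating lesion: a premature stop codon, a frameshift
#' (indel of length not divisible by 3), an ablated start codon, or an
#' ablated terminal stop codon.
#'
#' @param cds a valid ORF (starts ATG, ends with a stop codon).
#' @param mode one of `"premature_stop"`, `"frameshift"`, `"lost_start"`,
#'   `"lost_stop"`.
#' @param seed integer seed for the lesion position.
#' @param at optional codon index (for `premature_stop`) or nt position (for
#'   `frameshift`) overriding the random position.
#' @param k indel length for `frameshift`; `k %% 3 == 0` is rejected because
#'   in-frame indels do not pseudogenize.
#' @return list with `cds` (mutated) and `event` (mode, position, detail).
#' @export
pseudogenize <- function(cds, mode, seed = 1L, at = NULL, k = 1L) {
  n <- nchar(cds)
  if (n %% 3L != 0L || substr(cds, 1L, 3L) != "ATG" ||
      !substr(cds, n - 2L, n) %in% stop_codons)
    stop("cds is not a valid ORF")
  n_codons <- n / 3L
  with_seed(seed, switch(mode,
    premature_stop = {
      ci <- if (!is.null(at)) as.integer(at)
            else sample(seq(floor(n_codons * 0.25), floor(n_codons * 0.75)), 1L)
      stopifnot(ci > 1L, ci < n_codons)
      s <- sample(stop_codons, 1L)
      out <- paste0(substr(cds, 1L, 3L * (ci - 1L)), s,
                    substr(cds, 3L * ci + 1L, n))
      list(cds = out, event = list(mode = mode, pos_nt = 3L * ci - 2L,
                                   detail = s))
    },
    frameshift = {
      if (k %% 3L == 0L)
        stop("an indel of a multiple of three nucleotides is not a frameshift")
      pos <- if (!is.null(at)) as.integer(at)
             else sample(seq(floor(n * 0.25), floor(n * 0.75)), 1L)
      del <- runif(1) < 0.5
      out <- if (del)
        paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + k, n))
      else
        paste0(substr(cds, 1L, pos),
               paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""),
               substr(cds, pos + 1L, n))
      list(cds = out, event = list(mode = mode, pos_nt = pos,
                                   detail = if (del) paste0("-", k)
                                            else paste0("+", k)))
    },
    lost_start = {
      list(cds = paste0("CTG", substr(cds, 4L, n)),
           event = list(mode = mode, pos_nt = 1L, detail = "ATG->CTG"))
    },
    lost_stop = {
      repl <- sample(setdiff(SENSE_CODONS, "ATG"), 1L)
      list(cds = paste0(substr(cds, 1L, n - 3L), repl),
           event = list(mode = mode, pos_nt = n - 2L,
                        detail = paste0(substr(cds, n - 2L, n), "->", repl)))
    },
    stop("unknown pseudogenization mode: ", mode)))
}

#' Build a mosaic recombinant from two aligned parents
#'
#' @param parentA,parentB equal-length sequences in aligned coordinates.
#' @param breakpoints sorted positions strictly inside the sequence; segment
#'   `[1, b1]` comes from parent A, `(b1, b2]` from B, and so on.
#' @return list with `seq` and `origin` (per-position `"A"`/`"B"`).
#' @export
simulate_recombinant <- function(parentA, parentB, breakpoints = integer()) {
  n <- nchar(parentA)
  if (nchar(parentB) != n) stop("parents must have equal length")
  bp <- as.integer(breakpoints)
  if (length(bp)) {
    if (is.unsorted(bp, strictly = TRUE)) stop("breakpoints must be sorted")
    if (any(bp <= 0L) || any(bp >= n)) stop("breakpoints out of range")
  }
  bounds <- c(0L, bp, n)
  a <- chars(parentA); b <- chars(parentB)
  origin <- character(n)
  out <- character(n)
  for (s in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    src <- if (s %% 2L == 1L) "A" else "B"
    out[idx] <- if (src == "A") a[idx] else b[idx]
    origin[idx] <- src
  }
  list(seq = paste(out, collapse = ""), origin = origin)
}

## Deterministic framework-marker proteins (~180 aa, fixed per name).
.marker_protein <- function(name) {
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  with_seed(derive_seed(20190614L, paste0("marker:", name)),
            paste0("M", paste(sample(aa20, 179L, TRUE), collapse = "")))
}

#' Framework marker protein panel
#'
#' The six block-demarcating marker proteins (plus the extended-region anchor
#' HIST1H2AA) used both by the simulator (planted as single-exon genes) and
#' by [locate_markers()] as queries. MICB/BAT1 is treated as one composite
#' marker.
#'
#' @return a named [Biostrings::AAStringSet].
#' @export
marker_panel <- function() {
  Biostrings::AAStringSet(setNames(vapply(MARKER_NAMES, .marker_protein, ""),
                                   MARKER_NAMES))
}

## Reverse-translate a protein deterministically (per-position codon choice).
.backtranslate <- function(prot, seed) {
  tab <- split(SENSE_CODONS,
               vapply(SENSE_CODONS, function(cd) translate_str(cd), ""))
  with_seed(seed, paste(vapply(chars(prot), function(a)
    sample(tab[[a]], 1L), ""), collapse = ""))
}

## Gene structure on the genome: exons separated by introns. Returns the
## forward-oriented gene string and exon coordinates relative to gene start
## (0-based half-open).
.lay_gene <- function(cds, domains, intron_bp, gc, n_exons_present = 6L) {
  exd <- domains[seq_len(n_exons_present), , drop = FALSE]
  pieces <- character(); exon_at <- NULL; cur <- 0L
  for (e in seq_len(nrow(exd))) {
    if (e > 1L) {
      pieces <- c(pieces, .random_dna(intron_bp, gc))
      cur <- cur + intron_bp
    }
    piece <- substr(cds, exd$nt_start[e], exd$nt_end[e])
    w <- nchar(piece)   # lesions may shift the CDS length off the table
    pieces <- c(pieces, piece)
    exon_at <- rbind(exon_at, c(cur, cur + w))
    cur <- cur + w
  }
  list(seq = paste(pieces, collapse = ""), exons = exon_at, width = cur)
}

#' Plant a synthetic assembly with a truth set
#'
#' Scaffold 1 carries the framework markers in their conserved order
#' (HIST1H2AA, MOG, RNF39, TRIM26, ABCF1, TCF19, MICB/BAT1) with class I
#' genes planted inside the extended class I, alpha, kappa and beta
#' intervals; the remaining scaffolds carry outside-region genes, partial
#' genes truncated at N-runs, and mosaic recombinants.
#'
#' @param config a [sim_config()].
#' @return an object of class `mhci_sim`: list with `assembly`
#'   ([Biostrings::DNAStringSet]), `truth` (data.frame, 0-based half-open
#'   coordinates), `gene_seqs` (planted forward-strand gene regions),
#'   `marker_truth`, `panel` (query proteins, marker proteins, reference CDS),
#'   `domains` (ancestral domain table) and `config`.
#' @export
plant_scaffolds <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  rng_seed <- derive_seed(cfg$seed, "plant")
  anc <- simulate_mhci_cds(cfg)

  comp_genes <- list()   # per compartment: list of locus descriptors
  idx <- 0L
  alleles <- if (length(cfg$insertion_alleles)) cfg$insertion_alleles else 0L
  modes <- cfg$pseudogene_modes
  mk_locus <- function(compartment, kind) {
    idx <<- idx + 1L
    id <- sprintf("G%02d", idx)
    lin_div <- cfg$divergence / 2
    if (kind == "functional") {
      al <- alleles[(idx - 1L) %% length(alleles) + 1L]
      sim <- simulate_mhci_cds(cfg, list(name = id, insertion_codons = al,
                                         divergence = lin_div))
      list(id = id, kind = kind, cds = sim$cds, domains = sim$domains,
           allele = al, class = "PFG", completeness = "intact",
           n_exons = 6L, mode = NA_character_, breakpoints = integer())
    } else if (kind == "pseudogene") {
      ## the focal lineage's alpha-1 insertion is shared by its pseudogenes
      al <- alleles[(idx - 1L) %% length(alleles) + 1L]
      sim <- simulate_mhci_cds(cfg, list(name = id, insertion_codons = al,
                                         divergence = lin_div))
      mode <- modes[(idx - 1L) %% length(modes) + 1L]
      ps <- pseudogenize(sim$cds, mode, seed = derive_seed(rng_seed, id))
      dom <- sim$domains
      ## a frameshift indel changes the CDS length; keep the final exon
      ## boundary on the sequence end so the whole lesioned ORF is planted
      dom$nt_end[6L] <- dom$nt_end[6L] + (nchar(ps$cds) - nchar(sim$cds))
      list(id = id, kind = kind, cds = ps$cds, domains = dom,
           allele = al, class = "pseudogene", completeness = "intact",
           n_exons = 6L, mode = mode, breakpoints = integer())
    } else { # partial
      al <- alleles[(idx - 1L) %% length(alleles) + 1L]
      sim <- simulate_mhci_cds(cfg, list(name = id, insertion_codons = al,
                                         divergence = lin_div))
      ke <- 3L + (idx %% 3L)    # 3..5 exons present
      list(id = id, kind = kind, cds = sim$cds, domains = sim$domains,
           allele = al, class = "PFG", completeness = "partial",
           n_exons = ke, mode = NA_character_, breakpoints = integer())
    }
  }
  for (comp in c("extendedI", "alpha", "kappa", "beta", "outside")) {
    g <- list()
    for (i in seq_len(cfg$n_functional[[comp]]))
      g <- c(g, list(mk_locus(comp, "functional")))
    for (i in seq_len(cfg$n_pseudogene[[comp]]))
      g <- c(g, list(mk_locus(comp, "pseudogene")))
    for (i in seq_len(cfg$n_partial[[comp]]))
      g <- c(g, list(mk_locus(comp, "partial")))
    comp_genes[[comp]] <- g
  }

  ## recombinants: parents are two outside functional loci with equal alleles
  if (cfg$n_recombinants > 0L) {
    of <- Filter(function(g) g$kind == "functional", comp_genes$outside)
    if (length(of) < 2L)
      stop("need >= 2 outside functional loci to plant recombinants")
    als <- vapply(of, function(g) g$allele, integer(1))
    pair <- NULL
    for (a in unique(als)) if (sum(als == a) >= 2L) {
      pair <- of[which(als == a)[1:2]]; break
    }
    if (is.null(pair))
      stop("no pair of equal-allele outside parents for recombination")
    for (r in seq_len(cfg$n_recombinants)) {
      idx <- idx + 1L
      id <- sprintf("G%02d", idx)
      n <- nchar(pair[[1]]$cds)
      bp <- 3L * ((n %/% 2L) %/% 3L)   # codon-boundary interior breakpoint
      mos <- simulate_recombinant(pair[[1]]$cds, pair[[2]]$cds, bp)
      dom <- pair[[1]]$domains
      comp_genes$outside <- c(comp_genes$outside, list(list(
        id = id, kind = "recombinant", cds = mos$seq, domains = dom,
        allele = pair[[1]]$allele, class = "PFG", completeness = "intact",
        n_exons = 6L, mode = NA_character_, breakpoints = bp,
        parents = c(pair[[1]]$id, pair[[2]]$id))))
    }
  }

  ## ---- lay out scaffolds ----
  gc <- cfg$intergenic_gc; spacer <- cfg$intergenic_bp
  truth <- list(); marker_truth <- list(); gene_seqs <- list()

  place <- with_seed(rng_seed, {
    scaffolds <- vector("list", cfg$n_scaffolds)

    put_gene <- function(pieces, cur, g, scaffold_id, block_label) {
      lay <- .lay_gene(g$cds, g$domains, cfg$intron_bp, gc, g$n_exons)
      strand <- if (runif(1) < 0.5) "+" else "-"
      seq_fwd <- if (strand == "+") lay$seq else revcomp(lay$seq)
      pieces <- c(pieces, seq_fwd)
      start <- cur; end <- cur + lay$width
      cur <- end
      if (g$completeness == "partial") {
        ## N-run adjacent to the truncated side (3' of the gene)
        nrun <- strrep("N", cfg$n_run_bp)
        if (strand == "+") { pieces <- c(pieces, nrun); cur <- cur + cfg$n_run_bp }
        else {
          ## on minus strand the truncation faces left: insert N before gene
          k <- length(pieces)
          pieces <- c(pieces[seq_len(k - 1L)], nrun, pieces[k])
          start <- start + cfg$n_run_bp; end <- end + cfg$n_run_bp
          cur <- cur + cfg$n_run_bp
        }
      }
      truth[[g$id]] <<- data.frame(
        locus_id = g$id, scaffold_id = scaffold_id,
        start = start, end = end, strand = strand,
        planted_class = g$class, planted_completeness = g$completeness,
        insertion_codons = g$allele, block_label = block_label,
        breakpoints = paste(g$breakpoints, collapse = ","),
        n_exons = g$n_exons,
        pseudogene_mode = g$mode, stringsAsFactors = FALSE)
      gene_seqs[[g$id]] <<- seq_fwd
      list(pieces = pieces, cur = cur)
    }

    put_marker <- function(pieces, cur, name, scaffold_id) {
      prot <- .marker_protein(name)
      mcds <- paste0(.backtranslate(prot, derive_seed(rng_seed, name)), "TAA")
      pieces <- c(pieces, mcds)
      marker_truth[[name]] <<- data.frame(
        marker = name, scaffold_id = scaffold_id,
        start = cur, end = cur + nchar(mcds), strand = "+",
        stringsAsFactors = FALSE)
      list(pieces = pieces, cur = cur + nchar(mcds))
    }

    gap <- function(pieces, cur, n) list(pieces = c(pieces, .random_dna(n, gc)),
                                         cur = cur + n)

    ## scaffold 1: [ext genes] between HIST1H2AA..MOG, then blocks
    sid <- "scaffold_1"
    st <- list(pieces = character(), cur = 0L)
    st <- gap(st$pieces, st$cur, spacer)
    st <- put_marker(st$pieces, st$cur, "HIST1H2AA", sid)
    st <- gap(st$pieces, st$cur, spacer)
    for (g in comp_genes$extendedI) {
      st <- put_gene(st$pieces, st$cur, g, sid, "extendedI")
      st <- gap(st$pieces, st$cur, spacer)
    }
    st <- put_marker(st$pieces, st$cur, "MOG", sid)
    st <- gap(st$pieces, st$cur, spacer)
    for (g in comp_genes$alpha) {
      st <- put_gene(st$pieces, st$cur, g, sid, "alpha")
      st <- gap(st$pieces, st$cur, spacer)
    }
    st <- put_marker(st$pieces, st$cur, "RNF39", sid)
    st <- gap(st$pieces, st$cur, spacer)
    st <- put_marker(st$pieces, st$cur, "TRIM26", sid)
    st <- gap(st$pieces, st$cur, spacer)
    for (g in comp_genes$kappa) {
      st <- put_gene(st$pieces, st$cur, g, sid, "kappa")
      st <- gap(st$pieces, st$cur, spacer)
    }
    st <- put_marker(st$pieces, st$cur, "ABCF1", sid)
    st <- gap(st$pieces, st$cur, spacer)
    st <- put_marker(st$pieces, st$cur, "TCF19", sid)
    st <- gap(st$pieces, st$cur, spacer)
    for (g in comp_genes$beta) {
      st <- put_gene(st$pieces, st$cur, g, sid, "beta")
      st <- gap(st$pieces, st$cur, spacer)
    }
    st <- put_marker(st$pieces, st$cur, "MICB_BAT1", sid)
    if (st$cur > cfg$scaffold_length[1L])
      stop("planted features overflow scaffold_1 (need ", st$cur, " bp, have ",
           cfg$scaffold_length[1L], ")")
    st <- gap(st$pieces, st$cur, cfg$scaffold_length[1L] - st$cur)
    scaffolds[[1L]] <- paste(st$pieces, collapse = "")

    ## remaining scaffolds: outside genes round-robin
    out_genes <- comp_genes$outside
    if (cfg$n_scaffolds < 2L && length(out_genes))
      stop("outside genes require n_scaffolds >= 2")
    nrest <- max(cfg$n_scaffolds - 1L, 1L)
    for (s in seq_len(cfg$n_scaffolds - 1L)) {
      sid <- paste0("scaffold_", s + 1L)
      mine <- out_genes[seq_along(out_genes) %% nrest == (s %% nrest)]
      st <- list(pieces = character(), cur = 0L)
      st <- gap(st$pieces, st$cur, spacer)
      for (g in mine) {
        st <- put_gene(st$pieces, st$cur, g, sid, "outside")
        st <- gap(st$pieces, st$cur, spacer)
      }
      if (st$cur > cfg$scaffold_length[s + 1L])
        stop("planted features overflow ", sid, " (need ", st$cur,
             " bp, have ", cfg$scaffold_length[s + 1L], ")")
      st <- gap(st$pieces, st$cur, cfg$scaffold_length[s + 1L] - st$cur)
      scaffolds[[s + 1L]] <- paste(st$pieces, collapse = "")
    }
    scaffolds
  })

  assembly <- Biostrings::DNAStringSet(setNames(
    unlist(place), paste0("scaffold_", seq_len(cfg$n_scaffolds))))
  truth_df <- do.call(rbind, truth[order(names(truth))])
  rownames(truth_df) <- NULL
  marker_df <- do.call(rbind, marker_truth)
  rownames(marker_df) <- NULL

  ## query / confirmation panels: the ancestor and a mildly diverged relative
  relative <- simulate_mhci_cds(cfg, list(name = "panel_rel",
                                          insertion_codons = 0L,
                                          divergence = 0.04))
  queries <- Biostrings::AAStringSet(c(MHCI_anc = anc$protein,
                                       MHCI_rel = relative$protein))
  panel_cds <- Biostrings::DNAStringSet(c(MHCI_anc = anc$cds,
                                          MHCI_rel = relative$cds))

  structure(list(assembly = assembly, truth = truth_df,
                 gene_seqs = Biostrings::DNAStringSet(unlist(gene_seqs)),
                 marker_truth = marker_df,
                 panel = list(queries = queries, markers = marker_panel(),
                              cds = panel_cds),
                 domains = anc$domains, config = cfg),
            class = "mhci_sim")
}

#' @export
print.mhci_sim <- function(x, ...) {
  cat("mhci_sim:", length(x$assembly), "scaffolds,",
      nrow(x$truth), "planted class I loci,",
      nrow(x$marker_truth), "framework markers (seed ",
      x$config$seed, ")\n", sep = " ")
  invisible(x)
}

#' Write a simulated assembly and its truth set to disk
#'
#' Emits the assembly FASTA (60-column wrap), the truth set as GFF3 (gene
#' features with `locus_id`, `planted_class`, `block_label` attributes) and
#' TSV, the query/marker/reference panels, and a structured config record.
#'
#' @param sim an `mhci_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "mhci_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(assembly = file.path(dir, "assembly.fa"),
             truth_gff = file.path(dir, "truth.gff3"),
             truth_tsv = file.path(dir, "truth.tsv"),
             queries = file.path(dir, "queries.faa"),
             markers = file.path(dir, "markers.faa"),
             panel_cds = file.path(dir, "panel_cds.fa"),
             config = file.path(dir, "sim_config.txt"))
  Biostrings::writeXStringSet(sim$assembly, paths["assembly"], width = 60L)
  tr <- sim$truth
  gff <- data.frame(
    seqid = tr$scaffold_id, source = "mhciscan_sim", type = "gene",
    start = tr$start + 1L, end = tr$end, score = ".",
    strand = tr$strand, phase = ".",
    attributes = sprintf("ID=%s;locus_id=%s;planted_class=%s;block_label=%s",
                         tr$locus_id, tr$locus_id, tr$planted_class,
                         tr$block_label),
    stringsAsFactors = FALSE)
  write_gff3(gff, paths["truth_gff"])
  write_tsv(tr, paths["truth_tsv"])
  Biostrings::writeXStringSet(sim$panel$queries, paths["queries"], width = 60L)
  Biostrings::writeXStringSet(sim$panel$markers, paths["markers"], width = 60L)
  Biostrings::writeXStringSet(sim$panel$cds, paths["panel_cds"], width = 60L)
  cfg <- sim$config
  lines <- vapply(names(cfg), function(k)
    paste0(k, "\t", paste(cfg[[k]], collapse = ",")), "")
  writeLines(c("# mhciscan simulation config", lines), paths["config"])
  invisible(paths)
}

#' Simulate a clonal (recombination-free) sequence family
#'
#' Descendants of one ancestor under independent Jukes-Cantor divergence;
#' used for type-I-error control of the recombination statistics.
#'
#' @param n sequences; @param len alignment length (nt);
#' @param divergence expected substitutions/site from the ancestor;
#' @param seed integer seed.
#' @return character matrix (`n` rows) of equal-length sequences.
#' @export
simulate_clonal_family <- function(n, len, divergence, seed = 1L) {
  with_seed(seed, {
    anc <- .random_dna(len, 0.5)
    m <- t(vapply(seq_len(n),
                  function(i) chars(.jc_mutate(anc, divergence)),
                  character(len)))
    rownames(m) <- paste0("t", seq_len(n))
    m
  })
}

#' Simulate a mosaic recombination triplet
#'
#' Two parents at the given divergence plus a recombinant taking its left
#' segment from parent A and its right from parent B.
#'
#' @param len alignment length; @param divergence parent-parent divergence;
#' @param breakpoint interior position (default midpoint); @param seed seed.
#' @return list with `aln` (3 x len character matrix: `rec`, `pA`, `pB`) and
#'   `breakpoint`.
#' @export
simulate_mosaic_triplet <- function(len, divergence, breakpoint = len %/% 2L,
                                    seed = 1L) {
  stopifnot(breakpoint > 0L, breakpoint < len)
  with_seed(seed, {
    anc <- .random_dna(len, 0.5)
    pA <- .jc_mutate(anc, divergence / 2)
    pB <- .jc_mutate(anc, divergence / 2)
    rec <- simulate_recombinant(pA, pB, breakpoint)$seq
    aln <- rbind(rec = chars(rec), pA = chars(pA), pB = chars(pB))
    list(aln = aln, breakpoint = as.integer(breakpoint))
  })
}

#' Random additive (tree) metric with its true splits
#'
#' Generates a random binary tree on `n` taxa with uniform branch lengths and
#' returns the exact path-length distance matrix together with the tree's
#' splits; used to verify that the split network reduces to the tree in the
#' compatible case.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param seed integer seed.
#' @param bl_range branch-length range.
#' @return list with `D` (distance matrix), `splits` (list of character
#'   vectors: the smaller side of each split, external and internal) and
#'   `weights` (named by canonical split key, see [split_key()]).
#' @export
simulate_additive_metric <- function(n_taxa, seed = 1L,
                                     bl_range = c(0.01, 0.2)) {
  stopifnot(n_taxa >= 4L)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  with_seed(seed, {
    ## random binary tree by sequential joining; D via edge accumulation
    D <- matrix(0, n_taxa, n_taxa, dimnames = list(taxa, taxa))
    groups <- as.list(taxa)           # active clades (tips below each node)
    splits <- list(); weights <- numeric()
    add_edge <- function(members, bl) {
      others <- setdiff(taxa, members)
      D[members, others] <<- D[members, others] + bl
      D[others, members] <<- D[others, members] + bl
      if (length(members) >= 1L && length(others) >= 1L) {
        key <- split_key(members, taxa)
        if (length(members) < n_taxa) {
          splits[[length(splits) + 1L]] <<- members
          weights[key] <<- (if (key %in% names(weights)) weights[key] else 0) + bl
        }
      }
    }
    ## pendant edges
    for (t in taxa) add_edge(t, runif(1, bl_range[1], bl_range[2]))
    while (length(groups) > 2L) {
      pick <- sample(length(groups), 2L)
      merged <- c(groups[[pick[1]]], groups[[pick[2]]])
      groups <- c(groups[-pick], list(merged))
      if (length(merged) < n_taxa - 1L)   # root edge would be redundant
        add_edge(merged, runif(1, bl_range[1], bl_range[2]))
    }
    list(D = D, splits = splits, weights = weights, taxa = taxa)
  })
}
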