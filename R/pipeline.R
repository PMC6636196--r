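## End-to-end orchestration: search -> gene models -> region map ->
## insertions -> recombination screen -> split network, with seeded
## determinism, file emission in standard formats and a machine-readable
## run manifest.

#' Pipeline run configuration
#'
#' Collects inputs (in-memory objects or file paths), stage toggles, stage
#' parameter sets and the global seed. The global seed fans out to
#' per-stage seeds via [derive_seed()].
#'
#' @param assembly [Biostrings::DNAStringSet] or FASTA path.
#' @param queries class I query proteins ([Biostrings::AAStringSet] or
#'   FASTA path).
#' @param markers framework marker proteins (default [marker_panel()]).
#' @param panel_cds reference-panel coding sequences for similarity
#'   confirmation ([Biostrings::DNAStringSet] or FASTA path).
#' @param domain_tab reference domain table (`domain`, `aa_start`,
#'   `aa_end`).
#' @param out_dir output directory (`NULL`: no files written).
#' @param seed global integer seed.
#' @param stages logical toggles: `regionmap`, `insertions`, `recomb`,
#'   `network`.
#' @param search,genemodel,recomb stage parameter sets.
#' @param max_locus_gap,min_locus_nt locus merging gap and length filter.
#' @param gap_threshold_bp split-detection threshold for the region map.
#' @param bootstrap_B,bootstrap_threshold split-network bootstrap settings.
#' @param exons_network exons projected into the recombination/network
#'   alignment (default 2:5).
#' @return a `run_config` list.
#' @export
run_config <- function(assembly, queries, markers = marker_panel(),
                       panel_cds = NULL, domain_tab = NULL, out_dir = NULL,
                       seed = 1L,
                       stages = c(regionmap = TRUE, insertions = TRUE,
                                  recomb = TRUE, network = TRUE),
                       search = search_params(),
                       genemodel = genemodel_params(),
                       recomb = recomb_params(),
                       max_locus_gap = 1000L, min_locus_nt = 400L,
                       gap_threshold_bp = 1e6,
                       bootstrap_B = 100L, bootstrap_threshold = 70,
                       exons_network = 2:5) {
  load_fa <- function(x, type) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      read_fasta(x, type) else x
  }
  cfg <- list(assembly = load_fa(assembly, "dna"),
              queries = load_fa(queries, "protein"),
              markers = load_fa(markers, "protein"),
              panel_cds = load_fa(panel_cds, "dna"),
              domain_tab = domain_tab, out_dir = out_dir,
              seed = as.integer(seed),
              stages = stages, search = search, genemodel = genemodel,
              recomb = recomb, max_locus_gap = as.integer(max_locus_gap),
              min_locus_nt = as.integer(min_locus_nt),
              gap_threshold_bp = gap_threshold_bp,
              bootstrap_B = as.integer(bootstrap_B),
              bootstrap_threshold = bootstrap_threshold,
              exons_network = exons_network)
  if (is.null(cfg$panel_cds)) stop("panel_cds is required")
  if (is.null(cfg$domain_tab)) stop("domain_tab is required")
  class(cfg) <- "run_config"
  cfg
}

#' Build a run configuration from a simulated assembly
#'
#' @param sim an `mhci_sim` from [plant_scaffolds()].
#' @param ... overrides passed to [run_config()].
#' @export
run_config_from_sim <- function(sim, ...) {
  stopifnot(inherits(sim, "mhci_sim"))
  run_config(assembly = sim$assembly, queries = sim$panel$queries,
             markers = sim$panel$markers, panel_cds = sim$panel$cds,
             domain_tab = sim$domains, seed = sim$config$seed, ...)
}

## Project the coding nucleotides of each model onto the reference columns
## of the chosen exons: a reference-coordinate alignment (gaps where a
## column is unaligned). Loci covering less than `min_cov` of the region
## are dropped.
exon_region_alignment <- function(gene_models, exons = 2:5, min_cov = 0.6) {
  dt <- gene_models$domain_tab
  sel <- dt[dt$exon %in% exons, ]
  cols <- min(sel$aa_start):max(sel$aa_end)
  rows <- list()
  for (id in names(gene_models$details)) {
    d <- gene_models$details[[id]]
    pr <- d$alignment$pairs
    pr <- pr[pr$ref_col %in% cols, , drop = FALSE]
    if (nrow(pr) / length(cols) < min_cov) next
    s <- rep("---", length(cols))
    i <- match(pr$ref_col, cols)
    s[i] <- substring(d$cds, pr$dna_end - 2L, pr$dna_end)
    rows[[id]] <- paste(s, collapse = "")
  }
  if (!length(rows)) return(NULL)
  .aln_matrix(unlist(rows))
}

## Lightweight content hash for provenance (rolling hash over serialized
## object, sampled).
cfg_hash <- function(x) {
  b <- serialize(x, NULL, version = 2L)
  h <- 0
  for (v in as.integer(b[seq(1L, length(b),
                             by = max(1L, length(b) %/% 4096L))]))
    h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full class I characterization pipeline
#'
#' Executes translated search, locus merging and filtering, gene-model
#' curation and classification, region mapping, alpha-1 insertion calling,
#' recombination screening and split-network construction, honoring the
#' stage toggles. Re-running with the same configuration gives identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress to stderr.
#' @return object of class `mhci_run`: `hits`, `loci`, `gene_models`,
#'   `repertoire`, `region` (or NULL), `insertions` (or NULL), `recomb`
#'   (or NULL), `network` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  stage <- function(name) isTRUE(config$stages[[name]])

  log_msg("stage search", verbose = verbose)
  hits <- search_assembly(config$queries, config$assembly, config$search,
                          verbose = verbose)
  locus_set <- merge_redundant_hits(hits, config$max_locus_gap)
  locus_set <- length_filter(locus_set, config$min_locus_nt,
                             evalue_max = config$search$evalue_max)
  if (!nrow(locus_set$loci))
    stop("stage search: no loci survived merging and filtering")

  log_msg("stage genemodel", verbose = verbose)
  gm <- build_gene_models(locus_set, config$assembly, config$queries,
                          config$domain_tab, config$panel_cds,
                          config$genemodel)
  if (is.null(gm$models) || !nrow(gm$models))
    stop("stage genemodel: no alignable gene models")
  confirmed <- gm$models[gm$models$confirmed, , drop = FALSE]
  gm$details <- gm$details[confirmed$locus_id]
  gm$models <- confirmed
  rep_tab <- repertoire_table(gm)

  region <- NULL
  if (stage("regionmap")) {
    log_msg("stage regionmap", verbose = verbose)
    region <- map_region(config$assembly, config$markers, gm$models,
                         config$search, config$gap_threshold_bp)
    gm$models <- region$models
  }

  ins <- NULL
  if (stage("insertions")) {
    log_msg("stage insertions", verbose = verbose)
    a1 <- extract_alpha1(gm)
    dt <- config$domain_tab
    a1r <- dt[dt$domain == "alpha1", ]
    refs <- Biostrings::AAStringSet(vapply(
      setNames(as.character(config$queries), names(config$queries)),
      function(p) substr(p, a1r$aa_start, a1r$aa_end), ""))
    names(refs) <- paste0("ref_", names(refs))
    if (length(a1) >= 1L) {
      msa <- profile_align_alpha1(a1, refs)
      calls <- call_insertions(msa)
      ins <- list(alpha1 = a1, msa = msa, calls = calls)
    }
  }

  rec <- NULL
  aln <- exon_region_alignment(gm, config$exons_network)
  if (stage("recomb") && !is.null(aln) && nrow(aln) >= 3L) {
    log_msg("stage recomb", verbose = verbose)
    rec <- scan_recombination(aln, config$recomb,
                              seed = derive_seed(config$seed, "recomb"))
  } else if (stage("network")) {
    log_msg("recomb stage off: network built on unpruned alignment",
            verbose = TRUE)
  }

  net <- NULL
  if (stage("network") && !is.null(aln)) {
    log_msg("stage network", verbose = verbose)
    naln <- if (!is.null(rec)) rec$pruned else aln
    if (nrow(naln) >= 4L) {
      net <- neighbornet(naln, on_saturation = "cap")
      net <- bootstrap_support(naln, net, B = config$bootstrap_B,
                               seed = derive_seed(config$seed, "network"),
                               threshold = config$bootstrap_threshold)
    }
  }

  manifest <- list(
    package = "mhciscan",
    version = as.character(utils::packageVersion("mhciscan")),
    seed = config$seed,
    config_hash = cfg_hash(config[setdiff(names(config), "out_dir")]),
    stages = as.list(config$stages),
    n_scaffolds = length(config$assembly),
    n_queries = length(config$queries),
    n_loci = nrow(locus_set$loci),
    n_models = nrow(gm$models),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  run <- structure(list(hits = hits, loci = locus_set, gene_models = gm,
                        repertoire = rep_tab, region = region,
                        insertions = ins, recomb = rec, network = net,
                        manifest = manifest), class = "mhci_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.mhci_run <- function(x, ...) {
  cat("mhci_run (seed ", x$manifest$seed, ", ",
      round(x$manifest$elapsed_s), "s)\n", sep = "")
  print(x$gene_models)
  if (!is.null(x$region)) print(x$region)
  if (!is.null(x$insertions))
    cat("insertion calls:", nrow(x$insertions$calls), "\n")
  if (!is.null(x$recomb))
    cat("consensus recombinants:",
        sum(x$recomb$events$consensus), "\n")
  if (!is.null(x$network)) print(x$network)
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' Emits gene models (GFF3 + TSV), the repertoire table, region map (BED +
#' TSV), insertion calls and MSA, recombination events, pruned alignment,
#' the split network (NEXUS + TSV) and a JSON manifest.
#'
#' @param run an `mhci_run`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- run$gene_models$models
  write_tsv(m, file.path(dir, "gene_models.tsv"))
  gff <- data.frame(
    seqid = m$scaffold_id, source = "mhciscan", type = "gene",
    start = m$g_start + 1L, end = m$g_end, score = ".",
    strand = m$strand, phase = ".",
    attributes = sprintf("ID=%s;functional_class=%s;completeness=%s%s",
                         m$locus_id, m$functional_class, m$completeness,
                         if (!is.null(m$assignment))
                           paste0(";block=", m$assignment) else ""),
    stringsAsFactors = FALSE)
  write_gff3(gff, file.path(dir, "gene_models.gff3"))
  write_tsv(run$repertoire, file.path(dir, "repertoire.tsv"))
  if (!is.null(run$region)) {
    bl <- run$region$blocks
    bl <- bl[bl$defined, , drop = FALSE]
    if (nrow(bl))
      write_bed(data.frame(chrom = bl$scaffold_id, start = bl$g_start,
                           end = bl$g_end, name = bl$block, score = 0,
                           strand = "."),
                file.path(dir, "blocks.bed"))
    write_tsv(run$region$marker_loci, file.path(dir, "marker_loci.tsv"))
    write_tsv(run$region$splits, file.path(dir, "region_splits.tsv"))
  }
  if (!is.null(run$insertions)) {
    write_tsv(run$insertions$calls, file.path(dir, "insertion_calls.tsv"))
    aln <- run$insertions$msa$aln
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(apply(aln, 1L, paste, collapse = "")),
      file.path(dir, "alpha1_msa.faa"), width = 60L)
  }
  if (!is.null(run$recomb)) {
    write_tsv(run$recomb$events, file.path(dir, "recombination_events.tsv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(apply(run$recomb$pruned, 1L, paste,
                                     collapse = "")),
      file.path(dir, "pruned_alignment.fa"), width = 60L)
  }
  if (!is.null(run$network)) {
    write_splits_nexus(run$network, file.path(dir, "network.nex"))
    write_tsv(run$network$splits, file.path(dir, "network_splits.tsv"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
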