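## Validated plain-text readers/writers for the pipeline's own emissions.
## Conventions: GFF3 is 1-based closed, BED is 0-based half-open, FASTA is
## wrapped at 60 columns (via Biostrings). Malformed records error with the
## offending line number.

GFF3_COLS <- c("seqid", "source", "type", "start", "end", "score", "strand",
               "phase", "attributes")

#' Write a GFF3 table
#'
#' @param df data.frame with the nine GFF3 columns (`start`/`end` 1-based
#'   closed).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(df, path) {
  stopifnot(all(GFF3_COLS %in% names(df)))
  if (any(df$end < df$start))
    stop("GFF3 record with end < start: row ",
         which(df$end < df$start)[1L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df))
    writeLines(do.call(paste, c(df[GFF3_COLS], sep = "\t")), con)
  invisible(path)
}

#' Read a GFF3 file written by this package
#'
#' @param path input file.
#' @return data.frame with the nine GFF3 columns; `start`/`end` integer.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx))
    return(setNames(data.frame(matrix(nrow = 0, ncol = 9)), GFF3_COLS))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) != 9L)
      stop("malformed GFF3 record (", length(p), " fields) at line ", idx[k])
    s <- suppressWarnings(as.integer(p[4L])); e <- suppressWarnings(as.integer(p[5L]))
    if (is.na(s) || is.na(e))
      stop("non-numeric GFF3 coordinates at line ", idx[k])
    if (e < s)
      stop("GFF3 end < start at line ", idx[k])
  }
  m <- do.call(rbind, parts)
  df <- setNames(as.data.frame(m, stringsAsFactors = FALSE), GFF3_COLS)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

## Pull one `key=value` attribute out of a GFF3 attribute string.
gff3_attr <- function(attributes, key) {
  m <- regmatches(attributes,
                  regexec(paste0("(?:^|;)", key, "=([^;]*)"), attributes))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
}

#' Write intervals as BED6 (0-based half-open)
#'
#' @param df data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  stopifnot(all(cols %in% names(df)))
  if (any(df$end < df$start))
    stop("BED record with end < start: row ", which(df$end < df$start)[1L])
  writeLines(do.call(paste, c(df[cols], sep = "\t")), path)
  invisible(path)
}

#' Read a BED6 file
#' @param path input file.
#' @return data.frame with the six BED columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  idx <- which(nzchar(lines) & !grepl("^(track|browser|#)", lines))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (!length(idx))
    return(setNames(data.frame(matrix(nrow = 0, ncol = 6)), cols))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) < 6L)
      stop("malformed BED record (", length(p), " fields) at line ", idx[k])
    s <- suppressWarnings(as.integer(p[2L])); e <- suppressWarnings(as.integer(p[3L]))
    if (is.na(s) || is.na(e) || e < s)
      stop("bad BED coordinates at line ", idx[k])
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  df <- setNames(as.data.frame(m, stringsAsFactors = FALSE), cols)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' Write / read a TSV table (header, no quoting, no row names)
#' @param df data.frame. @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read FASTA as DNA or protein
#' @param path FASTA file. @param type `"dna"` or `"protein"`.
#' @return a Biostrings XStringSet.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (type == "dna") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
}
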