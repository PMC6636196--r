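## NeighborNet split networks: Jukes-Cantor distances with pairwise
## deletion, the agglomerative NeighborNet circular ordering, non-negative
## least-squares estimation of circular split weights, bootstrap support
## over alignment columns, and SplitsTree-compatible NEXUS export.

#' Canonical key of a split (bipartition)
#'
#' The key is the sorted, `|`-joined side that does not contain the
#' lexicographically smallest taxon, so a split and its complement map to
#' the same key.
#'
#' @param members character vector: one side of the split.
#' @param taxa all taxa.
#' @return character key.
#' @export
split_key <- function(members, taxa) {
  ref <- sort(taxa)[1L]
  side <- if (ref %in% members) setdiff(taxa, members) else members
  paste(sort(side), collapse = "|")
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise deletion: sites where either sequence has a gap or ambiguity
#' are excluded for that pair. `d = -(3/4) ln(1 - (4/3) p)` for the observed
#' difference proportion `p`.
#'
#' @param aln aligned sequences (character matrix, named vector or
#'   XStringSet).
#' @param on_saturation `"error"` stops when some pair has `p >= 0.75`
#'   (reporting the pair); `"cap"` caps `p` just below saturation and flags
#'   the pair in `attr(, "saturated")`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
jc_distance <- function(aln, on_saturation = c("error", "cap")) {
  on_saturation <- match.arg(on_saturation)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  base <- c("A", "C", "G", "T")
  ok <- matrix(m %in% base, nrow = n)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- character()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- ok[i, ] & ok[j, ]
    if (!any(v)) stop("no comparable sites between ", rownames(m)[i],
                      " and ", rownames(m)[j])
    p <- mean(m[i, v] != m[j, v])
    if (p >= 0.75) {
      pair <- paste(rownames(m)[i], rownames(m)[j], sep = "/")
      if (on_saturation == "error")
        stop("Jukes-Cantor saturation (p >= 0.75) for pair ", pair)
      sat <- c(sat, pair)
      p <- 0.7499
    }
    D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  attr(D, "saturated") <- sat
  D
}

## Mean distance between two node sets.
.cluster_dist <- function(D, a, b) mean(D[a, b])

#' NeighborNet circular ordering
#'
#' Agglomerative NeighborNet selection and reduction: clusters (chains of
#' one or two active nodes) are joined by a neighbor-joining-style criterion
#' at the cluster level, the junction nodes are chosen by the corresponding
#' node-level criterion, and chains longer than two nodes are reduced by
#' replacing three consecutive nodes with two (distance updates 2/3-1/3).
#' Expansion of the reductions yields a circular ordering of the taxa.
#' Deterministic; ties break lexicographically by taxon label.
#'
#' @param D symmetric distance matrix with labelled rows/columns.
#' @return character vector: taxa in circular order.
#' @export
neighbornet_ordering <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  taxa <- rownames(D)
  n <- length(taxa)
  if (n <= 3L) return(sort(taxa))

  labels <- taxa                     # grows with reduction nodes
  clusters <- as.list(seq_len(n))    # chains of node indices
  reductions <- list()
  nred <- 0L

  ## canonical cluster order: by smallest taxon-ish label (determinism)
  canon <- function() {
    keys <- vapply(clusters, function(cl) min(labels[cl]), "")
    clusters <<- clusters[order(keys)]
  }

  while (length(clusters) > 1L) {
    canon()
    m <- length(clusters)
    if (m == 2L) {
      pick <- c(1L, 2L)
    } else {
      Dc <- matrix(0, m, m)
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
        Dc[i, j] <- Dc[j, i] <- .cluster_dist(D, clusters[[i]], clusters[[j]])
      R <- rowSums(Dc)
      Q <- (m - 2) * Dc - outer(R, R, `+`)
      diag(Q) <- Inf
      w <- which(Q == min(Q), arr.ind = TRUE)
      w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
      pick <- sort(w[1L, ])
    }
    A <- clusters[[pick[1L]]]; B <- clusters[[pick[2L]]]
    ## node-level selection: nodes of A and B individually, other clusters
    ## as units
    others <- clusters[-pick]
    mh <- length(others) + length(A) + length(B)
    bestQ <- Inf; bx <- A[1L]; by <- B[1L]
    for (x in A) for (y in B) {
      Rx <- sum(vapply(c(as.list(setdiff(A, x)), as.list(setdiff(B, y)),
                         others),
                       function(u) .cluster_dist(D, x, u), 0)) + D[x, y]
      Ry <- sum(vapply(c(as.list(setdiff(A, x)), as.list(setdiff(B, y)),
                         others),
                       function(u) .cluster_dist(D, y, u), 0)) + D[x, y]
      Qh <- (mh - 2) * D[x, y] - Rx - Ry
      better <- Qh < bestQ - 1e-12 ||
        (abs(Qh - bestQ) <= 1e-12 &&
           paste(labels[x], labels[y]) < paste(labels[bx], labels[by]))
      if (better) { bestQ <- Qh; bx <- x; by <- y }
    }
    ## orient chains so bx and by meet at the junction
    if (A[1L] == bx && length(A) > 1L) A <- rev(A)
    if (B[length(B)] == by && length(B) > 1L) B <- rev(B)
    chain <- c(A, B)
    ## reduce to a chain of two nodes
    while (length(chain) > 2L) {
      x <- chain[1L]; y <- chain[2L]; z <- chain[3L]
      nred <- nred + 1L
      for (nm in c("a", "b")) labels <- c(labels, sprintf("red%d%s", nred, nm))
      u <- length(labels) - 1L; v <- length(labels)
      du <- (2 / 3) * D[x, ] + (1 / 3) * D[y, ]
      dv <- (1 / 3) * D[y, ] + (2 / 3) * D[z, ]
      duv <- (D[x, y] + D[y, z] + D[x, z]) / 3
      D <- rbind(cbind(D, u = du, v = dv),
                 u = c(du, 0, duv), v = c(dv, duv, 0))
      rownames(D) <- colnames(D) <- labels
      reductions[[nred]] <- c(u = u, v = v, x = x, y = y, z = z)
      chain <- c(u, v, chain[-(1:3)])
    }
    clusters <- c(clusters[-pick], list(chain))
  }

  cycle <- clusters[[1L]]
  ## expand reductions in reverse order
  for (k in rev(seq_along(reductions))) {
    rd <- reductions[[k]]
    iu <- match(rd["u"], cycle); iv <- match(rd["v"], cycle)
    len <- length(cycle)
    if (is.na(iu) || is.na(iv))
      stop("internal error: reduction nodes missing from cycle")   # nocov
    nxt <- function(i) i %% len + 1L
    if (nxt(iu) == iv) {
      repl <- c(rd["x"], rd["y"], rd["z"]); at <- iu
    } else if (nxt(iv) == iu) {
      repl <- c(rd["z"], rd["y"], rd["x"]); at <- iv
    } else stop("internal error: reduced pair not adjacent")       # nocov
    before <- if (at > 1L) cycle[seq_len(at - 1L)] else integer()
    ## handle wrap-around adjacency (pair spans the end of the vector)
    if (at == len) {
      cycle <- c(repl[2L:3L], cycle[2:(len - 1L)], repl[1L])
    } else {
      cycle <- c(before, repl, if (at + 2L <= len) cycle[(at + 2L):len])
    }
  }
  ## rotate so the lexicographically smallest taxon is first, and fix
  ## reflection so the second element is the smaller neighbour
  ord <- labels[cycle]
  i0 <- which.min(match(ord, sort(taxa)))
  ord <- c(ord[i0:length(ord)], ord[seq_len(i0 - 1L)])
  if (length(ord) > 2L && ord[2L] > ord[length(ord)])
    ord <- c(ord[1L], rev(ord[-1L]))
  ord
}

#' All splits compatible with a circular ordering
#'
#' @param ordering circular taxon ordering.
#' @return list of character vectors (one side per split); every contiguous
#'   arc of the circle not containing the first taxon.
#' @export
circular_splits <- function(ordering) {
  n <- length(ordering)
  out <- list()
  for (i in 2:n) for (j in i:n)
    out[[length(out) + 1L]] <- ordering[i:j]
  out
}

#' Fit circular split weights by non-negative least squares
#'
#' The split-decomposition model `d(a, b) = sum of weights of splits
#' separating a and b` is fit over all splits compatible with the circular
#' ordering, with non-negativity enforced (Lawson-Hanson NNLS). On an
#' additive (tree) metric whose splits are compatible with the ordering the
#' fit is exact and non-tree splits get zero weight.
#'
#' @param D distance matrix.
#' @param ordering circular ordering of `rownames(D)`.
#' @param prune_epsilon splits with weight below this are dropped.
#' @return data.frame: `key` (canonical split key), `side` (taxa, joined by
#'   `|`), `size` (taxa on the side), `weight`.
#' @export
fit_split_weights <- function(D, ordering, prune_epsilon = 1e-8) {
  taxa <- ordering
  n <- length(taxa)
  splits <- circular_splits(ordering)
  pos <- setNames(seq_len(n), ordering)
  pairs <- utils::combn(taxa, 2L)
  np <- ncol(pairs); ns <- length(splits)
  C <- matrix(0, np, ns)
  in_split <- vapply(splits, function(s) pos[taxa] %in% pos[s],
                     logical(n))   # n x ns
  pi1 <- match(pairs[1L, ], taxa); pi2 <- match(pairs[2L, ], taxa)
  for (k in seq_len(ns)) C[, k] <- in_split[pi1, k] != in_split[pi2, k]
  dvec <- D[cbind(pairs[1L, ], pairs[2L, ])]
  fit <- pracma::lsqnonneg(C, dvec)
  w <- fit$x
  keep <- which(w > prune_epsilon)
  out <- data.frame(
    key = vapply(splits[keep], split_key, "", taxa = taxa),
    side = vapply(splits[keep], function(s) paste(sort(s), collapse = "|"),
                  ""),
    size = vapply(splits[keep], length, 0L),
    weight = w[keep], stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}

#' Build a NeighborNet split network
#'
#' @param x an alignment (matrix/XStringSet/named vector) or a distance
#'   matrix (with `is_distance = TRUE`).
#' @param is_distance set TRUE when `x` is already a distance matrix.
#' @param prune_epsilon minimum retained split weight.
#' @param on_saturation passed to [jc_distance()].
#' @return object of class `split_network`: `taxa` (circular order),
#'   `splits` (data.frame; `support` NA until [bootstrap_support()]),
#'   `D` (the distance matrix used).
#' @export
neighbornet <- function(x, is_distance = FALSE, prune_epsilon = 1e-8,
                        on_saturation = "error") {
  D <- if (is_distance) x else jc_distance(x, on_saturation)
  ord <- neighbornet_ordering(D)
  sp <- fit_split_weights(D, ord, prune_epsilon)
  sp$support <- NA_real_
  sp$strong <- NA
  structure(list(taxa = ord, splits = sp, D = D), class = "split_network")
}

#' @export
print.split_network <- function(x, ...) {
  cat("split_network:", length(x$taxa), "taxa,", nrow(x$splits),
      "splits (", sum(x$splits$size > 1), "non-trivial )\n")
  invisible(x)
}

#' Bootstrap support for the splits of a network
#'
#' Alignment columns are resampled with replacement `B` times; the support
#' of a split is the percentage of replicate networks containing the same
#' bipartition. Splits are annotated `strong` when support exceeds
#' `threshold` percent.
#'
#' @param aln the alignment the network was built from.
#' @param net a `split_network` built from `aln`.
#' @param B replicates (>= 100).
#' @param seed integer seed.
#' @param threshold strong-support threshold in percent (default 70:
#'   "greater than" semantics).
#' @param prune_epsilon minimum split weight counted in replicates.
#' @return the network with `support` and `strong` filled in.
#' @export
bootstrap_support <- function(aln, net, B = 1000L, seed = 1L,
                              threshold = 70, prune_epsilon = 1e-8) {
  stopifnot(B >= 100L, inherits(net, "split_network"))
  m <- .aln_matrix(aln)
  stopifnot(setequal(rownames(m), net$taxa))
  counts <- setNames(numeric(nrow(net$splits)), net$splits$key)
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      Db <- jc_distance(m[, cols, drop = FALSE], on_saturation = "cap")
      ordb <- neighbornet_ordering(Db)
      spb <- fit_split_weights(Db, ordb, prune_epsilon)
      hit <- names(counts) %in% spb$key
      counts[hit] <- counts[hit] + 1
    }
  })
  net$splits$support <- 100 * counts / B
  net$splits$strong <- net$splits$support > threshold
  net
}

#' Write a split network as a SplitsTree-compatible NEXUS file
#'
#' Emits Taxa, Distances and Splits blocks (cyclic split system with
#' weights; bootstrap supports as confidences when present).
#'
#' @param net a `split_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_splits_nexus <- function(net, path) {
  taxa <- net$taxa
  n <- length(taxa)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#nexus")
  w("BEGIN Taxa;")
  w("DIMENSIONS ntax=", n, ";")
  w("TAXLABELS")
  for (i in seq_len(n)) w("[", i, "] '", taxa[i], "'")
  w(";")
  w("END; [Taxa]")
  w("BEGIN Distances;")
  w("DIMENSIONS ntax=", n, ";")
  w("FORMAT labels=left diagonal triangle=both;")
  w("MATRIX")
  for (i in seq_len(n))
    w("'", taxa[i], "' ", paste(formatC(net$D[taxa[i], taxa],
                                        format = "g", digits = 8),
                                collapse = " "))
  w(";")
  w("END; [Distances]")
  has_conf <- !all(is.na(net$splits$support))
  w("BEGIN Splits;")
  w("DIMENSIONS ntax=", n, " nsplits=", nrow(net$splits), ";")
  w("FORMAT labels=no weights=yes confidences=",
    if (has_conf) "yes" else "no", ";")
  w("PROPERTIES fit=-1.0 cyclic;")
  w("CYCLE ", paste(seq_len(n), collapse = " "), ";")
  w("MATRIX")
  for (k in seq_len(nrow(net$splits))) {
    side <- strsplit(net$splits$side[k], "|", fixed = TRUE)[[1L]]
    idx <- sort(match(side, taxa))
    w("[", k, ", size=", length(idx), "]\t",
      formatC(net$splits$weight[k], format = "g", digits = 8),
      if (has_conf) paste0("\t", formatC(net$splits$support[k],
                                         format = "f", digits = 1)) else "",
      "\t", paste(idx, collapse = " "), ",")
  }
  w(";")
  w("END; [Splits]")
  invisible(path)
}
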