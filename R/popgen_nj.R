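#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining (Studier–Keppler update). Negative
#' branch-length estimates at a join are clamped to zero with the length
#' transferred to the sibling branch, preserving path lengths through the
#' joined pair.
#'
#' @param d symmetric distance matrix (plain distances, not squared) with
#'   sample ids as dimnames, or a `dist` object.
#' @return An unrooted `phylo` object (class from the \pkg{ape} package)
#'   with a trifurcating root node.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 samples")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  ids <- seq_len(n)                # active node ids; tips are 1..n
  D <- d
  storage.mode(D) <- "double"
  next_id <- n
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, unname(len))
  }
  while (length(ids) > 3L) {
    k <- length(ids)
    R <- rowSums(D)
    Q <- (k - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    m <- arrayInd(which.min(Q), dim(Q))
    i <- min(m); j <- max(m)
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (k - 2))
    lj <- dij - li
    if (li < 0) { lj <- dij; li <- 0 }
    if (lj < 0) { li <- dij; lj <- 0 }
    next_id <- next_id + 1L
    add_edge(next_id, ids[i], li)
    add_edge(next_id, ids[j], lj)
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    ids <- c(ids[keep], next_id)
  }
  # final trifurcation
  next_id <- next_id + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  fl <- pmax(c(l1, l2, l3), 0)
  for (a in 1:3) add_edge(next_id, ids[a], fl[a])
  # renumber internals so the root is n+1 and parents precede children
  n_internal <- next_id - n
  renum <- function(v) ifelse(v <= n, v, 3L * n - 1L - v)
  edge <- cbind(renum(edges[, 1L]), renum(edges[, 2L]))
  phy <- structure(list(edge = edge, edge.length = lens,
                        tip.label = labels, Nnode = n_internal),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Neighbor-joining tree from genotypes
#'
#' Convenience wrapper building the tree metric from a genotype matrix:
#' `"ibs"` (default) uses `1 - IBS` via [ibs_distance()]; `"euclidean"` uses
#' the square root of [squared_distance_matrix()] entries.
#'
#' @param g a [genotype_matrix()] or `labeled_collection`.
#' @param metric `"ibs"` or `"euclidean"`.
#' @param loci optional locus subset.
#' @return An unrooted `phylo` object.
#' @export
nj_genotypes <- function(g, metric = c("ibs", "euclidean"), loci = NULL) {
  metric <- match.arg(metric)
  if (inherits(g, "labeled_collection")) g <- g$g
  if (!is.null(loci)) g <- subset_genotypes(g, loci = loci)
  d <- switch(metric,
              ibs = ibs_distance(g),
              euclidean = sqrt(squared_distance_matrix(g)$d2))
  nj_tree(d)
}

# Canonical bipartition keys of all non-trivial internal edges of a tree.
# Each key is the sorted tip set on the side containing the smallest label.
bipartition_keys <- function(phy) {
  tips <- sort(phy$tip.label)
  anchor <- tips[1L]
  n <- length(phy$tip.label)
  parts <- ape::prop.part(phy)   # tip index sets per internal node
  keys <- character(0)
  for (p in parts) {
    set <- phy$tip.label[p]
    if (length(set) <= 1L || length(set) >= n - 1L) next
    if (!(anchor %in% set)) set <- setdiff(phy$tip.label, set)
    keys <- c(keys, paste(sort(set), collapse = "|"))
  }
  unique(keys)
}

#' Locus-bootstrap support for a neighbor-joining tree
#'
#' Builds a reference NJ tree, then resamples loci with replacement
#' `n_boot` times, rebuilds the tree each time, and scores every internal
#' edge of the reference tree by the percentage of replicates containing the
#' same leaf bipartition. Supports are attached as internal node labels
#' (newick-standard placement; the root label is empty).
#'
#' @param g a [genotype_matrix()] or `labeled_collection`.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param metric tree metric, see [nj_genotypes()].
#' @param loci optional locus subset.
#' @return The reference `phylo` with `node.label` holding integer percent
#'   supports, plus attribute `n_boot`.
#' @export
bootstrap_support <- function(g, n_boot = 200L, seed = NULL,
                              metric = c("ibs", "euclidean"), loci = NULL) {
  metric <- match.arg(metric)
  if (inherits(g, "labeled_collection")) g <- g$g
  if (!is.null(loci)) g <- subset_genotypes(g, loci = loci)
  if (ncol(g$dosage) < 2L) stop("need at least 2 loci to bootstrap")
  ref <- nj_genotypes(g, metric = metric)
  n <- length(ref$tip.label)
  rep_keys <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      li <- sample(ncol(g$dosage), replace = TRUE)
      # resampling duplicates locus ids; rebuild under unique names
      Xb <- g$dosage[, li, drop = FALSE]
      colnames(Xb) <- paste0("b", seq_along(li))
      gb <- genotype_matrix(Xb, g$sample_ids, colnames(Xb))
      bipartition_keys(nj_genotypes(gb, metric = metric))
    })
  })
  # support per internal node of the reference tree
  anchor <- sort(ref$tip.label)[1L]
  parts <- ape::prop.part(ref)
  node_lab <- character(ref$Nnode)
  for (v in seq_along(parts)) {
    set <- ref$tip.label[parts[[v]]]
    if (length(set) <= 1L || length(set) >= n - 1L) { node_lab[v] <- ""; next }
    if (!(anchor %in% set)) set <- setdiff(ref$tip.label, set)
    key <- paste(sort(set), collapse = "|")
    hits <- vapply(rep_keys, function(ks) key %in% ks, logical(1))
    node_lab[v] <- as.character(round(100 * mean(hits)))
  }
  ref$node.label <- node_lab
  attr(ref, "n_boot") <- as.integer(n_boot)
  ref
}

#' Are a taxon's accessions monophyletic in a tree?
#'
#' @param phy a `phylo` object.
#' @param tips tip labels of the putative clade.
#' @return `TRUE` when `tips` form one side of some edge of the (unrooted)
#'   tree.
#' @export
is_clade <- function(phy, tips) {
  n <- length(phy$tip.label)
  if (length(tips) %in% c(1L, n)) return(TRUE)
  anchor <- sort(phy$tip.label)[1L]
  set <- sort(tips)
  if (!(anchor %in% set)) set <- sort(setdiff(phy$tip.label, set))
  key <- paste(set, collapse = "|")
  # include trivial splits around single tips
  if (length(setdiff(phy$tip.label, set)) == 1L) return(TRUE)
  key %in% bipartition_keys(phy)
}
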