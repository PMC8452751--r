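# Mean-imputed, centered dosage matrix (loci with no calls become all-zero).
impute_center <- function(g) {
  if (inherits(g, "labeled_collection")) g <- g$g
  X <- g$dosage
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- mu[j]
    X[, j] <- xj - mu[j]
  }
  X
}

#' Principal component analysis of a genotype matrix
#'
#' PCA of per-locus mean-imputed, centered dosages (no scaling). A constant
#' matrix yields all-zero eigenvalues rather than an error.
#'
#' @param g a [genotype_matrix()] or `labeled_collection`.
#' @param loci optional subset of loci.
#' @return List of class `genotype_pca`: `scores` (samples x components),
#'   `eigenvalues` (component variances, non-increasing), `pct_variance`.
#' @export
pca_genotypes <- function(g, loci = NULL) {
  if (inherits(g, "labeled_collection")) g <- g$g
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) < 2L) stop("need at least 2 samples")
  if (!is.null(loci)) g <- subset_genotypes(g, loci = loci)
  X <- impute_center(g)
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  tot <- sum(eig)
  structure(list(scores = pc$x, eigenvalues = eig,
                 pct_variance = if (tot > 0) 100 * eig / tot else eig * 0,
                 sample_ids = g$sample_ids),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("genotype_pca:", nrow(x$scores), "samples\n  variance explained:",
      paste0(sprintf("%.1f%%", x$pct_variance[1:k]), collapse = ", "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  invisible(x)
}

# Mean silhouette width of a hard clustering given a distance matrix.
mean_silhouette <- function(d, cluster) {
  n <- length(cluster)
  ks <- sort(unique(cluster))
  if (length(ks) < 2L) return(NA_real_)
  sizes <- table(factor(cluster, levels = ks))
  # mean distance from each point to each cluster
  agg <- sapply(ks, function(k) rowSums(d[, cluster == k, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(cluster[i], ks)
    ni <- sizes[[ci]]
    if (ni <= 1L) { s[i] <- 0; next }
    a <- agg[i, ci] / (ni - 1L)
    b <- min(agg[i, -ci] / as.numeric(sizes[-ci]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' DAPC-style cluster-number selection and discriminant analysis
#'
#' Mirrors the find-clusters workflow: PCA transformation, k-means over a
#' range of K on the retained PCs, model choice by BIC
#' (`n * log(WSS_K / n) + K * log(n)`) cross-checked by mean silhouette
#' width, then discriminant axes from the between/within scatter of the
#' chosen clustering and soft memberships from discriminant-space distances.
#' BIC decides when the two criteria disagree (the disagreement is
#' reported).
#'
#' @param g a [genotype_matrix()] or `labeled_collection`.
#' @param K_max largest number of clusters tried (K = 1..K_max).
#' @param n_pcs PCs retained; default: smallest number explaining >= 90\% of
#'   variance, capped at `n - K_max - 1`.
#' @param seed RNG seed for the k-means starts.
#' @param n_start random starts per k-means run.
#' @param loci optional locus subset.
#' @return List of class `dapc_result`: `K_range`, `bic`, `silhouette`,
#'   `chosen_K`, `silhouette_K`, `criteria_agree`, `n_pcs`, `cluster`
#'   (assignments at `chosen_K`), `membership` (rows sum to 1),
#'   `disc_scores`.
#' @export
dapc_clusters <- function(g, K_max = 20L, n_pcs = NULL, seed = NULL,
                          n_start = 10L, loci = NULL) {
  if (inherits(g, "labeled_collection")) g <- g$g
  n <- nrow(g$dosage)
  if (K_max >= n) stop("K_max must be smaller than the number of samples")
  pc <- pca_genotypes(g, loci = loci)
  if (is.null(n_pcs)) {
    cum <- cumsum(pc$pct_variance)
    n_pcs <- which(cum >= 90)[1L]
    if (is.na(n_pcs)) n_pcs <- length(pc$eigenvalues)
  }
  n_pcs <- max(1L, min(n_pcs, n - K_max - 1L, sum(pc$eigenvalues > 1e-12)))
  S <- pc$scores[, seq_len(n_pcs), drop = FALSE]
  Ks <- seq_len(K_max)
  dmat <- as.matrix(stats::dist(S))
  fits <- vector("list", K_max)
  wss <- bic <- sil <- rep(NA_real_, K_max)
  with_seed(seed, {
    for (K in Ks) {
      if (K == 1L) {
        wss[K] <- sum(scale(S, scale = FALSE)^2)
        sil[K] <- NA_real_
      } else {
        fit <- tryCatch(
          kmeans(S, centers = K, nstart = n_start, iter.max = 100L),
          error = function(e) NULL)   # K exceeds distinct points
        if (is.null(fit)) next
        fits[[K]] <- fit
        wss[K] <- fit$tot.withinss
        sil[K] <- mean_silhouette(dmat, fit$cluster)
      }
      bic[K] <- if (wss[K] > 0) n * log(wss[K] / n) + K * log(n) else -Inf
    }
  })
  chosen_K <- Ks[which.min(bic)]
  silhouette_K <- if (all(is.na(sil))) NA_integer_ else Ks[which.max(sil)]
  cluster <- if (chosen_K == 1L) rep(1L, n) else fits[[chosen_K]]$cluster
  da <- discriminant_axes(S, cluster)
  structure(list(K_range = Ks, bic = bic, silhouette = sil, wss = wss,
                 chosen_K = chosen_K, silhouette_K = silhouette_K,
                 criteria_agree = isTRUE(chosen_K == silhouette_K),
                 n_pcs = n_pcs, cluster = cluster,
                 membership = da$membership, disc_scores = da$scores,
                 sample_ids = g$sample_ids),
            class = "dapc_result")
}

# Discriminant axes by eigen-decomposition of W^-1 B on PC coordinates,
# plus soft memberships from squared distances to centroids.
discriminant_axes <- function(S, cluster) {
  n <- nrow(S); ks <- sort(unique(cluster)); K <- length(ks)
  if (K == 1L) {
    memb <- matrix(1, n, 1L, dimnames = list(rownames(S), "1"))
    return(list(scores = S[, 0, drop = FALSE], membership = memb))
  }
  centroids <- do.call(rbind, lapply(ks, function(k)
    colMeans(S[cluster == k, , drop = FALSE])))
  gm <- colMeans(S)
  W <- matrix(0, ncol(S), ncol(S))
  B <- matrix(0, ncol(S), ncol(S))
  for (j in seq_along(ks)) {
    Xk <- S[cluster == ks[j], , drop = FALSE]
    ck <- centroids[j, ]
    Xc <- sweep(Xk, 2L, ck)
    W <- W + crossprod(Xc)
    B <- B + nrow(Xk) * tcrossprod(ck - gm)
  }
  ridge <- diag(1e-8 * max(diag(W), 1), ncol(S))
  ev <- eigen(solve(W + ridge, B))
  r <- min(K - 1L, ncol(S))
  A <- Re(ev$vectors[, seq_len(r), drop = FALSE])
  scores <- S %*% A
  cen_d <- centroids %*% A
  d2 <- sapply(seq_len(K), function(j)
    rowSums(sweep(scores, 2L, cen_d[j, ])^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = n)
  # softmax of negative squared distance, scaled by the mean within spread
  tau <- mean(vapply(seq_len(n), function(i) d2[i, match(cluster[i], ks)],
                     numeric(1)))
  tau <- max(tau, 1e-8)
  logw <- -d2 / (2 * tau)
  logw <- logw - apply(logw, 1L, max)
  w <- exp(logw)
  memb <- w / rowSums(w)
  dimnames(memb) <- list(rownames(S), ks)
  list(scores = scores, membership = memb)
}

#' @export
print.dapc_result <- function(x, ...) {
  cat("dapc_result: chosen K =", x$chosen_K,
      sprintf("(BIC; silhouette suggests K = %s%s)",
              x$silhouette_K,
              if (isTRUE(x$criteria_agree)) ", agree" else ""), "\n")
  cat("  retained PCs:", x$n_pcs, "\n")
  invisible(x)
}
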