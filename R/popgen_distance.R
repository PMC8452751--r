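#' Pairwise squared-distance matrix from dosages
#'
#' Squared Euclidean distance on allele dosages, computed over loci
#' non-missing in both samples and rescaled by `L / L_obs(i, j)`
#' (pairwise-complete scaling), so entries stay on a common scale of `L`
#' loci. With `policy = "binary"` dosages are first recoded to presence of
#' the second allele (`d > 0`).
#'
#' @param g a [genotype_matrix()] (or a `labeled_collection`).
#' @param policy `"dosage"` (default) or `"binary"`.
#' @return List of class `squared_distance`: `d2` (symmetric matrix with
#'   zero diagonal), `sample_ids`, `n_loci`, `policy`.
#' @export
squared_distance_matrix <- function(g, policy = c("dosage", "binary")) {
  policy <- match.arg(policy)
  if (inherits(g, "labeled_collection")) g <- g$g
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) < 2L) stop("need at least 2 samples")
  X <- g$dosage
  if (policy == "binary") X <- (X > 0L) * 1L
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  storage.mode(X0) <- "double"; storage.mode(M) <- "double"
  S <- (X0^2) %*% t(M)
  cross <- X0 %*% t(X0)
  raw <- S + t(S) - 2 * cross
  L_obs <- M %*% t(M)
  if (any(L_obs[upper.tri(L_obs)] == 0)) {
    ij <- which(L_obs == 0 & upper.tri(L_obs), arr.ind = TRUE)[1L, ]
    stop("samples ", g$sample_ids[ij[1L]], " and ", g$sample_ids[ij[2L]],
         " share no non-missing loci")
  }
  d2 <- raw * ncol(X) / L_obs
  diag(d2) <- 0
  d2 <- (d2 + t(d2)) / 2
  dimnames(d2) <- list(g$sample_ids, g$sample_ids)
  structure(list(d2 = d2, sample_ids = g$sample_ids, n_loci = ncol(X),
                 policy = policy),
            class = "squared_distance")
}

#' Identity-by-state distance matrix
#'
#' `1 - IBS`, where IBS is the mean shared-allele fraction
#' (`1 - |d_i - d_j| / 2` per locus) over loci non-missing in both samples.
#' Bounded in `[0, 1]` and robust to missing data; the default tree metric.
#'
#' @param g a [genotype_matrix()] (or a `labeled_collection`).
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
ibs_distance <- function(g) {
  if (inherits(g, "labeled_collection")) g <- g$g
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$dosage
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  storage.mode(X0) <- "double"; storage.mode(M) <- "double"
  S <- (X0^2) %*% t(M)
  raw2 <- S + t(S) - 2 * (X0 %*% t(X0))      # sum (d_i - d_j)^2
  A0 <- (M & X == 0L) * 1; A2 <- (M & X == 2L) * 1
  opp <- A0 %*% t(A2); opp <- opp + t(opp)   # opposite-homozygote pairs
  abs_sum <- raw2 - 2 * opp                  # sum |d_i - d_j|
  L_obs <- M %*% t(M)
  if (any(L_obs[upper.tri(L_obs)] == 0)) stop("a sample pair shares no loci")
  d <- abs_sum / (2 * L_obs)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(g$sample_ids, g$sample_ids)
  d
}

# Core AMOVA sums of squares from a squared-distance matrix and labels.
amova_ss <- function(d2, labels) {
  N <- nrow(d2)
  ss_total <- sum(d2) / (2 * N)
  groups <- split(seq_len(N), labels)
  ss_within <- sum(vapply(groups, function(idx)
    sum(d2[idx, idx]) / (2 * length(idx)), numeric(1)))
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' Assemble AMOVA components from sums of squares
#'
#' Deterministic one-level AMOVA bookkeeping: degrees of freedom, mean
#' squares, the weighted group-size coefficient
#' `n0 = (N - sum(n_g^2) / N) / (k - 1)`, variance components
#' `sigma2_within = MS_within` and
#' `sigma2_among = max(0, (MS_among - MS_within) / n0)` (negative estimates
#' clamped to zero), percentages, and `PhiPT = sigma2_among /
#' (sigma2_among + sigma2_within)`.
#'
#' @param ss_among,ss_within sums of squares among/within groups.
#' @param group_sizes integer vector of group sizes (k >= 2, all >= 1).
#' @return List of class `amova_result`.
#' @export
amova_components <- function(ss_among, ss_within, group_sizes) {
  group_sizes <- as.numeric(group_sizes)
  k <- length(group_sizes)
  if (k < 2L) stop("need at least 2 groups")
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  N <- sum(group_sizes)
  df_among <- k - 1
  df_within <- N - k
  if (df_within <= 0) stop("no within-group degrees of freedom")
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(group_sizes^2) / N) / (k - 1)
  var_within <- max(0, ms_within)
  var_among <- max(0, (ms_among - ms_within) / n0)
  total_var <- var_among + var_within
  phipt <- if (total_var > 0) var_among / total_var else 0
  structure(list(
    df_among = df_among, df_within = df_within, df_total = df_among + df_within,
    ss_among = ss_among, ss_within = ss_within, ss_total = ss_among + ss_within,
    ms_among = ms_among, ms_within = ms_within,
    n0 = n0, var_among = var_among, var_within = var_within,
    pct_among = if (total_var > 0) 100 * var_among / total_var else 0,
    pct_within = if (total_var > 0) 100 * var_within / total_var else 100,
    phipt = phipt, p_value = NA_real_, n_perm = 0L,
    group_sizes = group_sizes), class = "amova_result")
}

#' One-level AMOVA with PhiPT and a permutation test
#'
#' Distance-based analysis of molecular variance:
#' `SS_total = sum_{i<j} d2_ij / N`,
#' `SS_within = sum_g sum_{i<j in g} d2_ij / n_g`, `SS_among` by
#' subtraction. PhiPT (an Fst analogue that suppresses within-individual
#' variance) is the among-group share of the summed variance components. The
#' p-value permutes group labels: `p = (1 + #{PhiPT_perm >= PhiPT_obs}) /
#' (n_perm + 1)`.
#'
#' @param d2 a [squared_distance_matrix()] result (or a bare symmetric
#'   matrix of squared distances).
#' @param labels group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed RNG seed for the permutations.
#' @return An `amova_result` (see [amova_components()]) with `p_value`,
#'   `n_perm` and `phipt_perm` filled in.
#' @export
amova <- function(d2, labels, n_perm = 999L, seed = NULL) {
  if (inherits(d2, "squared_distance")) d2 <- d2$d2
  stopifnot(is.matrix(d2), nrow(d2) == ncol(d2))
  labels <- as.character(labels)
  if (length(labels) != nrow(d2)) stop("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("groups of size 1 not allowed: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  ss <- amova_ss(d2, labels)
  res <- amova_components(ss[["among"]], ss[["within"]], as.integer(sizes))
  names(res$group_sizes) <- names(sizes)
  if (n_perm > 0L) {
    obs <- res$phipt
    perm_phi <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        lab_b <- sample(labels)
        ss_b <- amova_ss(d2, lab_b)
        amova_components(ss_b[["among"]], ss_b[["within"]], as.integer(sizes))$phipt
      }, numeric(1))
    })
    res$p_value <- (1 + sum(perm_phi >= obs)) / (n_perm + 1)
    res$n_perm <- as.integer(n_perm)
    res$phipt_perm <- perm_phi
  }
  res
}

#' @export
print.amova_result <- function(x, digits = 3, ...) {
  cat("AMOVA (one level)\n")
  tab <- data.frame(
    Source = c("Among pops", "Within pops", "Total"),
    df = c(x$df_among, x$df_within, x$df_total),
    SS = round(c(x$ss_among, x$ss_within, x$ss_total), digits),
    MS = c(round(x$ms_among, digits), round(x$ms_within, digits), NA),
    Est.var = round(c(x$var_among, x$var_within, x$var_among + x$var_within), digits),
    Pct = round(c(x$pct_among, x$pct_within, 100), 0))
  print(tab, row.names = FALSE)
  cat(sprintf("PhiPT = %.3f", x$phipt))
  if (!is.na(x$p_value))
    cat(sprintf("  (P = %.3g, %d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Pairwise PhiPT between all group pairs
#'
#' Runs [amova()] on every pair of groups' samples. By reporting convention
#' PhiPT values sit below the diagonal and permutation p-values above it.
#'
#' @param g a [genotype_matrix()] or `labeled_collection`.
#' @param labels group labels (taken from the collection when omitted).
#' @param n_perm,seed permutation settings per pair.
#' @param policy distance policy, see [squared_distance_matrix()].
#' @return List of class `pairwise_phipt`: `phipt` and `p` (k x k matrices),
#'   `n_perm`.
#' @export
pairwise_phipt <- function(g, labels = NULL, n_perm = 999L, seed = NULL,
                           policy = "dosage") {
  if (inherits(g, "labeled_collection")) {
    labels <- labels %||% unname(g$taxa)
    g <- g$g
  }
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels)
  sd2 <- squared_distance_matrix(g, policy = policy)
  d2 <- sd2$d2
  grp <- sort(unique(labels))
  k <- length(grp)
  phi <- matrix(NA_real_, k, k, dimnames = list(grp, grp))
  pv <- matrix(NA_real_, k, k, dimnames = list(grp, grp))
  diag(phi) <- 0
  seeds <- if (is.null(seed)) vector("list", k * k) else NULL
  pair_no <- 0L
  for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
    pair_no <- pair_no + 1L
    idx <- which(labels %in% c(grp[a], grp[b]))
    res <- amova(d2[idx, idx, drop = FALSE], labels[idx], n_perm = n_perm,
                 seed = if (is.null(seed)) NULL else seed + pair_no)
    phi[b, a] <- phi[a, b] <- res$phipt
    pv[a, b] <- pv[b, a] <- res$p_value
  }
  structure(list(phipt = phi, p = pv, n_perm = as.integer(n_perm)),
            class = "pairwise_phipt")
}

#' @export
print.pairwise_phipt <- function(x, digits = 3, ...) {
  k <- nrow(x$phipt)
  out <- matrix("", k, k, dimnames = dimnames(x$phipt))
  out[lower.tri(out)] <- sprintf("%.*f", digits, x$phipt[lower.tri(x$phipt)])
  if (!all(is.na(x$p)))
    out[upper.tri(out)] <- sprintf("%.3f", x$p[upper.tri(x$p)])
  cat("Pairwise PhiPT (below diagonal); permutation P (above)\n")
  print(as.data.frame(out), right = TRUE)
  invisible(x)
}
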