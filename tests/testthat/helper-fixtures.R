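# Shared fixture builders. Everything is generated in code; no data files.

# Tiny genotype matrix with known alleles.
tiny_genotypes <- function() {
  d <- rbind(s1 = c(0L, 0L, 2L, 1L),
             s2 = c(0L, 1L, 2L, NA),
             s3 = c(2L, 2L, 0L, 0L),
             s4 = c(2L, NA, 0L, 0L))
  colnames(d) <- paste0("L", 1:4)
  genotype_matrix(d, alleles = cbind(rep("A", 4), rep("G", 4)))
}

# Two clean groups fixed for opposite alleles at every locus.
two_group_fixture <- function(n_per = 4L, n_loci = 6L) {
  d <- rbind(matrix(0L, n_per, n_loci), matrix(2L, n_per, n_loci))
  rownames(d) <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  colnames(d) <- paste0("L", seq_len(n_loci))
  g <- genotype_matrix(d)
  meta <- data.frame(sample_id = rownames(d),
                     taxon = rep(c("alpha", "beta"), each = n_per))
  attach_labels(g, meta)
}

# Down-scaled synthetic collection for fast pipeline-level tests.
small_collection <- function(seed = 11L, factor = 0.15, ...) {
  cfg <- scale_config(collection_config(seed = seed, ...), factor)
  simulate_collection(cfg)
}

# Clean collection: deterministic machinery tests. Planted calls are exact
# (no flips, no heterozygote injection); missingness and the planted hybrids
# remain, so denominators and the joint-pair logic are still exercised.
clean_collection <- function(seed = 7L, factor = 0.3) {
  base <- collection_config(seed = seed, fixation = 1, het_rate = 0,
                            missing_max = 0.05, high_missing_rate = 0.05)
  cfg <- unclass(scale_config(base, factor))
  cfg$contrast_loci["G1"] <- max(2L, cfg$contrast_loci[["G1"]])  # keep a pair
  simulate_collection(do.call(collection_config, cfg))
}

# Naive per-entry marker summary used as a counting oracle.
naive_marker_summary <- function(g) {
  d <- g$dosage
  do.call(rbind, lapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    called <- x[!is.na(x)]
    n <- length(called)
    p_alt <- if (n) sum(called) / (2 * n) else NA_real_
    data.frame(locus_id = g$locus_ids[j], n_called = n,
               missing_rate = mean(is.na(x)),
               het_rate = if (n) mean(called == 1L) else NA_real_,
               p_alt = p_alt, maf = min(p_alt, 1 - p_alt),
               he = 1 - p_alt^2 - (1 - p_alt)^2)
  }))
}

# Brute-force squared distances with pairwise-complete rescaling.
naive_d2 <- function(g) {
  X <- g$dosage
  n <- nrow(X); L <- ncol(X)
  out <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- !is.na(X[i, ]) & !is.na(X[j, ])
    out[i, j] <- sum((X[i, shared] - X[j, shared])^2) * L / sum(shared)
  }
  out
}

# Spreadsheet-style independent AMOVA assembly (scalar arithmetic only).
naive_amova_components <- function(ss_among, ss_within, sizes) {
  k <- length(sizes); N <- sum(sizes)
  msa <- ss_among / (k - 1)
  msw <- ss_within / (N - k)
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  va <- max(0, (msa - msw) / n0)
  list(msa = msa, msw = msw, n0 = n0, va = va,
       phipt = if (va + msw > 0) va / (va + msw) else 0)
}
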