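#' Allele frequencies at one locus
#'
#' Frequencies of the two alleles from dosage calls, missing excluded:
#' `p_alt = sum(dosage) / (2 * n_called)`.
#'
#' @param g a [genotype_matrix()].
#' @param locus locus id or column index.
#' @return Named numeric vector `c(p_ref, p_alt)`.
#' @export
allele_frequencies <- function(g, locus) {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- if (is.character(locus)) match(locus, g$locus_ids) else locus
  if (is.na(j)) stop("unknown locus: ", locus)
  d <- g$dosage[, j]
  n <- sum(!is.na(d))
  if (n == 0L) stop("locus ", g$locus_ids[j], " has no non-missing calls")
  p_alt <- sum(d, na.rm = TRUE) / (2 * n)
  c(p_ref = 1 - p_alt, p_alt = p_alt)
}

#' Gene diversity (expected heterozygosity)
#'
#' `He = 1 - sum(p^2)` over allele frequencies `p`.
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @return Gene diversity in `[0, 1)`.
#' @export
gene_diversity <- function(p) {
  stopifnot(is.numeric(p), abs(sum(p) - 1) < 1e-8)
  1 - sum(p^2)
}

#' Polymorphism information content
#'
#' Botstein-style PIC:
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @return PIC value; for biallelic loci bounded by 0.375.
#' @export
pic <- function(p) {
  stopifnot(is.numeric(p), abs(sum(p) - 1) < 1e-8)
  p2 <- p^2
  cross <- (sum(p2)^2 - sum(p2^2)) / 2   # sum_{i<j} p_i^2 p_j^2
  1 - sum(p2) - 2 * cross
}

#' Per-marker summary statistics
#'
#' One row per locus: calls, missing rate, observed heterozygote rate,
#' allele frequencies, MAF, gene diversity and PIC. Loci with no non-missing
#' calls are flagged (`all_missing = TRUE`) and carry `NA` statistics.
#'
#' @param g a [genotype_matrix()].
#' @return A data frame of class `marker_summary`.
#' @export
summarize_markers <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  n_samples <- nrow(d)
  called <- colSums(!is.na(d))
  miss <- 1 - called / n_samples
  het <- ifelse(called > 0, colSums(d == 1L, na.rm = TRUE) / called, NA_real_)
  p_alt <- ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  he <- 1 - (p_alt^2 + (1 - p_alt)^2)
  pic_v <- he - 2 * p_alt^2 * (1 - p_alt)^2
  out <- data.frame(
    locus_id = g$locus_ids, n_called = as.integer(called),
    missing_rate = miss, het_rate = het, p_ref = 1 - p_alt, p_alt = p_alt,
    maf = maf, he = he, pic = pic_v, all_missing = called == 0L,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("marker_summary", "data.frame")
  out
}

#' Marker quality-filter cascade
#'
#' Keeps a locus iff `maf >= maf_min` and `pic >= pic_min` and
#' `het_rate <= het_max` and `missing_rate <= missing_max` (removal rules are
#' strict inequalities, so boundary values are kept). Each rejected locus is
#' annotated with the first failing rule in the fixed order MAF, PIC,
#' heterozygosity, missing; membership is conjunctive regardless of that
#' order. Loci with undefined statistics (all calls missing) fail the MAF
#' rule.
#'
#' @param summaries a [summarize_markers()] table.
#' @param maf_min,pic_min,het_max,missing_max thresholds; defaults are the
#'   rates used for KASP panel curation (MAF < 5\%, PIC < 18\%, het > 9\%,
#'   missing > 24\% removed).
#' @return Data frame with `locus_id`, `kept` and `reason`
#'   (`NA` for kept loci; otherwise `"MAF"`, `"PIC"`, `"het"`, `"missing"`).
#' @export
filter_markers <- function(summaries, maf_min = 0.05, pic_min = 0.18,
                           het_max = 0.09, missing_max = 0.24) {
  stopifnot(is.data.frame(summaries),
            all(c("locus_id", "maf", "pic", "het_rate", "missing_rate")
                %in% names(summaries)))
  fail_maf <- is.na(summaries$maf) | summaries$maf < maf_min
  fail_pic <- !is.na(summaries$pic) & summaries$pic < pic_min
  fail_het <- !is.na(summaries$het_rate) & summaries$het_rate > het_max
  fail_mis <- summaries$missing_rate > missing_max
  reason <- rep(NA_character_, nrow(summaries))
  reason[fail_mis] <- "missing"
  reason[fail_het] <- "het"
  reason[fail_pic] <- "PIC"
  reason[fail_maf] <- "MAF"       # assigned last so the first rule wins
  data.frame(locus_id = summaries$locus_id, kept = is.na(reason),
             reason = reason, stringsAsFactors = FALSE)
}
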