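# build a labeled collection straight from a dosage matrix and taxon vector
lg_from <- function(d, taxa) {
  g <- genotype_matrix(d, rownames(d), colnames(d))
  attach_labels(g, data.frame(sample_id = rownames(d), taxon = taxa))
}

test_that("diagnostic_allele picks the minor allele fixed in the target", {
  # target (10) fixed alt, complex (80) fixed ref: overall p_alt ~ 0.11
  d <- cbind(L = c(rep(2L, 10), rep(0L, 80)))
  rownames(d) <- paste0("s", 1:90)
  lg <- lg_from(d, c(rep("t", 10), rep("c", 80)))
  ct <- group_contrast("X", "t", "c")
  expect_equal(diagnostic_allele(lg, ct, "L"), 2L)
  # 50/50 split along the boundary: deterministic via the minor tie-break
  d2 <- cbind(L = c(rep(2L, 45), rep(0L, 45)))
  rownames(d2) <- paste0("s", 1:90)
  lg2 <- lg_from(d2, c(rep("t", 45), rep("c", 45)))
  expect_equal(diagnostic_allele(lg2, ct, "L"), 2L)
  # monomorphic locus: no diagnostic allele
  d3 <- cbind(L = rep(0L, 90)); rownames(d3) <- paste0("s", 1:90)
  expect_true(is.na(diagnostic_allele(lg_from(d3, c(rep("t", 10), rep("c", 80))),
                                      ct, "L")))
})

test_that("recovered diagnostic alleles equal planted truth", {
  sim <- clean_collection(seed = 21)
  planted <- names(sim$truth$locus_contrast)[
    sim$truth$locus_contrast != "background"]
  hits <- vapply(planted, function(l) {
    ct <- sim$contrasts[[sim$truth$locus_contrast[[l]]]]
    identical(diagnostic_allele(sim$lg, ct, l),
              sim$truth$diagnostic_allele[[l]])
  }, logical(1))
  expect_true(all(hits))
})

test_that("concordance matches expectations and a per-accession tally", {
  lg <- two_group_fixture()
  ct <- group_contrast("AB", "beta", "alpha")
  sc <- concordance(lg, ct, "L1")
  expect_equal(unname(sc$per_group), c(1, 1))
  expect_true(sc$pass)
  # 81-of-88 scenario: fails the strict 0.97 rule
  d <- cbind(L = c(rep(2L, 81), rep(0L, 7), rep(0L, 100)))
  rownames(d) <- paste0("s", 1:188)
  lg2 <- lg_from(d, c(rep("barthii", 88), rep("glaberrima", 100)))
  sc2 <- concordance(lg2, group_contrast("G1", "barthii", "glaberrima"), "L")
  expect_equal(sc2$per_group[["barthii"]], 81 / 88)
  expect_false(sc2$pass)
  # brute-force tally on random data, het = mismatch, missing excluded
  withr::local_seed(14)
  d3 <- matrix(sample(c(0:2, NA), 40 * 3, replace = TRUE), 40, 3,
               dimnames = list(paste0("s", 1:40), paste0("L", 1:3)))
  taxa <- sample(c("t", "c"), 40, replace = TRUE, prob = c(.4, .6))
  lg3 <- lg_from(d3, taxa)
  ct3 <- group_contrast("Z", "t", "c")
  for (l in colnames(d3)) {
    a <- diagnostic_allele(lg3, ct3, l)
    if (is.na(a)) next
    sc3 <- concordance(lg3, ct3, l)
    hom <- if (a == 2L) 2L else 0L
    for (t in c("t", "c")) {
      x <- d3[taxa == t, l]
      e <- if (t == "t") hom else 2L - hom
      expect_equal(sc3$per_group[[t]], mean(x[!is.na(x)] == e))
    }
  }
})

test_that("selection recovers planted structure on a low-noise collection", {
  sim <- clean_collection(seed = 9)
  filt <- filter_markers(summarize_markers(sim$lg$g))
  sel <- select_diagnostic_markers(sim$lg, sim$contrasts,
                                   loci = filt$locus_id[filt$kept])
  truth <- sim$truth$locus_contrast
  for (cid in setdiff(names(sim$contrasts), "G1")) {
    planted <- names(truth)[truth == cid]
    kept_planted <- intersect(planted, filt$locus_id[filt$kept])
    expect_setequal(sel$markers[[cid]], kept_planted)
  }
  # zero background loci pass anywhere
  bg <- names(truth)[truth == "background"]
  expect_length(intersect(unlist(sel$markers), bg), 0L)
  # G1 singletons blocked by hybrids; the pair fallback recovers the contrast
  expect_length(sel$markers$G1, 0L)
  prs <- joint_diagnostic_pairs(sim$lg, sim$contrasts$G1,
                                loci = filt$locus_id[filt$kept])
  expect_gt(nrow(prs), 0L)
  expect_true(all(c(prs$locus1, prs$locus2) %in% names(truth)[truth == "G1"]))
})

test_that("threshold semantics: 0.95-fixation locus and monotonicity", {
  # 38/40 target accessions carry the diagnostic state: concordance 0.95
  d <- cbind(L = c(rep(2L, 38), 0L, 0L, rep(0L, 60)))
  rownames(d) <- paste0("s", 1:100)
  lg <- lg_from(d, c(rep("t", 40), rep("c", 60)))
  ct <- list(X = group_contrast("X", "t", "c"))
  expect_length(select_diagnostic_markers(lg, ct, threshold = 0.97)$markers$X, 0L)
  expect_equal(select_diagnostic_markers(lg, ct, threshold = 0.94)$markers$X, "L")
  # raising the threshold never grows a marker set
  sim <- small_collection(seed = 31)
  lo <- select_diagnostic_markers(sim$lg, sim$contrasts, threshold = 0.90)
  hi <- select_diagnostic_markers(sim$lg, sim$contrasts, threshold = 0.99)
  for (cid in names(sim$contrasts))
    expect_true(all(hi$markers[[cid]] %in% lo$markers[[cid]]))
  # an all-missing locus is never selected
  d2 <- cbind(L1 = c(rep(2L, 5), rep(0L, 5)), L2 = rep(NA_integer_, 10))
  rownames(d2) <- paste0("s", 1:10)
  lg2 <- lg_from(d2, rep(c("t", "c"), each = 5))
  sel2 <- select_diagnostic_markers(lg2, list(X = group_contrast("X", "t", "c")))
  expect_false("L2" %in% sel2$markers$X)
})

test_that("joint pairs rescue independent errors and flag hybrids", {
  # two loci, each 0.95 concordant in the target, error accessions disjoint
  n_t <- 40L; n_c <- 40L
  l1 <- c(rep(2L, n_t), rep(0L, n_c)); l1[1:2] <- 0L
  l2 <- c(rep(2L, n_t), rep(0L, n_c)); l2[3:4] <- 0L
  d <- cbind(A = l1, B = l2); rownames(d) <- paste0("s", 1:80)
  lg <- lg_from(d, rep(c("t", "c"), c(n_t, n_c)))
  ct <- group_contrast("X", "t", "c")
  prs <- joint_diagnostic_pairs(lg, ct, threshold = 0.97, floor = 0.85)
  expect_equal(nrow(prs), 1L)
  # one good call outvotes one bad one: every error accession is rescued
  expect_equal(prs$conc_t, 1)
  expect_true(prs$pass)
  # duplicated marker: the pair adds nothing beyond the singleton
  d2 <- cbind(A = l1, B = l1); rownames(d2) <- paste0("s", 1:80)
  prs2 <- joint_diagnostic_pairs(lg_from(d2, rep(c("t", "c"), c(n_t, n_c))), ct)
  expect_equal(prs2$conc_t, 38 / 40)
  expect_false(prs2$pass)
  expect_true(prs2$flagged)
  # hybrid scenario: the planted hybrids are exactly the discordant accessions
  sim <- clean_collection(seed = 33)
  filt <- filter_markers(summarize_markers(sim$lg$g))
  prs3 <- joint_diagnostic_pairs(sim$lg, sim$contrasts$G1,
                                 loci = filt$locus_id[filt$kept])
  best <- prs3[1L, ]
  hyb <- sim$truth$hybrid_ids
  n_barthii <- sum(sim$lg$taxa == "barthii")
  expect_equal(best$conc_barthii, (n_barthii - length(hyb)) / n_barthii,
               tolerance = 0.02)
  # identify the discordant barthii accessions for the best pair
  pair <- c(best$locus1, best$locus2)
  e <- vapply(pair, function(l)
    if (sim$truth$diagnostic_allele[[l]] == 2L) 2L else 0L, integer(1))
  rows <- which(sim$lg$taxa == "barthii")
  x <- sim$lg$g$dosage[rows, pair, drop = FALSE]
  m <- rowSums(sweep(x, 2L, e, "==") * !is.na(x), na.rm = TRUE)
  mm <- rowSums(sweep(x, 2L, e, "!=") * !is.na(x), na.rm = TRUE)
  discordant <- names(sim$lg$taxa[rows])[m < mm]
  expect_setequal(discordant, hyb)
})

test_that("minimal panel: greedy cover matches brute force and drops duplicates", {
  taxa <- paste0("T", 1:5)
  pairs <- utils::combn(taxa, 2L)
  # 10 markers, each separating exactly one distinct taxon pair
  expected <- matrix(0L, 5, 10, dimnames = list(taxa, paste0("M", 1:10)))
  for (k in 1:10) { expected[pairs[1, k], k] <- 2L; expected[pairs[2, k], k] <- 0L }
  markers <- data.frame(locus_id = paste0("M", 1:10), contrast_id = "X",
                        diagnostic_allele = 2L, flagged = FALSE,
                        mean_concordance = 1)
  panel <- structure(list(markers = markers, expected = expected,
                          threshold = 0.97, contrasts = NULL),
                     class = "panel_selection")
  red <- minimal_panel(panel, redundancy = 1L)
  # exhaustive optimum over all marker subsets
  sep_ok0 <- function(cols) {
    e <- expected[, cols, drop = FALSE]
    all(apply(pairs, 2L, function(p) any(e[p[1], ] != e[p[2], ])))
  }
  opt <- min(unlist(lapply(1:10, function(k)
    if (any(apply(utils::combn(10, k), 2L, sep_ok0))) k else NULL)))
  expect_equal(nrow(red$markers), opt)
  expect_true(sep_ok0(red$markers$locus_id))
  # richer geometry: markers splitting taxon subsets; compare to exhaustive
  withr::local_seed(5)
  expected2 <- matrix(sample(c(0L, 2L), 5 * 8, replace = TRUE), 5, 8,
                      dimnames = list(taxa, paste0("M", 1:8)))
  sep_ok <- function(cols) {
    e <- expected2[, cols, drop = FALSE]
    all(apply(pairs, 2L, function(p) any(e[p[1], ] != e[p[2], ])))
  }
  if (sep_ok(1:8)) {
    markers2 <- data.frame(locus_id = colnames(expected2), contrast_id = "X",
                           diagnostic_allele = 2L, flagged = FALSE,
                           mean_concordance = 1)
    panel2 <- structure(list(markers = markers2, expected = expected2,
                             threshold = 0.97, contrasts = NULL),
                        class = "panel_selection")
    red2 <- minimal_panel(panel2, redundancy = 1L)
    sizes <- unlist(lapply(1:8, function(k)
      if (any(apply(utils::combn(8, k), 2L, sep_ok))) k else NULL))
    expect_equal(nrow(red2$markers), min(sizes))  # greedy is optimal here
    expect_true(sep_ok(red2$markers$locus_id))
  }
  # duplicate columns are never both retained at redundancy 1
  exp_dup <- expected2[, c(1, 1, 2, 3, 4, 5), drop = FALSE]
  colnames(exp_dup) <- paste0("D", 1:6)
  if (all(apply(pairs, 2L, function(p) any(exp_dup[p[1], ] != exp_dup[p[2], ])))) {
    markers3 <- data.frame(locus_id = colnames(exp_dup), contrast_id = "X",
                           diagnostic_allele = 2L, flagged = FALSE,
                           mean_concordance = 1)
    panel3 <- structure(list(markers = markers3, expected = exp_dup,
                             threshold = 0.97, contrasts = NULL),
                        class = "panel_selection")
    red3 <- minimal_panel(panel3, redundancy = 1L)
    expect_false(all(c("D1", "D2") %in% red3$markers$locus_id))
  }
  # unseparated pair is an error naming the pair
  exp_bad <- expected2; exp_bad["T2", ] <- exp_bad["T1", ]
  markers4 <- data.frame(locus_id = colnames(exp_bad), contrast_id = "X",
                         diagnostic_allele = 2L, flagged = FALSE,
                         mean_concordance = 1)
  panel4 <- structure(list(markers = markers4, expected = exp_bad,
                           threshold = 0.97, contrasts = NULL),
                      class = "panel_selection")
  expect_error(minimal_panel(panel4), "T1 / T2")
})

test_that("minimal panel classifies identically to the full panel", {
  sim <- clean_collection(seed = 17)
  filt <- filter_markers(summarize_markers(sim$lg$g))
  sel <- select_diagnostic_markers(sim$lg, sim$contrasts,
                                   loci = filt$locus_id[filt$kept])
  panel <- select_panel(sim$lg, sel)
  red <- minimal_panel(panel, sim$lg, redundancy = 2L)
  expect_true(attr(red, "classification_identical"))
  expect_lte(nrow(red$markers), nrow(panel$markers))
})

test_that("classification: exact match, permutation invariance, hybrids", {
  sim <- clean_collection(seed = 3)
  filt <- filter_markers(summarize_markers(sim$lg$g))
  sel <- select_diagnostic_markers(sim$lg, sim$contrasts,
                                   loci = filt$locus_id[filt$kept])
  panel <- select_panel(sim$lg, sel)
  # an accession matching the expected haplotype exactly
  x <- panel$expected["glaberrima", ]
  res <- classify_accession(x, panel)
  expect_equal(res$taxon, "glaberrima")
  expect_equal(res$mismatches[["glaberrima"]], 0L)
  # locus order permutation changes nothing
  res2 <- classify_accession(x[sample(names(x))], panel)
  expect_equal(res2$taxon, res$taxon)
  expect_equal(res2$mismatches, res$mismatches[names(res2$mismatches)])
  # all panel loci missing -> unclassifiable
  x_na <- x; x_na[] <- NA_integer_
  expect_true(classify_accession(x_na, panel)$unclassifiable)
  # hybrids are classified glaberrima (or at least not clean barthii)
  cls <- classify_collection(sim$lg, panel)
  hyb <- cls[cls$sample_id %in% sim$truth$hybrid_ids, ]
  expect_true(all(hyb$assigned == "glaberrima" | hyb$tie))
  # and every barthii assigned to glaberrima is a planted hybrid
  stray <- cls$sample_id[cls$labeled == "barthii" &
                           cls$assigned == "glaberrima"]
  expect_true(all(stray %in% sim$truth$hybrid_ids))
})

test_that("haplotype pattern is seeded, clamped, and ordered", {
  sim <- small_collection(seed = 19)
  filt <- filter_markers(summarize_markers(sim$lg$g))
  sel <- select_diagnostic_markers(sim$lg, sim$contrasts,
                                   loci = filt$locus_id[filt$kept])
  panel <- select_panel(sim$lg, sel)
  pat <- haplotype_pattern(sim$lg, panel, n_per_group = 8, seed = 2)
  per_taxon <- table(pat$taxon)
  sizes <- group_sizes(sim$lg)
  expect_equal(as.integer(per_taxon[names(sizes)]),
               unname(pmin(sizes, 8L)))
  expect_identical(pat, haplotype_pattern(sim$lg, panel, n_per_group = 8,
                                          seed = 2))
  # larger than any group: everything used, no error
  pat2 <- haplotype_pattern(sim$lg, panel, n_per_group = 10000, seed = 2)
  expect_equal(nrow(pat2), sum(sizes))
  # loci ordered by contrast then id
  loci_cols <- setdiff(names(pat), c("sample_id", "taxon"))
  ord <- order(panel$markers$contrast_id, panel$markers$locus_id)
  expect_identical(loci_cols, panel$markers$locus_id[ord])
  expect_true(all(unlist(pat[loci_cols]) %in% c("0", "1", "H", NA)))
})
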