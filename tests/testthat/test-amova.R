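test_that("squared distances: closed forms and the brute-force oracle", {
  d <- rbind(a = rep(0L, 6), b = rep(0L, 6), c = rep(2L, 6))
  g <- genotype_matrix(d)
  d2 <- squared_distance_matrix(g)$d2
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 4 * 6)           # opposite homozygotes over L loci
  expect_equal(diag(d2), c(a = 0, b = 0, c = 0))
  # random matrix with holes vs per-pair loop
  withr::local_seed(4)
  X <- matrix(sample(c(0:2, NA), 15 * 12, replace = TRUE,
                     prob = c(.3, .1, .3, .3)), 15, 12,
              dimnames = list(paste0("s", 1:15), paste0("L", 1:12)))
  g2 <- genotype_matrix(X)
  expect_equal(squared_distance_matrix(g2)$d2, naive_d2(g2))
  # zero shared loci is an error naming the pair
  X3 <- rbind(p = c(0L, NA), q = c(NA, 2L))
  expect_error(squared_distance_matrix(genotype_matrix(X3)), "p.*q")
})

test_that("ibs distance agrees with a per-pair loop and is bounded", {
  withr::local_seed(6)
  X <- matrix(sample(c(0:2, NA), 12 * 10, replace = TRUE), 12, 10,
              dimnames = list(paste0("s", 1:12), paste0("L", 1:10)))
  g <- genotype_matrix(X)
  d <- ibs_distance(g)
  for (i in 1:11) for (j in (i + 1):12) {
    sh <- !is.na(X[i, ]) & !is.na(X[j, ])
    expect_equal(d[i, j], mean(abs(X[i, sh] - X[j, sh]) / 2))
  }
  expect_true(all(d >= 0 & d <= 1))
})

test_that("amova_components reproduces the printed worked example", {
  r <- amova_components(4848.905, 162.642, c(88, 169, 69, 178, 121))
  expect_equal(r$ss_total, 5011.547)
  expect_equal(c(r$df_among, r$df_within, r$df_total), c(4, 620, 624))
  expect_equal(r$ms_among, 1212.226, tolerance = 1e-6)
  expect_equal(round(r$ms_within, 3), 0.262)
  expect_equal(r$var_among, 9.992, tolerance = 1e-4)
  expect_equal(round(r$var_within, 3), 0.262)
  expect_equal(round(r$pct_among), 97)
  expect_equal(round(r$phipt, 3), 0.974)
  # no among-group SS: PhiPT is zero
  expect_equal(amova_components(0, 10, c(5, 5))$phipt, 0)
  # negative among-component clamps to zero
  expect_equal(amova_components(0.1, 100, c(10, 10))$var_among, 0)
})

test_that("amova_components agrees with an independent arithmetic oracle", {
  withr::local_seed(12)
  for (rep in 1:20) {
    sizes <- sample(3:40, sample(2:6, 1), replace = TRUE)
    ssa <- runif(1, 0, 500); ssw <- runif(1, 0, 200)
    r <- amova_components(ssa, ssw, sizes)
    o <- naive_amova_components(ssa, ssw, sizes)
    expect_equal(r$ms_among, o$msa, tolerance = 1e-9)
    expect_equal(r$ms_within, o$msw, tolerance = 1e-9)
    expect_equal(r$n0, o$n0, tolerance = 1e-9)
    expect_equal(r$var_among, o$va, tolerance = 1e-9)
    expect_equal(r$phipt, o$phipt, tolerance = 1e-9)
  }
})

test_that("amova SS decomposition matches a double-loop oracle", {
  withr::local_seed(23)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    X <- matrix(sample(c(0:2, NA), n * 8, replace = TRUE,
                       prob = c(.35, .1, .35, .2)), n, 8,
                dimnames = list(paste0("s", 1:n), paste0("L", 1:8)))
    labels <- sample(c("u", "v", "w"), n, replace = TRUE)
    while (min(table(labels)) < 2)
      labels <- sample(c("u", "v", "w"), n, replace = TRUE)
    g <- genotype_matrix(X)
    d2 <- squared_distance_matrix(g)$d2
    res <- amova(d2, labels, n_perm = 0)
    # brute force: SS_total and SS_within from explicit pair loops
    sst <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d2[i, j]
    sst <- sst / n
    ssw2 <- sum(vapply(unique(labels), function(grp) {
      idx <- which(labels == grp)
      s <- 0
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b) s <- s + d2[idx[a], idx[b]]
      s / length(idx)
    }, numeric(1)))
    expect_equal(res$ss_total, sst, tolerance = 1e-9)
    expect_equal(res$ss_within, ssw2, tolerance = 1e-9)
    expect_equal(res$ss_among + res$ss_within, res$ss_total, tolerance = 1e-9)
    expect_gte(res$phipt, 0); expect_lte(res$phipt, 1)
  }
})

test_that("amova null and perfect-structure limits", {
  # labels random w.r.t. data: phipt ~ 0, p large
  withr::local_seed(2)
  X <- matrix(sample(c(0L, 2L), 40 * 20, replace = TRUE), 40, 20,
              dimnames = list(paste0("s", 1:40), paste0("L", 1:20)))
  g <- genotype_matrix(X)
  d2 <- squared_distance_matrix(g)
  res <- amova(d2, rep(c("u", "v"), each = 20), n_perm = 199, seed = 9)
  expect_lt(res$phipt, 0.2)
  expect_gt(res$p_value, 0.05)
  # two internally identical groups fixed for opposite alleles
  lg <- two_group_fixture(n_per = 5, n_loci = 8)
  res2 <- amova(squared_distance_matrix(lg$g), lg$taxa, n_perm = 99, seed = 1)
  expect_equal(res2$ss_within, 0)
  expect_equal(res2$phipt, 1)
  expect_lte(res2$p_value, 0.05)
  # permutation estimator can never be exactly zero
  expect_gte(res2$p_value, 1 / 100)
  # group of size 1 is rejected
  expect_error(amova(squared_distance_matrix(lg$g),
                     c("u", rep("v", 9)), n_perm = 0), "size 1")
})

test_that("noise injection weakly decreases PhiPT", {
  withr::local_seed(31)
  base <- two_group_fixture(n_per = 10, n_loci = 20)
  phi0 <- amova(squared_distance_matrix(base$g), base$taxa, n_perm = 0)$phipt
  d <- base$g$dosage
  flip <- matrix(runif(length(d)) < 0.10, nrow(d))
  d[flip] <- 2L - d[flip]
  noisy <- genotype_matrix(d, rownames(d), colnames(d))
  phi1 <- amova(squared_distance_matrix(noisy), base$taxa, n_perm = 0)$phipt
  expect_lte(phi1, phi0)
})

test_that("pairwise PhiPT: null, maximum, and the expected ordering", {
  withr::local_seed(44)
  # a single group split at random: ~0
  X <- matrix(sample(c(0L, 2L), 30 * 15, replace = TRUE), 30, 15,
              dimnames = list(paste0("s", 1:30), paste0("L", 1:15)))
  pw0 <- pairwise_phipt(genotype_matrix(X), rep(c("u", "v"), 15),
                        n_perm = 0)
  expect_lt(pw0$phipt["v", "u"], 0.15)
  # fully fixed opposite groups: 1
  lg <- two_group_fixture()
  pw1 <- pairwise_phipt(lg$g, lg$taxa, n_perm = 49, seed = 2)
  expect_equal(pw1$phipt["beta", "alpha"], 1)
  # on a study-like collection, the wild/cultivated African pair is closest
  sim <- small_collection(seed = 27)
  filt <- filter_markers(summarize_markers(sim$lg$g))
  sel <- select_diagnostic_markers(sim$lg, sim$contrasts,
                                   loci = filt$locus_id[filt$kept])
  panel <- select_panel(sim$lg, sel)
  pw <- pairwise_phipt(subset_genotypes(sim$lg$g, loci = panel$markers$locus_id),
                       unname(sim$lg$taxa), n_perm = 0)
  lower <- pw$phipt[lower.tri(pw$phipt)]
  bg <- pw$phipt["glaberrima", "barthii"]
  expect_equal(bg, min(lower))
})
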