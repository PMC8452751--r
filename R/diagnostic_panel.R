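#' Define a taxon-group contrast
#'
#' A contrast opposes a `target` taxon set to a `complex` (complement) set.
#' The two sets must be disjoint; their union is the contrast's universe and
#' may be a subset of all taxa (a restricted contrast such as wild vs
#' cultivated African rice only involves those two taxa).
#'
#' @param id contrast identifier, e.g. `"G1"`.
#' @param target,complex character vectors of taxon labels.
#' @return An object of class `group_contrast`.
#' @export
group_contrast <- function(id, target, complex) {
  target <- as.character(target); complex <- as.character(complex)
  if (length(target) == 0L || length(complex) == 0L)
    stop("contrast ", id, ": target and complex must be non-empty")
  if (length(intersect(target, complex)))
    stop("contrast ", id, ": target and complex overlap")
  structure(list(id = id, target = target, complex = complex,
                 universe = c(target, complex)),
            class = "group_contrast")
}

#' Default six-group diagnostic contrasts for the Oryza collection
#'
#' G1 separates wild from cultivated African rice (restricted to those two
#' taxa); G2 the African complex from Asian rice plus *O. longistaminata*;
#' G3 Asian from African species; G4, G5 and G6 single out
#' *O. longistaminata*, indica and japonica respectively.
#'
#' @param taxa the five taxon labels in canonical order.
#' @return Named list of [group_contrast()] objects `G1`..`G6`.
#' @export
default_contrasts <- function(taxa = c("barthii", "glaberrima",
                                       "longistaminata", "indica", "japonica")) {
  stopifnot(length(taxa) == 5L)
  b <- taxa[1L]; g <- taxa[2L]; l <- taxa[3L]; i <- taxa[4L]; j <- taxa[5L]
  list(
    G1 = group_contrast("G1", b, g),
    G2 = group_contrast("G2", c(b, g), c(l, i, j)),
    G3 = group_contrast("G3", c(i, j), c(b, g, l)),
    G4 = group_contrast("G4", l, c(b, g, i, j)),
    G5 = group_contrast("G5", i, c(b, g, l, j)),
    G6 = group_contrast("G6", j, c(b, g, l, i))
  )
}

# Frequency of the second (alt) allele among a set of rows, per locus.
.p_alt <- function(dosage, rows = seq_len(nrow(dosage))) {
  d <- dosage[rows, , drop = FALSE]
  called <- colSums(!is.na(d))
  ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
}

#' Diagnostic allele of a locus for a contrast
#'
#' Picks the allele whose homozygous state is expected in the target group:
#' the collection-wide minor allele when it is the majority state within the
#' target; otherwise the allele maximally enriched in target relative to
#' complex, with ties broken toward the minor allele.
#'
#' @param lg a `labeled_collection` (see [attach_labels()]).
#' @param contrast a [group_contrast()].
#' @param locus locus id or index.
#' @return Allele index `1` or `2` (dosage counts allele 2), or
#'   `NA_integer_` when the locus is monomorphic (no diagnostic allele).
#' @export
diagnostic_allele <- function(lg, contrast, locus) {
  sc <- score_contrast(lg, contrast, loci = locus)
  sc$diag_allele[[1L]]
}

# Vectorized scoring of one contrast over many loci.
# Returns list(diag_allele, concordance [taxa x loci], n [taxa x loci]).
score_contrast <- function(lg, contrast, loci = lg$g$locus_ids) {
  stopifnot(inherits(lg, "labeled_collection"), inherits(contrast, "group_contrast"))
  missing_taxa <- setdiff(contrast$universe, unique(lg$taxa))
  if (length(missing_taxa))
    stop("contrast ", contrast$id, ": taxa absent from collection: ",
         paste(missing_taxa, collapse = ", "))
  li <- if (is.character(loci)) match(loci, lg$g$locus_ids) else loci
  if (anyNA(li)) stop("unknown locus id")
  d <- lg$g$dosage[, li, drop = FALSE]
  loci <- lg$g$locus_ids[li]
  p_all <- .p_alt(d)                       # collection-wide alt freq
  tr <- which(lg$taxa %in% contrast$target)
  cr <- which(lg$taxa %in% contrast$complex)
  p_t <- .p_alt(d, tr); p_c <- .p_alt(d, cr)
  minor <- ifelse(p_all <= 0.5, 2L, 1L)    # allele index of global minor; tie -> alt
  minor_freq_target <- ifelse(minor == 2L, p_t, 1 - p_t)
  enrich_alt <- p_t - p_c
  enriched <- ifelse(enrich_alt > 0, 2L,
                     ifelse(enrich_alt < 0, 1L, minor))  # tie -> minor allele
  diag_allele <- ifelse(minor_freq_target > 0.5, minor, enriched)
  mono <- !is.na(p_all) & (p_all == 0 | p_all == 1)
  diag_allele[mono | is.na(p_all)] <- NA_integer_
  # expected homozygous dosage: target carries diag allele, complex the other
  taxa_u <- contrast$universe
  conc <- matrix(NA_real_, length(taxa_u), length(loci),
                 dimnames = list(taxa_u, loci))
  n_mat <- matrix(0L, length(taxa_u), length(loci),
                  dimnames = list(taxa_u, loci))
  hom_diag <- ifelse(diag_allele == 2L, 2L, 0L)  # dosage of the diagnostic homozygote
  for (t in taxa_u) {
    rows <- which(lg$taxa == t)
    dt <- d[rows, , drop = FALSE]
    expected <- if (t %in% contrast$target) hom_diag else 2L - hom_diag
    called <- colSums(!is.na(dt))
    match_n <- colSums(dt == rep(expected, each = nrow(dt)), na.rm = TRUE)
    conc[t, ] <- ifelse(called > 0 & !is.na(diag_allele),
                        match_n / called, NA_real_)
    n_mat[t, ] <- as.integer(called)
  }
  list(diag_allele = structure(as.integer(diag_allele), names = loci),
       concordance = conc, n = n_mat)
}

#' Minor-allele concordance of a marker for a contrast
#'
#' For every taxon in the contrast's universe, the fraction of that taxon's
#' accessions (non-missing at the locus) carrying the expected homozygous
#' state: the diagnostic allele for target taxa, the other allele for
#' complex taxa. Heterozygotes count as mismatches; missing calls are
#' excluded from the denominator.
#'
#' @param lg a `labeled_collection`.
#' @param contrast a [group_contrast()].
#' @param locus locus id or index.
#' @param threshold per-taxon pass threshold; the marker passes only when
#'   every universe taxon's concordance strictly exceeds it.
#' @return A list of class `diagnostic_score` with elements `locus_id`,
#'   `contrast_id`, `diagnostic_allele`, `per_group` (named fractions),
#'   `n_per_group` and `pass`.
#' @export
concordance <- function(lg, contrast, locus, threshold = 0.97) {
  sc <- score_contrast(lg, contrast, loci = locus)
  per_group <- sc$concordance[, 1L]
  pass <- !anyNA(per_group) && all(per_group > threshold)
  structure(list(locus_id = colnames(sc$concordance)[1L],
                 contrast_id = contrast$id,
                 diagnostic_allele = sc$diag_allele[[1L]],
                 per_group = per_group, n_per_group = sc$n[, 1L],
                 pass = pass, threshold = threshold),
            class = "diagnostic_score")
}

#' @export
print.diagnostic_score <- function(x, ...) {
  cat(sprintf("diagnostic_score %s / contrast %s (allele %s): %s\n",
              x$locus_id, x$contrast_id,
              ifelse(is.na(x$diagnostic_allele), "-", x$diagnostic_allele),
              if (x$pass) "PASS" else "fail"))
  print(round(x$per_group, 4))
  invisible(x)
}

#' Select diagnostic markers for each contrast
#'
#' A locus is assigned to every contrast where all universe taxa exceed the
#' concordance threshold. Loci passing no contrast are reported as
#' non-diagnostic.
#'
#' @param lg a `labeled_collection`.
#' @param contrasts list of [group_contrast()]s, e.g. [default_contrasts()].
#' @param threshold per-taxon concordance threshold (strictly exceeded).
#' @param loci candidate loci (default all), typically the survivors of
#'   [filter_markers()].
#' @return List of class `diagnostic_selection`: `markers` (named list,
#'   contrast id -> character vector of passing loci), `scores` (long data
#'   frame of per-taxon minimum concordance per locus x contrast),
#'   `non_diagnostic` (loci passing nothing) and `threshold`.
#' @export
select_diagnostic_markers <- function(lg, contrasts = default_contrasts(),
                                      threshold = 0.97, loci = NULL) {
  loci <- loci %||% lg$g$locus_ids
  markers <- list(); rows <- list()
  for (cid in names(contrasts)) {
    sc <- score_contrast(lg, contrasts[[cid]], loci = loci)
    cmin <- apply(sc$concordance, 2L, function(x) if (anyNA(x)) NA_real_ else min(x))
    pass <- !is.na(cmin) & cmin > threshold
    markers[[cid]] <- names(which(pass))
    rows[[cid]] <- data.frame(
      locus_id = loci, contrast_id = cid,
      diagnostic_allele = unname(sc$diag_allele),
      min_concordance = unname(cmin),
      mean_concordance = unname(colMeans(sc$concordance)),
      pass = unname(pass), stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  assigned <- unique(unlist(markers))
  structure(list(markers = markers, scores = scores,
                 non_diagnostic = setdiff(loci, assigned),
                 threshold = threshold, contrasts = contrasts),
            class = "diagnostic_selection")
}

#' @export
print.diagnostic_selection <- function(x, ...) {
  cat("diagnostic_selection (threshold", x$threshold, "):\n")
  for (cid in names(x$markers))
    cat(sprintf("  %s: %d marker(s)\n", cid, length(x$markers[[cid]])))
  cat("  non-diagnostic:", length(x$non_diagnostic), "\n")
  invisible(x)
}

#' Jointly-diagnostic marker pairs for a contrast
#'
#' Among loci that individually fail the concordance threshold, searches for
#' pairs whose two-locus expected haplotype recovers diagnosis. An accession
#' agrees with the pair when its matches are at least as many as its
#' mismatches over the pair's non-missing loci (so one marker's call rescues
#' the other's missing or discordant call); accessions missing both loci are
#' excluded. Pairs whose per-taxon concordance does not exceed `threshold`
#' are still reported, flagged, mirroring the practice of retaining a
#' best-available pair. The search space is restricted to loci whose minimum
#' per-taxon concordance reaches `floor`.
#'
#' @param lg a `labeled_collection`.
#' @param contrast a [group_contrast()].
#' @param threshold pass threshold for the pair (strict).
#' @param floor candidate-locus minimum singleton concordance.
#' @param loci candidate loci (default all).
#' @return Data frame, one row per pair, with per-taxon concordance columns
#'   (`conc_<taxon>`), `min_concordance`, `pass` and `flagged`, sorted by
#'   decreasing `min_concordance`. Zero rows when no candidates.
#' @export
joint_diagnostic_pairs <- function(lg, contrast, threshold = 0.97,
                                   floor = 0.85, loci = NULL) {
  loci <- loci %||% lg$g$locus_ids
  sc <- score_contrast(lg, contrast, loci = loci)
  cmin <- apply(sc$concordance, 2L, function(x) if (anyNA(x)) NA_real_ else min(x))
  cand <- names(which(!is.na(cmin) & cmin >= floor & cmin <= threshold))
  empty <- data.frame(locus1 = character(0), locus2 = character(0),
                      min_concordance = numeric(0), pass = logical(0),
                      flagged = logical(0))
  if (length(cand) < 2L) return(empty)
  taxa_u <- contrast$universe
  d <- lg$g$dosage[, cand, drop = FALSE]
  # expected dosage per taxon x candidate locus
  exp_mat <- sapply(cand, function(l) {
    a <- sc$diag_allele[[l]]
    ifelse(taxa_u %in% contrast$target,
           ifelse(a == 2L, 2L, 0L), ifelse(a == 2L, 0L, 2L))
  })
  if (is.null(dim(exp_mat))) exp_mat <- matrix(exp_mat, nrow = length(taxa_u))
  dimnames(exp_mat) <- list(taxa_u, cand)
  pairs <- utils::combn(cand, 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    l1 <- pairs[1L, k]; l2 <- pairs[2L, k]
    conc <- setNames(numeric(length(taxa_u)), taxa_u)
    for (t in taxa_u) {
      rows <- which(lg$taxa == t)
      x1 <- d[rows, l1]; x2 <- d[rows, l2]
      e1 <- exp_mat[t, l1]; e2 <- exp_mat[t, l2]
      m  <- (!is.na(x1) & x1 == e1) + (!is.na(x2) & x2 == e2)
      mm <- (!is.na(x1) & x1 != e1) + (!is.na(x2) & x2 != e2)
      informative <- (m + mm) > 0
      conc[t] <- if (any(informative))
        mean(m[informative] >= mm[informative]) else NA_real_
    }
    cm <- if (anyNA(conc)) NA_real_ else min(conc)
    row <- data.frame(locus1 = l1, locus2 = l2, stringsAsFactors = FALSE)
    for (t in taxa_u) row[[paste0("conc_", t)]] <- conc[[t]]
    row$min_concordance <- cm
    row$pass <- !is.na(cm) && cm > threshold
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  res$flagged <- !res$pass
  res <- res[order(-res$min_concordance, res$locus1, res$locus2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a QC panel from a diagnostic selection
#'
#' Takes every contrast's passing singleton markers; for contrasts with no
#' passing singleton, falls back to the best jointly-diagnostic pair (its
#' two loci are added, flagged). Expected homozygous dosages per taxon are
#' taken from the contrast definition for universe taxa and from the
#' empirical modal homozygote for taxa outside a restricted contrast's
#' universe.
#'
#' @param lg a `labeled_collection`.
#' @param selection a [select_diagnostic_markers()] result.
#' @param pair_floor candidate floor passed to [joint_diagnostic_pairs()].
#' @return An object of class `panel_selection`: `markers` (data frame with
#'   `locus_id`, `contrast_id`, `diagnostic_allele`, `flagged`,
#'   `mean_concordance`), `expected` (taxa x panel-loci matrix of expected
#'   dosage), `threshold`.
#' @export
select_panel <- function(lg, selection, pair_floor = 0.85) {
  stopifnot(inherits(selection, "diagnostic_selection"))
  contrasts <- selection$contrasts
  taxa <- sort(unique(lg$taxa))
  rows <- list()
  for (cid in names(contrasts)) {
    singles <- selection$markers[[cid]]
    sc_rows <- selection$scores[selection$scores$contrast_id == cid, ]
    if (length(singles)) {
      idx <- match(singles, sc_rows$locus_id)
      rows[[cid]] <- data.frame(
        locus_id = singles, contrast_id = cid,
        diagnostic_allele = sc_rows$diagnostic_allele[idx],
        flagged = FALSE, mean_concordance = sc_rows$mean_concordance[idx],
        stringsAsFactors = FALSE)
    } else {
      prs <- joint_diagnostic_pairs(lg, contrasts[[cid]],
                                    threshold = selection$threshold,
                                    floor = pair_floor,
                                    loci = sc_rows$locus_id)
      if (nrow(prs) == 0L) next
      best <- prs[1L, ]
      pl <- c(best$locus1, best$locus2)
      idx <- match(pl, sc_rows$locus_id)
      rows[[cid]] <- data.frame(
        locus_id = pl, contrast_id = cid,
        diagnostic_allele = sc_rows$diagnostic_allele[idx],
        flagged = TRUE, mean_concordance = sc_rows$mean_concordance[idx],
        stringsAsFactors = FALSE)
    }
  }
  markers <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(markers) || nrow(markers) == 0L)
    stop("no contrast yielded any diagnostic marker")
  expected <- panel_expected(lg, markers, contrasts, taxa)
  structure(list(markers = markers, expected = expected,
                 threshold = selection$threshold, contrasts = contrasts),
            class = "panel_selection")
}

# taxa x loci matrix of expected homozygous dosage for a panel.
panel_expected <- function(lg, markers, contrasts, taxa) {
  expected <- matrix(NA_integer_, length(taxa), nrow(markers),
                     dimnames = list(taxa, markers$locus_id))
  d <- lg$g$dosage
  for (k in seq_len(nrow(markers))) {
    ct <- contrasts[[markers$contrast_id[k]]]
    a <- markers$diagnostic_allele[k]
    hom_diag <- if (a == 2L) 2L else 0L
    hom_other <- 2L - hom_diag
    for (t in taxa) {
      if (t %in% ct$target) expected[t, k] <- hom_diag
      else if (t %in% ct$complex) expected[t, k] <- hom_other
      else {
        x <- d[lg$taxa == t, markers$locus_id[k]]
        n2 <- sum(x == 2L, na.rm = TRUE); n0 <- sum(x == 0L, na.rm = TRUE)
        expected[t, k] <- if (n2 > n0) 2L else 0L
      }
    }
  }
  expected
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("panel_selection:", nrow(x$markers), "markers across",
      length(unique(x$markers$contrast_id)), "contrasts\n")
  print(table(x$markers$contrast_id))
  if (any(x$markers$flagged))
    cat("  flagged (joint-pair, below threshold):",
        paste(x$markers$locus_id[x$markers$flagged], collapse = ", "), "\n")
  invisible(x)
}

#' Reduce a panel to a minimal marker set by greedy set cover
#'
#' A marker separates a taxon pair when the two taxa have different expected
#' homozygous states at it. The greedy pass repeatedly keeps the marker
#' covering the most still-uncovered pairs (ties broken by higher mean
#' concordance, then lexicographic locus id) until every pair is covered by
#' `redundancy` markers where available. The reduced panel is then checked
#' to classify every accession identically to the full panel.
#'
#' @param panel a [select_panel()] result.
#' @param lg the `labeled_collection` used to verify classification equality
#'   (optional but recommended).
#' @param redundancy markers required per taxon pair (capped at the number
#'   available for that pair).
#' @return A `panel_selection` restricted to the kept markers, with
#'   attribute `classification_identical` (`NA` when `lg` not supplied).
#' @export
minimal_panel <- function(panel, lg = NULL, redundancy = 2L) {
  stopifnot(inherits(panel, "panel_selection"))
  taxa <- rownames(panel$expected)
  pair_idx <- utils::combn(seq_along(taxa), 2L)
  n_pairs <- ncol(pair_idx)
  sep <- matrix(FALSE, nrow(panel$markers), n_pairs)
  for (p in seq_len(n_pairs)) {
    sep[, p] <- panel$expected[pair_idx[1L, p], ] != panel$expected[pair_idx[2L, p], ]
  }
  avail <- colSums(sep)
  if (any(avail == 0L)) {
    p <- which(avail == 0L)[1L]
    stop("panel does not separate taxon pair ",
         taxa[pair_idx[1L, p]], " / ", taxa[pair_idx[2L, p]])
  }
  need <- pmin(redundancy, avail)
  have <- rep(0L, n_pairs)
  kept <- logical(nrow(panel$markers))
  while (any(have < need)) {
    open <- have < need
    gain <- rowSums(sep[, open, drop = FALSE]) * (!kept)
    best <- which(gain == max(gain))
    if (max(gain) == 0L) break   # cannot improve further
    if (length(best) > 1L) {
      mc <- panel$markers$mean_concordance[best]
      best <- best[mc == max(mc)]
      if (length(best) > 1L)
        best <- best[order(panel$markers$locus_id[best])][1L]
    }
    kept[best] <- TRUE
    have <- have + as.integer(sep[best, , drop = TRUE] & (have < need))
  }
  # never split a flagged joint pair: both of its loci travel together
  for (cid in unique(panel$markers$contrast_id)) {
    sel <- panel$markers$contrast_id == cid & panel$markers$flagged
    if (any(sel & kept)) kept[sel] <- TRUE
  }
  reduced <- panel
  reduced$markers <- panel$markers[kept, , drop = FALSE]
  reduced$expected <- panel$expected[, kept, drop = FALSE]
  same <- NA
  if (!is.null(lg)) {
    full <- classify_collection(lg, panel)
    red <- classify_collection(lg, reduced)
    same <- identical(full$taxon, red$taxon)
  }
  attr(reduced, "classification_identical") <- same
  reduced
}

#' Classify one accession against a panel
#'
#' Assigns the taxon whose expected haplotype has the fewest mismatches over
#' the accession's non-missing panel loci. Heterozygotes mismatch every
#' expected homozygote. Ties are reported and broken alphabetically; the
#' accession is flagged `intermediate` when the runner-up is within one
#' mismatch of the best taxon.
#'
#' @param x named dosage vector (names = locus ids) or a single-row
#'   [genotype_matrix()].
#' @param panel a `panel_selection`.
#' @return List with `taxon`, `mismatches` (named vector), `n_used`, `ties`,
#'   `intermediate`, `unclassifiable`.
#' @export
classify_accession <- function(x, panel) {
  if (inherits(x, "genotype_matrix")) {
    stopifnot(nrow(x$dosage) == 1L)
    x <- x$dosage[1L, ]
  }
  loci <- colnames(panel$expected)
  v <- x[loci]
  use <- !is.na(v)
  if (!any(use))
    return(list(taxon = NA_character_, mismatches = NULL, n_used = 0L,
                ties = character(0), intermediate = FALSE, unclassifiable = TRUE))
  mism <- apply(panel$expected[, use, drop = FALSE], 1L,
                function(e) sum(e != v[use]))
  best <- min(mism)
  ties <- names(mism)[mism == best]
  second <- if (length(mism) > 1L) sort(mism)[2L] else Inf
  list(taxon = sort(ties)[1L], mismatches = mism, n_used = sum(use),
       ties = ties, intermediate = (second - best) <= 1L,
       unclassifiable = FALSE)
}

#' Classify every accession of a collection
#'
#' @param lg a `labeled_collection` (labels are carried through for
#'   comparison, not used in classification).
#' @param panel a `panel_selection`.
#' @return Data frame with one row per accession: `sample_id`, `labeled`
#'   (the metadata taxon), `assigned`, `mismatches` (of the assigned taxon),
#'   `n_used`, `tie`, `intermediate`, `unclassifiable`.
#' @export
classify_collection <- function(lg, panel) {
  loci <- colnames(panel$expected)
  li <- match(loci, lg$g$locus_ids)
  if (anyNA(li)) stop("panel loci missing from collection: ",
                      paste(loci[is.na(li)], collapse = ", "))
  d <- lg$g$dosage[, li, drop = FALSE]
  taxa <- rownames(panel$expected)
  n <- nrow(d)
  # mismatch counts via one pass per taxon
  mism <- matrix(0L, n, length(taxa), dimnames = list(lg$g$sample_ids, taxa))
  for (t in taxa) {
    e <- panel$expected[t, ]
    mism[, t] <- rowSums(d != rep(e, each = n), na.rm = TRUE)
  }
  n_used <- rowSums(!is.na(d))
  ord <- apply(mism, 1L, function(m) sort(m)[1:2])
  best <- ord[1L, ]; second <- ord[2L, ]
  assigned <- apply(mism, 1L, function(m) sort(names(m)[m == min(m)])[1L])
  tie <- apply(mism, 1L, function(m) sum(m == min(m)) > 1L)
  assigned[n_used == 0L] <- NA_character_
  data.frame(sample_id = lg$g$sample_ids, labeled = unname(lg$taxa),
             assigned = unname(assigned), mismatches = unname(best),
             n_used = unname(n_used), tie = unname(tie),
             intermediate = unname((second - best) <= 1L),
             unclassifiable = unname(n_used == 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Haplotype-pattern table for a panel
#'
#' A compact per-accession view of panel allele states, with up to
#' `n_per_group` accessions sampled (seeded) per taxon. States are `"0"`
#' (homozygous non-diagnostic allele... the first allele), `"1"` (homozygous
#' second allele), `"H"` (heterozygous) and `NA` (missing). Loci are ordered
#' by contrast group, then id.
#'
#' @param lg a `labeled_collection`.
#' @param panel a `panel_selection`.
#' @param n_per_group accessions drawn per taxon (whole group when smaller).
#' @param seed RNG seed for the draw.
#' @return Data frame: `sample_id`, `taxon`, then one character column per
#'   panel locus.
#' @export
haplotype_pattern <- function(lg, panel, n_per_group = 8L, seed = 1L) {
  ord <- order(panel$markers$contrast_id, panel$markers$locus_id)
  loci <- panel$markers$locus_id[ord]
  taxa <- sort(unique(lg$taxa))
  picked <- with_seed(seed, {
    unlist(lapply(taxa, function(t) {
      ids <- lg$g$sample_ids[lg$taxa == t]
      if (length(ids) > n_per_group) sort(sample(ids, n_per_group)) else ids
    }), use.names = FALSE)
  })
  d <- lg$g$dosage[picked, match(loci, lg$g$locus_ids), drop = FALSE]
  states <- matrix(NA_character_, nrow(d), ncol(d),
                   dimnames = list(picked, loci))
  states[!is.na(d) & d == 0L] <- "0"
  states[!is.na(d) & d == 2L] <- "1"
  states[!is.na(d) & d == 1L] <- "H"
  out <- data.frame(sample_id = picked, taxon = unname(lg$taxa[picked]),
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(states, stringsAsFactors = FALSE, row.names = NULL))
}
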