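#' Configuration for a synthetic Oryza-like collection
#'
#' The defaults emulate the structure of the motivating genebank study:
#' five taxa with 88/169/69/178/121 accessions; 65 planted group-diagnostic
#' loci split 4/28/16/9/7/1 across the six default contrasts plus 93
#' unstructured background loci (158 total); near-complete fixation of the
#' diagnostic allele per group (0.99, with 0.93 for the wild-vs-cultivated
#' African contrast, whose markers are blurred by hybrid accessions);
#' heterozygote calls injected at 0.5\% (observed heterozygosity was 0–1\%);
#' per-locus missingness uniform on 0–11\% with one designated high-missing
#' diagnostic locus at 21\%; and seven intermediate "hybrid" accessions
#' labeled as wild African rice but carrying the cultivated haplotype at the
#' G1 loci.
#'
#' @param group_sizes named taxon sizes.
#' @param contrast_loci named planted-locus counts per contrast id.
#' @param n_background unstructured loci.
#' @param fixation probability an accession carries its group's expected
#'   homozygote at a planted locus; scalar or named per-contrast vector.
#' @param het_rate per-call heterozygote injection probability.
#' @param missing_max upper bound of the per-locus uniform missing rate.
#' @param high_missing_rate missing rate of the single designated
#'   high-missing locus (the second G1 locus when present).
#' @param n_hybrids wild-African accessions overwritten with the cultivated
#'   haplotype at the G1 loci.
#' @param maf_range background minor-allele-frequency range (frequencies
#'   shared across taxa; no drift model).
#' @param seed RNG seed used by [simulate_collection()].
#' @return List of class `collection_config`.
#' @export
collection_config <- function(group_sizes = c(barthii = 88L, glaberrima = 169L,
                                              longistaminata = 69L,
                                              indica = 178L, japonica = 121L),
                              contrast_loci = c(G1 = 4L, G2 = 28L, G3 = 16L,
                                                G4 = 9L, G5 = 7L, G6 = 1L),
                              n_background = 93L,
                              fixation = c(G1 = 0.93, G2 = 0.99, G3 = 0.99,
                                           G4 = 0.99, G5 = 0.99, G6 = 0.99),
                              het_rate = 0.005, missing_max = 0.11,
                              high_missing_rate = 0.21, n_hybrids = 7L,
                              maf_range = c(0.05, 0.5), seed = 1L) {
  if (length(fixation) == 1L && is.null(names(fixation)))
    fixation <- setNames(rep(fixation, length(contrast_loci)), names(contrast_loci))
  cfg <- list(group_sizes = group_sizes, contrast_loci = contrast_loci,
              n_background = as.integer(n_background), fixation = fixation,
              het_rate = het_rate, missing_max = missing_max,
              high_missing_rate = high_missing_rate,
              n_hybrids = as.integer(n_hybrids), maf_range = maf_range,
              seed = seed)
  validate_config(cfg)
  structure(cfg, class = "collection_config")
}

validate_config <- function(cfg) {
  rates <- c(cfg$fixation, cfg$het_rate, cfg$missing_max,
             cfg$high_missing_rate, cfg$maf_range)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(cfg$group_sizes < 2L)) stop("every group needs at least 2 samples")
  if (is.null(names(cfg$group_sizes)) || length(cfg$group_sizes) < 2L)
    stop("group_sizes must be a named vector of >= 2 taxa")
  if (!setequal(names(cfg$contrast_loci), names(cfg$fixation)))
    stop("fixation must be named by the same contrast ids as contrast_loci")
  if (cfg$n_hybrids > 0) {
    if (!"barthii" %in% names(cfg$group_sizes))
      stop("hybrids require a 'barthii' group")
    if (cfg$n_hybrids > cfg$group_sizes[["barthii"]])
      stop("n_hybrids (", cfg$n_hybrids, ") exceeds the barthii group size")
  }
  if (cfg$n_background < 0L) stop("n_background must be >= 0")
  invisible(cfg)
}

#' Scale a collection configuration
#'
#' Multiplies group sizes and locus counts by `factor` (rounded; planted
#' contrasts keep at least one locus), leaving all rates unchanged. Used to
#' build fast test fixtures with the same statistical structure.
#'
#' @param cfg a [collection_config()].
#' @param factor positive scale factor.
#' @return A new `collection_config`.
#' @export
scale_config <- function(cfg, factor) {
  stopifnot(inherits(cfg, "collection_config"), factor > 0)
  sizes <- as.integer(round(cfg$group_sizes * factor))
  names(sizes) <- names(cfg$group_sizes)
  if (any(sizes < 2L))
    stop("scaling would drop group(s) below 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  loci <- pmax(1L, as.integer(round(cfg$contrast_loci * factor)))
  # a contrast that had at least a pair keeps a pair (joint-pair search and
  # taxon-pair separation stay exercisable on scaled fixtures)
  loci <- pmax(loci, pmin(cfg$contrast_loci, 2L))
  names(loci) <- names(cfg$contrast_loci)
  cfg2 <- unclass(cfg)
  cfg2$group_sizes <- sizes
  cfg2$contrast_loci <- loci
  cfg2$n_background <- max(1L, as.integer(round(cfg$n_background * factor)))
  cfg2$n_hybrids <- min(as.integer(round(cfg$n_hybrids * factor)),
                        if ("barthii" %in% names(sizes)) sizes[["barthii"]] else 0L)
  do.call(collection_config, cfg2)
}

#' Simulate a genotype collection with planted diagnostic structure
#'
#' Planted loci: accessions in a contrast's target group are homozygous for
#' the diagnostic allele with probability `fixation`, else for the opposite
#' allele; complex-group accessions (and taxa outside a restricted
#' contrast's universe) mirror this around the non-diagnostic homozygote.
#' Hybrid accessions then overwrite their G1 calls with the cultivated
#' (glaberrima) state. Heterozygotes are injected independently per call,
#' missing calls masked per locus, and each locus's allele orientation
#' (which allele the dosage counts) is randomized so that downstream
#' minor-allele logic is exercised. Background loci draw homozygotes from
#' allele frequencies shared across taxa. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [collection_config()].
#' @param contrasts contrast definitions whose ids match
#'   `cfg$contrast_loci`; default [default_contrasts()] restricted to the
#'   configured taxa.
#' @return List of class `synthetic_collection` with elements `lg` (a
#'   `labeled_collection`), `truth` (planted contrast per locus, diagnostic
#'   allele index, hybrid ids, realized per-group concordances) and `cfg`.
#' @export
simulate_collection <- function(cfg = collection_config(),
                                contrasts = NULL) {
  validate_config(cfg)
  taxa <- names(cfg$group_sizes)
  if (is.null(contrasts)) {
    contrasts <- default_contrasts()
    contrasts <- contrasts[names(cfg$contrast_loci)]
    if (any(vapply(contrasts, is.null, logical(1))))
      stop("contrast ids in contrast_loci must be among G1..G6, ",
           "or pass matching `contrasts`")
  }
  for (ct in contrasts) {
    extra <- setdiff(ct$universe, taxa)
    if (length(extra))
      stop("contrast ", ct$id, " references unknown taxa: ",
           paste(extra, collapse = ", "))
  }
  n <- sum(cfg$group_sizes)
  taxon_of <- rep(taxa, cfg$group_sizes)
  prefix <- toupper(substr(taxa, 1L, 4L))
  sample_ids <- unlist(lapply(seq_along(taxa), function(i)
    sprintf("%s_%03d", prefix[i], seq_len(cfg$group_sizes[i]))),
    use.names = FALSE)
  cids <- rep(names(cfg$contrast_loci), cfg$contrast_loci)
  locus_ids <- c(
    unlist(lapply(names(cfg$contrast_loci), function(cid)
      sprintf("ARC-%s-%02d", cid, seq_len(cfg$contrast_loci[[cid]]))),
      use.names = FALSE),
    sprintf("BG-%03d", seq_len(cfg$n_background)))
  L_diag <- length(cids)
  L <- L_diag + cfg$n_background
  with_seed(cfg$seed, {
    dos <- matrix(NA_integer_, n, L, dimnames = list(sample_ids, locus_ids))
    orient <- sample(c(1L, 2L), L, replace = TRUE)  # allele index counted as "2"
    truth_contrast <- c(cids, rep("background", cfg$n_background))
    diag_allele <- rep(NA_integer_, L)
    # planted loci: expected state 2 for target, 0 otherwise (pre-orientation).
    # The hybrid contrast (G1) is special: when hybrids are planted they are
    # the sole source of discordance at its loci (the configured G1 fixation
    # documents the realized hybrid-induced level, e.g. 81/88 ~ 0.93); with
    # n_hybrids = 0 the G1 loci revert to i.i.d. flips like every contrast.
    hybrid_contrast <- if (cfg$n_hybrids > 0L) "G1" else NA_character_
    for (l in seq_len(L_diag)) {
      ct <- contrasts[[cids[l]]]
      expected <- ifelse(taxon_of %in% ct$target, 2L, 0L)
      if (identical(cids[l], hybrid_contrast)) {
        dos[, l] <- expected
      } else {
        err <- runif(n) >= cfg$fixation[[cids[l]]]
        dos[, l] <- ifelse(err, 2L - expected, expected)
      }
    }
    # hybrids: barthii accessions carrying the glaberrima (complex) state at G1
    hybrid_ids <- character(0)
    if (cfg$n_hybrids > 0L && "G1" %in% cids) {
      barthii_rows <- which(taxon_of == "barthii")
      hybrid_rows <- sort(sample(barthii_rows, cfg$n_hybrids))
      hybrid_ids <- sample_ids[hybrid_rows]
      dos[hybrid_rows, cids == "G1"] <- 0L   # cultivated/complex homozygote
    }
    # background loci: shared allele frequencies, no group structure
    if (cfg$n_background > 0L) {
      p <- runif(cfg$n_background, cfg$maf_range[1L], cfg$maf_range[2L])
      for (b in seq_len(cfg$n_background))
        dos[, L_diag + b] <- 2L * rbinom(n, 1L, p[b])
    }
    # orientation flip: dosage counts allele `orient[l]`
    flip <- orient == 1L
    dos[, flip] <- 2L - dos[, flip]
    diag_allele[seq_len(L_diag)] <- ifelse(flip[seq_len(L_diag)], 1L, 2L)
    # heterozygote injection, then missingness
    het_mask <- matrix(runif(n * L) < cfg$het_rate, n, L)
    dos[het_mask] <- 1L
    miss_rate <- runif(L, 0, cfg$missing_max)
    g1_loci <- which(cids == "G1")
    if (length(g1_loci))
      miss_rate[g1_loci[min(2L, length(g1_loci))]] <- cfg$high_missing_rate
    miss_mask <- matrix(runif(n * L) < rep(miss_rate, each = n), n, L)
    dos[miss_mask] <- NA_integer_
    # allele letters per locus
    pairs <- t(replicate(L, sample(c("A", "C", "G", "T"), 2L)))
    g <- genotype_matrix(dos, sample_ids, locus_ids, alleles = pairs)
    meta <- data.frame(sample_id = sample_ids, taxon = taxon_of,
                       is_hybrid = sample_ids %in% hybrid_ids,
                       stringsAsFactors = FALSE)
    lg <- attach_labels(g, meta)
    # realized per-group concordance of each planted locus
    conc <- vector("list", L_diag)
    for (l in seq_len(L_diag)) {
      ct <- contrasts[[cids[l]]]
      hom_diag <- if (diag_allele[l] == 2L) 2L else 0L
      per <- vapply(ct$universe, function(t) {
        x <- dos[taxon_of == t, l]
        e <- if (t %in% ct$target) hom_diag else 2L - hom_diag
        x <- x[!is.na(x)]
        if (length(x)) mean(x == e) else NA_real_
      }, numeric(1))
      conc[[l]] <- per
    }
    names(conc) <- locus_ids[seq_len(L_diag)]
    truth <- list(
      locus_contrast = setNames(truth_contrast, locus_ids),
      diagnostic_allele = setNames(diag_allele, locus_ids),
      hybrid_ids = hybrid_ids,
      per_group_concordance = conc,
      missing_rate = setNames(miss_rate, locus_ids))
    structure(list(lg = lg, truth = truth, cfg = cfg, contrasts = contrasts),
              class = "synthetic_collection")
  })
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat("synthetic_collection:", sum(x$cfg$group_sizes), "samples x",
      length(x$truth$locus_contrast), "loci (",
      sum(x$truth$locus_contrast != "background"), "planted diagnostic )\n")
  cat("  hybrids:", length(x$truth$hybrid_ids), " seed:", x$cfg$seed, "\n")
  invisible(x)
}
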