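#' Run the full QC-panel pipeline
#'
#' Chains the stages of the marker-validation workflow on a labeled
#' collection: per-marker summaries, the quality-filter cascade, contrast
#' concordance scoring, panel assembly (with joint-pair fallback), greedy
#' minimal-panel reduction, accession classification, haplotype pattern, and
#' the validation battery (AMOVA with PhiPT, pairwise PhiPT, PCA, NJ tree,
#' DAPC) computed on the selected panel loci. A stage failure is re-raised
#' with the stage name. When `out_dir` is given, tables, the newick tree,
#' the panel JSON and a machine-readable `manifest.json` of headline numbers
#' are written there.
#'
#' @param lg a `labeled_collection`.
#' @param contrasts contrast list, default [default_contrasts()].
#' @param thresholds list overriding [filter_markers()] defaults.
#' @param concordance_threshold per-taxon diagnostic threshold.
#' @param n_perm AMOVA permutations (also pairwise).
#' @param n_boot NJ bootstrap replicates (0 = plain tree).
#' @param K_max DAPC search limit.
#' @param seed master seed; stage seeds are derived from it.
#' @param redundancy minimal-panel markers per taxon pair.
#' @param out_dir optional output directory (created if needed).
#' @return List of class `qc_pipeline` with elements `summary`, `filter`,
#'   `selection`, `panel`, `minimal`, `classification`, `pattern`, `amova`,
#'   `pairwise`, `pca`, `tree`, `dapc`, `manifest`.
#' @export
run_pipeline <- function(lg, contrasts = default_contrasts(),
                         thresholds = list(), concordance_threshold = 0.97,
                         n_perm = 999L, n_boot = 0L, K_max = 20L,
                         seed = 1L, redundancy = 2L, out_dir = NULL) {
  stopifnot(inherits(lg, "labeled_collection"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  summ <- stage("stats", summarize_markers(lg$g))
  filt <- stage("filter", do.call(filter_markers, c(list(summ), thresholds)))
  kept <- filt$locus_id[filt$kept]
  sel <- stage("score", select_diagnostic_markers(
    lg, contrasts, threshold = concordance_threshold, loci = kept))
  panel <- stage("select-panel", select_panel(lg, sel))
  minimal <- stage("minimal-panel", minimal_panel(panel, lg, redundancy = redundancy))
  classification <- stage("classify", classify_collection(lg, panel))
  pattern <- stage("pattern", haplotype_pattern(lg, panel, seed = seed))
  panel_loci <- panel$markers$locus_id
  d2 <- stage("distance", squared_distance_matrix(
    subset_genotypes(lg$g, loci = panel_loci)))
  am <- stage("amova", amova(d2, lg$taxa, n_perm = n_perm, seed = seed + 1L))
  pw <- stage("pairwise-phipt", pairwise_phipt(
    subset_genotypes(lg$g, loci = panel_loci), unname(lg$taxa),
    n_perm = n_perm, seed = seed + 2L))
  pca <- stage("pca", pca_genotypes(lg$g, loci = panel_loci))
  tree <- stage("nj", if (n_boot > 0L)
    bootstrap_support(lg$g, n_boot = n_boot, seed = seed + 3L, loci = panel_loci)
    else nj_genotypes(lg$g, loci = panel_loci))
  dapc <- stage("dapc", dapc_clusters(lg$g, K_max = K_max, seed = seed + 4L,
                                      loci = panel_loci))
  manifest <- list(
    seed = seed, n_samples = length(lg$g$sample_ids),
    n_loci = length(lg$g$locus_ids), n_kept = length(kept),
    panel_size = nrow(panel$markers),
    minimal_panel_size = nrow(minimal$markers),
    minimal_panel_identical = attr(minimal, "classification_identical"),
    markers_per_contrast = as.list(table(panel$markers$contrast_id)),
    phipt = am$phipt, phipt_p = am$p_value, pct_among = am$pct_among,
    chosen_K = dapc$chosen_K,
    pca_pct_first3 = round(pca$pct_variance[1:min(3, length(pca$pct_variance))], 2),
    concordance_threshold = concordance_threshold,
    thresholds = if (length(thresholds)) thresholds else "defaults",
    n_perm = n_perm, n_boot = n_boot, K_max = K_max)
  out <- structure(list(summary = summ, filter = filt, selection = sel,
                        panel = panel, minimal = minimal,
                        classification = classification, pattern = pattern,
                        amova = am, pairwise = pw, pca = pca, tree = tree,
                        dapc = dapc, manifest = manifest),
                   class = "qc_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.qc_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("qc_pipeline:", m$n_samples, "samples,", m$n_loci, "loci\n")
  cat(sprintf("  filter kept %d; panel %d markers (minimal %d, identical: %s)\n",
              m$n_kept, m$panel_size, m$minimal_panel_size,
              m$minimal_panel_identical))
  cat(sprintf("  PhiPT %.3f (P %s); chosen K = %d\n", m$phipt,
              format(m$phipt_p), m$chosen_K))
  invisible(x)
}

# Serialize a panel as JSON: loci, contrast, diagnostic allele, expected
# haplotype per taxon, provenance.
panel_to_json <- function(panel, path) {
  obj <- list(threshold = panel$threshold,
              markers = panel$markers,
              expected_haplotypes = as.data.frame(t(panel$expected)))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write.table(res$summary, fp("marker_summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(res$filter, fp("marker_filter.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(res$selection$scores, fp("concordance_scores.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  panel_to_json(res$panel, fp("panel.json"))
  panel_to_json(res$minimal, fp("panel_minimal.json"))
  write.table(res$classification, fp("classification.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(res$pattern, fp("haplotype_pattern.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  am <- res$amova
  amova_tab <- data.frame(
    source = c("Among pops", "Within pops", "Total"),
    df = c(am$df_among, am$df_within, am$df_total),
    SS = c(am$ss_among, am$ss_within, am$ss_total),
    MS = c(am$ms_among, am$ms_within, NA),
    est_var = c(am$var_among, am$var_within, am$var_among + am$var_within),
    pct = c(am$pct_among, am$pct_within, 100))
  write.table(amova_tab, fp("amova.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(res$pairwise$phipt, fp("pairwise_phipt.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(res$pairwise$p, fp("pairwise_phipt_p.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(res$pca$scores[, 1:min(10, ncol(res$pca$scores)), drop = FALSE],
              fp("pca_scores.tsv"), sep = "\t", quote = FALSE, col.names = NA)
  ape::write.tree(res$tree, fp("nj_tree.nwk"))
  dapc_tab <- data.frame(sample_id = res$dapc$sample_ids,
                         cluster = res$dapc$cluster,
                         round(res$dapc$membership, 6))
  write.table(dapc_tab, fp("dapc_membership.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a collection and write it to disk
#'
#' Writes the genotype matrix (dosage dialect), the sample metadata and the
#' planted truth (JSON) to `out_dir`. Re-running with the same config
#' reproduces the files byte-identically.
#'
#' @param cfg a [collection_config()].
#' @param out_dir output directory.
#' @return The `synthetic_collection`, invisibly.
#' @export
cmd_simulate <- function(cfg = collection_config(), out_dir) {
  sim <- simulate_collection(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_table(sim$lg$g, file.path(out_dir, "genotypes.tsv"),
                       dialect = "dosage")
  write_sample_metadata(sim$lg$meta, file.path(out_dir, "metadata.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(locus_contrast = as.list(truth$locus_contrast),
         diagnostic_allele = as.list(truth$diagnostic_allele),
         hybrid_ids = truth$hybrid_ids,
         config = unclass(sim$cfg)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(sim)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic collection),
#' `pipeline` (run [run_pipeline()] on genotype + metadata tables),
#' `stats` (marker summary + filter only). Data go to files; logs to
#' stderr. Invoked by the `inst/cli/oryzaqc` script.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Exit status 0 invisibly; stops on usage errors.
#' @export
qc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: oryzaqc <simulate|stats|pipeline> [options]",
    "  simulate --out DIR [--seed N] [--scale F]",
    "  stats    --genotypes FILE [--dialect D] --out DIR",
    "  pipeline --genotypes FILE --metadata FILE --out DIR",
    "           [--dialect D] [--seed N] [--n-perm N] [--n-boot N] [--k-max N]",
    sep = "\n")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1L]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0L) return(default)
    if (i == length(args)) stop("missing value for --", name, call. = FALSE)
    args[i + 1L]
  }
  out_dir <- opt("out")
  if (is.null(out_dir)) stop(usage, call. = FALSE)
  if (cmd == "simulate") {
    cfg <- collection_config(seed = as.integer(opt("seed", "1")))
    scale <- as.numeric(opt("scale", "1"))
    if (scale != 1) cfg <- scale_config(cfg, scale)
    cmd_simulate(cfg, out_dir)
    message("wrote synthetic collection to ", out_dir)
  } else if (cmd == "stats") {
    g <- read_genotype_table(opt("genotypes"), dialect = opt("dialect", "auto"))
    summ <- summarize_markers(g)
    filt <- filter_markers(summ)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(summ, file.path(out_dir, "marker_summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(filt, file.path(out_dir, "marker_filter.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    message("kept ", sum(filt$kept), " of ", nrow(filt), " markers")
  } else if (cmd == "pipeline") {
    g <- read_genotype_table(opt("genotypes"), dialect = opt("dialect", "auto"))
    meta <- read_sample_metadata(opt("metadata"))
    lg <- attach_labels(g, meta)
    res <- run_pipeline(lg, seed = as.integer(opt("seed", "1")),
                        n_perm = as.integer(opt("n-perm", "999")),
                        n_boot = as.integer(opt("n-boot", "0")),
                        K_max = as.integer(opt("k-max", "20")),
                        out_dir = out_dir)
    message("pipeline complete; PhiPT = ", round(res$manifest$phipt, 3),
            ", chosen K = ", res$manifest$chosen_K)
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
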