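#' Biallelic genotype matrix
#'
#' Container for a samples-by-loci matrix of allele dosages. Dosage is the
#' count of the locus's second listed allele, so values are 0 (homozygous for
#' the first allele), 1 (heterozygous) or 2 (homozygous for the second
#' allele); missing calls are `NA`. All downstream statistics are symmetric in
#' allele labelling, so which allele is listed second is only a bookkeeping
#' convention.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids,locus_ids character vectors naming rows/columns; default
#'   to the dimnames of `dosage`.
#' @param alleles optional character matrix (`n_loci` x 2) of single-letter
#'   allele labels per locus (rows may contain `NA` when alleles are unknown,
#'   e.g. dosage-only input).
#' @param chrom,pos optional per-locus chromosome labels and 1-based
#'   positions; descriptive only, never used in computation.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            locus_ids = colnames(dosage), alleles = NULL,
                            chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(dosage)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(dosage))
    stop("sample_ids length (", length(sample_ids), ") != rows (", nrow(dosage), ")")
  if (length(locus_ids) != ncol(dosage))
    stop("locus_ids length (", length(locus_ids), ") != columns (", ncol(dosage), ")")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(locus_ids)) stop("duplicated locus ids")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage values must be 0, 1, 2 or NA")
  if (!is.null(alleles)) {
    alleles <- as.matrix(alleles)
    if (nrow(alleles) != length(locus_ids) || ncol(alleles) != 2L)
      stop("alleles must be an n_loci x 2 matrix")
    known <- !is.na(alleles[, 1L]) & !is.na(alleles[, 2L])
    if (any(known)) {
      ok <- alleles[known, 1L] != alleles[known, 2L] &
        alleles[known, 1L] %in% c("A", "C", "G", "T") &
        alleles[known, 2L] %in% c("A", "C", "G", "T")
      if (!all(ok))
        stop("invalid allele pair at locus ", locus_ids[known][!ok][1L])
    }
    rownames(alleles) <- locus_ids
  }
  dimnames(dosage) <- list(sample_ids, locus_ids)
  for (v in c("chrom", "pos")) {
    val <- get(v)
    if (!is.null(val) && length(val) != length(locus_ids))
      stop(v, " must have one entry per locus")
  }
  structure(
    list(dosage = dosage, sample_ids = sample_ids, locus_ids = locus_ids,
         alleles = alleles, chrom = chrom, pos = pos),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$locus_ids), "loci\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.1f%%; alleles %s\n", 100 * miss,
              if (is.null(x$alleles)) "unknown" else "recorded"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param samples,loci index vectors (ids, positions or logical).
#' @return A `genotype_matrix` restricted to the requested samples/loci.
#' @export
subset_genotypes <- function(x, samples = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  li <- if (is.null(loci)) seq_along(x$locus_ids) else loci
  if (is.character(li)) li <- match(li, x$locus_ids)
  if (is.character(si)) si <- match(si, x$sample_ids)
  if (anyNA(li) || anyNA(si)) stop("unknown sample or locus id in subset")
  d <- x$dosage[si, li, drop = FALSE]
  genotype_matrix(d, rownames(d), colnames(d),
                  alleles = if (!is.null(x$alleles)) x$alleles[li, , drop = FALSE],
                  chrom = x$chrom[li], pos = x$pos[li])
}

#' Flip the allele orientation of loci
#'
#' Recodes which allele is counted by the dosage (`d -> 2 - d`) and swaps the
#' allele labels for the given loci. All summary statistics are invariant
#' under this recoding.
#'
#' @param x a [genotype_matrix()].
#' @param loci loci to flip (default all).
#' @return The recoded `genotype_matrix`.
#' @export
flip_alleles <- function(x, loci = x$locus_ids) {
  stopifnot(inherits(x, "genotype_matrix"))
  li <- if (is.character(loci)) match(loci, x$locus_ids) else loci
  if (anyNA(li)) stop("unknown locus id")
  d <- x$dosage
  d[, li] <- 2L - d[, li]
  al <- x$alleles
  if (!is.null(al)) al[li, ] <- al[li, 2:1, drop = FALSE]
  genotype_matrix(d, x$sample_ids, x$locus_ids, alleles = al,
                  chrom = x$chrom, pos = x$pos)
}

#' Attach taxon labels to a genotype matrix
#'
#' Joins per-sample metadata onto a genotype matrix, preserving the matrix's
#' sample order. Every sample must have exactly one taxon label.
#'
#' @param g a [genotype_matrix()].
#' @param meta data frame with at least columns `sample_id` and `taxon`.
#' @return An object of class `labeled_collection`: a list with elements
#'   `g` (the genotype matrix), `taxa` (character vector aligned with
#'   `g$sample_ids`) and `meta` (the full metadata rows, reordered).
#' @export
attach_labels <- function(g, meta) {
  stopifnot(inherits(g, "genotype_matrix"), is.data.frame(meta))
  if (!all(c("sample_id", "taxon") %in% names(meta)))
    stop("metadata needs columns 'sample_id' and 'taxon'")
  idx <- match(g$sample_ids, meta$sample_id)
  if (anyNA(idx)) {
    missing_ids <- g$sample_ids[is.na(idx)]
    stop("samples missing from metadata: ", paste(missing_ids, collapse = ", "))
  }
  taxa <- as.character(meta$taxon[idx])
  names(taxa) <- g$sample_ids
  structure(list(g = g, taxa = taxa, meta = meta[idx, , drop = FALSE]),
            class = "labeled_collection")
}

#' @export
print.labeled_collection <- function(x, ...) {
  cat("labeled_collection:", length(x$taxa), "samples,",
      length(x$g$locus_ids), "loci\n")
  print(table(x$taxa))
  invisible(x)
}

#' Per-taxon sample counts of a labeled collection
#' @param x a `labeled_collection`.
#' @return Named integer vector of group sizes.
#' @export
group_sizes <- function(x) {
  stopifnot(inherits(x, "labeled_collection"))
  tab <- table(x$taxa)
  structure(as.integer(tab), names = names(tab))
}
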