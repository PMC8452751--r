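# Tokens treated as a missing genotype call on input.
MISSING_TOKENS <- c("NA", "--", "NN", "N", "", ".", "-", "?", "../..")

# IUPAC ambiguity codes accepted as heterozygous single-letter calls.
IUPAC_HET <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

iupac_code <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  codes <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
  unname(codes[key])
}

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

split_call <- function(tok) {
  # normalize one genotype call token to a pair of allele letters, or NA
  tok <- toupper(gsub("[/|: ]", "", tok))
  if (is.na(tok) || tok %in% gsub("[/|: ]", "", MISSING_TOKENS)) return(NULL)
  if (nchar(tok) == 1L) {
    if (tok %in% c("A", "C", "G", "T")) return(c(tok, tok))
    if (tok %in% names(IUPAC_HET)) return(IUPAC_HET[[tok]])
    stop("unknown allele character '", tok, "'")
  }
  if (nchar(tok) == 2L) {
    al <- strsplit(tok, "")[[1L]]
    if (!all(al %in% c("A", "C", "G", "T")))
      stop("unknown allele character in call '", tok, "'")
    return(al)
  }
  stop("malformed genotype call '", tok, "'")
}

calls_to_dosage <- function(calls, locus_id) {
  # calls: character vector for one locus; returns list(dosage, alleles)
  pairs <- vector("list", length(calls))
  for (i in seq_along(calls)) {
    p <- tryCatch(split_call(calls[i]), error = function(e)
      stop("locus ", locus_id, ": ", conditionMessage(e), call. = FALSE))
    pairs[i] <- list(p)   # keep NULL (missing call) as an element
  }
  seen <- sort(unique(unlist(pairs)))
  if (length(seen) > 2L)
    stop("locus ", locus_id, " has >2 alleles: ", paste(seen, collapse = ","))
  alleles <- c(seen, NA_character_)[1:2]  # alphabetical; second NA if monomorphic
  dos <- rep(NA_integer_, length(calls))
  for (i in seq_along(calls)) {
    p <- pairs[[i]]
    if (is.null(p)) next
    dos[i] <- sum(p == alleles[2L] & !is.na(alleles[2L]))
  }
  list(dosage = dos, alleles = alleles)
}

#' Read a genotype table
#'
#' Reads delimited-text genotype tables in three dialects:
#' \describe{
#'   \item{`dosage`}{samples in rows, loci in columns, entries 0/1/2/NA;
#'     first column `sample_id`.}
#'   \item{`calls`}{same layout, entries are allele-pair calls (`"AA"`,
#'     `"AG"`, `"A/G"`) or single letters including IUPAC heterozygote codes
#'     (`R Y S W K M`). Allele pairs per locus are inferred from the data and
#'     ordered alphabetically; dosage counts the second allele.}
#'   \item{`hapmap`}{loci in rows with leading columns `rs#`, `alleles`
#'     (e.g. `"A/G"`), `chrom`, `pos`, then one column per sample holding
#'     single-letter calls.}
#' }
#' The delimiter is a comma for `.csv` paths, tab otherwise. Missing-call
#' tokens (`NA`, `--`, `NN`, `N`, empty, `.`) become `NA`.
#'
#' The `calls` dialect carries no allele metadata, so a column in which only
#' one allele is observed reads back as dosage 0 for that homozygote
#' (orientation is unknowable); the `hapmap` dialect preserves orientation
#' exactly. All statistics are invariant to orientation.
#'
#' @param path file to read.
#' @param dialect `"auto"` (sniff hapmap by its header), `"dosage"`,
#'   `"calls"` or `"hapmap"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, dialect = c("auto", "dosage", "calls", "hapmap")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- delim_for(path)
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    comment.char = "", quote = "\"")
  if (dialect == "auto") {
    dialect <- if (tolower(names(raw)[1L]) %in% c("rs#", "rs", "locus_id") &&
                   "alleles" %in% tolower(names(raw))) "hapmap" else {
      body <- unlist(raw[, -1L, drop = FALSE], use.names = FALSE)
      body <- body[!(toupper(body) %in% MISSING_TOKENS)]
      if (length(body) && all(grepl("^[012]$", body))) "dosage" else "calls"
    }
  }
  if (dialect == "hapmap") return(read_hapmap(raw, path))
  ids <- raw[[1L]]
  loci <- names(raw)[-1L]
  if (length(loci) == 0L)
    return(genotype_matrix(matrix(NA_integer_, length(ids), 0L), ids, character(0)))
  if (dialect == "dosage") {
    d <- sapply(raw[-1L], function(col) {
      col[toupper(col) %in% MISSING_TOKENS] <- NA
      bad <- !is.na(col) & !col %in% c("0", "1", "2")
      if (any(bad))
        stop("non-dosage value '", col[bad][1L], "' (use dialect='calls'?)")
      as.integer(col)
    })
    d <- matrix(d, nrow = length(ids), dimnames = list(ids, loci))
    return(genotype_matrix(d, ids, loci))
  }
  # calls dialect
  out <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  alleles <- matrix(NA_character_, length(loci), 2L)
  for (j in seq_along(loci)) {
    res <- calls_to_dosage(raw[[j + 1L]], loci[j])
    out[, j] <- res$dosage
    alleles[j, ] <- res$alleles
  }
  known <- !is.na(alleles[, 1L]) & !is.na(alleles[, 2L])
  genotype_matrix(out, ids, loci,
                  alleles = if (any(known)) alleles else NULL)
}

read_hapmap <- function(raw, path) {
  lower <- tolower(names(raw))
  need <- c("alleles", "chrom", "pos")
  if (!all(need %in% lower))
    stop("hapmap table needs columns rs#, alleles, chrom, pos: ", path)
  meta_idx <- match(need, lower)
  loci <- raw[[1L]]
  al <- strsplit(toupper(raw[[meta_idx[1L]]]), "/", fixed = TRUE)
  bad <- lengths(al) != 2L
  if (any(bad)) stop("malformed alleles field at locus ", loci[bad][1L])
  alleles <- do.call(rbind, al)
  first_sample <- max(meta_idx) + 1L
  sample_cols <- seq(first_sample, ncol(raw))
  ids <- names(raw)[sample_cols]
  d <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  for (l in seq_along(loci)) {
    for (s in seq_along(ids)) {
      p <- tryCatch(split_call(raw[[sample_cols[s]]][l]), error = function(e)
        stop("locus ", loci[l], ": ", conditionMessage(e), call. = FALSE))
      if (is.null(p)) next
      if (!all(p %in% alleles[l, ]))
        stop("locus ", loci[l], ": call '", raw[[sample_cols[s]]][l],
             "' inconsistent with alleles ", paste(alleles[l, ], collapse = "/"))
      d[s, l] <- sum(p == alleles[l, 2L])
    }
  }
  genotype_matrix(d, ids, loci, alleles = alleles,
                  chrom = raw[[meta_idx[2L]]],
                  pos = suppressWarnings(as.integer(raw[[meta_idx[3L]]])))
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]. Output is bit-stable for a fixed
#' input (no timestamps). The `calls` and `hapmap` dialects require allele
#' labels on the matrix.
#'
#' @param g a [genotype_matrix()].
#' @param path output file; comma-separated if it ends in `.csv`, else tab.
#' @param dialect one of `"dosage"`, `"calls"`, `"hapmap"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, dialect = c("dosage", "calls", "hapmap")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "genotype_matrix"))
  sep <- delim_for(path)
  if (dialect == "dosage") {
    df <- data.frame(sample_id = g$sample_ids, check.names = FALSE)
    for (j in seq_along(g$locus_ids)) df[[g$locus_ids[j]]] <- g$dosage[, j]
  } else {
    if (is.null(g$alleles) || anyNA(g$alleles))
      stop("dialect '", dialect, "' needs allele labels for every locus")
    if (dialect == "calls") {
      df <- data.frame(sample_id = g$sample_ids, check.names = FALSE)
      for (j in seq_along(g$locus_ids)) {
        a <- g$alleles[j, ]
        tok <- c(paste0(a[1L], a[1L]), paste0(a[1L], a[2L]), paste0(a[2L], a[2L]))
        df[[g$locus_ids[j]]] <- ifelse(is.na(g$dosage[, j]), "NA",
                                       tok[g$dosage[, j] + 1L])
      }
    } else {
      df <- data.frame("rs#" = g$locus_ids,
                       alleles = paste(g$alleles[, 1L], g$alleles[, 2L], sep = "/"),
                       chrom = g$chrom %||% rep(NA, length(g$locus_ids)),
                       pos = g$pos %||% rep(NA, length(g$locus_ids)),
                       check.names = FALSE)
      for (s in seq_along(g$sample_ids)) {
        a1 <- g$alleles[, 1L]; a2 <- g$alleles[, 2L]
        het <- mapply(iupac_code, a1, a2)
        col <- rep("NA", length(g$locus_ids))
        d <- g$dosage[s, ]
        col[!is.na(d) & d == 0L] <- a1[!is.na(d) & d == 0L]
        col[!is.na(d) & d == 1L] <- het[!is.na(d) & d == 1L]
        col[!is.na(d) & d == 2L] <- a2[!is.na(d) & d == 2L]
        df[[g$sample_ids[s]]] <- col
      }
    }
  }
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read sample metadata
#'
#' @param path delimited text with at least columns `sample_id` and `taxon`
#'   (comma-separated for `.csv`, tab otherwise).
#' @return A data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read.table(path, sep = delim_for(path), header = TRUE,
                     check.names = FALSE, colClasses = "character",
                     quote = "\"", comment.char = "")
  if (!all(c("sample_id", "taxon") %in% names(meta)))
    stop("metadata needs columns 'sample_id' and 'taxon'")
  meta
}

#' Write sample metadata
#' @param meta data frame with `sample_id` and `taxon` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = delim_for(path), row.names = FALSE,
              quote = FALSE, na = "NA")
  invisible(path)
}
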