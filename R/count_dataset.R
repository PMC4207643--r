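#' Per-gene count container for mRNA and footprint libraries
#'
#' A `count_dataset` holds an integer matrix of read counts, one row per gene
#' and one column per (molecule, source, replicate) combination, together with
#' column metadata and a provenance tag recording which resampling steps have
#' been applied (`"raw"`, `"downsampled"` or `"hypergeometric"`).
#'
#' Columns belonging to the same sequencing library share a `library` id in
#' `col_data`. For parental samples each column is its own library; for a
#' diploid hybrid the two allele columns of one replicate come from a single
#' library and share an id, so that library-level resampling treats them
#' jointly.
#'
#' @param counts integer matrix of non-negative counts; rownames are gene ids.
#' @param col_data data.frame with columns `molecule` (`"mrna"` or `"fp"`),
#'   `source`, `replicate` and optionally `library`; one row per count column.
#' @param provenance one of `"raw"`, `"downsampled"`, `"hypergeometric"`.
#' @param seeds named list of seeds used by resampling steps (bookkeeping).
#' @return an object of class `count_dataset`.
#' @export
count_dataset <- function(counts, col_data, provenance = "raw", seeds = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (nrow(counts) == 0L) stop("no genes")
  if (any(!is.finite(counts))) stop("non-finite counts")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("non-integer counts")
  storage.mode(counts) <- "double"  # totals can exceed .Machine$integer.max
  col_data <- as.data.frame(col_data, stringsAsFactors = FALSE)
  needed <- c("molecule", "source", "replicate")
  if (!all(needed %in% names(col_data))) {
    stop("col_data must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(col_data) != ncol(counts)) stop("col_data rows must match count columns")
  if (!all(col_data$molecule %in% c("mrna", "fp"))) {
    stop("molecule must be 'mrna' or 'fp'")
  }
  if (is.null(col_data$library)) {
    col_data$library <- paste(col_data$molecule, col_data$source,
                              col_data$replicate, sep = "_")
  }
  provenance <- match.arg(provenance, c("raw", "downsampled", "hypergeometric"))
  colnames(counts) <- paste(col_data$molecule, col_data$source,
                            col_data$replicate, sep = "_")
  if (anyDuplicated(colnames(counts))) stop("duplicate (molecule, source, replicate) columns")
  structure(
    list(counts = counts, col_data = col_data, provenance = provenance,
         seeds = seeds),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d columns [%s]\n",
              nrow(x$counts), ncol(x$counts), x$provenance))
  tot <- tapply(colSums(x$counts), x$col_data$library, sum)
  cat("library totals:\n")
  print(round(tot))
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

genes <- function(x) rownames(x$counts)

# subset genes, keeping metadata
subset_genes <- function(x, keep) {
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Read a tab-delimited count table
#'
#' Expects a one-line header `gene<TAB>molecule_source_rep ...` where
#' `molecule` is `mrna` or `fp`. Lines starting with `#` are metadata and are
#' ignored (provenance/seed annotations written by [write_counts()]).
#'
#' @param path file path.
#' @param provenance provenance tag to assign (default `"raw"`).
#' @return a [count_dataset()].
#' @export
read_counts <- function(path, provenance = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("no genes in ", path)
  tab <- utils::read.delim(text = lines, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene") stop("first column must be 'gene'")
  if (ncol(tab) < 2L) stop("missing count columns")
  cn <- names(tab)[-1]
  parts <- strsplit(cn, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed column header(s): ", paste(cn[bad], collapse = ", "),
         " (expected molecule_source_rep)")
  }
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene ids: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("invalid count for gene %s in column %s (line %d)",
                   tab$gene[bad[1]], cn[j], bad[1] + 1L))
    }
  }
  rownames(m) <- tab$gene
  cd <- data.frame(
    molecule = vapply(parts, `[`, "", 1L),
    source = vapply(parts, `[`, "", 2L),
    replicate = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  # hybrid allele columns of one replicate come from the same library
  hyb <- grepl("allele", cd$source, fixed = TRUE)
  cd$library <- ifelse(hyb, paste(cd$molecule, cd$replicate, sep = "_"),
                       paste(cd$molecule, cd$source, cd$replicate, sep = "_"))
  count_dataset(m, cd, provenance = provenance)
}

#' Write a count table in the dialect read by [read_counts()]
#'
#' Provenance and seeds are embedded as `#`-prefixed metadata lines.
#'
#' @param x a [count_dataset()].
#' @param path output file path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_dataset"))
  meta <- c(sprintf("# provenance: %s", x$provenance))
  if (length(x$seeds)) {
    meta <- c(meta, sprintf("# seed %s: %s", names(x$seeds),
                            vapply(x$seeds, format, "")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate SNP-level allele counts to gene level
#'
#' Allele counts of all SNPs mapped to a gene are summed, per count column.
#' Genes with no SNPs are absent from the output.
#'
#' @param snp_counts data.frame with a `snp` id column and count columns named
#'   `molecule_source_rep` as in [read_counts()].
#' @param gene_map data.frame with columns `snp`, `gene` and optionally
#'   `strand`; a SNP may map to at most one gene per strand.
#' @return a [count_dataset()] with provenance `"raw"`.
#' @export
aggregate_snps_to_genes <- function(snp_counts, gene_map) {
  stopifnot(is.data.frame(snp_counts), is.data.frame(gene_map))
  if (!"snp" %in% names(snp_counts)) stop("snp_counts needs a 'snp' column")
  if (!all(c("snp", "gene") %in% names(gene_map))) {
    stop("gene_map needs 'snp' and 'gene' columns")
  }
  strand <- gene_map$strand %||% rep("+", nrow(gene_map))
  key <- paste(gene_map$snp, strand)
  multi <- tapply(gene_map$gene, key, function(g) length(unique(g)))
  if (any(multi > 1L)) {
    stop("SNP mapped to two genes on the same strand: ",
         names(multi)[multi > 1L][1])
  }
  mm <- merge(snp_counts, gene_map[, c("snp", "gene")], by = "snp")
  if (nrow(mm) == 0L) stop("no genes")
  cn <- setdiff(names(snp_counts), "snp")
  agg <- rowsum(as.matrix(mm[, cn, drop = FALSE]), group = mm$gene)
  parts <- strsplit(cn, "_", fixed = TRUE)
  cd <- data.frame(
    molecule = vapply(parts, `[`, "", 1L),
    source = vapply(parts, `[`, "", 2L),
    replicate = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  hyb <- grepl("allele", cd$source, fixed = TRUE)
  cd$library <- ifelse(hyb, paste(cd$molecule, cd$replicate, sep = "_"),
                       paste(cd$molecule, cd$source, cd$replicate, sep = "_"))
  count_dataset(agg, cd, provenance = "raw")
}
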