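#' Sum replicate columns of a count dataset
#'
#' Collapses the replicate dimension: one output column per
#' (molecule, source), containing the integer sum over replicates. Datasets
#' with a single replicate per combination are returned unchanged apart from
#' the replicate label.
#'
#' @param x a [count_dataset()].
#' @return a [count_dataset()] with one column per (molecule, source).
#' @export
sum_replicates <- function(x) {
  stopifnot(inherits(x, "count_dataset"))
  cd <- x$col_data
  grp <- paste(cd$molecule, cd$source, sep = "_")
  idx <- split(seq_len(ncol(x$counts)), grp)
  # keep original column order (first occurrence of each group)
  idx <- idx[order(vapply(idx, min, 1L))]
  m <- vapply(idx, function(j) rowSums(x$counts[, j, drop = FALSE]),
              numeric(nrow(x$counts)))
  rownames(m) <- rownames(x$counts)
  first <- vapply(idx, `[`, 1L, 1L)
  cd2 <- data.frame(
    molecule = cd$molecule[first],
    source = cd$source[first],
    replicate = "1",
    stringsAsFactors = FALSE
  )
  hyb <- grepl("allele", cd2$source, fixed = TRUE)
  cd2$library <- ifelse(hyb, cd2$molecule,
                        paste(cd2$molecule, cd2$source, sep = "_"))
  count_dataset(m, cd2, provenance = x$provenance, seeds = x$seeds)
}

#' Downsample all libraries to the smallest library size
#'
#' The library with the lowest total count remains as observed; every other
#' library is resampled down to exactly that total. The default draws reads
#' without replacement (multivariate hypergeometric over the library's
#' reads); multinomial sampling with replacement is available for
#' sensitivity checks.
#'
#' @param x a [count_dataset()] with provenance `"raw"`.
#' @param seed integer seed for reproducibility (NULL uses the current RNG
#'   stream).
#' @param method `"hypergeometric"` (without replacement, default) or
#'   `"multinomial"`.
#' @return a [count_dataset()] with provenance `"downsampled"`; all library
#'   totals equal the minimum input library total.
#' @export
downsample_libraries <- function(x, seed = NULL,
                                 method = c("hypergeometric", "multinomial")) {
  stopifnot(inherits(x, "count_dataset"))
  method <- match.arg(method)
  if (x$provenance != "raw") stop("downsampling expects a 'raw' dataset")
  libs <- split(seq_len(ncol(x$counts)), x$col_data$library)
  totals <- vapply(libs, function(j) sum(x$counts[, j]), numeric(1))
  if (any(totals == 0)) {
    stop("library with zero total counts: ", names(totals)[totals == 0][1])
  }
  target <- min(totals)
  local_seed(seed)
  counts <- x$counts
  for (nm in names(libs)) {
    if (totals[[nm]] == target) next
    j <- libs[[nm]]
    v <- as.vector(counts[, j])
    v2 <- if (method == "hypergeometric") {
      mvhyper_draw(v, target)
    } else {
      as.vector(stats::rmultinom(1L, target, v))
    }
    counts[, j] <- v2
  }
  out <- x
  out$counts <- counts
  out$provenance <- "downsampled"
  out$seeds <- c(x$seeds, list(downsample = seed))
  out
}

# Identify, for a two-source dataset with summed replicates, the column pair
# compared for each molecule. Returns list(mrna = c(i, j), fp = c(i, j)) with
# the first element of each pair being the reference (BY-side) source.
comparison_pairs <- function(x) {
  cd <- x$col_data
  src <- unique(cd$source)
  if (length(src) != 2L) {
    stop("comparison requires exactly two sources, found: ",
         paste(src, collapse = ", "))
  }
  if (any(table(cd$molecule, cd$source) != 1L)) {
    stop("one column per (molecule, source) required; sum replicates first")
  }
  get <- function(mol, s) which(cd$molecule == mol & cd$source == s)
  list(mrna = c(get("mrna", src[1]), get("mrna", src[2])),
       fp = c(get("fp", src[1]), get("fp", src[2])),
       sources = src)
}

#' Per-gene hypergeometric equalization of mRNA and footprint pairs
#'
#' For each gene, the compared samples are grouped into an mRNA pair and a
#' footprint pair (two strains, or the two alleles of the hybrid). The pair
#' with the smaller sum of counts remains as observed; the other pair is
#' replaced by a hypergeometric draw of that smaller sum from its pooled
#' counts. This equalizes statistical power between the mRNA and footprint
#' tests gene by gene.
#'
#' @param x a [count_dataset()] with provenance `"downsampled"` and one
#'   column per (molecule, source).
#' @param seed integer seed.
#' @return a [count_dataset()] with provenance `"hypergeometric"`; for every
#'   gene the mRNA pair sum equals the footprint pair sum.
#' @export
hypergeometric_equalize <- function(x, seed = NULL) {
  stopifnot(inherits(x, "count_dataset"))
  if (x$provenance != "downsampled") {
    stop("hypergeometric equalization expects a 'downsampled' dataset")
  }
  pr <- comparison_pairs(x)
  counts <- x$counts
  a1 <- counts[, pr$mrna[1]]; a2 <- counts[, pr$mrna[2]]
  b1 <- counts[, pr$fp[1]];   b2 <- counts[, pr$fp[2]]
  sm <- a1 + a2
  sf <- b1 + b2
  local_seed(seed)
  # resample the footprint pair where the mRNA pair is smaller, and vice versa
  i <- which(sf > sm)
  if (length(i)) {
    nb1 <- stats::rhyper(length(i), b1[i], b2[i], sm[i])
    counts[i, pr$fp[1]] <- nb1
    counts[i, pr$fp[2]] <- sm[i] - nb1
  }
  j <- which(sm > sf)
  if (length(j)) {
    na1 <- stats::rhyper(length(j), a1[j], a2[j], sf[j])
    counts[j, pr$mrna[1]] <- na1
    counts[j, pr$mrna[2]] <- sf[j] - na1
  }
  out <- x
  out$counts <- counts
  out$provenance <- "hypergeometric"
  out$seeds <- c(x$seeds, list(hypergeometric = seed))
  out
}

#' Remove genes with insufficient or zero counts
#'
#' A gene is excluded when, in the equalized (hypergeometric) dataset, either
#' compared pair has a sum of counts below `min_pair` (default 20, boundary
#' inclusive: a sum of exactly 20 is retained), or any individual sample has
#' a count of zero. The two rules are not redundant: one member of a pair can
#' exceed the threshold while the other is zero. Exclusions decided on the
#' equalized data are applied to the downsampled dataset as well; raw data
#' are never filtered.
#'
#' @param hyper the hypergeometric-equalized [count_dataset()].
#' @param down the matching downsampled [count_dataset()] (optional).
#' @param min_pair minimum pair sum (inclusive).
#' @return list with elements `hypergeometric`, `downsampled` (filtered
#'   datasets) and `report` (data.frame of excluded genes and the rule(s)
#'   that fired).
#' @export
filter_genes <- function(hyper, down = NULL, min_pair = 20) {
  stopifnot(inherits(hyper, "count_dataset"))
  if (hyper$provenance != "hypergeometric") {
    stop("filter is decided on the hypergeometric dataset")
  }
  pr <- comparison_pairs(hyper)
  cc <- hyper$counts[, c(pr$mrna, pr$fp), drop = FALSE]
  pair_lo <- pmin(hyper$counts[, pr$mrna[1]] + hyper$counts[, pr$mrna[2]],
                  hyper$counts[, pr$fp[1]] + hyper$counts[, pr$fp[2]])
  low <- pair_lo < min_pair
  zero <- apply(cc == 0, 1L, any)
  rule <- character(nrow(cc))
  rule[low] <- sprintf("pair<%d", min_pair)
  rule[zero & !low] <- "zero count"
  rule[zero & low] <- sprintf("pair<%d; zero count", min_pair)
  drop <- low | zero
  report <- data.frame(gene = rownames(cc)[drop], rule = rule[drop],
                       stringsAsFactors = FALSE)
  keep <- !drop
  out_down <- if (!is.null(down)) {
    stopifnot(inherits(down, "count_dataset"))
    if (!all(rownames(hyper$counts) %in% rownames(down$counts))) {
      stop("downsampled dataset does not contain the filtered genes")
    }
    subset_genes(down, rownames(hyper$counts)[keep])
  } else NULL
  list(hypergeometric = subset_genes(hyper, keep),
       downsampled = out_down,
       report = report)
}
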