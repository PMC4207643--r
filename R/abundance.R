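#' Per-library abundance fractions
#'
#' For every count column, the fraction of the column's library total
#' contributed by each gene, plus the log10 fraction where the count is
#' positive. Fractions within one library sum to 1 over the analyzed genes;
#' for hybrid data the two allele columns of a replicate share a library and
#' the denominator is their joint total.
#'
#' @param x a [count_dataset()].
#' @return list with matrices `fraction` and `log10_fraction` (NA where the
#'   count is zero), in the column layout of `x`.
#' @export
abundance_fractions <- function(x) {
  stopifnot(inherits(x, "count_dataset"))
  libs <- split(seq_len(ncol(x$counts)), x$col_data$library)
  frac <- x$counts
  for (j in libs) frac[, j] <- x$counts[, j, drop = FALSE] / sum(x$counts[, j])
  lf <- ifelse(frac > 0, log10(frac), NA_real_)
  list(fraction = frac, log10_fraction = lf)
}

#' Translational efficiency on log10 scale
#'
#' TE is the ratio of footprint abundance to mRNA abundance, so
#' `log10(TE) = log10(footprint fraction) - log10(mRNA fraction)` per gene
#' and source. Genes with a zero fraction in either molecule are flagged
#' undefined (NA).
#'
#' @param x a [count_dataset()] with one column per (molecule, source).
#' @return matrix of log10 TE values, one column per source.
#' @export
compute_te <- function(x) {
  stopifnot(inherits(x, "count_dataset"))
  ab <- abundance_fractions(x)$log10_fraction
  cd <- x$col_data
  src <- unique(cd$source)
  out <- sapply(src, function(s) {
    i_fp <- which(cd$molecule == "fp" & cd$source == s)
    i_m <- which(cd$molecule == "mrna" & cd$source == s)
    if (length(i_fp) != 1L || length(i_m) != 1L) {
      stop("need one mRNA and one footprint column per source (sum replicates first)")
    }
    ab[, i_fp] - ab[, i_m]
  })
  rownames(out) <- rownames(x$counts)
  out
}

#' Log2 fold change between two compared counts
#'
#' Sign convention: positive means higher in the first (BY-side) sample.
#' A zero in either count yields a non-finite value flagged `FALSE` in
#' `finite`; such genes are excluded from tests requiring finite values.
#' A gene with both counts zero is an error at the single-pair level and NA
#' in the vectorized form.
#'
#' @param a,b non-negative counts (vectors), `a` = BY or BY allele.
#' @return data.frame with columns `log2fc` and `finite`.
#' @export
compute_log2fc <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  if (length(a) == 1L && a == 0 && b == 0) stop("both counts zero")
  fc <- log2(a / b)
  data.frame(log2fc = fc, finite = is.finite(fc))
}

# Fold-change table (mRNA, footprint, TE) for a filtered two-source dataset.
# TE fold change is the footprint minus the mRNA log2 fold change.
fold_change_table <- function(x) {
  pr <- comparison_pairs(x)
  m <- compute_log2fc(x$counts[, pr$mrna[1]], x$counts[, pr$mrna[2]])
  f <- compute_log2fc(x$counts[, pr$fp[1]], x$counts[, pr$fp[2]])
  data.frame(
    gene = rownames(x$counts),
    mrna_fc = m$log2fc, fp_fc = f$log2fc,
    te_fc = f$log2fc - m$log2fc,
    finite = m$finite & f$finite,
    stringsAsFactors = FALSE
  )
}
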