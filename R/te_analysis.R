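#' Differential mRNA, footprint and TE analysis of a two-source dataset
#'
#' The central fitting function. Starting from raw counts for two compared
#' sources (the BY and RM parents, or the two alleles of their hybrid), it
#' runs the full power-equalizing testing chain:
#'
#' 1. replicates are summed per (molecule, source);
#' 2. libraries are downsampled without replacement to the smallest library
#'    total ([downsample_libraries()]);
#' 3. per gene, mRNA and footprint pairs are equalized to the smaller pair
#'    sum by hypergeometric resampling ([hypergeometric_equalize()]);
#' 4. genes with any pair sum below 20 or any zero count are removed from
#'    the equalized and downsampled datasets ([filter_genes()]);
#' 5. differential mRNA and footprint expression are tested by exact
#'    two-sided binomial tests on the equalized counts; differential TE by a
#'    G-test on the downsampled 2x2 (molecule x source) table, where the TE
#'    signal survives because mRNA and footprints are not forced to the same
#'    level;
#' 6. p-values are corrected by Bonferroni (default), Storey q-values or
#'    Benjamini-Hochberg, and log2 fold changes (positive = higher in the
#'    first source, BY side) are computed from the downsampled counts;
#' 7. TE-significant genes are classified into directional categories and
#'    the four directional ratio tests are run.
#'
#' @param data a raw [count_dataset()] with exactly two sources.
#' @param correction multiple-testing correction: `"bonferroni"` (default),
#'   `"qvalue"` or `"BH"`.
#' @param alpha significance level applied to the corrected values.
#' @param seed integer seed; the downsampling and equalization seeds are
#'   derived from it (`seed` and `seed + 1`).
#' @param min_pair gene filter threshold (inclusive pair-sum minimum).
#' @param downsample_method passed to [downsample_libraries()].
#' @return object of class `te_analysis`: a list with `results` (per-gene
#'   data.frame), `categories`, `directional`, `datasets` (raw, downsampled,
#'   hypergeometric), `filter_report`, `sources`, `correction`, `alpha`,
#'   `seeds`, `n` (per-stage gene counts) and `call`.
#' @seealso [run_parent_analysis()], [run_hybrid_analysis()] for the
#'   orchestrated pipeline; [ma_slope()] for the cis/trans decomposition.
#' @export
te_analysis <- function(data, correction = c("bonferroni", "qvalue", "BH"),
                        alpha = 0.05, seed = NULL, min_pair = 20,
                        downsample_method = "hypergeometric") {
  stopifnot(inherits(data, "count_dataset"))
  correction <- match.arg(correction)
  seeds <- if (is.null(seed)) list(downsample = NULL, equalize = NULL)
           else list(downsample = as.integer(seed),
                     equalize = as.integer(seed) + 1L)
  summed <- sum_replicates(data)
  down <- downsample_libraries(summed, seed = seeds$downsample,
                               method = downsample_method)
  hyper <- hypergeometric_equalize(down, seed = seeds$equalize)
  flt <- filter_genes(hyper, down, min_pair = min_pair)
  hyper <- flt$hypergeometric
  down <- flt$downsampled
  pr <- comparison_pairs(hyper)

  fc <- fold_change_table(down)
  mrna_p <- binom_two_sided(hyper$counts[, pr$mrna[1]],
                            hyper$counts[, pr$mrna[1]] +
                              hyper$counts[, pr$mrna[2]])
  fp_p <- binom_two_sided(hyper$counts[, pr$fp[1]],
                          hyper$counts[, pr$fp[1]] + hyper$counts[, pr$fp[2]])
  gt <- g_test_cells(down$counts[, pr$mrna[1]], down$counts[, pr$mrna[2]],
                     down$counts[, pr$fp[1]], down$counts[, pr$fp[2]])
  adjust <- switch(correction,
                   bonferroni = function(p) bonferroni(p, alpha)$adjusted,
                   qvalue = storey_qvalues,
                   BH = function(p) stats::p.adjust(p, "BH"))
  results <- data.frame(
    gene = rownames(hyper$counts),
    mrna_fc = fc$mrna_fc, fp_fc = fc$fp_fc, te_fc = fc$te_fc,
    mrna_p = mrna_p, fp_p = fp_p,
    te_stat = gt$statistic, te_p = gt$p.value,
    stringsAsFactors = FALSE
  )
  results$mrna_padj <- adjust(results$mrna_p)
  results$fp_padj <- adjust(results$fp_p)
  results$te_padj <- adjust(results$te_p)
  results$sig_mrna <- results$mrna_padj < alpha
  results$sig_fp <- results$fp_padj < alpha
  results$sig_te <- results$te_padj < alpha
  results$category <- suppressMessages(classify_te_genes(results))

  categories <- tabulate_categories(results$category)
  directional <- directional_tests(categories)
  out <- list(
    results = results,
    categories = categories,
    directional = directional,
    datasets = list(raw = data, downsampled = down, hypergeometric = hyper),
    filter_report = flt$report,
    sources = pr$sources,
    correction = correction, alpha = alpha, seeds = seeds,
    n = c(loaded = nrow(data$counts), analyzed = nrow(results),
          excluded = nrow(flt$report)),
    call = match.call()
  )
  class(out) <- "te_analysis"
  out
}

#' @export
print.te_analysis <- function(x, ...) {
  cat("Differential translation analysis (", x$sources[1], " vs ",
      x$sources[2], ")\n", sep = "")
  cat(sprintf("  genes: %d loaded, %d analyzed, %d excluded by count filter\n",
              x$n[["loaded"]], x$n[["analyzed"]], x$n[["excluded"]]))
  cat(sprintf("  correction: %s at alpha = %g\n", x$correction, x$alpha))
  cat(sprintf("  significant: %d mRNA, %d footprint, %d TE\n",
              sum(x$results$sig_mrna), sum(x$results$sig_fp),
              sum(x$results$sig_te)))
  invisible(x)
}

#' @export
summary.te_analysis <- function(object, ...) {
  r <- object$results
  out <- list(
    sources = object$sources,
    n = object$n,
    correction = object$correction,
    alpha = object$alpha,
    significant = c(mrna = sum(r$sig_mrna), fp = sum(r$sig_fp),
                    te = sum(r$sig_te)),
    twofold = c(mrna = sum(r$sig_mrna & abs(r$mrna_fc) >= 1),
                fp = sum(r$sig_fp & abs(r$fp_fc) >= 1),
                te = sum(r$sig_te & abs(r$te_fc) >= 1)),
    direction_agreement = {
      any_sig <- r$sig_mrna | r$sig_fp
      c(agree = sum(any_sig & r$mrna_fc * r$fp_fc > 0), of = sum(any_sig))
    },
    categories = object$categories,
    directional = object$directional
  )
  class(out) <- "summary.te_analysis"
  out
}

#' @export
print.summary.te_analysis <- function(x, ...) {
  cat("Comparison:", x$sources[1], "vs", x$sources[2], "\n")
  cat(sprintf("Analyzed genes: %d (of %d; %d excluded)\n",
              x$n[["analyzed"]], x$n[["loaded"]], x$n[["excluded"]]))
  cat(sprintf("Correction: %s, alpha = %g\n", x$correction, x$alpha))
  tab <- rbind(significant = x$significant, `and >= 2-fold` = x$twofold)
  colnames(tab) <- c("mRNA", "footprint", "TE")
  print(tab)
  cat(sprintf("Direction agreement among significant genes: %d / %d (%.0f%%)\n",
              x$direction_agreement[["agree"]], x$direction_agreement[["of"]],
              100 * x$direction_agreement[["agree"]] /
                max(x$direction_agreement[["of"]], 1L)))
  cat("\nTE-gene categories:\n")
  print(x$categories, row.names = FALSE)
  cat("\nDirectional tests:\n")
  print(x$directional, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.te_analysis <- function(object, ...) {
  m <- as.matrix(object$results[, c("mrna_fc", "fp_fc", "te_fc")])
  rownames(m) <- object$results$gene
  colnames(m) <- c("mRNA", "footprint", "TE")
  m
}

#' Scatter of mRNA vs footprint log2 fold changes
#'
#' Genes on the diagonal have equal mRNA and footprint differences;
#' TE-significant genes are coloured by their directional category.
#'
#' @param x a `te_analysis` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.te_analysis <- function(x, ...) {
  r <- x$results
  pal <- c(fp_only = "#377eb8", reinforced = "#4daf4a", buffered = "#ff7f00",
           completely_buffered = "#e41a1c", inverted = "#984ea3",
           neither = "#999999", not_te = "#dddddd")
  col <- pal[r$category]
  graphics::plot(r$mrna_fc, r$fp_fc, col = col, pch = 16, cex = 0.5,
                 xlab = "mRNA log2 fold change",
                 ylab = "footprint log2 fold change", ...)
  graphics::abline(0, 1, col = "grey", lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::legend("topleft", legend = names(pal), col = pal, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(x)
}
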