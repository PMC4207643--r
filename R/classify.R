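# Classification of TE-significant genes by the relationship between their
# mRNA and footprint differences, and directional ratio tests over the
# resulting categories.

TE_CATEGORIES <- c("fp_only", "reinforced", "buffered", "completely_buffered",
                   "inverted", "neither")

#' Classify TE-significant genes by mRNA/footprint relationship
#'
#' For each gene with a significant TE difference, the mRNA and footprint
#' significance calls and fold-change signs determine one of six mutually
#' exclusive categories:
#' * `fp_only` — significant footprint difference without a significant
#'   mRNA difference;
#' * `reinforced` — both significant, same direction, footprint difference
#'   larger in magnitude;
#' * `buffered` — both significant, same direction, mRNA difference larger
#'   (partial buffering);
#' * `completely_buffered` — significant mRNA difference without a
#'   significant footprint difference;
#' * `inverted` — both significant, opposite directions;
#' * `neither` — neither mRNA nor footprint difference significant.
#'
#' Genes without a significant TE difference are labelled `not_te`. An exact
#' magnitude tie between significant same-direction differences is assigned
#' `buffered` (deterministic; logged via a message when it fires). A zero
#' fold change with a significant flag is treated as agreeing in sign with
#' anything (logged likewise).
#'
#' @param results data.frame with columns `mrna_fc`, `fp_fc`, `sig_mrna`,
#'   `sig_fp`, `sig_te` (see [te_analysis()] or [harmonize_external()]).
#' @return character vector of categories, one per row of `results`.
#' @export
classify_te_genes <- function(results) {
  need <- c("mrna_fc", "fp_fc", "sig_mrna", "sig_fp", "sig_te")
  if (!all(need %in% names(results))) {
    stop("missing columns: ", paste(setdiff(need, names(results)), collapse = ", "))
  }
  if (any(is.na(results$sig_mrna) | is.na(results$sig_fp) |
            is.na(results$sig_te))) {
    stop("missing significance flags")
  }
  m <- results$sig_mrna; f <- results$sig_fp
  # zero fold changes sign-agree with anything
  zero_fc <- (results$mrna_fc == 0 & m) | (results$fp_fc == 0 & f)
  if (any(zero_fc, na.rm = TRUE)) {
    message(sum(zero_fc, na.rm = TRUE),
            " significant gene(s) with zero fold change; treated as sign-agreeing")
  }
  same_dir <- results$mrna_fc * results$fp_fc >= 0
  tie <- m & f & same_dir & abs(results$fp_fc) == abs(results$mrna_fc)
  if (any(tie, na.rm = TRUE)) {
    message(sum(tie, na.rm = TRUE),
            " |FP| = |mRNA| tie(s); assigned 'buffered'")
  }
  cat_ <- ifelse(!m & !f, "neither",
          ifelse(f & !m, "fp_only",
          ifelse(m & !f, "completely_buffered",
          ifelse(!same_dir, "inverted",
          ifelse(abs(results$fp_fc) > abs(results$mrna_fc),
                 "reinforced", "buffered")))))
  ifelse(results$sig_te, cat_, "not_te")
}

#' Tabulate TE categories
#'
#' @param categories character vector from [classify_te_genes()].
#' @return data.frame with `category`, `count`, `fraction` over the six
#'   categories; the counts sum to the number of TE-significant genes
#'   (attribute `total`).
#' @export
tabulate_categories <- function(categories) {
  te <- categories[categories != "not_te"]
  bad <- setdiff(unique(te), TE_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  counts <- table(factor(te, levels = TE_CATEGORIES))
  total <- sum(counts)
  out <- data.frame(category = TE_CATEGORIES,
                    count = as.integer(counts),
                    fraction = if (total > 0) as.numeric(counts) / total
                               else rep(NA_real_, length(TE_CATEGORIES)),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Directional ratio tests over TE categories
#'
#' Tests whether translation more often increases than decreases gene
#' expression differences, over the four comparisons that arise by including
#' or excluding the `fp_only` genes from the numerator and the `inverted`
#' genes from the denominator:
#' * `R_vs_B` — reinforced vs (buffered + completely buffered);
#' * `R_vs_BI` — reinforced vs (buffered + completely buffered + inverted);
#' * `RF_vs_B` — (reinforced + fp_only) vs (buffered + completely buffered);
#' * `RF_vs_BI` — (reinforced + fp_only) vs (buffered + completely buffered
#'   + inverted).
#'
#' Each ratio is tested against an equal-frequency null with the chi-squared
#' goodness-of-fit test of [chi2_equal_frequency()].
#'
#' @param categories a category table from [tabulate_categories()], or a
#'   character vector of per-gene categories.
#' @return data.frame with `comparison`, `numerator`, `denominator`,
#'   `ratio`, `statistic`, `p.value`. A zero denominator yields `NA` ratio
#'   and p.
#' @export
directional_tests <- function(categories) {
  if (is.character(categories)) categories <- tabulate_categories(categories)
  stopifnot(is.data.frame(categories),
            all(c("category", "count") %in% names(categories)))
  n <- stats::setNames(categories$count, categories$category)
  buff <- n[["buffered"]] + n[["completely_buffered"]]
  comps <- list(
    R_vs_B = c(n[["reinforced"]], buff),
    R_vs_BI = c(n[["reinforced"]], buff + n[["inverted"]]),
    RF_vs_B = c(n[["reinforced"]] + n[["fp_only"]], buff),
    RF_vs_BI = c(n[["reinforced"]] + n[["fp_only"]], buff + n[["inverted"]])
  )
  out <- data.frame(
    comparison = names(comps),
    numerator = vapply(comps, `[`, 0, 1L),
    denominator = vapply(comps, `[`, 0, 2L),
    stringsAsFactors = FALSE
  )
  out$ratio <- ifelse(out$denominator > 0,
                      out$numerator / out$denominator, NA_real_)
  ok <- out$numerator + out$denominator > 0
  out$statistic <- out$p.value <- NA_real_
  if (any(ok)) {
    tst <- chi2_equal_frequency(out$numerator[ok], out$denominator[ok])
    out$statistic[ok] <- tst$statistic
    out$p.value[ok] <- tst$p.value
  }
  rownames(out) <- NULL
  out
}

#' Harmonize an external fold-change/p-value table for classification
#'
#' Adapts a published differential-translation table (fold changes and
#' p-values for mRNA, footprint and TE) to the unified result layout
#' consumed by [classify_te_genes()], applying one of three significance
#' rules consistently to all three tests: `bonferroni` (raw p against
#' alpha/m), `qvalue` (Storey q < alpha) or `precorrected` (the table's
#' p-values are already multiplicity-adjusted; compare directly to alpha).
#'
#' @param table data.frame of the external dataset.
#' @param mapping named list mapping the required fields `gene`, `mrna_fc`,
#'   `mrna_p`, `fp_fc`, `fp_p`, `te_p` (and optionally `te_fc`) to column
#'   names of `table`.
#' @param rule significance rule (see above).
#' @param alpha significance level.
#' @return data.frame with columns `gene`, `mrna_fc`, `fp_fc`, `te_fc`,
#'   `mrna_p`, `fp_p`, `te_p`, `sig_mrna`, `sig_fp`, `sig_te`, `category`.
#' @export
harmonize_external <- function(table, mapping,
                               rule = c("bonferroni", "qvalue", "precorrected"),
                               alpha = 0.05) {
  rule <- match.arg(rule)
  need <- c("gene", "mrna_fc", "mrna_p", "fp_fc", "fp_p", "te_p")
  missing_map <- setdiff(need, names(mapping))
  if (length(missing_map)) {
    stop("mapping lacks required field(s): ", paste(missing_map, collapse = ", "))
  }
  for (fld in c(need, intersect("te_fc", names(mapping)))) {
    if (!mapping[[fld]] %in% names(table)) {
      stop("column not found in table: ", mapping[[fld]], " (for ", fld, ")")
    }
  }
  out <- data.frame(
    gene = table[[mapping$gene]],
    mrna_fc = table[[mapping$mrna_fc]],
    fp_fc = table[[mapping$fp_fc]],
    mrna_p = table[[mapping$mrna_p]],
    fp_p = table[[mapping$fp_p]],
    te_p = table[[mapping$te_p]],
    stringsAsFactors = FALSE
  )
  out$te_fc <- if ("te_fc" %in% names(mapping)) {
    table[[mapping$te_fc]]
  } else {
    out$fp_fc - out$mrna_fc
  }
  flag <- switch(rule,
    precorrected = function(p) p < alpha,
    bonferroni = function(p) p < alpha / sum(!is.na(p)),
    qvalue = function(p) storey_qvalues(p) < alpha
  )
  out$sig_mrna <- flag(out$mrna_p)
  out$sig_fp <- flag(out$fp_p)
  out$sig_te <- flag(out$te_p)
  out$category <- classify_te_genes(out)
  out
}
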