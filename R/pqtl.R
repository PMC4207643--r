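# Comparison of mRNA and footprint differences to protein-QTL effects.
# pQTL effect sizes are signed allele-frequency differences from a
# bulk-segregant experiment; summing them per gene gives a rough expectation
# of the aggregate trans-acting effect on that protein.

#' Sum pQTL effects per gene
#'
#' Effects are signed allele-frequency differences in \[-1, 1\]; the per-gene
#' aggregate is their arithmetic sum, so opposite-sign effects of equal
#' magnitude cancel.
#'
#' @param effects data.frame with columns `gene` and `effect`, one row per
#'   pQTL.
#' @return named numeric vector of summed effects per gene.
#' @export
sum_pqtl_effects <- function(effects) {
  stopifnot(is.data.frame(effects),
            all(c("gene", "effect") %in% names(effects)))
  if (nrow(effects) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(abs(effects$effect) > 1)) {
    stop("allele-frequency difference outside [-1, 1]")
  }
  s <- tapply(effects$effect, effects$gene, sum)
  stats::setNames(as.numeric(s), names(s))
}

#' Read a tab-delimited pQTL effect table
#'
#' Dialect: `gene<TAB>effects` where `effects` is a comma-separated list of
#' signed allele-frequency differences, one per pQTL.
#'
#' @param path file path.
#' @return long-format data.frame with columns `gene` and `effect`.
#' @export
read_pqtl_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "effects") %in% names(tab))) {
    stop("pQTL table needs columns 'gene' and 'effects'")
  }
  eff <- strsplit(tab$effects, ",", fixed = TRUE)
  data.frame(gene = rep(tab$gene, lengths(eff)),
             effect = as.numeric(unlist(eff)),
             stringsAsFactors = FALSE)
}

#' Spearman correlation of summed pQTL effects with expression differences
#'
#' Rank correlation (average-rank tie handling, t-distribution p
#' approximation) between the per-gene summed pQTL effects and the mRNA and
#' footprint log2 fold changes, over the genes present in both inputs.
#'
#' @param effects named numeric vector from [sum_pqtl_effects()].
#' @param mrna_fc,fp_fc named numeric vectors of log2 fold changes.
#' @param min_overlap minimum number of shared genes.
#' @return data.frame with one row per molecule: `molecule`, `rho`,
#'   `p.value`, `n`.
#' @export
correlate_with_expression <- function(effects, mrna_fc, fp_fc,
                                      min_overlap = 10) {
  stopifnot(!is.null(names(effects)), !is.null(names(mrna_fc)),
            !is.null(names(fp_fc)))
  g <- Reduce(intersect, list(names(effects), names(mrna_fc), names(fp_fc)))
  if (length(g) == 0L) stop("no gene overlap")
  if (length(g) < min_overlap) {
    stop("fewer than ", min_overlap, " overlapping genes")
  }
  one <- function(molecule, fc) {
    ct <- stats::cor.test(effects[g], fc[g], method = "spearman",
                          exact = FALSE)
    data.frame(molecule = molecule, rho = unname(ct$estimate),
               p.value = ct$p.value, n = length(g),
               stringsAsFactors = FALSE)
  }
  rbind(one("mrna", mrna_fc), one("fp", fp_fc))
}

#' Bootstrap contrast of the mRNA and footprint pQTL correlations
#'
#' Resamples genes with replacement `B` times; in each replicate both
#' Spearman correlations (effects vs mRNA fold change, effects vs footprint
#' fold change) are recomputed. The contrast p-value is the fraction of
#' replicates in which the mRNA correlation strictly exceeds the footprint
#' correlation (ties count against the mRNA correlation).
#'
#' @inheritParams correlate_with_expression
#' @param B number of bootstrap replicates (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed integer seed.
#' @return list with `p` (fraction of replicates with rho_mRNA >
#'   rho_footprint), `boot_mrna`, `boot_fp`, `n`, `B`.
#' @export
bootstrap_correlation_contrast <- function(effects, mrna_fc, fp_fc, B = 1000,
                                           seed = NULL, min_overlap = 10) {
  if (B < 100) warning("fewer than 100 bootstrap replicates")
  g <- Reduce(intersect, list(names(effects), names(mrna_fc), names(fp_fc)))
  if (length(g) < min_overlap) {
    stop("fewer than ", min_overlap, " overlapping genes")
  }
  e <- effects[g]; m <- mrna_fc[g]; f <- fp_fc[g]
  n <- length(g)
  local_seed(seed)
  boot_m <- boot_f <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    boot_m[b] <- stats::cor(e[i], m[i], method = "spearman")
    boot_f[b] <- stats::cor(e[i], f[i], method = "spearman")
  }
  list(p = mean(boot_m > boot_f), boot_mrna = boot_m, boot_fp = boot_f,
       n = n, B = B)
}
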