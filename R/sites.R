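#' Flag SNP sites unsuitable for allele-specific quantification
#'
#' Applies the coverage and allele-frequency filters for unbiased ASE
#' quantification to a hybrid-DNA site table: sites with very high or very
#' low coverage are removed, as are sites where the BY-allele frequency is
#' outside the accepted band. Bounds are exclusive as printed: depth exactly
#' `cov_min` or `cov_max`, and frequency exactly `freq_min` or `freq_max`,
#' are retained. Sites inside known duplication regions are additionally
#' flagged. The filters commute: flags are computed independently, and
#' `retained` is true iff no exclusion flag is set.
#'
#' @param sites data.frame with `by_count`, `rm_count` and `depth` columns
#'   (as produced by [generate_unbiased_hybrid_dna()]).
#' @param cov_min,cov_max coverage bounds (depth < cov_min or > cov_max
#'   excluded).
#' @param freq_min,freq_max BY-allele frequency bounds (frequency < freq_min
#'   or > freq_max excluded).
#' @param duplication_regions optional data.frame (`chrom`, `start`, `end`,
#'   1-based inclusive), e.g. from [detect_duplication_regions()].
#' @return the site table with logical columns `coverage_low`,
#'   `coverage_high`, `freq_out_of_range`, `duplication_region`, `retained`.
#' @export
apply_site_filters <- function(sites, cov_min = 30, cov_max = 100,
                               freq_min = 0.3, freq_max = 0.7,
                               duplication_regions = NULL) {
  stopifnot(is.data.frame(sites))
  need <- c("by_count", "rm_count", "depth")
  if (!all(need %in% names(sites))) {
    stop("site table needs columns: ", paste(need, collapse = ", "))
  }
  freq <- sites$by_count / (sites$by_count + sites$rm_count)
  sites$coverage_low <- sites$depth < cov_min
  sites$coverage_high <- sites$depth > cov_max
  sites$freq_out_of_range <- freq < freq_min | freq > freq_max
  in_dup <- rep(FALSE, nrow(sites))
  if (!is.null(duplication_regions) && nrow(duplication_regions)) {
    for (i in seq_len(nrow(duplication_regions))) {
      r <- duplication_regions[i, ]
      in_dup <- in_dup | (sites$chrom == r$chrom &
                            sites$pos >= r$start & sites$pos <= r$end)
    }
  }
  sites$duplication_region <- in_dup
  sites$retained <- !(sites$coverage_low | sites$coverage_high |
                        sites$freq_out_of_range | sites$duplication_region)
  sites
}

#' Compare an observed site table against its unbiased simulation
#'
#' Stratifies sites by depth and compares the distribution of BY-allele
#' frequencies in the observed table to a simulated unbiased table generated
#' at the same depths (Binomial(depth, 0.5) null). Reports per-stratum
#' frequency quantiles for both tables and, over a grid of frequency
#' cutoffs, the excess tail mass in the observed data — the cutoffs where
#' observed exceeds simulated localize the biased population.
#'
#' @param observed,simulated site tables with `by_count`, `rm_count`,
#'   `depth`; the simulated table must have been generated at the observed
#'   depths.
#' @param depth_breaks stratum boundaries for depth.
#' @param cutoffs frequency cutoffs for the tail comparison.
#' @return list with `quantiles` (per-stratum data.frame) and `excess`
#'   (data.frame of cutoff, observed and simulated lower-tail fractions, and
#'   their difference).
#' @export
calibrate_against_null <- function(observed, simulated,
                                   depth_breaks = c(0, 30, 50, 70, 100, Inf),
                                   cutoffs = seq(0.05, 0.45, by = 0.05)) {
  stopifnot(is.data.frame(observed), is.data.frame(simulated))
  if (nrow(observed) == 0L) stop("empty observed table")
  if (nrow(observed) != nrow(simulated) ||
        !identical(sort(observed$depth), sort(simulated$depth))) {
    stop("depth mismatch between observed and simulated tables")
  }
  fr_o <- observed$by_count / (observed$by_count + observed$rm_count)
  fr_s <- simulated$by_count / (simulated$by_count + simulated$rm_count)
  probs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  stratum_o <- cut(observed$depth, depth_breaks, include.lowest = TRUE)
  stratum_s <- cut(simulated$depth, depth_breaks, include.lowest = TRUE)
  qs <- do.call(rbind, lapply(levels(stratum_o), function(lv) {
    io <- stratum_o == lv; is <- stratum_s == lv
    if (!any(io)) return(NULL)
    data.frame(stratum = lv, prob = probs,
               observed = unname(stats::quantile(fr_o[io], probs)),
               simulated = unname(stats::quantile(fr_s[is], probs)))
  }))
  excess <- data.frame(
    cutoff = cutoffs,
    observed_tail = vapply(cutoffs, function(f) mean(fr_o < f), numeric(1)),
    simulated_tail = vapply(cutoffs, function(f) mean(fr_s < f), numeric(1))
  )
  excess$excess <- excess$observed_tail - excess$simulated_tail
  list(quantiles = qs, excess = excess)
}

#' Detect candidate segmental-duplication regions from parental coverage
#'
#' Scans sites (sorted by chromosome and position) for maximal runs of at
#' least `window` sites whose RM/BY parental DNA coverage ratio is at or
#' above `ratio_threshold`; each run becomes one region spanning its first
#' to last qualifying site. To be robust to sampling noise in per-site
#' coverage, runs interrupted by at most `gap` consecutive sub-threshold
#' sites are merged (the interrupting sites are absorbed into the region).
#' Such regions indicate a segmental duplication present in RM but not BY,
#' which biases hybrid allelic ratios towards RM (~2:1).
#'
#' @param sites data.frame with `chrom`, `pos`, `by_parent_cov`,
#'   `rm_parent_cov`, sorted by chromosome then position.
#' @param window minimum number of qualifying sites per region.
#' @param ratio_threshold minimum RM/BY coverage ratio.
#' @param gap maximum number of consecutive sub-threshold sites absorbed
#'   into a run.
#' @return data.frame of regions: `chrom`, `start`, `end` (1-based positions
#'   of the first/last qualifying site), `mean_ratio`, `n_sites` (sites
#'   spanned).
#' @export
detect_duplication_regions <- function(sites, window = 10,
                                       ratio_threshold = 1.7, gap = 2) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "by_parent_cov", "rm_parent_cov")
  if (!all(need %in% names(sites))) {
    stop("site table needs columns: ", paste(need, collapse = ", "))
  }
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    stop("sites must be sorted by chromosome and position")
  }
  ratio <- sites$rm_parent_cov / pmax(sites$by_parent_cov, 1)
  hit <- ratio >= ratio_threshold
  out <- list()
  for (chr in unique(sites$chrom)) {
    i <- which(sites$chrom == chr)
    q <- which(hit[i])
    if (!length(q)) next
    # split qualifying sites into clusters separated by more than `gap`
    # non-qualifying sites
    cluster <- cumsum(c(1L, diff(q) > gap + 1L))
    for (cl in split(q, cluster)) {
      if (length(cl) < window) next
      idx <- i[cl[1]:cl[length(cl)]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = sites$pos[idx[1]],
        end = sites$pos[idx[length(idx)]],
        mean_ratio = mean(ratio[idx]), n_sites = length(idx),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_ratio = numeric(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write retained sites as a BED whitelist
#'
#' Converts the 1-based inclusive site positions to BED's 0-based half-open
#' intervals.
#'
#' @param sites a flagged site table from [apply_site_filters()].
#' @param path output path.
#' @export
write_site_whitelist_bed <- function(sites, path) {
  stopifnot(is.data.frame(sites), "retained" %in% names(sites))
  keep <- sites[sites$retained, ]
  bed <- data.frame(chrom = keep$chrom, start = keep$pos - 1L, end = keep$pos)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
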