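#' Configuration for the synthetic expression-data generator
#'
#' Defines the generative conditions for parent and hybrid allele-specific
#' mRNA/footprint count datasets with known cis, trans and translation (TE)
#' effects. Defaults emulate processed yeast counts: a few thousand genes,
#' mRNA abundance whose central 95% spans about 3.5 orders of magnitude
#' (log10 SD 0.9), roughly 100-fold TE variation (log10 SD 0.5), footprint
#' libraries ~50% deeper than mRNA libraries, and mild gamma-Poisson
#' overdispersion.
#'
#' @param n_genes number of genes.
#' @param baseline_log10_mean,baseline_log10_sd mean and SD of baseline log10
#'   mRNA abundance (the mean is arbitrary: abundances are normalized to
#'   library size).
#' @param te_log10_sd SD of baseline log10 TE across genes.
#' @param library_sizes named numeric vector of total counts per library;
#'   names `mrna_BY`, `mrna_RM`, `fp_BY`, `fp_RM` for the parents and
#'   `mrna_hyb1`, `mrna_hyb2`, `fp_hyb1`, `fp_hyb2` for the two hybrid
#'   replicates (a hybrid library spans both alleles).
#' @param frac_cis,frac_trans,frac_te fractions of genes carrying a cis,
#'   trans, or translation-specific effect.
#' @param effect_size_log2_sd SD of effect sizes (log2 scale).
#' @param dispersion gamma-Poisson overdispersion; 0 gives Poisson counts.
#' @param overlapping_effects if `FALSE` (default) the three effect classes
#'   are disjoint gene sets and the fractions must sum to at most 1; if
#'   `TRUE` each class is assigned independently.
#' @param te_reinforce_prob probability that a TE effect's sign is set to
#'   match the sign of the gene's total mRNA effect (cis + trans), when that
#'   effect is nonzero; the complement gets the opposing sign. 0.5 (default)
#'   leaves TE directions independent of mRNA differences; values above 0.5
#'   make translation preferentially reinforce mRNA differences.
#' @param seed integer seed controlling all randomness of the generator.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4000,
                       baseline_log10_mean = 0,
                       baseline_log10_sd = 0.9,
                       te_log10_sd = 0.5,
                       library_sizes = NULL,
                       frac_cis = 0, frac_trans = 0, frac_te = 0,
                       effect_size_log2_sd = 0.5,
                       dispersion = 0.05,
                       overlapping_effects = FALSE,
                       te_reinforce_prob = 0.5,
                       seed = 1L) {
  if (is.null(library_sizes)) {
    library_sizes <- c(mrna_BY = 5e6, mrna_RM = 5e6,
                       fp_BY = 7.5e6, fp_RM = 7.5e6,
                       mrna_hyb1 = 2.5e6, mrna_hyb2 = 2.5e6,
                       fp_hyb1 = 3.75e6, fp_hyb2 = 3.75e6)
  }
  cfg <- list(n_genes = n_genes, baseline_log10_mean = baseline_log10_mean,
              baseline_log10_sd = baseline_log10_sd, te_log10_sd = te_log10_sd,
              library_sizes = library_sizes, frac_cis = frac_cis,
              frac_trans = frac_trans, frac_te = frac_te,
              effect_size_log2_sd = effect_size_log2_sd,
              dispersion = dispersion,
              overlapping_effects = overlapping_effects,
              te_reinforce_prob = te_reinforce_prob, seed = seed)
  num <- unlist(cfg[c("n_genes", "baseline_log10_mean", "baseline_log10_sd",
                      "te_log10_sd", "frac_cis", "frac_trans", "frac_te",
                      "effect_size_log2_sd", "dispersion",
                      "te_reinforce_prob", "seed")])
  if (any(!is.finite(num))) stop("non-finite configuration value")
  if (n_genes < 1) stop("zero genes")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop("all library sizes must be positive")
  }
  need <- c("mrna_BY", "mrna_RM", "fp_BY", "fp_RM",
            "mrna_hyb1", "mrna_hyb2", "fp_hyb1", "fp_hyb2")
  if (!all(need %in% names(library_sizes))) {
    stop("library_sizes must name: ", paste(need, collapse = ", "))
  }
  fr <- c(frac_cis, frac_trans, frac_te)
  if (any(fr < 0 | fr > 1)) stop("effect fractions must be in [0, 1]")
  if (!overlapping_effects && sum(fr) > 1 + 1e-12) {
    stop("effect fractions sum to > 1; set overlapping_effects = TRUE")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (te_reinforce_prob < 0 || te_reinforce_prob > 1) {
    stop("te_reinforce_prob must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# counts for one library: expected fractions scaled to library size, with
# gamma-Poisson noise (dispersion phi: variance mu + phi * mu^2)
.sim_library <- function(rates, size, dispersion) {
  mu <- rates / sum(rates) * size
  if (dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
}

#' Generate a parent + hybrid expression dataset with known truth
#'
#' Per gene, the expected mRNA rate of a source is
#' `baseline * 2^(cis + trans)` (BY side; RM carries the baseline), and the
#' expected footprint rate is the mRNA rate times the gene's TE times
#' `2^te_effect`. Cis and TE effects apply to the BY parent and to the
#' matching BY allele of the hybrid; trans effects apply only in the
#' parents, since trans-acting variants influence both alleles of the
#' hybrid equally. Hybrid replicates are independent draws from the same
#' rates. Counts are gamma-Poisson with the configured dispersion, scaled so
#' column totals match the configured library sizes in expectation.
#'
#' @param config a [sim_config()].
#' @return list with elements `parents` and `hybrid` (raw [count_dataset()]s)
#'   and `truth` (data.frame of per-gene true effects on log2 scale, baseline
#'   log10 abundance and log10 TE, with the generating seed as an attribute).
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  local_seed(config$seed)
  ids <- sprintf("gene%05d", seq_len(g))
  b <- stats::rnorm(g, config$baseline_log10_mean, config$baseline_log10_sd)
  te0 <- stats::rnorm(g, 0, config$te_log10_sd)

  cis <- trans <- te <- numeric(g)
  draw <- function(idx) {
    v <- numeric(g)
    v[idx] <- stats::rnorm(length(idx), 0, config$effect_size_log2_sd)
    v
  }
  if (config$overlapping_effects) {
    cis <- draw(which(stats::runif(g) < config$frac_cis))
    trans <- draw(which(stats::runif(g) < config$frac_trans))
    te <- draw(which(stats::runif(g) < config$frac_te))
  } else {
    n_cis <- round(config$frac_cis * g)
    n_trans <- round(config$frac_trans * g)
    n_te <- round(config$frac_te * g)
    perm <- sample.int(g)
    cis <- draw(perm[seq_len(n_cis)])
    trans <- draw(perm[n_cis + seq_len(n_trans)])
    te <- draw(perm[n_cis + n_trans + seq_len(n_te)])
  }
  # optional directional coupling: orient TE effects towards (or against)
  # the gene's mRNA difference
  if (config$te_reinforce_prob != 0.5) {
    idx <- which(te != 0 & (cis + trans) != 0)
    if (length(idx)) {
      align <- stats::runif(length(idx)) < config$te_reinforce_prob
      te[idx] <- ifelse(align, 1, -1) * sign(cis[idx] + trans[idx]) *
        abs(te[idx])
    }
  }

  base <- 10^b
  te_ratio <- 10^te0
  # parental mRNA and footprint rates (BY carries cis + trans + te)
  m_by <- base * 2^(cis + trans)
  m_rm <- base
  f_by <- m_by * te_ratio * 2^te
  f_rm <- m_rm * te_ratio
  # hybrid allele rates (cis and te only)
  hm_by <- base * 2^cis
  hm_rm <- base
  hf_by <- hm_by * te_ratio * 2^te
  hf_rm <- hm_rm * te_ratio

  ls <- config$library_sizes
  phi <- config$dispersion
  pmat <- cbind(
    .sim_library(m_by, ls[["mrna_BY"]], phi),
    .sim_library(m_rm, ls[["mrna_RM"]], phi),
    .sim_library(f_by, ls[["fp_BY"]], phi),
    .sim_library(f_rm, ls[["fp_RM"]], phi)
  )
  rownames(pmat) <- ids
  parents <- count_dataset(
    pmat,
    data.frame(molecule = c("mrna", "mrna", "fp", "fp"),
               source = c("BY", "RM", "BY", "RM"),
               replicate = "1", stringsAsFactors = FALSE),
    provenance = "raw", seeds = list(simulation = config$seed)
  )

  # a hybrid library covers both alleles: stack the two allele rate vectors
  hyb_lib <- function(m_rates_by, m_rates_rm, size) {
    v <- .sim_library(c(m_rates_by, m_rates_rm), size, phi)
    cbind(v[seq_len(g)], v[g + seq_len(g)])
  }
  hm1 <- hyb_lib(hm_by, hm_rm, ls[["mrna_hyb1"]])
  hm2 <- hyb_lib(hm_by, hm_rm, ls[["mrna_hyb2"]])
  hf1 <- hyb_lib(hf_by, hf_rm, ls[["fp_hyb1"]])
  hf2 <- hyb_lib(hf_by, hf_rm, ls[["fp_hyb2"]])
  hmat <- cbind(hm1, hm2, hf1, hf2)
  rownames(hmat) <- ids
  hcd <- data.frame(
    molecule = rep(c("mrna", "fp"), each = 4L),
    source = rep(c("BYallele", "RMallele"), times = 4L),
    replicate = rep(rep(c("1", "2"), each = 2L), times = 2L),
    stringsAsFactors = FALSE
  )
  hcd$library <- paste(hcd$molecule, "hyb", hcd$replicate, sep = "_")
  hybrid <- count_dataset(hmat, hcd, provenance = "raw",
                          seeds = list(simulation = config$seed))

  truth <- data.frame(gene = ids, cis = cis, trans = trans, te = te,
                      baseline_log10 = b, te_log10 = te0,
                      stringsAsFactors = FALSE)
  attr(truth, "seed") <- config$seed
  list(parents = parents, hybrid = hybrid, truth = truth, config = config)
}

#' Simulate unbiased hybrid-DNA allele counts at SNP sites
#'
#' Per site, the BY-allele count is Binomial(depth, 0.5) and the RM count is
#' the complement; this is the null model for technically unbiased
#' allele-specific quantification. Parental DNA coverages (used by
#' duplication-region detection) are drawn Poisson around the site depth.
#'
#' @param depths positive integer sequencing depths, one per site.
#' @param seed integer seed.
#' @return data.frame of class site table: `chrom`, `pos` (1-based,
#'   consecutive), `by_count`, `rm_count`, `depth`, `by_parent_cov`,
#'   `rm_parent_cov`, `source`.
#' @export
generate_unbiased_hybrid_dna <- function(depths, seed = NULL) {
  if (length(depths) == 0L) stop("depths must be non-empty")
  if (any(!is.finite(depths)) || any(depths <= 0) ||
        any(depths != round(depths))) {
    stop("depths must be positive integers")
  }
  local_seed(seed)
  n <- length(depths)
  by <- stats::rbinom(n, depths, 0.5)
  data.frame(
    chrom = "chrSim", pos = seq_len(n),
    by_count = by, rm_count = depths - by, depth = depths,
    by_parent_cov = stats::rpois(n, depths),
    rm_parent_cov = stats::rpois(n, depths),
    source = "hybrid-DNA", stringsAsFactors = FALSE
  )
}

#' Inject technical bias artifacts into a SNP site table
#'
#' Two artifact classes are injected, mirroring the failure modes the site
#' filter is designed to remove: (i) a fraction of sites gets a systematic
#' allele-count skew (counts redrawn Binomial(depth, `bias_freq`)); (ii)
#' sites inside duplication regions get doubled RM-parent DNA coverage and
#' their hybrid allelic ratio redrawn around 1/3 (a 2:1 bias towards the RM
#' genome, as produced by a segmental duplication present only in RM). Truth
#' labels are attached in a `bias_class` column.
#'
#' @param sites site table from [generate_unbiased_hybrid_dna()].
#' @param bias_fraction fraction of non-duplication sites to skew.
#' @param duplication_regions data.frame with `chrom`, `start`, `end`
#'   (1-based, inclusive), or NULL.
#' @param seed integer seed.
#' @param bias_freq target BY-allele frequency of skewed sites (default 0.2).
#' @return the site table with modified counts and a `bias_class` column
#'   (`"none"`, `"skewed"` or `"duplication"`).
#' @export
inject_bias_artifacts <- function(sites, bias_fraction = 0,
                                  duplication_regions = NULL, seed = NULL,
                                  bias_freq = 0.2) {
  stopifnot(is.data.frame(sites), bias_fraction >= 0, bias_fraction <= 1)
  local_seed(seed)
  sites$bias_class <- "none"
  in_dup <- rep(FALSE, nrow(sites))
  if (!is.null(duplication_regions) && nrow(duplication_regions)) {
    dr <- duplication_regions[order(duplication_regions$chrom,
                                    duplication_regions$start), ]
    same <- dr$chrom[-1] == dr$chrom[-nrow(dr)]
    if (any(same & dr$start[-1] <= dr$end[-nrow(dr)])) {
      stop("overlapping duplication regions")
    }
    for (i in seq_len(nrow(dr))) {
      in_dup <- in_dup | (sites$chrom == dr$chrom[i] &
                            sites$pos >= dr$start[i] & sites$pos <= dr$end[i])
    }
    k <- sum(in_dup)
    if (k) {
      sites$rm_parent_cov[in_dup] <- 2L * sites$rm_parent_cov[in_dup]
      nb <- stats::rbinom(k, sites$depth[in_dup], 1 / 3)
      sites$by_count[in_dup] <- nb
      sites$rm_count[in_dup] <- sites$depth[in_dup] - nb
      sites$bias_class[in_dup] <- "duplication"
    }
  }
  n_skew <- round(bias_fraction * sum(!in_dup))
  if (n_skew > 0) {
    cand <- which(!in_dup)
    pick <- cand[sample.int(length(cand), n_skew)]
    nb <- stats::rbinom(n_skew, sites$depth[pick], bias_freq)
    sites$by_count[pick] <- nb
    sites$rm_count[pick] <- sites$depth[pick] - nb
    sites$bias_class[pick] <- "skewed"
  }
  sites
}
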