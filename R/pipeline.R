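# End-to-end orchestration: parent and hybrid analyses from count tables,
# deterministic result files and a machine-readable run manifest.

#' Read a pipeline configuration file
#'
#' YAML key-value file; recognized keys include input paths
#' (`parent_counts`, `hybrid_snp_counts`, `gene_map`, `eqtl_table`,
#' `pqtl_table`), `correction`, `alpha`, `seed`, `bootstrap_B` and
#' `output_dir`. Missing keys fall back to the defaults of the functions
#' they feed.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1)) {
    stop("alpha must be in (0, 1)")
  }
  cfg
}

#' Run the parental differential-translation analysis
#'
#' Loads (or accepts) a raw parent count dataset and runs the full
#' [te_analysis()] chain: downsample, equalize, filter, binomial tests for
#' mRNA and footprints, G-test for TE, correction, fold changes,
#' classification and directional tests.
#'
#' @param counts path to a count table in the [read_counts()] dialect, or a
#'   raw [count_dataset()].
#' @param correction,alpha,seed passed to [te_analysis()].
#' @param output_dir if non-NULL, results are written there via
#'   [write_results()].
#' @return list of class `te_bundle` with the `te_analysis` fit and a run
#'   manifest.
#' @export
run_parent_analysis <- function(counts, correction = "bonferroni",
                                alpha = 0.05, seed = 1L, output_dir = NULL) {
  data <- if (inherits(counts, "count_dataset")) counts else read_counts(counts)
  fit <- te_analysis(data, correction = correction, alpha = alpha, seed = seed)
  bundle <- .make_bundle("parent", fit, seed = seed)
  if (!is.null(output_dir)) write_results(bundle, output_dir)
  bundle
}

#' Run the hybrid allele-specific analysis
#'
#' SNP-level allele counts are aggregated to genes (if a gene map is given),
#' replicates are summed, and the same chain as in
#' [run_parent_analysis()] is applied to the two alleles. When a parent
#' bundle is supplied, cis/trans MA and SMA slopes of hybrid on parental
#' fold changes are estimated with bootstrap confidence intervals for both
#' mRNA and footprints; without parent results the slopes are skipped with a
#' notice. In reproducibility mode the two replicates are analysed
#' separately (requires exactly 2 replicates) and per-replicate fold changes
#' plus their Spearman agreement are returned instead.
#'
#' @param counts path to a count table, a raw [count_dataset()], or (with
#'   `gene_map`) a SNP-level data.frame for [aggregate_snps_to_genes()].
#' @param gene_map optional SNP-to-gene map.
#' @param parent optional parent bundle or `te_analysis` for slope
#'   estimation.
#' @param reproducibility analyse replicates separately instead of summing.
#' @param B bootstrap replicates for the slopes.
#' @param correction,alpha,seed passed to [te_analysis()].
#' @param output_dir if non-NULL, results are written there.
#' @return list of class `te_bundle`; in slope mode it additionally holds
#'   `slopes`, in reproducibility mode `replicate_fc` and
#'   `replicate_agreement`.
#' @export
run_hybrid_analysis <- function(counts, gene_map = NULL, parent = NULL,
                                reproducibility = FALSE, B = 1000,
                                correction = "bonferroni", alpha = 0.05,
                                seed = 1L, output_dir = NULL) {
  data <- if (inherits(counts, "count_dataset")) {
    counts
  } else if (is.data.frame(counts)) {
    if (is.null(gene_map)) stop("SNP-level counts require a gene_map")
    aggregate_snps_to_genes(counts, gene_map)
  } else {
    read_counts(counts)
  }
  if (reproducibility) {
    reps <- unique(data$col_data$replicate)
    if (length(reps) != 2L) {
      stop("reproducibility mode requires exactly 2 replicates")
    }
    fcs <- lapply(reps, function(r) {
      keep <- data$col_data$replicate == r
      sub <- count_dataset(data$counts[, keep, drop = FALSE],
                           data$col_data[keep, ], provenance = "raw")
      fit_r <- te_analysis(sub, correction = correction, alpha = alpha,
                           seed = seed)
      fit_r$results
    })
    shared <- intersect(fcs[[1]]$gene, fcs[[2]]$gene)
    agree <- vapply(c("mrna_fc", "fp_fc", "te_fc"), function(cn) {
      stats::cor(fcs[[1]][[cn]][match(shared, fcs[[1]]$gene)],
                 fcs[[2]][[cn]][match(shared, fcs[[2]]$gene)],
                 method = "spearman")
    }, numeric(1))
    out <- list(kind = "hybrid-reproducibility", replicate_fc = fcs,
                replicate_agreement = agree, n_shared = length(shared),
                seed = seed)
    class(out) <- "te_bundle"
    return(out)
  }
  fit <- te_analysis(data, correction = correction, alpha = alpha, seed = seed)
  bundle <- .make_bundle("hybrid", fit, seed = seed)
  if (!is.null(parent)) {
    pfit <- if (inherits(parent, "te_bundle")) parent$analysis else parent
    stopifnot(inherits(pfit, "te_analysis"))
    shared <- intersect(pfit$results$gene, fit$results$gene)
    px <- pfit$results[match(shared, pfit$results$gene), ]
    hy <- fit$results[match(shared, fit$results$gene), ]
    bundle$slopes <- list(
      mrna = bootstrap_slope(px$mrna_fc, hy$mrna_fc, method = "MA", B = B,
                             seed = seed + 2L),
      fp = bootstrap_slope(px$fp_fc, hy$fp_fc, method = "MA", B = B,
                           seed = seed + 3L),
      mrna_sma = bootstrap_slope(px$mrna_fc, hy$mrna_fc, method = "SMA",
                                 B = B, seed = seed + 2L),
      fp_sma = bootstrap_slope(px$fp_fc, hy$fp_fc, method = "SMA", B = B,
                               seed = seed + 3L)
    )
    bundle$manifest$n_shared_genes <- length(shared)
  } else {
    message("no parent results supplied; cis/trans slopes skipped")
  }
  if (!is.null(output_dir)) write_results(bundle, output_dir)
  bundle
}

.make_bundle <- function(kind, fit, seed) {
  manifest <- list(
    kind = kind,
    package_version = as.character(utils::packageVersion("riboase")),
    seed = seed,
    seeds_used = fit$seeds,
    correction = fit$correction,
    alpha = fit$alpha,
    genes = as.list(fit$n),
    significant = list(mrna = sum(fit$results$sig_mrna),
                       fp = sum(fit$results$sig_fp),
                       te = sum(fit$results$sig_te)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(kind = kind, analysis = fit, manifest = manifest),
            class = "te_bundle")
}

#' @export
print.te_bundle <- function(x, ...) {
  cat("te_bundle:", x$kind, "\n")
  if (!is.null(x$analysis)) print(x$analysis)
  if (!is.null(x$slopes)) {
    cat("cis/trans slopes:\n")
    for (nm in c("mrna", "fp")) print(x$slopes[[nm]])
  }
  if (!is.null(x$replicate_agreement)) {
    cat("replicate Spearman agreement:\n")
    print(round(x$replicate_agreement, 3))
  }
  invisible(x)
}

#' Write a result bundle to a directory
#'
#' Deterministic file set with stable column order and gene sort: count
#' tables at the three provenance levels, the per-gene test results, the
#' category and directional-test tables, the exclusion report, slope
#' estimates (when present) and a JSON manifest listing every file written.
#' Two runs with the same seeds produce byte-identical result tables (the
#' manifest differs only in its timestamp).
#'
#' @param bundle a `te_bundle` from [run_parent_analysis()] or
#'   [run_hybrid_analysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "te_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("unwritable directory: ", dir)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  fit <- bundle$analysis
  if (!is.null(fit)) {
    for (lv in names(fit$datasets)) {
      p <- file.path(dir, paste0("counts_", lv, ".tsv"))
      write_counts(fit$datasets[[lv]], p)
      paths <- c(paths, p)
    }
    res <- fit$results[order(fit$results$gene), ]
    wt(res, "test_results.tsv")
    wt(fit$categories, "te_categories.tsv")
    wt(fit$directional, "directional_tests.tsv")
    wt(fit$filter_report[order(fit$filter_report$gene), , drop = FALSE],
       "excluded_genes.tsv")
  }
  if (!is.null(bundle$slopes)) {
    sl <- do.call(rbind, lapply(names(bundle$slopes), function(nm) {
      s <- bundle$slopes[[nm]]
      data.frame(comparison = nm, method = s$method, slope = s$slope,
                 ci_lower = s$ci[1], ci_upper = s$ci[2], B = s$B, n = s$n,
                 excludes_0 = s$excludes_0, excludes_1 = s$excludes_1,
                 stringsAsFactors = FALSE)
    }))
    wt(sl, "slopes.tsv")
    p <- file.path(dir, "slopes.json")
    jsonlite::write_json(sl, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  manifest <- bundle$manifest %||% list(kind = bundle$kind)
  manifest$files <- basename(paths)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, mp))
}
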