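# cis/trans decomposition by the slope of hybrid allelic fold changes on
# parental fold changes. A slope of 1 indicates purely cis-acting variation
# (the parental difference is fully recapitulated between the hybrid
# alleles); a slope of 0 indicates purely trans-acting variation.

# drop pairs with non-finite values, count them
.finite_xy <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep], dropped = sum(!keep))
}

#' Major-axis (MA) slope
#'
#' First principal axis of the bivariate scatter, symmetric in the errors of
#' x and y:
#' `slope = (Syy - Sxx + sqrt((Syy - Sxx)^2 + 4 Sxy^2)) / (2 Sxy)`
#' from the sample variances/covariance, with
#' `intercept = mean(y) - slope * mean(x)`. Non-finite pairs are dropped and
#' counted.
#'
#' @param x parental log2 fold changes.
#' @param y hybrid allelic log2 fold changes.
#' @return object of class `slope_estimate`.
#' @export
ma_slope <- function(x, y) {
  f <- .finite_xy(x, y)
  if (length(f$x) < 3L) stop("need at least 3 finite pairs")
  sxx <- stats::var(f$x); syy <- stats::var(f$y); sxy <- stats::cov(f$x, f$y)
  if (sxy == 0) {
    if (syy == sxx) stop("orientation undefined: Sxy = 0 and Sxx = Syy")
    slope <- if (syy < sxx) 0 else Inf
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  structure(list(method = "MA", slope = slope,
                 intercept = mean(f$y) - slope * mean(f$x),
                 n = length(f$x), n_dropped = f$dropped),
            class = "slope_estimate")
}

#' Standardized major-axis (SMA) slope
#'
#' `slope = sign(Sxy) * sqrt(Syy / Sxx)`; symmetric in x and y in the sense
#' that SMA(x, y) * SMA(y, x) = 1.
#'
#' @inheritParams ma_slope
#' @return object of class `slope_estimate`.
#' @export
sma_slope <- function(x, y) {
  f <- .finite_xy(x, y)
  if (length(f$x) < 3L) stop("need at least 3 finite pairs")
  sxx <- stats::var(f$x); syy <- stats::var(f$y); sxy <- stats::cov(f$x, f$y)
  if (sxx == 0) stop("zero variance in x")
  if (sxy == 0) stop("zero covariance: SMA sign undefined")
  slope <- sign(sxy) * sqrt(syy / sxx)
  structure(list(method = "SMA", slope = slope,
                 intercept = mean(f$y) - slope * mean(f$x),
                 n = length(f$x), n_dropped = f$dropped),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("%s slope: %.4f (intercept %.4f, n = %d", x$method, x$slope,
              x$intercept, x$n))
  if (x$n_dropped > 0) cat(sprintf(", %d non-finite pairs dropped", x$n_dropped))
  cat(")\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI [%.4f, %.4f] from %d bootstraps (%s); excludes 0: %s, excludes 1: %s\n",
                x$ci[1], x$ci[2], x$B, x$ci_type,
                x$excludes_0, x$excludes_1))
  }
  invisible(x)
}

#' @export
coef.slope_estimate <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Bootstrap confidence interval for an MA or SMA slope
#'
#' Resamples genes with replacement `B` times, refits the slope, and reports
#' the percentile 95% CI (bias-corrected and accelerated intervals are
#' available behind `ci_type = "bca"`). Flags whether the interval excludes
#' 0 (pure trans) and 1 (pure cis).
#'
#' @inheritParams ma_slope
#' @param method `"MA"` or `"SMA"`.
#' @param B number of bootstrap replicates (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed integer seed.
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @return `slope_estimate` with elements `boot` (replicate slopes), `ci`,
#'   `B`, `excludes_0`, `excludes_1`.
#' @export
bootstrap_slope <- function(x, y, method = c("MA", "SMA"), B = 1000,
                            seed = NULL, ci_type = c("percentile", "bca")) {
  method <- match.arg(method)
  ci_type <- match.arg(ci_type)
  if (B < 100) warning("fewer than 100 bootstrap replicates")
  fitfun <- if (method == "MA") ma_slope else sma_slope
  f <- .finite_xy(x, y)
  est <- fitfun(f$x, f$y)
  est$n_dropped <- f$dropped
  n <- length(f$x)
  local_seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    fitfun(f$x[i], f$y[i])$slope
  }, numeric(1))
  ci <- if (ci_type == "percentile") {
    unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  } else {
    .bca_ci(boot, est$slope, f$x, f$y, fitfun)
  }
  est$boot <- boot
  est$B <- B
  est$ci <- ci
  est$ci_type <- ci_type
  est$excludes_0 <- ci[1] > 0 || ci[2] < 0
  est$excludes_1 <- ci[1] > 1 || ci[2] < 1
  est
}

# BCa interval: bias correction from the bootstrap distribution, acceleration
# from the jackknife
.bca_ci <- function(boot, est, x, y, fitfun, conf = 0.95) {
  prop <- mean(boot < est)
  if (prop == 0 || prop == 1) {  # degenerate (e.g. noiseless data)
    return(unname(stats::quantile(boot, c((1 - conf) / 2, (1 + conf) / 2))))
  }
  z0 <- stats::qnorm(prop)
  n <- length(x)
  jack <- vapply(seq_len(n), function(i) fitfun(x[-i], y[-i])$slope, numeric(1))
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- c((1 - conf) / 2, (1 + conf) / 2)
  zq <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  unname(stats::quantile(boot, adj))
}

#' Slopes stratified by eQTL annotation class
#'
#' Splits genes into the classes local-only, distant-only and both (genes
#' with neither annotation are not fitted), estimates the bootstrap slope in
#' each class, and reports pairwise CI overlap. Annotation rows for unknown
#' genes are ignored with their count logged in the result.
#'
#' @param x,y named vectors of parental and hybrid log2 fold changes (names
#'   are gene ids).
#' @param annotation data.frame with columns `gene`, `has_local`,
#'   `has_distant` (logical).
#' @param method,B,seed passed to [bootstrap_slope()].
#' @param min_class classes smaller than this are still reported but flagged.
#' @return list with `slopes` (named list of `slope_estimate`s),
#'   `overlap` (pairwise logical CI-overlap matrix), `n_unknown`,
#'   `small_classes`.
#' @export
stratified_slopes <- function(x, y, annotation, method = "MA", B = 1000,
                              seed = NULL, min_class = 10) {
  stopifnot(!is.null(names(x)), !is.null(names(y)),
            all(c("gene", "has_local", "has_distant") %in% names(annotation)))
  known <- annotation$gene %in% names(x) & annotation$gene %in% names(y)
  n_unknown <- sum(!known)
  ann <- annotation[known, ]
  cls <- ifelse(ann$has_local & ann$has_distant, "both",
                ifelse(ann$has_local, "local_only",
                       ifelse(ann$has_distant, "distant_only", NA)))
  classes <- c("local_only", "distant_only", "both")
  local_seed(seed)
  slopes <- list()
  for (cl in classes) {
    g <- ann$gene[!is.na(cls) & cls == cl]
    if (length(g) < 3L) {
      slopes[[cl]] <- NULL
      next
    }
    slopes[[cl]] <- bootstrap_slope(x[g], y[g], method = method, B = B,
                                    seed = NULL)
  }
  fitted <- names(slopes)
  overlap <- matrix(NA, length(fitted), length(fitted),
                    dimnames = list(fitted, fitted))
  for (i in fitted) for (j in fitted) {
    ci_i <- slopes[[i]]$ci; ci_j <- slopes[[j]]$ci
    overlap[i, j] <- ci_i[1] <= ci_j[2] && ci_j[1] <= ci_i[2]
  }
  small <- fitted[vapply(slopes, function(s) s$n < min_class, logical(1))]
  list(slopes = slopes, overlap = overlap, n_unknown = n_unknown,
       small_classes = small,
       empty_classes = setdiff(classes, fitted))
}

#' Measurement-error variance of fold changes by abundance bin
#'
#' Genes are split into `n_bins` equal-size bins of increasing abundance;
#' within each bin the variance of the log2 fold change attributable to
#' measurement error is estimated as `var(rep1 - rep2) / 2` (half the
#' variance of the between-replicate difference, since independent replicate
#' errors enter the difference twice).
#'
#' @param rep1_fc,rep2_fc per-gene log2 fold changes from the two replicates.
#' @param abundance per-gene mean abundance used for binning.
#' @param n_bins number of bins.
#' @return data.frame with `bin`, `n`, `mean_abundance`, `error_variance`.
#' @export
replicate_error_by_bin <- function(rep1_fc, rep2_fc, abundance, n_bins = 10) {
  stopifnot(length(rep1_fc) == length(rep2_fc),
            length(rep1_fc) == length(abundance))
  keep <- is.finite(rep1_fc) & is.finite(rep2_fc) & is.finite(abundance)
  rep1_fc <- rep1_fc[keep]; rep2_fc <- rep2_fc[keep]
  abundance <- abundance[keep]
  n <- length(abundance)
  if (n < n_bins) stop("fewer genes than bins")
  bin <- ceiling(rank(abundance, ties.method = "first") / (n / n_bins))
  d <- rep1_fc - rep2_fc
  out <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(table(factor(bin, levels = seq_len(n_bins)))),
    mean_abundance = as.numeric(tapply(abundance, bin, mean)),
    error_variance = as.numeric(tapply(d, bin, stats::var)) / 2
  )
  out
}
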