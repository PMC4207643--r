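test_that("count tables round-trip through the writer and reader", {
  d <- make_parents(c(10, 0, 5), c(3, 8, 5), c(2, 2, 2), c(7, 1, 9))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_counts(d, p)
  d2 <- read_counts(p)
  expect_equal(d2$counts, d$counts)
  expect_equal(d2$col_data$molecule, d$col_data$molecule)
  expect_equal(d2$provenance, "raw")
})

test_that("malformed count tables are rejected with context", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmrna_BY_1\tmrna_RM_1", "gA\t5\t-2"), p)
  expect_error(read_counts(p), "gA.*mrna_RM_1")
  writeLines("gene\tmrna_BY_1", p)
  expect_error(read_counts(p), "no genes")
  writeLines(c("gene\tmrna_BY_1\tmrna_BY_1", "gA\t1\t2", "gA\t3\t4"), p)
  expect_error(read_counts(p), "duplicate gene ids")
  writeLines(c("gene\tbadheader", "gA\t1"), p)
  expect_error(read_counts(p), "malformed column")
  expect_error(read_counts("/nonexistent/file.tsv"), "not found")
})

test_that("constructor enforces the count invariants", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), NULL))
  cd <- data.frame(molecule = c("mrna", "fp"), source = "BY", replicate = "1")
  expect_s3_class(count_dataset(m, cd), "count_dataset")
  m2 <- m; m2[1] <- -1
  expect_error(count_dataset(m2, cd), "negative")
  m3 <- m; m3[1] <- 1.5
  expect_error(count_dataset(m3, cd), "non-integer")
  expect_error(count_dataset(matrix(1:4, 2), cd), "rownames")
})

test_that("SNP counts aggregate additively to genes", {
  snp <- data.frame(
    snp = c("s1", "s2", "s3"),
    mrna_BYallele_1 = c(3, 7, 11),
    mrna_RMallele_1 = c(5, 5, 2),
    fp_BYallele_1 = c(1, 2, 3),
    fp_RMallele_1 = c(0, 1, 4)
  )
  map <- data.frame(snp = c("s1", "s2", "s3"),
                    gene = c("gA", "gA", "gB"))
  d <- aggregate_snps_to_genes(snp, map)
  expect_equal(d$counts["gA", "mrna_BYallele_1"], 10)
  expect_equal(d$counts["gA", "mrna_RMallele_1"], 10)
  expect_equal(d$counts["gB", "fp_RMallele_1"], 4)
  # genes with no SNPs are absent
  expect_equal(sort(rownames(d$counts)), c("gA", "gB"))
  # one SNP, two genes, same strand: error
  map2 <- rbind(map, data.frame(snp = "s1", gene = "gC"))
  expect_error(aggregate_snps_to_genes(snp, map2), "two genes")
  # per-gene sums unaffected by other genes' rows
  d2 <- aggregate_snps_to_genes(snp[1:2, ], map[1:2, ])
  expect_equal(d2$counts["gA", ], d$counts["gA", ])
})

test_that("replicate summing is additive and conservative", {
  m <- cbind(c(4, 1), c(6, 2), c(10, 3), c(1, 1))
  rownames(m) <- c("gA", "gB")
  cd <- data.frame(molecule = c("mrna", "mrna", "fp", "fp"),
                   source = "BYallele",
                   replicate = c("1", "2", "1", "2"))
  d <- count_dataset(m, cd)
  s <- sum_replicates(d)
  expect_equal(ncol(s$counts), 2L)
  expect_equal(unname(s$counts["gA", "mrna_BYallele_1"]), 10)
  expect_equal(sum(s$counts), sum(d$counts))
  # single replicate: counts unchanged
  d1 <- make_parents(c(5, 2), c(1, 1), c(2, 2), c(3, 3))
  expect_equal(unname(sum_replicates(d1)$counts), unname(d1$counts))
})

test_that("downsampling matches the smallest library exactly", {
  set.seed(1)
  d <- make_parents(rpois(50, 200), rpois(50, 100), rpois(50, 400),
                    rpois(50, 150))
  ds <- downsample_libraries(d, seed = 2)
  expect_equal(ds$provenance, "downsampled")
  target <- min(colSums(d$counts))
  expect_true(all(colSums(ds$counts) == target))
  # the smallest library is untouched
  smallest <- which.min(colSums(d$counts))
  expect_equal(ds$counts[, smallest], d$counts[, smallest])
  # resampling never increases a count
  expect_true(all(ds$counts <= d$counts))
  # equal libraries in, identical data out
  d2 <- make_parents(c(10, 20), c(15, 15), c(5, 25), c(22, 8))
  expect_equal(downsample_libraries(d2, seed = 1)$counts, d2$counts)
  expect_error(downsample_libraries(make_parents(c(0, 0), c(1, 1), c(1, 1),
                                                 c(1, 1))),
               "zero total")
})

test_that("downsampling halves expected counts when total is halved", {
  # one library at 2N, the rest at N: every gene's expected count halves
  n_rep <- 400
  tot <- numeric(2)
  acc <- matrix(0, 2, 2)
  for (r in seq_len(n_rep)) {
    d <- make_parents(c(300, 100), c(100, 100), c(150, 50), c(120, 80))
    ds <- downsample_libraries(d)
    acc <- acc + ds$counts[, 1:2]
  }
  expect_equal(acc[1, 1] / n_rep, 150, tolerance = 0.03)
  expect_equal(acc[2, 1] / n_rep, 50, tolerance = 0.06)
})

test_that("hypergeometric equalization matches pair sums per gene", {
  d <- make_parents(c(50, 10), c(50, 10), c(100, 40), c(300, 5),
                    provenance = "raw")
  d$provenance <- "downsampled"
  h <- hypergeometric_equalize(d, seed = 1)
  expect_equal(h$provenance, "hypergeometric")
  pr <- riboase:::comparison_pairs(h)
  sm <- h$counts[, pr$mrna[1]] + h$counts[, pr$mrna[2]]
  sf <- h$counts[, pr$fp[1]] + h$counts[, pr$fp[2]]
  expect_equal(sm, sf)
  expect_true(all(h$counts <= d$counts))
  # gene with equal pair sums is untouched
  d2 <- make_parents(c(30), c(20), c(10), c(40))
  d2$provenance <- "downsampled"
  h2 <- hypergeometric_equalize(d2, seed = 1)
  expect_equal(h2$counts, d2$counts)
})

test_that("equalized counts have the closed-form hypergeometric mean", {
  # footprint pair (100, 300) resampled to the mRNA pair sum 100:
  # E[new fp_BY] = 100 * 100/400 = 25
  set.seed(3)
  n_rep <- 2000
  draws <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    d <- make_parents(50, 50, 100, 300)
    d$provenance <- "downsampled"
    draws[r] <- hypergeometric_equalize(d)$counts[1, "fp_BY_1"]
  }
  se <- sd(draws) / sqrt(n_rep)
  expect_lt(abs(mean(draws) - 25), 4 * se + 0.01)
})

test_that("gene filter applies both rules with inclusive boundaries", {
  d <- make_parents(
    mrna_by = c(10, 25, 10, 200),
    mrna_rm = c(9, 25, 10, 0),
    fp_by = c(30, 30, 300, 100),
    fp_rm = c(30, 30, 300, 100),
    genes = c("low", "ok", "boundary", "zero")
  )
  d$provenance <- "downsampled"
  h <- d; h$provenance <- "hypergeometric"
  # construct equalized-like data directly: pair sums 19/60, 50/60, 20/600,
  # 200/200
  flt <- filter_genes(h, d)
  expect_setequal(flt$report$gene, c("low", "zero"))
  expect_equal(flt$report$rule[flt$report$gene == "low"], "pair<20")
  expect_equal(flt$report$rule[flt$report$gene == "zero"], "zero count")
  expect_setequal(rownames(flt$hypergeometric$counts), c("ok", "boundary"))
  expect_setequal(rownames(flt$downsampled$counts), c("ok", "boundary"))
})

test_that("TE is the footprint/mRNA ratio on log scale", {
  # fractions 1e-4 (mRNA) and 1e-3 (footprint) give log10 TE = +1
  d <- make_parents(c(100, 333300, 666600), c(100, 450, 550),
                    c(1000, 399600, 599400), c(500, 500, 500))
  ab <- abundance_fractions(d)
  expect_equal(unname(ab$fraction["g001", "mrna_BY_1"]), 1e-4)
  expect_equal(unname(ab$fraction["g001", "fp_BY_1"]), 1e-3)
  te <- compute_te(d)
  expect_equal(unname(te["g001", "BY"]), 1)
  # equal fractions give TE 0
  d2 <- make_parents(c(10, 90), c(1, 9), c(30, 270), c(5, 45))
  expect_equal(unname(compute_te(d2)[, "BY"]), c(0, 0))
})

test_that("log2 fold changes follow the BY-positive convention", {
  expect_equal(compute_log2fc(40, 10)$log2fc, 2)
  expect_equal(compute_log2fc(10, 10)$log2fc, 0)
  r <- compute_log2fc(0, 15)
  expect_false(r$finite)
  expect_error(compute_log2fc(0, 0), "both counts zero")
})

test_that("TE fold change is exactly footprint minus mRNA fold change", {
  set.seed(4)
  d <- make_parents(rpois(30, 100) + 1, rpois(30, 100) + 1,
                    rpois(30, 200) + 1, rpois(30, 150) + 1)
  fc <- riboase:::fold_change_table(d)
  expect_identical(fc$te_fc, fc$fp_fc - fc$mrna_fc)
})
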