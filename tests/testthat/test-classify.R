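test_that("strong-effect genes classify into their published categories", {
  # ACS1: footprint-only ASE (mRNA p = 1, footprint -3.25 significant)
  r <- result_row("YAL054C", mrna_fc = 0.56, fp_fc = -3.25,
                  sig_mrna = FALSE, sig_fp = TRUE)
  expect_equal(classify_te_genes(r), "fp_only")
  # YDL124W: both significant, same sign, footprint larger -> reinforced
  r <- result_row("YDL124W", mrna_fc = 1.16, fp_fc = 2.17,
                  sig_mrna = TRUE, sig_fp = TRUE)
  expect_equal(classify_te_genes(r), "reinforced")
  # NPA3: both significant, opposite sign -> inverted
  r <- result_row("YJR072C", mrna_fc = 1.46, fp_fc = -0.68,
                  sig_mrna = TRUE, sig_fp = TRUE)
  expect_equal(classify_te_genes(r), "inverted")
  # both significant, same sign, mRNA larger -> buffered
  r <- result_row("g1", mrna_fc = 2, fp_fc = 1, sig_mrna = TRUE,
                  sig_fp = TRUE)
  expect_equal(classify_te_genes(r), "buffered")
  # mRNA only -> complete buffering
  r <- result_row("g2", mrna_fc = 2, fp_fc = 0.5, sig_mrna = TRUE,
                  sig_fp = FALSE)
  expect_equal(classify_te_genes(r), "completely_buffered")
  # nothing significant -> neither
  r <- result_row("g3", mrna_fc = 0.2, fp_fc = 0.3, sig_mrna = FALSE,
                  sig_fp = FALSE)
  expect_equal(classify_te_genes(r), "neither")
  # TE not significant -> not classified
  r <- result_row("g4", mrna_fc = 1, fp_fc = 2, sig_mrna = TRUE,
                  sig_fp = TRUE, sig_te = FALSE)
  expect_equal(classify_te_genes(r), "not_te")
})

test_that("ties and zero fold changes are deterministic and logged", {
  r <- result_row("g1", mrna_fc = 1, fp_fc = 1, sig_mrna = TRUE,
                  sig_fp = TRUE)
  expect_message(cl <- classify_te_genes(r), "tie")
  expect_equal(cl, "buffered")
  r2 <- result_row("g2", mrna_fc = 0, fp_fc = 1, sig_mrna = TRUE,
                   sig_fp = TRUE)
  expect_message(cl2 <- classify_te_genes(r2), "zero fold change")
  expect_equal(cl2, "reinforced")
  expect_error(classify_te_genes(result_row("g", 1, 1, NA, TRUE)),
               "missing significance")
})

test_that("classification is an exhaustive, exclusive partition", {
  set.seed(40)
  n <- 500
  r <- data.frame(
    gene = sprintf("g%03d", 1:n),
    mrna_fc = rnorm(n), fp_fc = rnorm(n),
    sig_mrna = runif(n) < 0.5, sig_fp = runif(n) < 0.5,
    sig_te = runif(n) < 0.6
  )
  cl <- suppressMessages(classify_te_genes(r))
  expect_equal(length(cl), n)
  te <- cl[r$sig_te]
  expect_true(all(te %in% riboase:::TE_CATEGORIES))
  expect_true(all(cl[!r$sig_te] == "not_te"))
  tab <- tabulate_categories(cl)
  expect_equal(sum(tab$count), sum(r$sig_te))
  expect_equal(attr(tab, "total"), sum(r$sig_te))
  # permutation invariance of the tabulation
  perm <- sample(n)
  expect_equal(tabulate_categories(cl[perm])$count, tab$count)
})

test_that("empty input tabulates to zero TE genes", {
  tab <- tabulate_categories(character(0))
  expect_equal(attr(tab, "total"), 0L)
  expect_true(all(tab$count == 0))
})

test_that("directional ratios from published category counts", {
  dt <- directional_tests(parent_category_table())
  dt <- dt[match(c("R_vs_B", "R_vs_BI", "RF_vs_B", "RF_vs_BI"),
                 dt$comparison), ]
  # printed values: 1.1 (0.3), 0.9, 2.0 (2e-49), 1.6 (7e-27)
  expect_equal(round(dt$ratio, 1), c(1.1, 0.9, 2.0, 1.6))
  expect_equal(dt$p.value[1], 0.26, tolerance = 0.02)
  expect_lt(dt$p.value[3], 1e-45); expect_gt(dt$p.value[3], 1e-52)
  expect_lt(dt$p.value[4], 1e-24); expect_gt(dt$p.value[4], 1e-29)
  # numerators/denominators pool partial and complete buffering
  expect_equal(dt$numerator, c(690, 690, 1301, 1301))
  expect_equal(dt$denominator, c(649, 808, 649, 808))
})

test_that("ratios from a tabulation equal gene-by-gene computation", {
  set.seed(41)
  n <- 400
  r <- data.frame(
    gene = sprintf("g%03d", 1:n),
    mrna_fc = rnorm(n), fp_fc = rnorm(n),
    sig_mrna = runif(n) < 0.6, sig_fp = runif(n) < 0.6,
    sig_te = runif(n) < 0.7
  )
  cl <- suppressMessages(classify_te_genes(r))
  via_tab <- directional_tests(tabulate_categories(cl))
  via_genes <- directional_tests(cl)
  expect_identical(via_tab, via_genes)
  # balanced case
  bal <- data.frame(category = riboase:::TE_CATEGORIES,
                    count = c(0L, 5L, 5L, 0L, 0L, 0L))
  db <- directional_tests(bal)
  expect_equal(db$ratio[db$comparison == "R_vs_B"], 1)
  expect_equal(db$p.value[db$comparison == "R_vs_B"], 1)
  # zero denominator flagged as NA
  nod <- data.frame(category = riboase:::TE_CATEGORIES,
                    count = c(1L, 5L, 0L, 0L, 0L, 0L))
  dn <- directional_tests(nod)
  expect_true(is.na(dn$ratio[dn$comparison == "R_vs_B"]))
})

test_that("external tables harmonize under each significance rule", {
  set.seed(42)
  n <- 300
  ext <- data.frame(
    orf = sprintf("o%03d", 1:n),
    m_lfc = rnorm(n), f_lfc = rnorm(n),
    m_p = runif(n), f_p = runif(n), t_p = runif(n)
  )
  mapping <- list(gene = "orf", mrna_fc = "m_lfc", fp_fc = "f_lfc",
                  mrna_p = "m_p", fp_p = "f_p", te_p = "t_p")
  # pre-corrected rule: direct comparison to alpha
  h <- suppressMessages(harmonize_external(ext, mapping, rule = "precorrected"))
  expect_identical(h$sig_mrna, ext$m_p < 0.05)
  expect_identical(h$te_fc, h$fp_fc - h$mrna_fc)
  expect_true(all(h$category[!h$sig_te] == "not_te"))
  # q-value rule on uniform p-values flags (almost) nothing
  h2 <- suppressMessages(harmonize_external(ext, mapping, rule = "qvalue"))
  expect_lt(mean(h2$sig_te), 0.01)
  # bonferroni rule
  h3 <- suppressMessages(harmonize_external(ext, mapping, rule = "bonferroni"))
  expect_identical(h3$sig_fp, ext$f_p < 0.05 / n)
  # missing column mapping is named in the error
  expect_error(harmonize_external(ext, mapping[-6]), "te_p")
  bad <- mapping; bad$te_p <- "nonexistent"
  expect_error(harmonize_external(ext, bad), "nonexistent")
})
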