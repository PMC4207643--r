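# shared fixture builders (all data generated in code)

# parent-style dataset (4 libraries) from explicit count columns
make_parents <- function(mrna_by, mrna_rm, fp_by, fp_rm,
                         genes = sprintf("g%03d", seq_along(mrna_by)),
                         provenance = "raw") {
  m <- cbind(mrna_by, mrna_rm, fp_by, fp_rm)
  rownames(m) <- genes
  count_dataset(
    m,
    data.frame(molecule = c("mrna", "mrna", "fp", "fp"),
               source = c("BY", "RM", "BY", "RM"),
               replicate = "1", stringsAsFactors = FALSE),
    provenance = provenance
  )
}

# small library sizes keep simulation-driven tests fast while leaving
# per-gene counts in the hundreds
small_libs <- function(scale = 1) {
  c(mrna_BY = 4e5, mrna_RM = 4e5, fp_BY = 6e5, fp_RM = 6e5,
    mrna_hyb1 = 2e5, mrna_hyb2 = 2e5, fp_hyb1 = 3e5, fp_hyb2 = 3e5) * scale
}

# results-table row for classification tests
result_row <- function(gene, mrna_fc, fp_fc, sig_mrna, sig_fp, sig_te = TRUE) {
  data.frame(gene = gene, mrna_fc = mrna_fc, fp_fc = fp_fc,
             sig_mrna = sig_mrna, sig_fp = sig_fp, sig_te = sig_te,
             stringsAsFactors = FALSE)
}

# category counts as printed for the parental comparison (fp-only,
# reinforced, buffered, mRNA-only, inverted, neither)
parent_category_table <- function() {
  data.frame(
    category = c("fp_only", "reinforced", "buffered", "completely_buffered",
                 "inverted", "neither"),
    count = c(611L, 690L, 229L, 420L, 159L, 119L),
    stringsAsFactors = FALSE
  )
}
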