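write_pipeline_inputs <- function(dir, n_genes = 30L, seed = 13L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  se <- simulate_expression(
    n_genes = n_genes, seed = seed, noise_sd = 0.2,
    modules = data.frame(n_genes = 6L, log2_effect = 2, cell_type = "hCM"))
  cls <- data.frame(gene = se$truth$gene[1:12],
                    class = rep(c("structural", "background"), each = 6))
  sm <- simulate_methylation(classes = cls, coverage_mean = 50, seed = seed)
  paths <- list(expression = file.path(dir, "expr.tsv"),
                design = file.path(dir, "design.tsv"),
                tss = file.path(dir, "tss.bed"))
  stabilitycore:::write_tsv_plain(se$expression, paths$expression)
  stabilitycore:::write_tsv_plain(se$design, paths$design)
  write_tss_bed(sm$tss, paths$tss)
  meth <- lapply(c(hESC = "hESC", hNSC = "hNSC", hCM = "hCM"), function(ct) {
    p <- file.path(dir, paste0("meth_", ct, ".tsv"))
    stabilitycore:::write_tsv_plain(
      sm$sites[sm$sites$cell_type == ct,
               c("chrom", "pos", "strand", "meth_count", "total_count")], p)
    p
  })
  paths$methylation <- meth
  paths$truth <- list(expression = se$truth, methylation = sm$truth)
  paths
}
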