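make_sites <- function(...) {
  # rows: list(chrom, pos, per-cell-type c(meth, total) ...)
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    cts <- setdiff(names(r), c("chrom", "pos"))
    purrr::map_dfr(cts, function(ct) {
      tibble::tibble(chrom = r$chrom, pos = r$pos, strand = "+",
                     cell_type = ct, meth_count = r[[ct]][1],
                     total_count = r[[ct]][2])
    })
  })
}

test_that("coverage filter keeps sites with >= 10x in every cell type (inclusive)", {
  sites <- make_sites(
    list(chrom = "chr1", pos = 100L, hESC = c(6L, 12L), hNSC = c(5L, 11L),
         hCM = c(1L, 10L)),                                    # boundary: kept
    list(chrom = "chr1", pos = 200L, hESC = c(6L, 12L), hNSC = c(4L, 9L),
         hCM = c(20L, 30L)))                                   # fails hNSC
  kept <- site_methylation(sites, min_cov = 10L)
  expect_setequal(unique(kept$pos), 100L)
  expect_equal(kept$frequency[kept$cell_type == "hESC"], 0.5)
  # idempotence
  expect_equal(site_methylation(kept, min_cov = 10L)[, names(kept)], kept)
})

test_that("a site missing from one cell type is dropped; bad counts error with coordinates", {
  sites <- make_sites(
    list(chrom = "chr1", pos = 100L, hESC = c(5L, 10L), hNSC = c(5L, 10L)))
  sites <- dplyr::bind_rows(sites, tibble::tibble(
    chrom = "chr1", pos = 300L, strand = "+", cell_type = "hCM",
    meth_count = 2L, total_count = 20L))
  kept <- site_methylation(sites, min_cov = 10L)
  expect_equal(nrow(kept), 0L)  # neither site observed in all 3 cell types

  bad <- make_sites(list(chrom = "chr2", pos = 50L, hESC = c(11L, 10L)))
  expect_error(site_methylation(bad), "chr2:50")
})

test_that("promoter level averages covered CpGs in a symmetric inclusive window", {
  tss <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5001L,
                        gene = c("g1"), score = 0L, strand = "+")
  sites <- make_sites(
    list(chrom = "chr1", pos = 4200L, hESC = c(8L, 10L)),   # TSS - 800
    list(chrom = "chr1", pos = 5200L, hESC = c(5L, 10L)),   # TSS + 200
    list(chrom = "chr1", pos = 6000L, hESC = c(10L, 10L)),  # exactly +1000
    list(chrom = "chr1", pos = 6001L, hESC = c(0L, 10L)))   # just outside
  f <- site_methylation(sites, min_cov = 10L)
  pm <- promoter_methylation(f, tss, window_bp = 1000L)
  expect_equal(pm$n_sites_used, 3L)
  expect_equal(pm$mean_mcpg, mean(c(0.8, 0.5, 1.0)))

  pm2 <- promoter_methylation(f, tss, window_bp = 999L)
  expect_equal(pm2$n_sites_used, 2L)
  expect_equal(pm2$mean_mcpg, 0.65)

  # no covered CpG in window, and a TSS on an absent chromosome
  tss3 <- tibble::tibble(chrom = c("chr1", "chrX"),
                         start = c(9000L, 100L), end = c(9001L, 101L),
                         gene = c("g2", "g3"), score = 0L, strand = "+")
  pm3 <- promoter_methylation(f, tss3)
  expect_true(all(is.na(pm3$mean_mcpg)))
  expect_true(all(pm3$n_sites_used == 0L))
})

test_that("minus-strand promoters measure from end - 1 and can restrict upstream", {
  tss <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5001L,
                        gene = "g1", score = 0L, strand = "-")
  sites <- make_sites(
    list(chrom = "chr1", pos = 5500L, hESC = c(10L, 10L)),  # upstream on -
    list(chrom = "chr1", pos = 4500L, hESC = c(0L, 10L)))   # downstream on -
  f <- site_methylation(sites)
  both <- promoter_methylation(f, tss, window_bp = 1000L)
  expect_equal(both$mean_mcpg, 0.5)
  up <- promoter_methylation(f, tss, window_bp = 1000L, upstream_only = TRUE)
  expect_equal(up$n_sites_used, 1L)
  expect_equal(up$mean_mcpg, 1.0)
})

test_that("adding a CpG at the current mean leaves the promoter level unchanged", {
  tss <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1001L,
                        gene = "g1", score = 0L, strand = "+")
  base <- make_sites(
    list(chrom = "chr1", pos = 900L, hESC = c(6L, 10L)),
    list(chrom = "chr1", pos = 1100L, hESC = c(8L, 10L)))
  f <- site_methylation(base)
  m0 <- promoter_methylation(f, tss)$mean_mcpg
  extra <- dplyr::bind_rows(f, tibble::tibble(
    chrom = "chr1", pos = 1200L, strand = "+", cell_type = "hESC",
    meth_count = 7L, total_count = 10L, frequency = 0.7))
  expect_equal(promoter_methylation(extra, tss)$mean_mcpg, m0)
  expect_equal(m0, 0.7)
})

test_that("differential methylation uses an inclusive 5-point delta against both refs", {
  pm <- tibble::tibble(
    gene = rep(c("hypo", "edge", "onesided", "hyper", "flat"), each = 3),
    cell_type = rep(c("hCM", "hESC", "hNSC"), 5),
    mean_mcpg = c(0.10, 0.70, 0.60,   # clear hypo
                  0.65, 0.70, 0.70,   # exact 0.05 boundary -> hypo
                  0.50, 0.52, 0.90,   # fails one reference
                  0.60, 0.50, 0.30,   # hyper vs both
                  0.50, 0.50, 0.50),
    n_sites_used = 5L)
  dm <- call_differential_methylation(pm, "hCM", c("hESC", "hNSC"))
  st <- setNames(dm$status, dm$gene)
  expect_equal(unname(st[c("hypo", "edge", "onesided", "hyper", "flat")]),
               c("hypo", "hypo", "none", "hyper", "none"))
  expect_equal(dm$meth_delta_vs_ref1[dm$gene == "hypo"], -0.6)
})

test_that("undefined promoters are skipped and reported, not called", {
  pm <- tibble::tibble(
    gene = rep(c("ok", "gap"), each = 3),
    cell_type = rep(c("hCM", "hESC", "hNSC"), 2),
    mean_mcpg = c(0.1, 0.7, 0.7, 0.1, NA, 0.7),
    n_sites_used = c(3L, 3L, 3L, 3L, 0L, 3L))
  dm <- call_differential_methylation(pm, "hCM", c("hESC", "hNSC"))
  expect_equal(dm$gene, "ok")
  expect_equal(attr(dm, "skipped"), "gap")
})

test_that("promoter classes use strict 70% and 10% bounds", {
  pm <- tibble::tibble(gene = "g", cell_type = c("a", "b", "c", "d"),
                       mean_mcpg = c(0.75, 0.05, 0.70, 0.10),
                       n_sites_used = 1L)
  cls <- classify_promoter(pm)
  expect_equal(cls$promoter_class,
               c("hypermethylated", "low", "intermediate", "intermediate"))
  pm$mean_mcpg[1] <- NA
  expect_error(classify_promoter(pm), "NA")
})

test_that("integration intersects demethylation with up-regulation", {
  dm <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g5"),
    meth_target = c(0.1, 0.1, 0.1, 0.05),
    meth_ref1 = c(0.8, 0.8, 0.8, 0.06),
    meth_ref2 = c(0.8, 0.8, 0.8, 0.06),
    meth_delta_vs_ref1 = c(-0.7, -0.7, -0.7, -0.01),
    meth_delta_vs_ref2 = c(-0.7, -0.7, -0.7, -0.01),
    status = c("hypo", "hypo", "hypo", "none"))
  de <- tibble::tibble(gene = c("g2", "g3", "g4"), direction = "up")
  out <- integrate_meth_expression(dm, de)
  expect_setequal(out$gene[out$category == "demethylated_upregulated"],
                  c("g2", "g3"))
  # hypo but not up: hypermethylated in both references
  expect_equal(out$category[out$gene == "g1"], "hypermethylated_promoter")
  # low everywhere, no DE record
  expect_equal(out$category[out$gene == "g5"], "low_methylation_promoter")
  expect_equal(out$direction[out$gene == "g5"], "absent")

  # disjoint lists yield no integrated calls
  de2 <- tibble::tibble(gene = "g9", direction = "up")
  out2 <- integrate_meth_expression(dm, de2)
  expect_equal(sum(out2$category == "demethylated_upregulated"), 0L)
})
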