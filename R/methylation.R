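#' Filter CpG sites by coverage in every cell type
#'
#' Implements the joint-coverage rule of differential promoter methylation:
#' only CpG sites sequenced to at least `min_cov` total reads in EVERY cell
#' type (intersection across the table's cell types, boundary inclusive)
#' enter the analysis. Methylation frequency (mCpG/CpG, in `[0, 1]`) is
#' computed on the surviving sites. The filter is idempotent.
#'
#' @param sites Long data frame of per-CpG counts with columns `chrom`,
#'   `pos` (0-based position of the CpG cytosine on the plus strand),
#'   `cell_type`, `meth_count`, `total_count`.
#' @param min_cov Minimum per-cell-type coverage (default 10).
#' @return A tibble of the surviving rows with an added `frequency` column.
#' @export
site_methylation <- function(sites, min_cov = 10L) {
  stopifnot(min_cov >= 1)
  sites <- tibble::as_tibble(sites)
  req <- c("chrom", "pos", "cell_type", "meth_count", "total_count")
  stopifnot(all(req %in% names(sites)))
  bad <- which(sites$meth_count > sites$total_count |
                 sites$meth_count < 0 | sites$total_count <= 0)
  if (length(bad) > 0L) {
    b <- bad[1]
    rlang::abort(sprintf(
      "invalid CpG counts at %s:%d (%s): meth %d of total %d",
      sites$chrom[b], sites$pos[b], sites$cell_type[b],
      sites$meth_count[b], sites$total_count[b]))
  }
  n_types <- length(unique(sites$cell_type))
  kept <- sites |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::filter(dplyr::n_distinct(.data$cell_type) == n_types,
                  all(.data$total_count >= min_cov)) |>
    dplyr::ungroup()
  kept$frequency <- kept$meth_count / kept$total_count
  kept
}

#' Average promoter methylation around each TSS
#'
#' For every gene and cell type, the promoter methylation level is the
#' unweighted mean of the mCpG/CpG frequencies of covered CpG sites lying
#' within `window_bp` of the transcription start site (symmetric, boundary
#' inclusive; `upstream_only = TRUE` restricts to the strand-aware upstream
#' side). Genes with no covered CpG in the window — including genes whose
#' chromosome is absent from the site table — get an undefined (`NA`)
#' level with `n_sites_used = 0` and are excluded from differential calls
#' downstream.
#'
#' @param sites Coverage-filtered site table from [site_methylation()]
#'   (must carry `frequency`).
#' @param tss TSS annotation: data frame with BED6 columns `chrom`,
#'   `start`, `end`, `gene`, `score`, `strand` (0-based half-open; the TSS
#'   is `start` on `+` and `end - 1` on `-`).
#' @param window_bp Half-window around the TSS in bp (default 1000).
#' @param upstream_only Restrict to the upstream side of the TSS.
#' @return A tibble with one row per gene and cell type: `gene`,
#'   `cell_type`, `mean_mcpg`, `n_sites_used`.
#' @export
promoter_methylation <- function(sites, tss, window_bp = 1000L,
                                 upstream_only = FALSE) {
  sites <- tibble::as_tibble(sites)
  stopifnot("frequency" %in% names(sites))
  tss <- tibble::as_tibble(tss)
  stopifnot(all(c("chrom", "start", "end", "gene", "strand") %in% names(tss)))
  cell_types <- sort(unique(sites$cell_type))
  tss$tss_pos <- ifelse(tss$strand == "-", tss$end - 1L, tss$start)

  per_gene <- purrr::map_dfr(seq_len(nrow(tss)), function(i) {
    offset <- sites$pos - tss$tss_pos[i]
    if (tss$strand[i] == "-") offset <- -offset
    win <- if (upstream_only) {
      offset >= -window_bp & offset <= 0
    } else {
      abs(offset) <= window_bp
    }
    in_window <- sites$chrom == tss$chrom[i] & win
    hit <- sites[in_window, ]
    out <- tibble::tibble(gene = tss$gene[i], cell_type = cell_types)
    if (nrow(hit) == 0L) {
      out$mean_mcpg <- NA_real_
      out$n_sites_used <- 0L
      return(out)
    }
    agg <- hit |>
      dplyr::group_by(.data$cell_type) |>
      dplyr::summarise(mean_mcpg = mean(.data$frequency),
                       n_sites_used = dplyr::n(), .groups = "drop")
    dplyr::left_join(out, agg, by = "cell_type") |>
      dplyr::mutate(n_sites_used = ifelse(is.na(.data$n_sites_used), 0L,
                                          .data$n_sites_used))
  })
  per_gene
}

#' Call differential promoter methylation against two references
#'
#' A promoter is hypermethylated in the target lineage when its mean mCpG
#' level exceeds EACH reference's level by at least `delta`, and
#' hypomethylated (demethylated) when each reference exceeds the target by
#' at least `delta`; the boundary is inclusive ("delta or more"). Genes
#' with an undefined promoter level in any cell type are skipped and
#' reported in the `skipped` attribute.
#'
#' @param pm Promoter table from [promoter_methylation()].
#' @param target Target cell type.
#' @param refs The two reference cell types.
#' @param delta Minimum methylation difference (default 0.05, i.e. 5
#'   percentage points).
#' @return A tibble: `gene`, `meth_target`, `meth_ref1`, `meth_ref2`,
#'   `meth_delta_vs_ref1`, `meth_delta_vs_ref2` (target minus reference),
#'   `status` in `{"hyper", "hypo", "none"}`. Attribute `skipped` holds
#'   the genes dropped for undefined levels.
#' @export
call_differential_methylation <- function(pm, target, refs, delta = 0.05) {
  stopifnot(length(refs) == 2L, delta >= 0, delta <= 1)
  wide <- tidyr::pivot_wider(pm[, c("gene", "cell_type", "mean_mcpg")],
                             names_from = "cell_type",
                             values_from = "mean_mcpg")
  need <- c(target, refs)
  missing_ct <- setdiff(need, names(wide))
  if (length(missing_ct) > 0L) {
    rlang::abort(sprintf("promoter table lacks cell type(s): %s",
                         paste(missing_ct, collapse = ", ")))
  }
  defined <- stats::complete.cases(wide[, need])
  skipped <- wide$gene[!defined]
  wide <- wide[defined, ]
  d1 <- wide[[target]] - wide[[refs[1]]]
  d2 <- wide[[target]] - wide[[refs[2]]]
  # inclusive boundary, robust to floating-point representation of the deltas
  ge <- function(x, y) x >= y - 1e-9
  out <- tibble::tibble(
    gene = wide$gene,
    meth_target = wide[[target]],
    meth_ref1 = wide[[refs[1]]],
    meth_ref2 = wide[[refs[2]]],
    meth_delta_vs_ref1 = d1,
    meth_delta_vs_ref2 = d2,
    status = dplyr::case_when(
      ge(d1, delta) & ge(d2, delta) ~ "hyper",
      ge(-d1, delta) & ge(-d2, delta) ~ "hypo",
      TRUE ~ "none"
    )
  )
  attr(out, "skipped") <- skipped
  out
}

#' Classify promoters by absolute methylation level
#'
#' The dichotomy observed among lineage-specific genes: structural genes
#' tend to carry hypermethylated promoters (> 70 %) in non-expressing
#' lineages, while developmental transcription factors keep low promoter
#' methylation (< 10 %) in all lineages. Both bounds are strict; levels in
#' between are `"intermediate"`.
#'
#' @param pm Promoter table from [promoter_methylation()] (or any data
#'   frame with a `mean_mcpg` column).
#' @return `pm` with an added `promoter_class` column
#'   (`"hypermethylated"`, `"low"`, `"intermediate"`).
#' @export
classify_promoter <- function(pm) {
  pm <- tibble::as_tibble(pm)
  if (anyNA(pm$mean_mcpg)) {
    rlang::abort("classify_promoter requires defined promoter levels (no NA)")
  }
  pm$promoter_class <- dplyr::case_when(
    pm$mean_mcpg > 0.70 ~ "hypermethylated",
    pm$mean_mcpg < 0.10 ~ "low",
    TRUE ~ "intermediate"
  )
  pm
}

#' Integrate promoter demethylation with up-regulation
#'
#' Intersects the hypomethylated promoters with the up-regulated DE calls:
#' genes demethylated in the target lineage AND at least two-fold
#' up-regulated against both references form the
#' `demethylated_upregulated` category. Remaining genes are categorized by
#' their promoter profile when reference levels are available:
#' `hypermethylated_promoter` when both references exceed 70 %,
#' `low_methylation_promoter` when all three lineages sit under 10 %, and
#' `other` otherwise.
#'
#' @param dm Differential-methylation table from
#'   [call_differential_methylation()].
#' @param de DE table from [call_de()].
#' @return A tibble with one row per gene present in `dm`: `gene`,
#'   `status` (methylation), `direction` (expression; `"absent"` when the
#'   gene is not in the DE table), `category`.
#' @export
integrate_meth_expression <- function(dm, de) {
  de_dir <- stats::setNames(de$direction, de$gene)
  dirs <- de_dir[dm$gene]
  dirs[is.na(dirs)] <- "absent"
  tibble::tibble(
    gene = dm$gene,
    status = dm$status,
    direction = unname(dirs),
    category = dplyr::case_when(
      dm$status == "hypo" & dirs == "up" ~ "demethylated_upregulated",
      dm$meth_ref1 > 0.70 & dm$meth_ref2 > 0.70 ~ "hypermethylated_promoter",
      dm$meth_target < 0.10 & dm$meth_ref1 < 0.10 & dm$meth_ref2 < 0.10 ~
        "low_methylation_promoter",
      TRUE ~ "other"
    )
  )
}
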