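#' Call differential expression of a target lineage against two references
#'
#' Implements the threshold filter used to define lineage-enriched genes on
#' a normalized log2 expression matrix: a gene is called "up" when its
#' mean in the target cell type is at least `fc_threshold`-fold above the
#' mean of EACH reference cell type (boundary inclusive), and "down" when
#' it is at least that far below both. Significance comes from a two-sided
#' t-test of the target replicates against each reference's replicates
#' (Welch by default); a gene is `significant` when both tests fall under
#' `p_threshold`. No multiple-testing correction is applied by default,
#' matching the plain P < 0.05 convention of threshold-based microarray
#' filters; set `adjust = "BH"` to use FDR-adjusted values instead.
#'
#' @param expression Data frame: first column `gene`, remaining columns one
#'   per sample (log2 scale, no missing values).
#' @param design Data frame with columns `sample`, `cell_type`; every cell
#'   type needs >= 2 replicates.
#' @param target Target cell type (e.g. the derived lineage).
#' @param refs Character vector of the two reference cell types.
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2, i.e. |log2 FC| >= 1).
#' @param p_threshold Per-test significance threshold (default 0.05).
#' @param var_equal `FALSE` (default) for Welch's t-test, `TRUE` for
#'   Student's.
#' @param pooled_refs If `TRUE`, a single t-test of target vs the pooled
#'   reference replicates replaces the two per-reference tests.
#' @param adjust `"none"` (default) or `"BH"` (Benjamini-Hochberg across
#'   genes, per comparison).
#' @return A tibble with one row per gene: `gene`, `log2fc_vs_ref1`,
#'   `log2fc_vs_ref2` (target mean minus reference mean; a difference of
#'   log2 means is the log2 ratio of geometric means), `p_ref1`, `p_ref2`,
#'   `p_value` (the larger of the two, or the pooled p), `significant`,
#'   and `direction` (`"up"`, `"down"`, `"none"`; fold-change criterion
#'   only).
#' @export
call_de <- function(expression, design, target, refs, fc_threshold = 2,
                    p_threshold = 0.05, var_equal = FALSE,
                    pooled_refs = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold < 1,
            length(refs) == 2L)
  m <- expression_matrix(expression, design, c(target, refs))
  groups <- attr(m, "groups")
  for (ct in c(target, refs)) {
    if (length(groups[[ct]]) < 2L) {
      rlang::abort(sprintf("cell type '%s' has %d replicate(s); need >= 2",
                           ct, length(groups[[ct]])))
    }
  }
  lfc_thr <- log2(fc_threshold)
  tgt <- m[, groups[[target]], drop = FALSE]
  r1 <- m[, groups[[refs[1]]], drop = FALSE]
  r2 <- m[, groups[[refs[2]]], drop = FALSE]
  lfc1 <- rowMeans(tgt) - rowMeans(r1)
  lfc2 <- rowMeans(tgt) - rowMeans(r2)
  if (pooled_refs) {
    p1 <- row_t_test(tgt, cbind(r1, r2), var_equal)
    p2 <- p1
  } else {
    p1 <- row_t_test(tgt, r1, var_equal)
    p2 <- row_t_test(tgt, r2, var_equal)
  }
  if (adjust == "BH") {
    p1 <- stats::p.adjust(p1, "BH")
    p2 <- stats::p.adjust(p2, "BH")
  }
  p <- pmax(p1, p2)
  tibble::tibble(
    gene = rownames(m),
    log2fc_vs_ref1 = unname(lfc1),
    log2fc_vs_ref2 = unname(lfc2),
    p_ref1 = p1,
    p_ref2 = p2,
    p_value = p,
    significant = !is.na(p) & p < p_threshold,
    # inclusive "at least" boundary, robust to floating-point means
    direction = dplyr::case_when(
      lfc1 >= lfc_thr - 1e-9 & lfc2 >= lfc_thr - 1e-9 ~ "up",
      lfc1 <= -lfc_thr + 1e-9 & lfc2 <= -lfc_thr + 1e-9 ~ "down",
      TRUE ~ "none"
    )
  )
}

expression_matrix <- function(expression, design, cell_types) {
  expression <- tibble::as_tibble(expression)
  design <- tibble::as_tibble(design)
  stopifnot("gene" %in% names(expression),
            all(c("sample", "cell_type") %in% names(design)))
  missing_ct <- setdiff(cell_types, design$cell_type)
  if (length(missing_ct) > 0L) {
    rlang::abort(sprintf("cell type(s) not in design: %s",
                         paste(missing_ct, collapse = ", ")))
  }
  design <- design[design$cell_type %in% cell_types, ]
  missing_s <- setdiff(design$sample, names(expression))
  if (length(missing_s) > 0L) {
    rlang::abort(sprintf("design sample(s) absent from expression matrix: %s",
                         paste(missing_s, collapse = ", ")))
  }
  m <- as.matrix(expression[, design$sample, drop = FALSE])
  if (anyNA(m)) rlang::abort("expression matrix contains missing values")
  rownames(m) <- as.character(expression$gene)
  attr(m, "groups") <- split(design$sample, design$cell_type)
  m
}

# Per-row two-sided t-test p-values; constant rows (zero variance in both
# groups) yield NA rather than an error.
row_t_test <- function(a, b, var_equal) {
  vapply(seq_len(nrow(a)), function(i) {
    tryCatch(stats::t.test(a[i, ], b[i, ], var.equal = var_equal)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Binarize expression into per-cell-type Boolean states
#'
#' Bridges the expression matrix to the Boolean network stage: each gene
#' gets a 0/1 value per cell type, and the columns of the result are the
#' observed stable states handed to [prune_network()].
#'
#' * `midrange` (default): a gene is ON in a cell type iff its mean there
#'   exceeds the midpoint between its lowest and highest cell-type means
#'   (a tie, including constant genes, resolves to OFF).
#' * `reference_fold`: ON iff the mean is at least 2-fold (>= 1 on the
#'   log2 scale) above the lowest cell-type mean.
#'
#' @inheritParams call_de
#' @param genes Optional gene subset (e.g. the nodes of a prior network);
#'   an error lists any requested gene absent from the matrix.
#' @param method `"midrange"` or `"reference_fold"`.
#' @return A tibble: `gene` plus one 0/1 column per cell type.
#' @export
binarize_expression <- function(expression, design, genes = NULL,
                                method = c("midrange", "reference_fold")) {
  method <- match.arg(method)
  design <- tibble::as_tibble(design)
  cell_types <- unique(design$cell_type)
  m <- expression_matrix(expression, design, cell_types)
  groups <- attr(m, "groups")
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(m))
    if (length(absent) > 0L) {
      rlang::abort(sprintf("gene(s) absent from the expression matrix: %s",
                           paste(absent, collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  means <- vapply(cell_types, function(ct) {
    rowMeans(m[, groups[[ct]], drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) means <- matrix(means, nrow = 1L,
                                     dimnames = list(rownames(m), cell_types))
  lo <- apply(means, 1L, min)
  state <- if (method == "midrange") {
    hi <- apply(means, 1L, max)
    means > (lo + hi) / 2
  } else {
    means >= lo + 1
  }
  out <- tibble::as_tibble(as.data.frame(state * 1L))
  names(out) <- cell_types
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)), out)
}

#' Extract one cell type's Boolean state from a binarized table
#'
#' @param binarized Output of [binarize_expression()].
#' @param cell_type Column to extract.
#' @return A named 0/1 integer vector usable with [prune_network()].
#' @export
as_boolean_state <- function(binarized, cell_type) {
  stopifnot(cell_type %in% names(binarized))
  boolean_state(stats::setNames(binarized[[cell_type]], binarized$gene))
}
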