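# Deterministic TSV writer: numeric columns serialized at 6 significant
# digits so re-runs are byte-identical and outputs diff cleanly.
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                        formatC(signif(df[[j]], 6), format = "g",
                                digits = 6))
    }
  }
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0L) do.call(paste, c(df, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read pipeline input tables
#'
#' Plain tab-separated readers for the pipeline's external formats:
#' expression matrix (first column `gene`, header = sample ids), design
#' (`sample`, `cell_type`), per-cell-type CpG counts (`chrom`, `pos`,
#' `strand`, `meth_count`, `total_count`), and a BED6 TSS annotation
#' (`chrom`, `start`, `end`, `gene`, `score`, `strand`; no header). `#`
#' lines are comments throughout.
#'
#' @param path File path.
#' @return A tibble.
#' @name pipeline_readers
NULL

#' @rdname pipeline_readers
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(out)[1] <- "gene"
  out
}

#' @rdname pipeline_readers
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(sample = "c", cell_type = "c"))
}

#' @rdname pipeline_readers
#' @param cell_type Label attached to the rows (per-cell-type count files).
#' @export
read_methylation_tsv <- function(path, cell_type) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = "c", pos = "i", strand = "c",
                          meth_count = "i", total_count = "i"))
  df$cell_type <- cell_type
  df[, c("chrom", "pos", "strand", "cell_type", "meth_count", "total_count")]
}

#' @rdname pipeline_readers
#' @export
read_tss_bed <- function(path) {
  readr::read_tsv(path, comment = "#",
                  col_names = c("chrom", "start", "end", "gene", "score",
                                "strand"),
                  col_types = readr::cols(
                    chrom = "c", start = "i", end = "i", gene = "c",
                    score = "d", strand = "c"))
}

#' Write a BED6 TSS annotation
#'
#' @param tss Tibble with BED6 columns (see [read_tss_bed()]).
#' @param path Output path.
#' @export
write_tss_bed <- function(tss, path) {
  writeLines(paste(tss$chrom, tss$start, tss$end, tss$gene, tss$score,
                   tss$strand, sep = "\t"), path)
  invisible(path)
}

#' Run the full stability-core pipeline
#'
#' Executes the stages in order — differential expression, site filtering,
#' promoter methylation, differential methylation, integration, expression
#' binarization, and (when a prior network is supplied) contextualization —
#' writing each stage's table plus a JSON run manifest into `out_dir`.
#' The manifest records the package version, input checksums, the fully
#' resolved configuration (seed included) and per-stage record counts, and
#' suffices to re-run the pipeline identically: `run_pipeline(manifest$config)`
#' reproduces every output byte for byte (the manifest's timestamp aside).
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   elements:
#'   * `expression`, `design`: paths (TSV) or data frames;
#'   * `methylation`: named list/vector of per-cell-type CpG count TSV
#'     paths, or a long data frame with a `cell_type` column;
#'   * `tss`: BED6 path or data frame;
#'   * `network`: optional prior SIF path or [signed_network()];
#'   * `target`, `refs`: the target cell type and its two references;
#'   * optional thresholds `fc_threshold` (2), `p_threshold` (0.05),
#'     `min_cov` (10), `window_bp` (1000), `delta` (0.05),
#'     `binarize_method` ("midrange"), `seed` (1), and `pruning` (a list of
#'     [pruning_config()] overrides);
#'   * `out_dir`: output directory.
#' @param out_dir Overrides `config$out_dir`.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) rlang::abort("config must name an output directory")
  for (field in c("expression", "design", "methylation", "tss", "target",
                  "refs")) {
    if (is.null(config[[field]])) {
      rlang::abort(sprintf("config is missing required field '%s'", field))
    }
  }
  if (length(config$refs) != 2L) rlang::abort("config$refs must name 2 cell types")
  defaults <- list(fc_threshold = 2, p_threshold = 0.05, min_cov = 10L,
                   window_bp = 1000L, delta = 0.05,
                   binarize_method = "midrange", seed = 1L, pruning = list())
  for (nm in names(defaults)) {
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  checksums <- list()
  load_table <- function(x, reader, label) {
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) {
        rlang::abort(sprintf("input file for '%s' not found: %s", label, x))
      }
      checksums[[label]] <<- unname(tools::md5sum(x))
      reader(x)
    } else {
      tibble::as_tibble(x)
    }
  }

  expression <- load_table(config$expression, read_expression_tsv, "expression")
  design <- load_table(config$design, read_design_tsv, "design")
  meth <- config$methylation
  sites_raw <- if (is.data.frame(meth)) {
    tibble::as_tibble(meth)
  } else {
    purrr::imap_dfr(as.list(meth), function(p, ct) {
      load_table(p, function(q) read_methylation_tsv(q, ct),
                 paste0("methylation_", ct))
    })
  }
  tss <- load_table(config$tss, read_tss_bed, "tss")
  network <- NULL
  if (!is.null(config$network)) {
    network <- if (inherits(config$network, "signed_network")) config$network
               else load_table(config$network, read_signed_network, "network")
  }

  counts <- list(genes_in = nrow(expression), sites_in = nrow(sites_raw))

  de <- call_de(expression, design, config$target, config$refs,
                fc_threshold = config$fc_threshold,
                p_threshold = config$p_threshold)
  counts$de_up <- sum(de$direction == "up")
  counts$de_down <- sum(de$direction == "down")
  write_tsv_plain(de, file.path(out_dir, "de_calls.tsv"))

  sites <- site_methylation(sites_raw, min_cov = config$min_cov)
  counts$sites_covered <- length(unique(paste(sites$chrom, sites$pos)))
  pm <- promoter_methylation(sites, tss, window_bp = config$window_bp)
  counts$promoters_defined <-
    sum(tapply(!is.na(pm$mean_mcpg), pm$gene, all))
  write_tsv_plain(pm, file.path(out_dir, "promoter_methylation.tsv"))

  dm <- call_differential_methylation(pm, config$target, config$refs,
                                      delta = config$delta)
  counts$meth_hyper <- sum(dm$status == "hyper")
  counts$meth_hypo <- sum(dm$status == "hypo")
  counts$meth_skipped <- length(attr(dm, "skipped"))
  write_tsv_plain(dm, file.path(out_dir, "dm_calls.tsv"))

  integrated <- integrate_meth_expression(dm, de)
  counts$integrated <- sum(integrated$category == "demethylated_upregulated")
  write_tsv_plain(integrated, file.path(out_dir, "integrated.tsv"))

  net_genes <- if (!is.null(network)) {
    intersect(network_nodes(network), expression$gene)
  } else NULL
  binarized <- binarize_expression(expression, design, genes = net_genes,
                                   method = config$binarize_method)
  write_tsv_plain(binarized, file.path(out_dir, "binarized_states.tsv"))

  ctx <- NULL
  if (!is.null(network)) {
    absent <- setdiff(network_nodes(network), expression$gene)
    if (length(absent) > 0L) {
      rlang::abort(sprintf(
        "network gene(s) absent from the expression matrix: %s",
        paste(absent, collapse = ", ")))
    }
    cfg <- do.call(pruning_config,
                   utils::modifyList(list(seed = config$seed), config$pruning))
    ctx <- prune_network(network,
                         as_boolean_state(binarized, config$target),
                         as_boolean_state(binarized, config$refs[1]),
                         config = cfg)
    counts$core_genes <- nrow(ctx$core)
    write_signed_network(ctx$best_network,
                         file.path(out_dir, "best_network.sif"))
    write_tsv_plain(ctx$core, file.path(out_dir, "stability_core.tsv"))
    write_tsv_plain(tidy(ctx$attractors), file.path(out_dir, "attractors.tsv"))
    write_tsv_plain(ctx$fitness_trace, file.path(out_dir, "fitness_trace.tsv"))
  }

  manifest <- list(
    tool = "stabilitycore",
    version = as.character(utils::packageVersion("stabilitycore")),
    timestamp = format(Sys.time(), tz = "UTC"),
    input_checksums = checksums,
    config = config[setdiff(names(config), "out_dir")],
    out_dir = out_dir,
    counts = counts
  )
  # data-frame inputs cannot be echoed into a small manifest; record paths only
  manifest$config <- purrr::map(manifest$config, function(x) {
    if (is.data.frame(x) || inherits(x, "signed_network")) "<in-memory>" else x
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(de = de, sites = sites, promoter_methylation = pm,
                 dm = dm, integrated = integrated, binarized = binarized,
                 contextualization = ctx, manifest = manifest))
}
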