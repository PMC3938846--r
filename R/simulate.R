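#' Simulate a log2 expression matrix with planted lineage modules
#'
#' Emulates the study design the package targets: three cell types (a
#' target lineage contrasted with two references) measured in biological
#' triplicate on a normalized log2 scale. Each gene draws a baseline level
#' from `Normal(baseline_mean, baseline_sd)`; genes belonging to a planted
#' module are shifted by the module's signed log2 effect in its target
#' cell type; every sample adds independent `Normal(0, noise_sd)` noise.
#' The default conditions — 3 x 3 design, sd 0.25 noise on the log2 scale,
#' and 2 log2-unit (four-fold) planted effects — represent a clean
#' microarray triplicate experiment with clear lineage modules.
#'
#' @param n_genes Number of genes.
#' @param cell_types Cell-type labels; the last is conventionally the
#'   target lineage.
#' @param replicates Replicates per cell type.
#' @param modules Data frame of planted modules with columns `n_genes`,
#'   `log2_effect` (signed), `cell_type`. Genes are assigned to modules
#'   from the front of the gene list, disjointly.
#' @param noise_sd Per-sample Gaussian noise sd (log2 scale).
#' @param baseline_mean,baseline_sd Baseline level distribution.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list: `expression` (tibble, `gene` + one column per sample),
#'   `design` (tibble `sample`, `cell_type`), `truth` (tibble `gene`,
#'   `cell_type`, `direction` with `"none"` for background genes).
#' @export
simulate_expression <- function(n_genes = 1000L,
                                cell_types = c("hESC", "hNSC", "hCM"),
                                replicates = 3L,
                                modules = data.frame(
                                  n_genes = c(30L, 20L),
                                  log2_effect = c(2, -2),
                                  cell_type = c("hCM", "hCM")),
                                noise_sd = 0.25,
                                baseline_mean = 7, baseline_sd = 1.2,
                                seed = 1L) {
  modules <- tibble::as_tibble(modules)
  stopifnot(noise_sd >= 0, sum(modules$n_genes) <= n_genes,
            all(modules$cell_type %in% cell_types))
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- as.vector(vapply(cell_types, function(ct) {
    paste0(ct, "_", seq_len(replicates))
  }, character(replicates)))
  design <- tibble::tibble(
    sample = samples,
    cell_type = rep(cell_types, each = replicates))

  effect <- matrix(0, nrow = n_genes, ncol = length(cell_types),
                   dimnames = list(genes, cell_types))
  truth_dir <- rep("none", n_genes)
  truth_ct <- rep(NA_character_, n_genes)
  at <- 1L
  for (i in seq_len(nrow(modules))) {
    idx <- seq.int(at, length.out = modules$n_genes[i])
    effect[idx, modules$cell_type[i]] <- modules$log2_effect[i]
    truth_dir[idx] <- if (modules$log2_effect[i] > 0) "up" else "down"
    truth_ct[idx] <- modules$cell_type[i]
    at <- at + modules$n_genes[i]
  }

  mat <- withr::with_seed(seed, {
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    vals <- baseline + effect[, design$cell_type] +
      matrix(stats::rnorm(n_genes * nrow(design), 0, noise_sd),
             nrow = n_genes)
    colnames(vals) <- design$sample
    vals
  })
  list(
    expression = dplyr::bind_cols(tibble::tibble(gene = genes),
                                  tibble::as_tibble(mat)),
    design = design,
    truth = tibble::tibble(gene = genes, cell_type = truth_ct,
                           direction = truth_dir)
  )
}

default_class_levels <- function(cell_types) {
  stopifnot(length(cell_types) == 3L)
  out <- tibble::tibble(class = c("structural", "tf", "background"))
  lv <- rbind(c(0.80, 0.80, 0.10),   # hypermethylated except in the target
              c(0.05, 0.05, 0.05),   # low everywhere (TF-like)
              c(0.45, 0.45, 0.45))   # unremarkable midrange
  for (i in seq_along(cell_types)) out[[cell_types[i]]] <- lv[, i]
  out
}

#' Simulate per-CpG methylation count tables with a TSS annotation
#'
#' Places promoters on one synthetic chromosome, spaced `spacing_bp` apart
#' so promoter windows never overlap, and draws per-CpG counts per cell
#' type: coverage from an over-dispersed negative binomial (bisulfite
#' capture depth varies strongly between sites), methylated counts from
#' `Binomial(coverage, class level)`. A configurable fraction of sites is
#' drawn at low coverage to exercise the joint 10x filter. Gene classes
#' emulate the promoter dichotomy of lineage-specific genes: `structural`
#' (hypermethylated in the references, demethylated in the target), `tf`
#' (low everywhere) and `background` (midrange everywhere); levels are
#' overridable per class and cell type.
#'
#' @param classes Either a named integer vector of gene counts per class
#'   (e.g. `c(structural = 8, tf = 7, background = 15)`) or a data frame
#'   with columns `gene`, `class` assigning specific gene identifiers.
#' @param class_levels Data frame: column `class` plus one column of
#'   methylation levels in `[0, 1]` per cell type. Defaults to the
#'   dichotomy above for a 3-type design.
#' @param cell_types Cell-type labels (last = target lineage).
#' @param cpg_per_promoter Poisson mean number of CpGs per promoter
#'   (at least 1 CpG is always placed).
#' @param coverage_mean,coverage_dispersion Negative-binomial depth
#'   (mu/size parameterization).
#' @param low_coverage_fraction Fraction of sites drawn at
#'   `low_coverage_mean` depth instead.
#' @param low_coverage_mean Mean depth of the under-covered sites.
#' @param window_bp CpGs are placed uniformly within this distance of the
#'   TSS.
#' @param spacing_bp Distance between consecutive TSSs (>= 3 kb keeps
#'   truth labels unambiguous).
#' @param exact_counts If `TRUE`, methylated counts are `round(level *
#'   coverage)` instead of binomial draws — a noise-free mode for
#'   threshold tests.
#' @param seed Integer seed.
#' @return A list: `sites` (long tibble `chrom`, `pos`, `strand`,
#'   `cell_type`, `meth_count`, `total_count`), `tss` (BED6 tibble),
#'   `truth` (tibble `gene`, `class` plus the class levels per cell type).
#' @export
simulate_methylation <- function(classes = c(structural = 8L, tf = 7L,
                                             background = 15L),
                                 class_levels = NULL,
                                 cell_types = c("hESC", "hNSC", "hCM"),
                                 cpg_per_promoter = 12,
                                 coverage_mean = 30, coverage_dispersion = 5,
                                 low_coverage_fraction = 0.1,
                                 low_coverage_mean = 4,
                                 window_bp = 900L, spacing_bp = 3000L,
                                 exact_counts = FALSE, seed = 1L) {
  if (is.null(class_levels)) class_levels <- default_class_levels(cell_types)
  class_levels <- tibble::as_tibble(class_levels)
  stopifnot(all(cell_types %in% names(class_levels)),
            all(as.matrix(class_levels[, cell_types]) >= 0),
            all(as.matrix(class_levels[, cell_types]) <= 1),
            coverage_mean >= 1, spacing_bp > 2L * window_bp)
  if (is.data.frame(classes)) {
    assign_df <- tibble::as_tibble(classes)
    stopifnot(all(c("gene", "class") %in% names(assign_df)))
  } else {
    assign_df <- tibble::tibble(
      gene = sprintf("m%04d", seq_len(sum(classes))),
      class = rep(names(classes), classes))
  }
  stopifnot(all(assign_df$class %in% class_levels$class))
  n_genes <- nrow(assign_df)

  tss_pos <- 1500L + (seq_len(n_genes) - 1L) * spacing_bp
  strand <- rep(c("+", "-"), length.out = n_genes)
  tss <- tibble::tibble(chrom = "chrS",
                        start = tss_pos, end = tss_pos + 1L,
                        gene = assign_df$gene, score = 0L, strand = strand)

  levels_by_class <- class_levels[match(assign_df$class, class_levels$class),
                                  cell_types]
  sites <- withr::with_seed(seed, {
    n_cpg <- pmax(1L, stats::rpois(n_genes, cpg_per_promoter))
    gene_idx <- rep(seq_len(n_genes), n_cpg)
    pos <- tss_pos[gene_idx] +
      round(stats::runif(sum(n_cpg), -window_bp, window_bp))
    # collapse accidental duplicates at the same coordinate
    keep <- !duplicated(pos)
    gene_idx <- gene_idx[keep]
    pos <- pos[keep]
    n_sites <- length(pos)
    purrr::map_dfr(cell_types, function(ct) {
      low <- stats::runif(n_sites) < low_coverage_fraction
      cov <- ifelse(
        low,
        stats::rnbinom(n_sites, mu = low_coverage_mean,
                       size = coverage_dispersion),
        stats::rnbinom(n_sites, mu = coverage_mean,
                       size = coverage_dispersion))
      cov <- pmax(1L, cov)
      lev <- levels_by_class[[ct]][gene_idx]
      meth <- if (exact_counts) round(lev * cov)
              else stats::rbinom(n_sites, cov, lev)
      tibble::tibble(chrom = "chrS", pos = pos, strand = "+",
                     cell_type = ct, meth_count = as.integer(meth),
                     total_count = as.integer(cov))
    })
  })
  truth <- dplyr::bind_cols(assign_df, levels_by_class)
  list(sites = dplyr::arrange(sites, .data$cell_type, .data$pos),
       tss = tss, truth = truth)
}

#' Simulate a prior signed network with a planted consistent core
#'
#' Builds the benchmark used to validate [prune_network()]: a planted
#' "true" network whose stability core is known, buried inside a prior
#' containing spurious interactions whose removal is required for
#' consistency.
#'
#' The planted core consists of disjoint positive activation circuits
#' (default two 3-gene cycles, mirroring a two-component stability core at
#' toy scale). Peripheral genes hang off the core through activation
#' chains. The two observed states set circuit 1 ON with circuit 2 OFF,
#' and vice versa; peripheral genes follow their upstream regulator.
#' Spurious edges are inhibitions planted WITHIN a circuit (alternating
#' between circuits): such an edge breaks the all-ON state of its circuit,
#' so every spurious edge must be pruned before both observed states are
#' fixed points. (Inhibitions BETWEEN the two circuits would be harmless
#' under these anti-correlated states — the inhibitor and its target are
#' never simultaneously active — and could not serve as planted noise.)
#'
#' The generator verifies its own guarantee with the package's attractor
#' machinery: the planted network must hold both observed states as fixed
#' points, and the full prior must not.
#'
#' @param circuit_sizes Integer vector of planted circuit lengths
#'   (default `c(3, 3)`).
#' @param n_peripheral Number of peripheral chain genes.
#' @param n_spurious Number of spurious intra-circuit inhibitions
#'   (alternating circuits; each circuit of length `k` offers
#'   `k * (k - 1) - k` non-cycle ordered pairs plus the parallel pairs).
#' @param seed Integer seed.
#' @param max_tries Re-draw attempts before giving up.
#' @return A list: `prior` ([signed_network()]), `truth_edges` (tibble
#'   `source`, `target`, `sign`, `role` in `{"core", "peripheral",
#'   "spurious"}`), `core_genes` (character), `core_components` (list of
#'   character vectors), `state_a`, `state_b` (named 0/1 vectors).
#' @export
simulate_prior_network <- function(circuit_sizes = c(3L, 3L),
                                   n_peripheral = 2L, n_spurious = 4L,
                                   seed = 1L, max_tries = 20L) {
  stopifnot(length(circuit_sizes) >= 1L, all(circuit_sizes >= 2L),
            n_peripheral >= 0L, n_spurious >= 0L)
  for (try in seq_len(max_tries)) {
    out <- withr::with_seed(seed + (try - 1L) * 1000L, {
      build_planted_prior(circuit_sizes, n_peripheral, n_spurious)
    })
    clean <- signed_network(out$truth_edges[out$truth_edges$role != "spurious", ],
                            nodes = out$nodes)
    prior <- signed_network(out$truth_edges, nodes = out$nodes)
    clean_ok <- is_fixed_point(clean, out$state_a) &&
      is_fixed_point(clean, out$state_b)
    prior_bad <- n_spurious == 0L ||
      !(is_fixed_point(prior, out$state_a) && is_fixed_point(prior, out$state_b))
    if (clean_ok && prior_bad) {
      return(list(prior = prior,
                  truth_edges = out$truth_edges,
                  core_genes = out$core_genes,
                  core_components = out$core_components,
                  state_a = out$state_a, state_b = out$state_b))
    }
  }
  rlang::abort("failed to generate a verified planted prior network")
}

is_fixed_point <- function(net, state) {
  all(synchronous_step(net, state) == check_state(net, state))
}

build_planted_prior <- function(circuit_sizes, n_peripheral, n_spurious) {
  n_circ <- length(circuit_sizes)
  circ_genes <- lapply(seq_len(n_circ), function(i) {
    sprintf("c%dg%d", i, seq_len(circuit_sizes[i]))
  })
  periph <- if (n_peripheral > 0L) sprintf("p%d", seq_len(n_peripheral))
            else character()
  nodes <- c(unlist(circ_genes), periph)

  core_edges <- purrr::map_dfr(circ_genes, function(g) {
    k <- length(g)
    tibble::tibble(source = g, target = g[c(seq_len(k)[-1], 1L)],
                   sign = 1L, role = "core")
  })
  # peripheral chain: p1 <- first gene of circuit 1, p2 <- p1, ...
  periph_edges <- NULL
  if (n_peripheral > 0L) {
    src <- c(circ_genes[[1]][1], periph[-length(periph)])
    periph_edges <- tibble::tibble(source = src, target = periph,
                                   sign = 1L, role = "peripheral")
  }
  # spurious intra-circuit inhibitions, alternating circuits
  spur <- NULL
  if (n_spurious > 0L) {
    pool <- purrr::map_dfr(seq_len(n_circ), function(i) {
      g <- circ_genes[[i]]
      pairs <- expand.grid(source = g, target = g, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$source != pairs$target, ]
      pairs$circuit <- i
      pairs
    })
    picks <- integer()
    by_circ <- split(seq_len(nrow(pool)), pool$circuit)
    avail <- lapply(by_circ, function(ix) sample(ix))
    ci <- 1L
    while (length(picks) < n_spurious) {
      have <- length(avail) ; found <- FALSE
      for (k in seq_len(have)) {
        j <- ((ci - 1L + k - 1L) %% have) + 1L
        if (length(avail[[j]]) > 0L) {
          picks <- c(picks, avail[[j]][1])
          avail[[j]] <- avail[[j]][-1]
          ci <- j + 1L
          found <- TRUE
          break
        }
      }
      if (!found) rlang::abort("n_spurious exceeds available intra-circuit pairs")
    }
    spur <- tibble::tibble(source = pool$source[picks],
                           target = pool$target[picks],
                           sign = -1L, role = "spurious")
  }
  truth_edges <- dplyr::bind_rows(core_edges, periph_edges, spur)

  # observed states: circuit 1 ON / others OFF, and the complement pattern
  on_a <- circ_genes[[1]]
  state_a <- stats::setNames(as.integer(nodes %in% on_a), nodes)
  on_b <- unlist(circ_genes[-1])
  state_b <- stats::setNames(as.integer(nodes %in% on_b), nodes)
  # peripheral genes copy their (unique) activator's value at the fixed point
  if (n_peripheral > 0L) {
    for (i in seq_along(periph)) {
      src <- periph_edges$source[i]
      state_a[periph[i]] <- state_a[[src]]
      state_b[periph[i]] <- state_b[[src]]
    }
  }
  list(truth_edges = truth_edges, nodes = nodes,
       core_genes = sort(unlist(circ_genes)),
       core_components = lapply(circ_genes, sort),
       state_a = state_a, state_b = state_b)
}
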