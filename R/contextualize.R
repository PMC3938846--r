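#' Consistency between a network's attractors and two observed stable states
#'
#' Measures how well the attractor landscape of the synchronous dynamics
#' supports two experimentally observed stable expression states (e.g. the
#' binarized profiles of two cell types). For each observed state the
#' best-matching attractor is found over the exhaustive attractor set and
#' scored by per-gene agreement:
#'
#' * a fixed point is compared gene by gene (credit 1 per agreeing gene);
#' * a cyclic attractor is compared through each gene's time-average over
#'   the cycle. A gene constant across the cycle earns full credit when it
#'   matches; an oscillating gene is not reliably in any state, so it earns
#'   at most half credit — 0.5 when its average rounds to (or ties at 0.5
#'   with) the observed value, 0 otherwise.
#'
#' The score is the mean over the two states of the best agreement
#' fraction. It equals 1 exactly when both observed states are fixed
#' points of the network.
#'
#' @param net A [signed_network()] (small enough for exhaustive attractor
#'   computation).
#' @param state_a,state_b Observed Boolean states, named 0/1 vectors over
#'   the network's genes.
#' @param rule Update rule; see [update_rules].
#' @param max_nodes_exhaustive Cap forwarded to [find_attractors()].
#' @return A single number in `[0, 1]`.
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B"), target = c("B", "A"), sign = 1))
#' consistency_score(net, c(A = 0, B = 0), c(A = 1, B = 1))  # 1
#' @export
consistency_score <- function(net, state_a, state_b, rule = "genysis",
                              max_nodes_exhaustive = 20L) {
  atts <- find_attractors(net, "exhaustive",
                          max_nodes_exhaustive = max_nodes_exhaustive,
                          rule = rule)
  sa <- check_state(net, boolean_state(state_a), "state_a")
  sb <- check_state(net, boolean_state(state_b), "state_b")
  (best_agreement(atts, sa) + best_agreement(atts, sb)) / 2
}

best_agreement <- function(atts, state) {
  nodes <- atts$nodes
  obs <- as.integer(state[nodes])
  max(vapply(atts$attractors, function(a) {
    mat <- vapply(a$states, decode_state, integer(length(nodes)),
                  nodes = nodes)
    if (a$length == 1L) {
      return(mean(mat[, 1] == obs))
    }
    avg <- rowMeans(mat)
    constant <- avg == 0 | avg == 1
    credit <- numeric(length(nodes))
    credit[constant] <- as.numeric(avg[constant] == obs[constant])
    osc <- !constant
    credit[osc] <- ifelse(avg[osc] == 0.5, 0.5,
                          ifelse(round(avg[osc]) == obs[osc], 0.5, 0))
    mean(credit)
  }, numeric(1)))
}

#' Configuration of the evolutionary pruning loop
#'
#' Hyperparameters of the estimation-of-distribution pruning in
#' [prune_network()]. Defaults converge in seconds on priors of up to
#' ~15 genes and are all overridable.
#'
#' @param population_size Individuals (candidate pruned networks) per
#'   generation (>= 2).
#' @param elite_fraction Fraction of the population, ranked by fitness,
#'   used to estimate the next generation's sampling distribution.
#' @param generations Number of resampling iterations after generation 0.
#' @param circuit_weight Mixing weight in `[0, 1]` between circuit-level
#'   and edge-level inclusion frequencies when resampling (see
#'   [prune_network()]).
#' @param init_keep_prob Probability an edge is kept in generation 0.
#' @param min_keep_prob,max_keep_prob Clamps on sampled keep probabilities,
#'   keeping every edge reachable (no probability collapses to 0 or 1).
#' @param seed Integer seed; same seed and inputs give identical results.
#' @param stop_on_perfect Stop as soon as the best individual reaches
#'   consistency 1.
#' @return A `pruning_config` list.
#' @export
pruning_config <- function(population_size = 100L, elite_fraction = 0.2,
                           generations = 50L, circuit_weight = 0.5,
                           init_keep_prob = 0.5, min_keep_prob = 0.02,
                           max_keep_prob = 0.98, seed = 1L,
                           stop_on_perfect = TRUE) {
  cfg <- list(population_size = as.integer(population_size),
              elite_fraction = elite_fraction,
              generations = as.integer(generations),
              circuit_weight = circuit_weight,
              init_keep_prob = init_keep_prob,
              min_keep_prob = min_keep_prob,
              max_keep_prob = max_keep_prob,
              seed = as.integer(seed),
              stop_on_perfect = isTRUE(stop_on_perfect))
  stopifnot(cfg$population_size >= 2L,
            cfg$elite_fraction > 0, cfg$elite_fraction <= 1,
            cfg$generations >= 0L,
            cfg$circuit_weight >= 0, cfg$circuit_weight <= 1,
            cfg$min_keep_prob >= 0,
            cfg$min_keep_prob <= cfg$max_keep_prob,
            cfg$max_keep_prob <= 1)
  structure(cfg, class = "pruning_config")
}

#' Contextualize a prior network by evolutionary pruning
#'
#' Prunes a literature-derived signed network so that its synchronous
#' attractors contain two observed stable cell states, using an
#' estimation-of-distribution algorithm (EDA):
#'
#' 1. Generation 0 keeps each edge independently with `init_keep_prob`.
#' 2. Each candidate subnetwork is scored by [consistency_score()]; ties
#'    are broken in favour of the candidate retaining MORE prior edges
#'    (contextualization should discard as little prior knowledge as the
#'    stability constraint allows).
#' 3. The top `elite_fraction` of the population is selected.
#' 4. Over the elites, the inclusion frequency of every positive circuit
#'    of the prior (all of its edges kept) and of every individual edge is
#'    estimated.
#' 5. The next generation keeps each edge with probability
#'    `circuit_weight * max(frequency of positive circuits through it) +
#'    (1 - circuit_weight) * edge frequency`, clamped to
#'    `[min_keep_prob, max_keep_prob]`. Edges lying on no positive circuit
#'    use their edge frequency alone. Taking the max over circuits favours
#'    keeping positive feedback circuits intact, the structures required
#'    for multistationarity.
#' 6. The loop stops after `generations` iterations, or earlier when
#'    `stop_on_perfect` and the best candidate reaches consistency 1.
#'
#' The best candidate ever seen is returned with its attractors, its
#' stability core, and the per-generation fitness trace.
#'
#' @param prior A [signed_network()] with at least one edge, small enough
#'   for exhaustive attractor computation.
#' @param state_a,state_b Observed stable states (named 0/1 vectors over
#'   the prior's genes), e.g. from [binarize_expression()].
#' @param config A [pruning_config()].
#' @param rule Update rule; see [update_rules].
#' @return A `contextualization` object with elements `best_network`,
#'   `best_fitness`, `attractors`, `core` (tibble from [stability_core()]),
#'   `fitness_trace` (tibble: `generation`, `best`, `mean`), `edges`
#'   (prior edges flagged `kept`), and `config`. See
#'   [tidy.contextualization()], [glance.contextualization()],
#'   [autoplot.contextualization()].
#' @export
prune_network <- function(prior, state_a, state_b, config = pruning_config(),
                          rule = "genysis") {
  stopifnot(inherits(prior, "signed_network"), inherits(config, "pruning_config"))
  if (nrow(prior) == 0L) rlang::abort("prior network has no edges to prune")
  sa <- check_state(prior, boolean_state(state_a), "state_a")
  sb <- check_state(prior, boolean_state(state_b), "state_b")
  n_edges <- nrow(prior)

  # positive circuits of the prior, as edge-row index sets
  pos <- positive_circuits(enumerate_elementary_circuits(prior))
  circuit_edges <- purrr::map(seq_len(nrow(pos)), function(i) {
    circuit_edge_rows(prior, pos$nodes[i], pos$edge_signs[i])
  })
  edge_in_circuit <- lapply(seq_len(n_edges), function(e) {
    which(vapply(circuit_edges, function(ce) e %in% ce, logical(1)))
  })

  score_cache <- new.env(parent = emptyenv())
  score_mask <- function(mask) {
    key <- rawToChar(as.raw(44L + mask))
    hit <- score_cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- consistency_score(keep_edges(prior, mask), sa, sb, rule = rule)
    score_cache[[key]] <- val
    val
  }

  withr::with_seed(config$seed, {
    pop <- matrix(stats::runif(config$population_size * n_edges) <
                    config$init_keep_prob,
                  nrow = config$population_size)
    n_elite <- max(1L, ceiling(config$elite_fraction * config$population_size))
    best <- list(fitness = -1, kept = -1L, mask = NULL)
    trace <- vector("list", config$generations + 1L)

    for (gen in 0:config$generations) {
      fitness <- apply(pop, 1L, score_mask)
      kept <- rowSums(pop)
      ord <- order(-fitness, -kept)
      top <- ord[1L]
      if (fitness[top] > best$fitness ||
          (fitness[top] == best$fitness && kept[top] > best$kept)) {
        best <- list(fitness = fitness[top], kept = kept[top],
                     mask = pop[top, ])
      }
      trace[[gen + 1L]] <- tibble::tibble(generation = gen,
                                          best = best$fitness,
                                          mean = mean(fitness))
      if (gen == config$generations) break
      if (config$stop_on_perfect && best$fitness >= 1) break
      elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      edge_freq <- colMeans(elites)
      circ_freq <- vapply(circuit_edges, function(ce) {
        mean(apply(elites[, ce, drop = FALSE], 1L, all))
      }, numeric(1))
      p <- vapply(seq_len(n_edges), function(e) {
        cs <- edge_in_circuit[[e]]
        if (length(cs) == 0L) {
          edge_freq[e]
        } else {
          config$circuit_weight * max(circ_freq[cs]) +
            (1 - config$circuit_weight) * edge_freq[e]
        }
      }, numeric(1))
      p <- pmin(pmax(p, config$min_keep_prob), config$max_keep_prob)
      pop <- matrix(stats::runif(config$population_size * n_edges) <
                      rep(p, each = config$population_size),
                    nrow = config$population_size)
    }
  })

  best_net <- keep_edges(prior, best$mask)
  edges <- tibble::as_tibble(as.data.frame(prior))
  edges$kept <- best$mask
  structure(list(
    best_network = best_net,
    best_fitness = best$fitness,
    attractors = find_attractors(best_net, "exhaustive", rule = rule),
    core = stability_core(best_net),
    fitness_trace = dplyr::bind_rows(trace[!vapply(trace, is.null, logical(1))]),
    edges = edges,
    config = config,
    rule = rule
  ), class = "contextualization")
}

# Map a circuit (pipe-joined genes + aligned edge signs) back to the row
# indices of the network's edge table.
circuit_edge_rows <- function(net, nodes_str, signs_str) {
  genes <- strsplit(nodes_str, "|", fixed = TRUE)[[1]]
  signs <- ifelse(strsplit(signs_str, "|", fixed = TRUE)[[1]] == "+", 1L, -1L)
  k <- length(genes)
  to <- genes[c(seq_len(k)[-1], 1L)]
  if (k == 1L) to <- genes
  vapply(seq_len(k), function(i) {
    which(net$source == genes[i] & net$target == to[i] & net$sign == signs[i])
  }, integer(1))
}

#' @export
print.contextualization <- function(x, ...) {
  cat(sprintf("# Contextualized network: consistency %.4f, %d/%d prior edges kept\n",
              x$best_fitness, sum(x$edges$kept), nrow(x$edges)))
  nc <- if (nrow(x$core) > 0L) length(unique(x$core$component)) else 0L
  cat(sprintf("# Stability core: %d gene(s) in %d strongly connected component(s)\n",
              nrow(x$core), nc))
  invisible(x)
}

#' Tidy the fitness trace of a contextualization
#'
#' @param x A `contextualization` from [prune_network()].
#' @param ... Unused.
#' @return Tibble with columns `generation`, `best` (best-ever
#'   consistency), `mean` (population mean consistency).
#' @export
tidy.contextualization <- function(x, ...) x$fitness_trace

#' One-row summary of a contextualization
#'
#' @inheritParams tidy.contextualization
#' @return One-row tibble: `best_fitness`, `edges_prior`, `edges_kept`,
#'   `core_genes`, `core_components`, `n_attractors`, `generations_run`.
#' @export
glance.contextualization <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    edges_prior = nrow(x$edges),
    edges_kept = sum(x$edges$kept),
    core_genes = nrow(x$core),
    core_components = if (nrow(x$core) > 0L) length(unique(x$core$component)) else 0L,
    n_attractors = length(x$attractors$attractors),
    generations_run = max(x$fitness_trace$generation)
  )
}

#' Plot the fitness trace of a contextualization
#'
#' @param object A `contextualization` from [prune_network()].
#' @param ... Unused.
#' @return A ggplot: best-ever and mean population consistency per
#'   generation.
#' @export
autoplot.contextualization <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fitness_trace, c("best", "mean"),
                            names_to = "series", values_to = "consistency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation,
                                   y = .data$consistency,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = "consistency with observed states",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
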