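test_that("consistency score is 1 exactly when both observed states are fixed points", {
  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  expect_equal(consistency_score(mut, c(A = 0, B = 0), c(A = 1, B = 1)), 1)

  iso <- signed_network(nodes = c("A", "B", "C"))
  expect_equal(consistency_score(iso, c(A = 1, B = 0, C = 1),
                                 c(A = 0, B = 1, C = 0)), 1)

  # single 4-cycle attractor, both genes average 0.5 -> tie credit
  negfb <- signed_network(data.frame(source = c("A", "B"),
                                     target = c("B", "A"),
                                     sign = c(1, -1)))
  expect_equal(consistency_score(negfb, c(A = 1, B = 0), c(A = 0, B = 1)),
               0.5)

  # one observed state stable, the other not
  expect_equal(consistency_score(mut, c(A = 0, B = 0), c(A = 1, B = 0)),
               0.75)
})

test_that("score 1 implies fixed points on random networks (cross-check)", {
  withr::local_seed(91)
  n_perfect <- 0L
  for (i in 1:40) {
    n <- sample(2:6, 1)
    net <- random_signed_network(n, sample(2:(2 * n), 1))
    nodes <- network_nodes(net)
    sa <- decode_state(sample(0:(2^n - 1), 1), nodes)
    sb <- decode_state(sample(0:(2^n - 1), 1), nodes)
    sc <- consistency_score(net, sa, sb)
    expect_gte(sc, 0)
    expect_lte(sc, 1)
    fp <- fixed_point_codes(net)
    both_fixed <- encode_state(sa, nodes) %in% fp &&
      encode_state(sb, nodes) %in% fp
    expect_equal(sc == 1, both_fixed)
    if (both_fixed) n_perfect <- n_perfect + 1L
  }
  expect_gte(n_perfect, 1L)  # the check must have been exercised both ways
})

test_that("consistency rejects oversized networks and foreign states", {
  withr::local_seed(3)
  net <- random_signed_network(8, 10)
  expect_error(consistency_score(net, decode_state(0, network_nodes(net)),
                                 decode_state(1, network_nodes(net)),
                                 max_nodes_exhaustive = 4L),
               "sampled")
  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  expect_error(consistency_score(mut, c(A = 1, X = 0), c(A = 0, B = 0)),
               "X")
})

test_that("an already-consistent prior scores 1 at generation 0 and keeps all edges", {
  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  ctx <- prune_network(mut, c(A = 0, B = 0), c(A = 1, B = 1),
                       pruning_config(population_size = 30, generations = 10,
                                      init_keep_prob = 0.9, seed = 4))
  expect_equal(ctx$best_fitness, 1)
  expect_equal(ctx$fitness_trace$generation[nrow(ctx$fitness_trace)], 0L)
  # maximal retention: no edge of the consistent prior is discarded
  expect_true(all(ctx$edges$kept))
  expect_equal(nrow(ctx$best_network), 2L)
})

test_that("generations = 0 evaluates only the initial population", {
  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  ctx <- prune_network(mut, c(A = 1, B = 0), c(A = 0, B = 1),
                       pruning_config(population_size = 10, generations = 0,
                                      seed = 9))
  expect_equal(nrow(ctx$fitness_trace), 1L)
  expect_equal(ctx$fitness_trace$generation, 0L)
})

test_that("pruning never adds edges and an empty prior errors", {
  sp <- simulate_prior_network(seed = 8)
  ctx <- prune_network(sp$prior, sp$state_a, sp$state_b,
                       pruning_config(population_size = 20, generations = 5,
                                      seed = 2, stop_on_perfect = FALSE))
  prior_keys <- paste(sp$prior$source, sp$prior$target, sp$prior$sign)
  best_keys <- paste(ctx$best_network$source, ctx$best_network$target,
                     ctx$best_network$sign)
  expect_true(all(best_keys %in% prior_keys))
  expect_equal(network_nodes(ctx$best_network), network_nodes(sp$prior))
  expect_equal(ctx$best_fitness,
               consistency_score(ctx$best_network, sp$state_a, sp$state_b))
  expect_error(prune_network(signed_network(nodes = c("A", "B")),
                             c(A = 0, B = 0), c(A = 1, B = 1)),
               "no edges")
})

test_that("same seed and inputs give identical contextualizations", {
  sp <- simulate_prior_network(seed = 14)
  cfg <- pruning_config(population_size = 25, generations = 8, seed = 77,
                        stop_on_perfect = FALSE)
  a <- prune_network(sp$prior, sp$state_a, sp$state_b, cfg)
  b <- prune_network(sp$prior, sp$state_a, sp$state_b, cfg)
  expect_identical(a$edges, b$edges)
  expect_identical(a$fitness_trace, b$fitness_trace)
  expect_identical(a$best_fitness, b$best_fitness)
  expect_identical(a$core, b$core)
})

test_that("best fitness trace is non-decreasing and the planted core is recovered", {
  sp <- simulate_prior_network(seed = 21)
  ctx <- prune_network(sp$prior, sp$state_a, sp$state_b,
                       pruning_config(population_size = 50, generations = 30,
                                      seed = 1, stop_on_perfect = FALSE))
  expect_true(all(diff(ctx$fitness_trace$best) >= 0))
  expect_equal(ctx$best_fitness, 1)
  expect_setequal(ctx$core$gene, sp$core_genes)
  comp_sets <- lapply(split(ctx$core$gene, ctx$core$component), sort)
  expect_setequal(vapply(comp_sets, paste, character(1), collapse = ","),
                  vapply(sp$core_components, paste, character(1),
                         collapse = ","))
})

test_that("tidy, glance and autoplot expose the contextualization result", {
  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  ctx <- prune_network(mut, c(A = 0, B = 0), c(A = 1, B = 1),
                       pruning_config(population_size = 10, generations = 3,
                                      seed = 5))
  expect_identical(tidy(ctx), ctx$fitness_trace)
  g <- glance(ctx)
  expect_equal(nrow(g), 1L)
  expect_equal(g$best_fitness, 1)
  expect_equal(g$edges_prior, 2L)
  p <- autoplot(ctx)
  expect_s3_class(p, "ggplot")
})
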