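test_that("synchronous step follows the activator/inhibitor rule", {
  inh <- signed_network(data.frame(source = "A", target = "B", sign = -1))
  expect_equal(synchronous_step(inh, c(A = 1, B = 1)), c(A = 1, B = 0))

  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  expect_equal(synchronous_step(mut, c(A = 1, B = 1)), c(A = 1, B = 1))

  negfb <- signed_network(data.frame(source = c("A", "B"),
                                     target = c("B", "A"),
                                     sign = c(1, -1)))
  # full orbit of the negative feedback loop: 00 -> 10 -> 11 -> 01 -> 00
  orbit <- list(c(A = 0, B = 0), c(A = 1, B = 0), c(A = 1, B = 1),
                c(A = 0, B = 1), c(A = 0, B = 0))
  for (i in 1:4) {
    expect_equal(synchronous_step(negfb, orbit[[i]]), orbit[[i + 1]])
  }
  expect_error(synchronous_step(negfb, c(A = 1, B = 0, C = 1)), "C")
  expect_error(synchronous_step(negfb, c(A = 1)), "missing gene.*B")
})

test_that("worked attractor examples hold and match the exhaustive oracle", {
  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  atts <- find_attractors(mut)
  fps <- Filter(function(a) a$length == 1L, atts$attractors)
  expect_equal(sort(vapply(fps, function(a) a$states, numeric(1))),
               c(0, 3))  # 00 and 11: the two stable cell states
  expect_equal(attractor_keys(atts), oracle_attractors(mut)$keys)

  # three isolated genes: identity dynamics, every state is a fixed point
  iso <- signed_network(nodes = c("A", "B", "C"))
  atts_iso <- find_attractors(iso)
  expect_equal(length(atts_iso$attractors), 8L)
  expect_true(all(vapply(atts_iso$attractors, function(a) a$length,
                         integer(1)) == 1L))

  negfb <- signed_network(data.frame(source = c("A", "B"),
                                     target = c("B", "A"),
                                     sign = c(1, -1)))
  atts_fb <- find_attractors(negfb)
  expect_equal(length(atts_fb$attractors), 1L)
  expect_equal(atts_fb$attractors[[1]]$length, 4L)
  expect_equal(atts_fb$attractors[[1]]$basin_size, 4L)
  expect_equal(attractor_keys(atts_fb), oracle_attractors(negfb)$keys)
})

test_that("exhaustive search refuses oversized networks and suggests sampling", {
  withr::local_seed(1)
  net <- random_signed_network(8, 12)
  expect_error(find_attractors(net, max_nodes_exhaustive = 6L),
               "sampled")
  expect_error(find_attractors(net, mode = "sampled"), "start_states")
})

test_that("sampled mode reaches the attractors of its start states", {
  negfb <- signed_network(data.frame(source = c("A", "B"),
                                     target = c("B", "A"),
                                     sign = c(1, -1)))
  atts <- find_attractors(negfb, mode = "sampled",
                          start_states = list(c(A = 0, B = 0)))
  expect_equal(length(atts$attractors), 1L)
  expect_equal(atts$attractors[[1]]$length, 4L)
  expect_true(is.na(atts$attractors[[1]]$basin_size))
  expect_equal(attractor_keys(atts), attractor_keys(find_attractors(negfb)))
})

test_that("attractors match the oracle on random networks with basin conservation", {
  withr::local_seed(2024)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    net <- random_signed_network(n, sample(2:(3 * n), 1))
    for (rule in c("genysis", "threshold")) {
      atts <- find_attractors(net, rule = rule)
      orc <- oracle_attractors(net, rule = rule)
      expect_equal(attractor_keys(atts), orc$keys)
      expect_equal(sum(vapply(atts$attractors, function(a) a$basin_size,
                              integer(1))), 2^n)
    }
  }
})

test_that("all-activating networks with full in-degree fix both extreme states", {
  withr::local_seed(7)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    # ring of activations plus random extra activating edges: every node
    # has at least one activator
    extra <- sample(n * (n - 1), sample(0:4, 1))
    pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
    pairs <- pairs[pairs$s != pairs$t, ][extra, ]
    net <- signed_network(data.frame(
      source = c(nodes, nodes[pairs$s]),
      target = c(nodes[c(2:n, 1)], nodes[pairs$t]),
      sign = 1))
    fp <- fixed_point_codes(net)
    expect_true(0 %in% fp)
    expect_true((2^n - 1) %in% fp)
  }
})

test_that("partial states complete to matching fixed points", {
  mut <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("B", "A"), sign = 1))
  comp <- complete_partial_state(mut, c(A = 1, B = NA))
  expect_equal(unique(comp$completion), 1L)
  expect_equal(comp$value[comp$gene == "B"], 1L)

  expect_error(complete_partial_state(mut, c(A = NA, B = NA)),
               "at least one gene")
  expect_error(complete_partial_state(mut, c(A = 1, B = 1)),
               "unknown")

  iso <- signed_network(nodes = c("A", "B"))
  comp2 <- complete_partial_state(iso, c(A = 1, B = NA))
  expect_equal(length(unique(comp2$completion)), 2L)
  expect_true(all(comp2$value[comp2$gene == "A"] == 1L))
  expect_setequal(comp2$value[comp2$gene == "B"], c(0L, 1L))

  # inconsistent observation: no fixed point matches
  negfb <- signed_network(data.frame(source = c("A", "B"),
                                     target = c("B", "A"),
                                     sign = c(1, -1)))
  expect_equal(nrow(complete_partial_state(negfb, c(A = 1, B = NA))), 0L)
})

test_that("state encoding round-trips and orders bits lexicographically", {
  nodes <- c("A", "B", "C")
  for (code in 0:7) {
    expect_equal(encode_state(decode_state(code, nodes), nodes), code)
  }
  expect_equal(decode_state(1, nodes), c(A = 1L, B = 0L, C = 0L))

  path <- withr::local_tempfile(fileext = ".tsv")
  st <- c(A = 1L, B = NA_integer_, C = 0L)
  write_boolean_state(st, path)
  expect_equal(read_boolean_state(path), st)
})
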