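#' Enumerate elementary circuits of a signed network
#'
#' An elementary circuit is a directed cycle visiting no gene twice
#' (length 1 = self-loop). Its sign is the product of its edge signs: a
#' circuit is positive iff it traverses an even number of inhibitions.
#' Positive circuits are the structures theory links to multistationarity,
#' so the contextualization stage samples over them.
#'
#' Enumeration uses Johnson's blocking/unblocking algorithm on the unsigned
#' support graph; where parallel activating and inhibiting edges connect
#' consecutive genes, one circuit is emitted per sign combination. Each
#' circuit is reported in canonical rotation, starting at its
#' lexicographically minimal gene, so the listing has no duplicates.
#'
#' @param net A [signed_network()].
#' @param max_len Optional maximum circuit length (number of genes); `Inf`
#'   enumerates all.
#' @param warn_above Emit a warning once more than this many circuits have
#'   been collected (counts explode combinatorially on dense graphs).
#' @return A tibble with one row per circuit: `circuit_id`, `length`,
#'   `sign` (+1/-1), `nodes` (genes joined by `|`), `edge_signs` (`+`/`-`
#'   joined by `|`, aligned with consecutive hops).
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B", "C", "A"), target = c("B", "C", "A", "C"),
#'   sign = 1))
#' enumerate_elementary_circuits(net)
#' @export
enumerate_elementary_circuits <- function(net, max_len = Inf,
                                          warn_above = 1e5) {
  stopifnot(inherits(net, "signed_network"))
  nodes <- network_nodes(net)
  n <- length(nodes)
  empty <- tibble::tibble(circuit_id = integer(), length = integer(),
                          sign = integer(), nodes = character(),
                          edge_signs = character())
  if (nrow(net) == 0L) return(empty)

  src <- match(net$source, nodes)
  tgt <- match(net$target, nodes)
  # signs available per ordered support arc
  arc_key <- paste(src, tgt)
  sign_by_arc <- split(net$sign, arc_key)
  # unsigned support adjacency, self-loops handled separately
  support <- unique(cbind(src, tgt)[src != tgt, , drop = FALSE])
  adj <- lapply(seq_len(n), function(v) {
    sort(support[support[, 1] == v, 2])
  })

  node_cycles <- list()
  if (n >= 2L && nrow(support) > 0L) {
    node_cycles <- if (is.finite(max_len)) {
      bounded_cycles(n, adj, max_len)
    } else {
      johnson_cycles(n, adj)
    }
  }
  # self-loops are length-1 circuits
  selfs <- sort(unique(src[src == tgt]))
  if (max_len >= 1) {
    node_cycles <- c(lapply(selfs, identity), node_cycles)
  }
  if (length(node_cycles) == 0L) return(empty)

  rows <- purrr::map(node_cycles, function(cyc) {
    k <- length(cyc)
    hops <- cbind(cyc, cyc[c(seq_len(k)[-1], 1L)])
    if (k == 1L) hops <- cbind(cyc, cyc)
    sign_opts <- lapply(seq_len(k), function(i) {
      sort(unique(sign_by_arc[[paste(hops[i, 1], hops[i, 2])]]),
           decreasing = TRUE)
    })
    combos <- expand.grid(rev(sign_opts), KEEP.OUT.ATTRS = FALSE)
    combos <- combos[, rev(seq_len(ncol(combos))), drop = FALSE]
    purrr::map(seq_len(nrow(combos)), function(r) {
      es <- as.integer(unlist(combos[r, ], use.names = FALSE))
      list(length = k, sign = prod(es),
           nodes = paste(nodes[cyc], collapse = "|"),
           edge_signs = paste(ifelse(es == 1L, "+", "-"), collapse = "|"))
    })
  })
  rows <- purrr::flatten(rows)
  if (length(rows) > warn_above) {
    rlang::warn(sprintf("%d elementary circuits enumerated (guard: %g)",
                        length(rows), warn_above))
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  out <- dplyr::arrange(out, .data$length, .data$nodes, .data$edge_signs)
  out$sign <- as.integer(out$sign)
  dplyr::bind_cols(tibble::tibble(circuit_id = seq_len(nrow(out))), out)
}

# Johnson's elementary-circuit algorithm on an unsigned digraph given as an
# adjacency list (no self-loops). Each cycle is returned as a vector of
# 1-based node indices whose first element is the minimal index, because
# start vertices s are processed in increasing order over the subgraph
# induced on {s, ..., n}.
johnson_cycles <- function(n, adj) {
  cycles <- list()
  for (s in seq_len(n)) {
    adj_s <- lapply(seq_len(n), function(v) {
      if (v < s) integer() else adj[[v]][adj[[v]] >= s]
    })
    if (length(adj_s[[s]]) == 0L) next
    blocked <- rep(FALSE, n)
    B <- lapply(seq_len(n), function(i) integer())
    stack <- integer()

    unblock <- function(u) {
      blocked[u] <<- FALSE
      pending <- B[[u]]
      B[[u]] <<- integer()
      for (w in pending) if (blocked[w]) unblock(w)
    }

    circuit <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in adj_s[[v]]) {
        if (w == s) {
          cycles[[length(cycles) + 1L]] <<- stack
          found <- TRUE
        } else if (!blocked[w]) {
          if (circuit(w)) found <- TRUE
        }
      }
      if (found) {
        unblock(v)
      } else {
        for (w in adj_s[[v]]) {
          if (!(v %in% B[[w]])) B[[w]] <<- c(B[[w]], v)
        }
      }
      stack <<- stack[-length(stack)]
      found
    }
    circuit(s)
  }
  cycles
}

# Plain depth-first enumeration of simple cycles up to a length bound;
# paths are restricted to vertices >= the start vertex so each cycle is
# found exactly once, already rooted at its minimal node.
bounded_cycles <- function(n, adj, max_len) {
  cycles <- list()
  for (s in seq_len(n)) {
    stack <- integer()
    on_path <- rep(FALSE, n)
    dfs <- function(v) {
      stack <<- c(stack, v)
      on_path[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w < s) next
        if (w == s) {
          cycles[[length(cycles) + 1L]] <<- stack
        } else if (!on_path[w] && length(stack) < max_len) {
          dfs(w)
        }
      }
      on_path[v] <<- FALSE
      stack <<- stack[-length(stack)]
    }
    dfs(s)
  }
  cycles
}

#' Keep only the positive circuits
#'
#' @param circuits A circuit tibble from [enumerate_elementary_circuits()].
#' @return The rows with `sign == +1`, order preserved.
#' @export
positive_circuits <- function(circuits) {
  dplyr::filter(circuits, .data$sign == 1L)
}

#' Write a circuit report
#'
#' Tab-separated `circuit_id`, `length`, `sign`, `nodes` (pipe-joined).
#'
#' @param circuits Circuit tibble.
#' @param path Output path.
#' @export
write_circuits <- function(circuits, path) {
  write_tsv_plain(circuits[, c("circuit_id", "length", "sign", "nodes")], path)
  invisible(path)
}
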