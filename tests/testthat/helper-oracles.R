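# Independent oracles for property tests. These deliberately re-derive the
# dynamics and circuit definitions from first principles with different
# algorithms than the package (literal per-state stepping + pointer doubling
# instead of vectorised tables + path-walk marking; naive DFS instead of
# Johnson), so agreement is evidence, not tautology.

random_signed_network <- function(n_nodes, n_edges, p_inhibit = 0.3,
                                  allow_self = TRUE) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  if (!allow_self) {
    loop <- src == tgt
    tgt[loop] <- vapply(src[loop], function(s) sample(setdiff(nodes, s), 1L),
                        character(1))
  }
  sign <- ifelse(runif(n_edges) < p_inhibit, -1L, 1L)
  signed_network(data.frame(source = src, target = tgt, sign = sign),
                 nodes = nodes)
}

# Literal one-step update of a single state, reading the rule off the edge
# table row by row.
oracle_step <- function(edges, nodes, state, rule = "genysis") {
  nxt <- state
  for (g in nodes) {
    inc <- edges[edges$target == g, , drop = FALSE]
    if (nrow(inc) == 0L) next
    act <- state[inc$source[inc$sign == 1L]]
    inh <- state[inc$source[inc$sign == -1L]]
    if (rule == "genysis") {
      act_ok <- if (length(act) == 0L) TRUE else any(act == 1L)
      nxt[g] <- as.integer(act_ok && !any(inh == 1L))
    } else {
      s <- sum(act) - sum(inh)
      nxt[g] <- if (s > 0) 1L else if (s < 0) 0L else state[[g]]
    }
  }
  nxt
}

# Exhaustive attractors by pointer doubling on the literal transition map.
# Returns list(cycles = sorted canonical code vectors, basin = named counts
# keyed by cycle string).
oracle_attractors <- function(net, rule = "genysis") {
  nodes <- network_nodes(net)
  edges <- as.data.frame(net)
  n <- length(nodes)
  N <- 2^n
  codes <- 0:(N - 1)
  succ <- vapply(codes, function(code) {
    st <- setNames(as.integer(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L)),
                   nodes)
    nx <- oracle_step(edges, nodes, st, rule)
    sum(nx * 2^(seq_len(n) - 1L))
  }, numeric(1))
  f <- succ + 1
  g <- f
  for (k in seq_len(ceiling(log2(max(N, 2))) + 1L)) g <- g[g]
  landing <- g                      # position after >= N steps: on a cycle
  cyc_states <- sort(unique(landing))
  seen <- rep(FALSE, N)
  cycles <- list()
  cyc_of <- integer(N)
  for (s in cyc_states) {
    if (seen[s]) next
    cyc <- s
    cur <- f[s]
    while (cur != s) {
      cyc <- c(cyc, cur)
      cur <- f[cur]
    }
    seen[cyc] <- TRUE
    id <- length(cycles) + 1L
    k <- which.min(cyc)
    cycles[[id]] <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)]) - 1
    cyc_of[cyc] <- id
  }
  basin <- tabulate(cyc_of[landing], nbins = length(cycles))
  keys <- vapply(cycles, paste, character(1), collapse = ",")
  ord <- order(keys)
  list(cycles = cycles[ord], basin = basin[ord], keys = keys[ord])
}

attractor_keys <- function(atts) {
  sort(vapply(atts$attractors, function(a) paste(a$states, collapse = ","),
              character(1)))
}

# Naive enumeration of signed elementary circuits: DFS over edges with
# distinct path nodes, canonical rotation, dedupe.
oracle_signed_circuits <- function(net) {
  edges <- as.data.frame(net)
  found <- new.env(parent = emptyenv())
  path_nodes <- character()
  path_signs <- integer()
  record <- function() {
    L <- length(path_nodes)
    ps <- path_signs[seq_len(L)]
    k <- which(path_nodes == min(path_nodes))[1]
    nn <- c(path_nodes[k:L], path_nodes[seq_len(k - 1L)])
    ss <- c(ps[k:L], ps[seq_len(k - 1L)])
    key <- paste(paste(nn, collapse = "|"),
                 paste(ss, collapse = "|"), sep = "::")
    found[[key]] <- list(nodes = paste(nn, collapse = "|"),
                         sign = prod(ss))
  }
  dfs <- function(cur, start) {
    out <- edges[edges$source == cur, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      tgt <- out$target[i]
      path_signs[length(path_nodes)] <<- out$sign[i]
      if (tgt == start) {
        record()
      } else if (!tgt %in% path_nodes) {
        path_nodes <<- c(path_nodes, tgt)
        dfs(tgt, start)
        path_nodes <<- path_nodes[-length(path_nodes)]
      }
    }
  }
  nodes <- network_nodes(net)
  for (s in nodes) {
    path_nodes <- s
    path_signs <- integer()
    dfs(s, s)
  }
  keys <- sort(ls(found))
  list(keys = keys,
       table = lapply(keys, function(k) found[[k]]))
}

circuit_keys <- function(circuits) {
  signs_numeric <- vapply(strsplit(circuits$edge_signs, "|", fixed = TRUE),
                          function(s) paste(ifelse(s == "+", 1L, -1L),
                                            collapse = "|"),
                          character(1))
  sort(paste(circuits$nodes, signs_numeric, sep = "::"))
}
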