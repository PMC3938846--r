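#' Synchronous Boolean update rules
#'
#' The update rule combining a gene's activators and inhibitors is not
#' uniquely determined by a signed edge list, so it is a pluggable choice:
#'
#' * `"genysis"` (default): a gene with no regulators holds its value;
#'   otherwise `next = (some activator is ON, vacuously true when the gene
#'   has inhibitors but no activators) AND (no inhibitor is ON)`. This is
#'   the rule of the classic synchronous attractor-computation scheme for
#'   signed networks: inhibition dominates, and activation is an OR.
#' * `"threshold"`: majority rule — `next = 1` when active activators
#'   outnumber active inhibitors, `0` when they are outnumbered, and the
#'   gene holds its value on a tie. Provided for sensitivity analysis of
#'   downstream results to the logic choice.
#'
#' @name update_rules
NULL

rule_names <- c("genysis", "threshold")

regulator_index <- function(net) {
  nodes <- network_nodes(net)
  tgt <- match(net$target, nodes)
  src <- match(net$source, nodes)
  act <- split(src[net$sign == 1L], tgt[net$sign == 1L])
  inh <- split(src[net$sign == -1L], tgt[net$sign == -1L])
  list(nodes = nodes,
       act = lapply(seq_along(nodes), function(i) act[[as.character(i)]] %||% integer()),
       inh = lapply(seq_along(nodes), function(i) inh[[as.character(i)]] %||% integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorised next value of node j over many states; `vals` is a list of
# logical vectors (one per node, TRUE = ON), all of equal length.
next_values <- function(vals, act_j, inh_j, cur_j, rule) {
  n_act <- length(act_j); n_inh <- length(inh_j)
  if (n_act + n_inh == 0L) return(cur_j)
  if (rule == "genysis") {
    act_ok <- if (n_act == 0L) TRUE else Reduce(`|`, vals[act_j])
    inh_on <- if (n_inh == 0L) FALSE else Reduce(`|`, vals[inh_j])
    act_ok & !inh_on
  } else {
    s <- 0L
    for (a in act_j) s <- s + vals[[a]]
    for (i in inh_j) s <- s - vals[[i]]
    ifelse(s > 0L, TRUE, ifelse(s < 0L, FALSE, cur_j))
  }
}

#' Advance a Boolean state by one synchronous step
#'
#' All genes update simultaneously from the current state, so the dynamics
#' are a deterministic function on the state space: every state has exactly
#' one successor.
#'
#' @param net A [signed_network()].
#' @param state Named 0/1 vector over the network's genes (see
#'   [boolean_state()]).
#' @param rule Update rule; see [update_rules].
#' @return The successor state, a named 0/1 integer vector in node order.
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B", sign = -1))
#' synchronous_step(net, c(A = 1, B = 1))  # B is inhibited
#' @export
synchronous_step <- function(net, state, rule = c("genysis", "threshold")) {
  rule <- match.arg(rule)
  state <- check_state(net, boolean_state(state))
  reg <- regulator_index(net)
  vals <- lapply(as.logical(state), identity)
  nxt <- vapply(seq_along(reg$nodes), function(j) {
    as.logical(next_values(vals, reg$act[[j]], reg$inh[[j]], vals[[j]], rule))
  }, logical(1))
  stats::setNames(as.integer(nxt), reg$nodes)
}

# Successor of every state: integer vector succ of length 2^n where
# succ[code + 1] is the 0-based code of the successor of 0-based `code`.
transition_table <- function(net, rule = "genysis") {
  reg <- regulator_index(net)
  n <- length(reg$nodes)
  codes <- 0:(2^n - 1L)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  vals <- lapply(bits, function(b) bitwAnd(codes, b) > 0L)
  succ <- integer(length(codes))
  for (j in seq_len(n)) {
    nxt <- next_values(vals, reg$act[[j]], reg$inh[[j]], vals[[j]], rule)
    succ <- succ + as.integer(nxt) * bits[j]
  }
  succ
}

# Attractors (terminal cycles) of the functional graph succ, with basins.
# Returns list(cycles = list of 1-based state index vectors in succession
# order, basin = integer counts).
attractors_from_successors <- function(succ) {
  N <- length(succ)
  comp <- integer(N)     # attractor id reached from each state
  flag <- integer(N)     # 0 unvisited, 1 finished, 2 on current path
  cycles <- list()
  path <- integer(min(N, 1024L))
  for (s in seq_len(N)) {
    if (flag[s] != 0L) next
    depth <- 0L
    cur <- s
    while (flag[cur] == 0L) {
      flag[cur] <- 2L
      depth <- depth + 1L
      if (depth > length(path)) path <- c(path, integer(length(path)))
      path[depth] <- cur
      cur <- succ[cur] + 1L
    }
    if (flag[cur] == 2L) {        # closed a new cycle on this path
      i <- depth
      while (path[i] != cur) i <- i - 1L
      id <- length(cycles) + 1L
      cycles[[id]] <- path[i:depth]
      aid <- id
    } else {
      aid <- comp[cur]
    }
    walked <- path[seq_len(depth)]
    comp[walked] <- aid
    flag[walked] <- 1L
  }
  list(cycles = cycles, basin = tabulate(comp, nbins = length(cycles)))
}

canonical_cycle <- function(codes) {
  k <- which.min(codes)
  if (k > 1L) codes <- c(codes[k:length(codes)], codes[seq_len(k - 1L)])
  codes
}

new_attractor_set <- function(attractors, nodes, rule, mode) {
  structure(list(attractors = attractors, nodes = nodes, rule = rule,
                 mode = mode),
            class = "bn_attractors")
}

#' Compute the attractors of a synchronous Boolean network
#'
#' In `exhaustive` mode the full successor map over all `2^n` states is
#' built and its terminal cycles extracted, giving every attractor together
#' with basin sizes that sum to `2^n`. Networks above
#' `max_nodes_exhaustive` genes are refused (the state space doubles per
#' gene); `sampled` mode instead follows trajectories from the supplied
#' start states and reports the attractors they reach.
#'
#' Attractors are deduplicated by canonical rotation: the cycle is rotated
#' to start at its minimal integer encoding, so a length-1 attractor is a
#' fixed point.
#'
#' @param net A [signed_network()].
#' @param mode `"exhaustive"` (default) or `"sampled"`.
#' @param start_states List of named 0/1 vectors (required in sampled mode).
#' @param max_nodes_exhaustive Refusal threshold for exhaustive mode.
#' @param rule Update rule; see [update_rules].
#' @return A `bn_attractors` object; see [tidy.bn_attractors()] for a tidy
#'   view. Each attractor holds `states` (integer codes in succession
#'   order), `length`, and `basin_size` (`NA` in sampled mode).
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B"), target = c("B", "A"), sign = 1))
#' find_attractors(net)  # two fixed points: 00 and 11
#' @export
find_attractors <- function(net, mode = c("exhaustive", "sampled"),
                            start_states = NULL, max_nodes_exhaustive = 20L,
                            rule = c("genysis", "threshold")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  nodes <- network_nodes(net)
  n <- length(nodes)
  if (mode == "exhaustive") {
    if (n > max_nodes_exhaustive) {
      rlang::abort(sprintf(
        paste0("network has %d genes; exhaustive attractor search is capped at ",
               "%d (2^n states). Use mode = 'sampled' with start states."),
        n, max_nodes_exhaustive))
    }
    res <- attractors_from_successors(transition_table(net, rule))
    atts <- purrr::map2(res$cycles, res$basin, function(cyc, b) {
      list(states = canonical_cycle(cyc - 1L), length = length(cyc),
           basin_size = b)
    })
  } else {
    if (length(start_states) == 0L) {
      rlang::abort("sampled mode requires a non-empty `start_states` list")
    }
    atts <- list()
    seen <- character()
    for (st in start_states) {
      st <- check_state(net, boolean_state(st))
      walked <- numeric(0)
      code <- encode_state(st, nodes)
      repeat {
        pos <- match(code, walked)
        if (!is.na(pos)) {
          cyc <- canonical_cycle(walked[pos:length(walked)])
          key <- paste(cyc, collapse = ",")
          if (!key %in% seen) {
            seen <- c(seen, key)
            atts[[length(atts) + 1L]] <-
              list(states = cyc, length = length(cyc), basin_size = NA_integer_)
          }
          break
        }
        walked <- c(walked, code)
        st <- synchronous_step(net, st, rule)
        code <- encode_state(st, nodes)
      }
    }
  }
  ord <- order(vapply(atts, function(a) a$states[1], numeric(1)))
  new_attractor_set(atts[ord], nodes, rule, mode)
}

#' @export
print.bn_attractors <- function(x, ...) {
  cat(sprintf("# %d attractor(s) of a %d-gene network (%s mode, %s rule)\n",
              length(x$attractors), length(x$nodes), x$mode, x$rule))
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    lab <- if (a$length == 1L) "fixed point" else sprintf("cycle of %d", a$length)
    basin <- if (is.na(a$basin_size)) "" else sprintf(", basin %d", a$basin_size)
    st <- decode_state(a$states[1], x$nodes)
    cat(sprintf("  [%d] %s%s: %s%s\n", i, lab, basin,
                paste0(st, collapse = ""),
                if (a$length > 1L) " ..." else ""))
  }
  invisible(x)
}

#' Tidy an attractor set
#'
#' @param x A `bn_attractors` object from [find_attractors()].
#' @param ... Unused.
#' @return A tibble with one row per attractor, state and gene: columns
#'   `attractor`, `length`, `basin_size`, `step` (position in the cycle),
#'   `gene`, `value`.
#' @export
tidy.bn_attractors <- function(x, ...) {
  purrr::imap_dfr(x$attractors, function(a, i) {
    purrr::imap_dfr(a$states, function(code, k) {
      tibble::tibble(attractor = i, length = a$length,
                     basin_size = a$basin_size, step = k - 1L,
                     gene = x$nodes, value = decode_state(code, x$nodes))
    })
  })
}

#' Fixed points of a network
#'
#' @param net A [signed_network()].
#' @inheritParams find_attractors
#' @return Integer codes of all states equal to their own successor.
#' @keywords internal
#' @export
fixed_point_codes <- function(net, rule = "genysis",
                              max_nodes_exhaustive = 20L) {
  n <- length(network_nodes(net))
  if (n > max_nodes_exhaustive) {
    rlang::abort("network too large for exhaustive fixed-point enumeration")
  }
  succ <- transition_table(net, rule)
  which(succ == (seq_along(succ) - 1L)) - 1L
}

#' Predict completions of a partially observed state
#'
#' Given gene values observed for only part of the network, returns every
#' fixed point of the synchronous dynamics consistent with the known
#' entries — the model-based predictions of the missing expression values.
#'
#' @param net A [signed_network()].
#' @param partial Named vector over (a subset of) the network's genes with
#'   values 0, 1 or `NA` (unknown). Genes absent from the vector are also
#'   treated as unknown. At least one value must be known, and at least one
#'   unknown.
#' @param rule Update rule; see [update_rules].
#' @return A tibble with columns `completion` (id), `gene`, `value`; zero
#'   rows when no fixed point matches.
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B"), target = c("B", "A"), sign = 1))
#' complete_partial_state(net, c(A = 1, B = NA))
#' @export
complete_partial_state <- function(net, partial,
                                   rule = c("genysis", "threshold")) {
  rule <- match.arg(rule)
  nodes <- network_nodes(net)
  extra <- setdiff(names(partial), nodes)
  if (length(extra) > 0L) {
    rlang::abort(sprintf("partial state names unknown gene(s): %s",
                         paste(extra, collapse = ", ")))
  }
  full <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  full[names(partial)] <- as.integer(partial)
  known <- which(!is.na(full))
  if (length(known) == 0L) {
    rlang::abort("partial state must fix at least one gene")
  }
  if (!anyNA(full)) {
    rlang::abort("partial state must leave at least one gene unknown")
  }
  fp <- fixed_point_codes(net, rule)
  ok <- fp[vapply(fp, function(code) {
    all(decode_state(code, nodes)[known] == full[known])
  }, logical(1))]
  purrr::imap_dfr(ok, function(code, i) {
    tibble::tibble(completion = i, gene = nodes,
                   value = unname(decode_state(code, nodes)))
  })
}
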