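#' Construct a signed regulatory network
#'
#' A signed network is the package's central container: a directed graph of
#' genes whose edges carry a regulatory sign, `+1` (activation, the "->" of a
#' literature interaction map) or `-1` (inhibition, "--|"). It is stored as a
#' tibble of edges with the full node set (including isolated genes) kept as
#' an attribute in deterministic lexicographic order, so that Boolean state
#' encodings built on top of it are reproducible.
#'
#' An activating and an inhibiting edge may coexist between the same ordered
#' gene pair; exact duplicate (source, target, sign) triples are collapsed.
#'
#' @param edges Data frame with columns `source`, `target` and `sign`
#'   (`+1`/`-1`, or the strings `"activates"`/`"inhibits"`). May have zero
#'   rows.
#' @param nodes Optional character vector of gene identifiers; the node set
#'   is the union of `nodes` and all edge endpoints.
#' @return A `signed_network`: a tibble of edges (columns `source`, `target`,
#'   `sign`) sorted by source, target, sign, with attribute `nodes`.
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("GATA4", "NKX2-5"),
#'   target = c("NKX2-5", "GATA4"),
#'   sign = c(1, 1)
#' ))
#' network_nodes(net)
#' @export
signed_network <- function(edges = NULL, nodes = character()) {
  if (is.null(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            sign = integer())
  }
  edges <- tibble::as_tibble(edges)
  req <- c("source", "target", "sign")
  if (!all(req %in% names(edges))) {
    rlang::abort(paste0("`edges` must have columns ",
                        paste(req, collapse = ", ")))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- parse_sign(edges$sign)
  edges <- dplyr::distinct(edges[, req])
  edges <- dplyr::arrange(edges, .data$source, .data$target,
                          dplyr::desc(.data$sign))
  all_nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  structure(edges, nodes = all_nodes,
            class = c("signed_network", class(tibble::tibble())))
}

parse_sign <- function(x) {
  if (is.character(x)) {
    out <- ifelse(x %in% c("activates", "+", "+1", "1"), 1L,
                  ifelse(x %in% c("inhibits", "-", "-1"), -1L, NA_integer_))
  } else {
    out <- as.integer(x)
    out[!out %in% c(-1L, 1L)] <- NA_integer_
  }
  if (anyNA(out)) {
    rlang::abort("edge signs must be +1/-1 (or 'activates'/'inhibits')")
  }
  out
}

#' Nodes of a signed network
#'
#' @param net A [signed_network()].
#' @return Character vector of gene identifiers in lexicographic order.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  attr(net, "nodes")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("# Signed network: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              length(network_nodes(x)), nrow(x),
              sum(x$sign == 1L), sum(x$sign == -1L)))
  NextMethod()
}

#' Keep a subset of edges of a network
#'
#' Pruning helper used by the contextualization loop: the node set is
#' preserved (pruning removes interactions, never genes).
#'
#' @param net A [signed_network()].
#' @param keep Logical vector along the rows of `net`, or integer row indices.
#' @return A `signed_network` on the same node set.
#' @export
keep_edges <- function(net, keep) {
  stopifnot(inherits(net, "signed_network"))
  signed_network(as.data.frame(net)[keep, , drop = FALSE],
                 nodes = network_nodes(net))
}

#' Read a signed network from a SIF-style edge list
#'
#' Parses the three-column tab-separated format
#' `source<TAB>activates|inhibits<TAB>target` (one interaction per line;
#' lines starting with `#` are comments). Duplicate identical triples are
#' collapsed with a warning; unknown relation tokens are an error reporting
#' the offending line number.
#'
#' @param path Path to the edge-list file.
#' @return A [signed_network()].
#' @export
read_signed_network <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(signed_network())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("line %d of '%s': expected 3 tab-separated fields",
                         idx[bad[1]], path))
  }
  m <- do.call(rbind, parts)
  rel <- m[, 2]
  unknown <- which(!rel %in% c("activates", "inhibits"))
  if (length(unknown) > 0L) {
    rlang::abort(sprintf(
      "line %d of '%s': unknown relation '%s' (expected 'activates' or 'inhibits')",
      idx[unknown[1]], path, rel[unknown[1]]))
  }
  edges <- tibble::tibble(source = m[, 1], target = m[, 3],
                          sign = ifelse(rel == "activates", 1L, -1L))
  n_dup <- nrow(edges) - nrow(dplyr::distinct(edges))
  if (n_dup > 0L) {
    rlang::warn(sprintf("%d duplicate edge line(s) collapsed in '%s'",
                        n_dup, path))
  }
  signed_network(edges)
}

#' Write a signed network as a SIF-style edge list
#'
#' Inverse of [read_signed_network()]: edges are written in canonical order
#' so that write(read(x)) is byte-identical.
#'
#' @param net A [signed_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signed_network <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  rel <- ifelse(net$sign == 1L, "activates", "inhibits")
  writeLines(paste(net$source, rel, net$target, sep = "\t"), path)
  invisible(path)
}

#' Strongly connected stability core of a network
#'
#' Decomposes the network into strongly connected components and keeps the
#' nontrivial ones: components with at least two genes, or single genes
#' carrying a self-loop. Their union is the feedback structure — the
#' "stability core" — capable of maintaining alternative stable expression
#' states; genes outside it sit on feed-forward paths and cannot by
#' themselves hold a cell state.
#'
#' @param net A [signed_network()].
#' @return A tibble with columns `component` (integer id, numbered by the
#'   lexicographically first gene of each component) and `gene`. Zero rows
#'   when the network has no nontrivial component.
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B", "C"), target = c("B", "A", "A"), sign = 1))
#' stability_core(net)
#' @export
stability_core <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  empty <- tibble::tibble(component = integer(), gene = character())
  if (nrow(net) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(
    dplyr::distinct(tibble::tibble(from = net$source, to = net$target)),
    directed = TRUE, vertices = network_nodes(net))
  comp <- igraph::components(g, mode = "strong")
  self <- unique(net$source[net$source == net$target])
  members <- split(names(comp$membership), comp$membership)
  keep <- vapply(members, function(g2) {
    length(g2) >= 2L || any(g2 %in% self)
  }, logical(1))
  members <- lapply(members[keep], sort)
  if (length(members) == 0L) return(empty)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  tibble::tibble(
    component = rep(seq_along(members), lengths(members)),
    gene = unlist(members, use.names = FALSE)
  )
}
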