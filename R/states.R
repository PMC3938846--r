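#' Boolean states of a network
#'
#' A Boolean state assigns 0/1 to every gene of a network; it is represented
#' as a named integer vector. States are encoded as integers with bit *i*
#' set iff the *i*-th gene (lexicographic node order) is 1, which makes
#' hashing, deduplication and the canonical rotation of cyclic attractors
#' reproducible across runs.
#'
#' @param values Numeric/logical vector of 0/1 values, or a data frame with
#'   columns `gene` and `value`.
#' @param genes Gene names (ignored when `values` is a data frame or already
#'   named).
#' @return Named integer vector of 0/1.
#' @examples
#' boolean_state(c(A = 1, B = 0))
#' @export
boolean_state <- function(values, genes = NULL) {
  if (is.data.frame(values)) {
    genes <- as.character(values$gene)
    values <- values$value
  }
  if (!is.null(genes)) names(values) <- genes
  if (is.null(names(values))) rlang::abort("state values must be named by gene")
  out <- as.integer(values)
  if (anyNA(out) || !all(out %in% c(0L, 1L))) {
    rlang::abort("state values must be 0 or 1 (use partial states for NA)")
  }
  names(out) <- names(values)
  out
}

check_state <- function(net, state, what = "state") {
  nodes <- network_nodes(net)
  extra <- setdiff(names(state), nodes)
  if (length(extra) > 0L) {
    rlang::abort(sprintf("%s names gene(s) not in the network: %s",
                         what, paste(extra, collapse = ", ")))
  }
  missing <- setdiff(nodes, names(state))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("%s is missing gene(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  state[nodes]
}

#' Encode / decode a Boolean state as an integer
#'
#' Bit *i* (least significant first) holds the value of the *i*-th gene in
#' lexicographic order.
#'
#' @param state Named 0/1 vector over `nodes`.
#' @param nodes Gene names in lexicographic order.
#' @return `encode_state`: a single integer code in `[0, 2^n)`.
#' @keywords internal
#' @export
encode_state <- function(state, nodes) {
  sum(as.integer(state[nodes]) * bitwShiftL(1L, seq_along(nodes) - 1L))
}

#' @rdname encode_state
#' @param code Integer state code.
#' @return `decode_state`: a named 0/1 integer vector over `nodes`.
#' @export
decode_state <- function(code, nodes) {
  vals <- as.integer(bitwAnd(bitwShiftR(code, seq_along(nodes) - 1L), 1L))
  names(vals) <- nodes
  vals
}

#' Read or write Boolean states
#'
#' Two-column tab-separated format `gene<TAB>value` with value `0`, `1`, or
#' `NA` for an unknown entry of a partial state. A `#` header comment is
#' allowed.
#'
#' @param path File path.
#' @return `read_boolean_state`: a named integer vector with `NA` for
#'   unknown values.
#' @export
read_boolean_state <- function(path) {
  df <- readr::read_tsv(path, col_names = c("gene", "value"), comment = "#",
                        col_types = readr::cols(gene = "c", value = "i"),
                        na = "NA")
  stats::setNames(df$value, df$gene)
}

#' @rdname read_boolean_state
#' @param state Named integer vector (NA allowed).
#' @export
write_boolean_state <- function(state, path) {
  ord <- order(names(state))
  writeLines(paste(names(state)[ord],
                   ifelse(is.na(state[ord]), "NA", state[ord]), sep = "\t"),
             path)
  invisible(path)
}
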