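# Interface detection: nodes are interface residues, edges are inter-chain
# residue pairs whose interaction coordinates (Cbeta, Calpha for glycine)
# lie within the 10 Angstrom cutoff.

#' Build the inter-chain interface graph
#'
#' Edges are all residue pairs across the two chains whose interaction
#' coordinates are strictly closer than `cutoff`; nodes are the residues
#' participating in at least one edge. Node ordering is deterministic:
#' chain-1 residues by sequence index, then chain-2 residues; edges are
#' ordered lexicographically by (chain-1 index, chain-2 index).
#'
#' @param cplx `complex_structure`.
#' @param cutoff interaction distance cutoff in Angstrom (strict `<`).
#' @return object of class `interface_graph`: `nodes` data.frame
#'   (`chain` 1/2, `index` residue index within its chain, `aa`), `edges`
#'   data.frame (`i`, `j` node row numbers with `i` in chain 1 and `j` in
#'   chain 2, `res1`, `res2` residue indices, `d_model` Angstrom), and empty
#'   slots `node_features`, `edge_features`, `edge_label` filled by the
#'   featurization and labeling steps.
#' @export
build_interface_graph <- function(cplx, cutoff = 10.0) {
  stopifnot(inherits(cplx, "complex_structure"))
  c1 <- cplx$chains[[1]]; c2 <- cplx$chains[[2]]
  x1 <- as_mat3(interaction_coordinate(c1))
  x2 <- as_mat3(interaction_coordinate(c2))
  # all-pairs squared distances (L1 x L2)
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * (x1 %*% t(x2))
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  hit <- which(dmat < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    cond <- structure(
      class = c("empty_interface", "error", "condition"),
      list(message = sprintf(
        "empty interface for %s: minimum inter-chain distance %.2f A >= %.1f A",
        cplx$target_id, min(dmat), cutoff),
        call = sys.call(-1), min_distance = min(dmat)))
    stop(cond)
  }
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  res1 <- sort(unique(hit[, 1]))
  res2 <- sort(unique(hit[, 2]))
  nodes <- data.frame(
    chain = c(rep(1L, length(res1)), rep(2L, length(res2))),
    index = c(res1, res2),
    aa = c(c1$aa[res1], c2$aa[res2]),
    stringsAsFactors = FALSE)
  node_id1 <- integer(chain_length(c1)); node_id1[res1] <- seq_along(res1)
  node_id2 <- integer(chain_length(c2))
  node_id2[res2] <- length(res1) + seq_along(res2)
  edges <- data.frame(
    i = node_id1[hit[, 1]],
    j = node_id2[hit[, 2]],
    res1 = as.integer(hit[, 1]),
    res2 = as.integer(hit[, 2]),
    d_model = dmat[hit])
  structure(list(target_id = cplx$target_id, nodes = nodes, edges = edges,
                 node_features = NULL, edge_features = NULL,
                 edge_label = NULL),
            class = "interface_graph")
}

#' @export
print.interface_graph <- function(x, ...) {
  cat("<interface_graph> ", x$target_id, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges",
      if (!is.null(x$node_features)) " [featurized]" else "",
      if (!is.null(x$edge_label)) " [labeled]" else "", "\n", sep = "")
  invisible(x)
}

#' Native distances for the model's edges
#'
#' For every edge of a model's interface graph, the interaction-coordinate
#' distance of the corresponding residue pair in the native structure.
#' Correspondence is by (chain, internal sequential index), which assumes
#' identical sequences; a sequence-identity guard (>= 95 percent over the
#' shorter chain) rejects misaligned inputs.
#'
#' @param graph `interface_graph` built from the model.
#' @param native `complex_structure` of the native.
#' @return numeric vector of native distances (Angstrom), one per edge.
#' @export
native_edge_distances <- function(graph, native) {
  stopifnot(inherits(graph, "interface_graph"),
            inherits(native, "complex_structure"))
  n1 <- native$chains[[1]]; n2 <- native$chains[[2]]
  bad1 <- graph$edges$res1[graph$edges$res1 > chain_length(n1)]
  bad2 <- graph$edges$res2[graph$edges$res2 > chain_length(n2)]
  if (length(bad1) > 0L || length(bad2) > 0L)
    stop("native structure lacks residue(s) ",
         paste(c(paste0("1:", unique(bad1)), paste0("2:", unique(bad2))),
               collapse = ", "),
         " referenced by the model's interface graph")
  check_sequence_match(graph, native)
  x1 <- as_mat3(interaction_coordinate(n1, graph$edges$res1))
  x2 <- as_mat3(interaction_coordinate(n2, graph$edges$res2))
  row_norm(x1 - x2)
}

check_sequence_match <- function(graph, native, min_identity = 0.95) {
  for (ch in 1:2) {
    nat <- native$chains[[ch]]
    nd <- graph$nodes[graph$nodes$chain == ch, , drop = FALSE]
    ok <- nd$index <= chain_length(nat)
    ident <- mean(nd$aa[ok] == nat$aa[nd$index[ok]])
    if (!all(ok) || ident < min_identity)
      stop("model/native sequence mismatch on chain ", ch,
           sprintf(" (identity %.2f over interface residues)", ident))
  }
  invisible(TRUE)
}

#' Dump an interface graph edge table to TSV
#'
#' One row per edge: residue indices, model distance and, when present,
#' native distance and edge label. For inspection and debugging.
#'
#' @param graph `interface_graph`.
#' @param path output TSV path.
#' @param d_native optional native distances (from
#'   [native_edge_distances()]).
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path, d_native = NULL) {
  tab <- data.frame(chain1_idx = graph$edges$res1,
                    chain2_idx = graph$edges$res2,
                    d_model = graph$edges$d_model)
  if (!is.null(d_native)) tab$d_native <- d_native
  if (!is.null(graph$edge_label)) tab$z_ij <- graph$edge_label
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
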