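# Ground-truth edge quality labels for training: z_ij compares the model's
# edge distance with the corresponding native distance.

#' Ground-truth edge quality label
#'
#' Two-branch label: `z = 1` when both the model distance and the native
#' distance are below 10 Angstrom (the edge is a correct interaction);
#' otherwise `z = 1 / (1 + ((d_model - d_native) / d0)^2)`, a Lorentzian
#' decay in the distance error with normalizing constant `d0` (10 Angstrom,
#' matching the interaction cutoff).
#'
#' @param d_model,d_native distances in Angstrom (positive); vectorized.
#' @param d0 normalizing constant in Angstrom.
#' @return label(s) in `(0, 1]`.
#' @export
edge_quality_label <- function(d_model, d_native, d0 = 10.0) {
  if (any(d_model <= 0) || any(d_native <= 0) || d0 <= 0)
    stop("distances and d0 must be positive")
  ifelse(d_model < 10 & d_native < 10,
         1,
         1 / (1 + ((d_model - d_native) / d0)^2))
}

#' Label a model's interface graph against its native structure
#'
#' Populates `edge_label` with [edge_quality_label()] evaluated on each
#' edge's model distance and the matched native distance.
#'
#' @param graph `interface_graph` of the model.
#' @param native `complex_structure` of the native.
#' @param d0 normalizing constant (Angstrom).
#' @return the graph with `edge_label` populated.
#' @export
label_graph <- function(graph, native, d0 = 10.0) {
  d_nat <- native_edge_distances(graph, native)
  graph$edge_label <- edge_quality_label(graph$edges$d_model, d_nat, d0 = d0)
  graph
}
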