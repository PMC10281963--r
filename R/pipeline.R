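# End-to-end glue: featurize and label whole decoy bundles, train, score,
# and evaluate.

# normalized Neff of a target's three alignments, computed once per target
# (the features are identical for all of a target's decoys)
bundle_neff <- function(tg) {
  c(normalized_neff(effective_sequence_count(tg$msa1), tg$msa1$query_length),
    normalized_neff(effective_sequence_count(tg$msa2), tg$msa2$query_length),
    normalized_neff(effective_sequence_count(tg$msa_paired),
                    tg$msa_paired$query_length))
}

#' Featurized, labeled training graphs from a decoy bundle
#'
#' Builds, featurizes and labels the interface graph of every decoy. A
#' decoy with an empty interface (ligand displaced beyond the interaction
#' cutoff everywhere) cannot form a graph; its entry in `graphs` is `NULL`
#' and its decoy id is reported in `skipped`. Such decoys carry no edges to
#' regress on, but they keep their ground-truth DockQ so that
#' ranking-based model selection in [train_gat()] can account for them
#' with the scoring convention Q = 0.
#'
#' @param bundle `decoy_bundle` from [simulate_bundle()].
#' @param sasa_points sphere points for the internal SASA computation.
#' @return list with `graphs` (labeled `interface_graph`s or `NULL`),
#'   `targets` (parallel character vector), `decoys` (decoy ids), `dockq`
#'   (true scores) and `skipped` (data.frame of decoys without an
#'   interface).
#' @export
prepare_training_graphs <- function(bundle, sasa_points = 92) {
  graphs <- list(); targets <- character(0); decoys <- character(0)
  dockq <- numeric(0)
  skipped <- data.frame(target = character(0), decoy = character(0))
  for (tg in bundle) {
    neff <- bundle_neff(tg)
    for (d in seq_along(tg$decoy_set$decoys)) {
      dec <- tg$decoy_set$decoys[[d]]
      g <- tryCatch(build_interface_graph(dec), empty_interface = function(e) NULL)
      if (is.null(g)) {
        skipped <- rbind(skipped,
                         data.frame(target = tg$target_id,
                                    decoy = tg$decoy_set$info$decoy[d]))
      } else {
        g <- featurize_graph(g, dec, msa_chain1 = neff[1],
                             msa_chain2 = neff[2], msa_paired = neff[3],
                             sasa_points = sasa_points)
        g <- label_graph(g, tg$native)
      }
      graphs[length(graphs) + 1L] <- list(g)   # keeps NULL entries
      targets <- c(targets, tg$target_id)
      decoys <- c(decoys, tg$decoy_set$info$decoy[d])
      dockq <- c(dockq, tg$decoy_set$info$dockq[d])
    }
  }
  list(graphs = graphs, targets = targets, decoys = decoys, dockq = dockq,
       skipped = skipped)
}

#' Score every decoy of a bundle with a trained network
#'
#' A decoy with an empty interface receives Q = 0 (no interface is treated
#' as a maximally wrong interface).
#'
#' @param bundle `decoy_bundle`.
#' @param params trained `gat_params`.
#' @param sasa_points sphere points for the internal SASA computation.
#' @param target_ids optional subset of targets to score.
#' @return `ranking_table` with one row per decoy (`target`, `decoy`,
#'   `score` = predicted Q, `dockq` = ground truth).
#' @export
score_bundle <- function(bundle, params, sasa_points = 92,
                         target_ids = NULL) {
  rows <- list()
  for (tg in bundle) {
    if (!is.null(target_ids) && !(tg$target_id %in% target_ids)) next
    info <- tg$decoy_set$info
    neff <- bundle_neff(tg)
    q <- vapply(seq_along(tg$decoy_set$decoys), function(d) {
      dec <- tg$decoy_set$decoys[[d]]
      g <- tryCatch(build_interface_graph(dec),
                    empty_interface = function(e) NULL)
      if (is.null(g)) return(0)
      g <- featurize_graph(g, dec, msa_chain1 = neff[1], msa_chain2 = neff[2],
                           msa_paired = neff[3], sasa_points = sasa_points)
      model_forward(g, params)$Q
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      ranking_table(rep(tg$target_id, nrow(info)), info$decoy, q, info$dockq)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Score a single complex model
#'
#' Builds, featurizes and scores the interface graph of one model.
#'
#' @param cplx `complex_structure` or path to a PDB file.
#' @param params `gat_params`.
#' @param msa_chain1,msa_chain2,msa_paired optional `iq_msa` objects or
#'   file paths.
#' @param dssp optional DSSP output file path.
#' @param on_empty_interface `"zero"` (return Q = 0) or `"error"`.
#' @return list with `Q` and `edge_scores` (`NULL` when the interface is
#'   empty and `on_empty_interface = "zero"`).
#' @export
score_complex <- function(cplx, params, msa_chain1 = NULL,
                          msa_chain2 = NULL, msa_paired = NULL, dssp = NULL,
                          on_empty_interface = c("zero", "error")) {
  on_empty_interface <- match.arg(on_empty_interface)
  if (is.character(cplx)) cplx <- read_complex_pdb(cplx)
  as_msa <- function(x) if (is.character(x)) read_msa(x) else x
  g <- tryCatch(build_interface_graph(cplx),
                empty_interface = function(e)
                  if (on_empty_interface == "zero") NULL else stop(e))
  if (is.null(g)) return(list(Q = 0, edge_scores = NULL))
  dssp_tab <- if (is.character(dssp)) read_dssp(dssp) else dssp
  g <- featurize_graph(g, cplx, msa_chain1 = as_msa(msa_chain1),
                       msa_chain2 = as_msa(msa_chain2),
                       msa_paired = as_msa(msa_paired), dssp = dssp_tab)
  fw <- model_forward(g, params)
  list(Q = fw$Q, edge_scores = fw$edge_scores, graph = g)
}
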