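# Ground-truth evaluation: Fnat, ligand and interface RMSD, DockQ with
# CAPRI classes, and the ranking/assessment metrics (success rate, hit
# rate, Spearman correlation, ROC-AUC, min-max normalization).

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# stacked atom coordinates for one chain: list(xyz, res, atom)
chain_atoms <- function(chain, atoms = c("N", "CA", "C", "O", "CB")) {
  xs <- list(); res <- integer(0); atom <- character(0)
  for (el in atoms) {
    m <- chain[[el]]
    fin <- which(is.finite(m[, 1]))
    if (length(fin) > 0L) {
      xs[[length(xs) + 1L]] <- m[fin, , drop = FALSE]
      res <- c(res, fin)
      atom <- c(atom, rep(el, length(fin)))
    }
  }
  list(xyz = do.call(rbind, xs), res = res, atom = atom)
}

# backbone coordinates present in BOTH structures, matched row-by-row
matched_backbone <- function(chain_a, chain_b, residues = NULL) {
  if (is.null(residues)) residues <- seq_len(chain_length(chain_a))
  A <- list(); B <- list()
  for (el in BACKBONE_ATOMS) {
    ma <- chain_a[[el]][residues, , drop = FALSE]
    mb <- chain_b[[el]][residues, , drop = FALSE]
    ok <- is.finite(ma[, 1]) & is.finite(mb[, 1])
    if (any(ok)) {
      A[[length(A) + 1L]] <- ma[ok, , drop = FALSE]
      B[[length(B) + 1L]] <- mb[ok, , drop = FALSE]
    }
  }
  list(a = do.call(rbind, A), b = do.call(rbind, B))
}

check_correspondence <- function(model, native) {
  if (model$L1 != native$L1 || model$L2 != native$L2)
    stop("model/native chain lengths differ (",
         model$L1, "/", model$L2, " vs ", native$L1, "/", native$L2, ")")
  for (ch in 1:2) {
    ident <- mean(model$chains[[ch]]$aa == native$chains[[ch]]$aa)
    if (ident < 0.95)
      stop("model/native sequences differ on chain ", ch,
           sprintf(" (identity %.2f)", ident))
  }
  invisible(TRUE)
}

# residue-pair contact map from any-heavy-atom distances
residue_contact_map <- function(cplx, cutoff) {
  a1 <- chain_atoms(cplx$chains[[1]])
  a2 <- chain_atoms(cplx$chains[[2]])
  d2 <- outer(rowSums(a1$xyz^2), rowSums(a2$xyz^2), "+") -
    2 * (a1$xyz %*% t(a2$xyz))
  close <- d2 < cutoff^2
  own1 <- matrix(0, length(a1$res), cplx$L1)
  own1[cbind(seq_along(a1$res), a1$res)] <- 1
  own2 <- matrix(0, length(a2$res), cplx$L2)
  own2[cbind(seq_along(a2$res), a2$res)] <- 1
  (t(own1) %*% close %*% own2) > 0
}

#' Fraction of native contacts reproduced in a model
#'
#' A native contact is an inter-chain residue pair with any pair of heavy
#' atoms (over the atoms present in the structures, typically backbone plus
#' Cbeta for decoys) closer than `contact_cutoff`. Fnat is the fraction of
#' those pairs that are also in contact in the model.
#'
#' @param model,native residue-correspondent `complex_structure`s.
#' @param contact_cutoff heavy-atom distance cutoff (Angstrom).
#' @return fraction in `[0, 1]`.
#' @export
compute_fnat <- function(model, native, contact_cutoff = 5.0) {
  check_correspondence(model, native)
  nat <- residue_contact_map(native, contact_cutoff)
  if (!any(nat))
    stop("native structure has no inter-chain contacts at ",
         contact_cutoff, " Angstrom; not a complex")
  mod <- residue_contact_map(model, contact_cutoff)
  sum(nat & mod) / sum(nat)
}

#' Ligand RMSD
#'
#' Backbone RMSD of the ligand (second) chain after superposing the model
#' onto the native using the receptor (first) chain backbone only.
#'
#' @param model,native residue-correspondent `complex_structure`s.
#' @return LRMS in Angstrom.
#' @export
compute_lrms <- function(model, native) {
  check_correspondence(model, native)
  rec <- matched_backbone(model$chains[[1]], native$chains[[1]])
  fit <- superpose_kabsch(rec$a, rec$b)
  lig <- matched_backbone(model$chains[[2]], native$chains[[2]])
  moved <- apply_transform(lig$a, fit$rotation, fit$translation)
  coord_rmsd(moved, lig$b)
}

# native-interface residues: any cross-chain interaction-coordinate pair
# within cutoff
native_interface_residues <- function(native, cutoff = 10.0) {
  x1 <- as_mat3(interaction_coordinate(native$chains[[1]]))
  x2 <- as_mat3(interaction_coordinate(native$chains[[2]]))
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * (x1 %*% t(x2))
  hit <- d2 < cutoff^2
  list(res1 = which(rowSums(hit) > 0), res2 = which(colSums(hit) > 0))
}

#' Interface RMSD
#'
#' Backbone RMSD over the native-interface residues (any cross-chain
#' Cbeta/Calpha pair within `iface_cutoff` in the native), after
#' superposing the model onto the native over exactly those residues.
#'
#' @param model,native residue-correspondent `complex_structure`s.
#' @param iface_cutoff interface definition cutoff (Angstrom).
#' @return iRMS in Angstrom.
#' @export
compute_irms <- function(model, native, iface_cutoff = 10.0) {
  check_correspondence(model, native)
  ifr <- native_interface_residues(native, iface_cutoff)
  b1 <- matched_backbone(model$chains[[1]], native$chains[[1]], ifr$res1)
  b2 <- matched_backbone(model$chains[[2]], native$chains[[2]], ifr$res2)
  A <- rbind(b1$a, b2$a); B <- rbind(b1$b, b2$b)
  superpose_kabsch(A, B)$rmsd
}

#' DockQ score from its components
#'
#' `DockQ = (Fnat + 1/(1+(LRMS/8.5)^2) + 1/(1+(iRMS/1.5)^2)) / 3`, with the
#' scaled-RMS constants d1 = 8.5 and d2 = 1.5 Angstrom, plus the standard
#' CAPRI class (incorrect < 0.23 <= acceptable < 0.49 <= medium < 0.80 <=
#' high).
#'
#' @param fnat fraction of native contacts.
#' @param lrms,irms RMS deviations in Angstrom.
#' @param d1,d2 scaling constants.
#' @return list of class `dockq_result`: `fnat`, `lrms`, `irms`, `dockq`,
#'   `capri_class`.
#' @export
compute_dockq <- function(fnat, lrms, irms, d1 = 8.5, d2 = 1.5) {
  stopifnot(fnat >= 0, fnat <= 1, lrms >= 0, irms >= 0)
  rms_scaled <- function(rms, d) 1 / (1 + (rms / d)^2)
  dockq <- (fnat + rms_scaled(lrms, d1) + rms_scaled(irms, d2)) / 3
  cls <- if (dockq < 0.23) "incorrect" else if (dockq < 0.49) "acceptable"
         else if (dockq < 0.80) "medium" else "high"
  structure(list(fnat = fnat, lrms = lrms, irms = irms, dockq = dockq,
                 capri_class = cls), class = "dockq_result")
}

#' DockQ of a model against its native
#'
#' Convenience wrapper computing Fnat, LRMS and iRMS and combining them
#' with [compute_dockq()].
#'
#' @param model,native residue-correspondent `complex_structure`s.
#' @param contact_cutoff Fnat contact cutoff (Angstrom).
#' @param iface_cutoff iRMS interface cutoff (Angstrom).
#' @return `dockq_result`.
#' @export
dockq_score <- function(model, native, contact_cutoff = 5.0,
                        iface_cutoff = 10.0) {
  compute_dockq(compute_fnat(model, native, contact_cutoff),
                compute_lrms(model, native),
                compute_irms(model, native, iface_cutoff))
}

# --- ranking metrics -----------------------------------------------------

#' Assemble a ranking table
#'
#' @param target,decoy identifiers (vectors of equal length).
#' @param score predicted quality per decoy.
#' @param dockq ground-truth DockQ per decoy.
#' @return data.frame of class `ranking_table`.
#' @export
ranking_table <- function(target, decoy, score, dockq) {
  out <- data.frame(target = as.character(target),
                    decoy = as.character(decoy),
                    score = score, dockq = dockq,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranking_table", "data.frame")
  out
}

# per-target top-N rows, descending score, stable on ties (input order)
top_n_rows <- function(tab, N) {
  unlist(lapply(split(seq_len(nrow(tab)), tab$target), function(ix) {
    ix[order(-tab$score[ix])][seq_len(min(N, length(ix)))]
  }), use.names = FALSE)
}

#' Top-N success rate
#'
#' Percentage of targets with at least one acceptable decoy
#' (DockQ >= `threshold`) among their top-N decoys ranked by predicted
#' score (descending; ties kept in input order).
#'
#' @param tab `ranking_table`.
#' @param N ranking depth.
#' @param threshold acceptability cutoff on DockQ.
#' @return percentage in `[0, 100]`.
#' @export
success_rate <- function(tab, N, threshold = 0.23) {
  top <- tab[top_n_rows(tab, N), , drop = FALSE]
  hit <- tapply(top$dockq >= threshold, top$target, any)
  100 * sum(hit) / length(unique(tab$target))
}

#' Top-N hit rate
#'
#' Acceptable decoys captured within the per-target top-N lists, as a
#' percentage of all acceptable decoys in the dataset.
#'
#' @inheritParams success_rate
#' @return percentage in `[0, 100]`.
#' @export
hit_rate <- function(tab, N, threshold = 0.23) {
  M <- sum(tab$dockq >= threshold)
  if (M == 0L) stop("no acceptable decoys in the dataset (M = 0)")
  top <- tab[top_n_rows(tab, N), , drop = FALSE]
  100 * sum(top$dockq >= threshold) / M
}

#' Spearman correlation between predicted and ground-truth quality
#'
#' Rank correlation with average-rank tie handling.
#'
#' @param pred predicted scores.
#' @param truth ground-truth DockQ values.
#' @return Spearman rho; `NA` with a warning if either vector has zero
#'   variance.
#' @export
score_correlation <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 3L)
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("zero variance; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(pred, truth, method = "spearman")
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen acceptable decoy outscores a randomly
#' chosen incorrect one, ties counted half (the normalized Mann-Whitney U
#' statistic).
#'
#' @param pred predicted scores.
#' @param labels logical, `TRUE` for acceptable decoys.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pred, labels) {
  stopifnot(length(pred) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("ROC-AUC needs both classes (", n1, " positive, ", n0, " negative)")
  r <- rank(pred)  # average ranks on ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Min-max normalization of raw energy scores
#'
#' `(X - Xmax) / (Xmin - Xmax)` per target: the lowest (best) energy maps
#' to 1 and the highest to 0, putting energy scores on the same
#' higher-is-better `[0, 1]` scale as predicted quality scores.
#'
#' @param raw numeric vector of raw scores for one target (>= 2 distinct
#'   values).
#' @return normalized scores in `[0, 1]`.
#' @export
minmax_normalize <- function(raw) {
  if (length(unique(raw)) < 2L)
    stop("min-max normalization undefined: all values equal")
  (raw - max(raw)) / (min(raw) - max(raw))
}

#' Summarize ranking performance of a decoy set
#'
#' SR and HR at the standard reporting depths plus Spearman rho and
#' ROC-AUC at the acceptability cutoff.
#'
#' @param tab `ranking_table`.
#' @param Ns ranking depths to evaluate.
#' @param threshold acceptability DockQ cutoff.
#' @return list with `summary` (data.frame of SR/HR per N), `spearman`,
#'   `auc` (`NA` when only one class is present).
#' @export
evaluate_ranking <- function(tab, Ns = c(1, 5, 10, 15, 20, 25, 30),
                             threshold = 0.23) {
  summ <- data.frame(
    N = Ns,
    SR = vapply(Ns, function(N) success_rate(tab, N, threshold), numeric(1)),
    HR = vapply(Ns, function(N) hit_rate(tab, N, threshold), numeric(1)))
  lab <- tab$dockq >= threshold
  auc <- if (any(lab) && !all(lab)) roc_auc(tab$score, lab) else NA_real_
  list(summary = summ,
       spearman = score_correlation(tab$score, tab$dockq),
       auc = auc)
}

#' Write per-decoy and summary evaluation TSVs
#'
#' @param tab `ranking_table` (optionally with extra columns such as
#'   `fnat`, `lrms`, `irms`, `capri_class`).
#' @param dir output directory (created if needed).
#' @param ... passed to [evaluate_ranking()].
#' @return list of written paths, invisibly.
#' @export
write_evaluation <- function(tab, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_decoy <- file.path(dir, "per_decoy.tsv")
  utils::write.table(as.data.frame(tab), per_decoy, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ev <- evaluate_ranking(tab, ...)
  summ <- ev$summary
  summ$spearman <- ev$spearman
  summ$auc <- ev$auc
  summary_path <- file.path(dir, "summary.tsv")
  utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(per_decoy = per_decoy, summary = summary_path))
}
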