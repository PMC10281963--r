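# Evolutionary node features: normalized effective sequence counts (Neff)
# from each monomer alignment and from the paired (concatenated) alignment.

#' Read a multiple sequence alignment (FASTA or A3M)
#'
#' A3M lowercase insertion columns are removed so every row aligns to the
#' query columns. Duplicate rows are retained; the first row is the query.
#'
#' @param path alignment file.
#' @return object of class `iq_msa`: list with `sequences` (character
#'   vector of equal-length upper-case rows), `names`, and `query_length`.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("MSA file not found: ", path)
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE, forceDNAtolower = FALSE),
    error = function(e) stop("empty or unreadable MSA file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (length(seqs) == 0L) stop("empty MSA file: ", path)
  rows <- vapply(seqs, function(s) gsub("[a-z.]", "", s), character(1))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment in ", path, " after removing insertion columns (",
         paste(unique(widths), collapse = ", "), ")")
  new_msa(unname(rows), names(seqs))
}

new_msa <- function(sequences, names = NULL) {
  stopifnot(length(sequences) >= 1L,
            length(unique(nchar(sequences))) == 1L)
  query_length <- sum(strsplit(sequences[[1]], "")[[1]] != "-")
  structure(list(sequences = sequences,
                 names = names %||% paste0("seq", seq_along(sequences)),
                 query_length = query_length),
            class = "iq_msa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an alignment as FASTA/A3M
#' @param msa `iq_msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  seqinr::write.fasta(as.list(msa$sequences), names = msa$names,
                      file.out = path, nbchar = 1e6)
  invisible(path)
}

#' Effective number of sequences (Neff)
#'
#' Neff is the sum over rows of the reciprocal of the number of rows
#' (including the row itself) with sequence identity strictly greater than
#' `identity_threshold` to it. Identity between two rows is the number of
#' positions where both rows carry the same non-gap residue, divided by the
#' alignment's query length.
#'
#' @param msa `iq_msa`.
#' @param identity_threshold clustering threshold (default 0.8, strict
#'   `>`).
#' @return Neff, a real number in `[1/N, N]` for N rows (equal to N when
#'   all rows are mutually dissimilar, 1 when all are identical).
#' @export
effective_sequence_count <- function(msa, identity_threshold = 0.8) {
  stopifnot(inherits(msa, "iq_msa"))
  mat <- do.call(rbind, strsplit(msa$sequences, ""))
  N <- nrow(mat)
  L <- msa$query_length
  nongap <- mat != "-"
  id <- matrix(0, N, N)
  for (i in seq_len(N)) {
    # positions matching row i's non-gap residue (a match implies non-gap
    # in both rows)
    same <- (mat == rep(mat[i, ], each = N)) & nongap
    id[i, ] <- rowSums(same) / L
  }
  clus <- rowSums(id > identity_threshold)
  sum(1 / clus)
}

#' Normalized effective sequence count
#'
#' @param neff Neff value.
#' @param L query length of the alignment.
#' @return `neff / sqrt(L)`.
#' @export
normalized_neff <- function(neff, L) {
  stopifnot(L >= 1)
  neff / sqrt(L)
}

#' Per-node evolutionary features
#'
#' Each node of chain c receives the normalized Neff of that chain's
#' monomer alignment; every node receives the same normalized Neff of the
#' paired alignment. A missing alignment contributes 0 with a warning.
#'
#' @param graph `interface_graph`.
#' @param msa_chain1,msa_chain2,msa_paired `iq_msa` objects, precomputed
#'   normalized-Neff scalars, or `NULL`.
#' @param identity_threshold passed to [effective_sequence_count()].
#' @return n x 2 matrix, columns `(neff_monomer, neff_paired)`.
#' @export
node_evolutionary_features <- function(graph, msa_chain1 = NULL,
                                       msa_chain2 = NULL, msa_paired = NULL,
                                       identity_threshold = 0.8) {
  norm_or_zero <- function(msa, what) {
    if (is.null(msa)) {
      warning("no ", what, " alignment supplied; Neff feature set to 0")
      return(0)
    }
    if (is.numeric(msa)) return(msa)   # precomputed normalized Neff
    normalized_neff(effective_sequence_count(msa, identity_threshold),
                    msa$query_length)
  }
  v1 <- norm_or_zero(msa_chain1, "chain-1")
  v2 <- norm_or_zero(msa_chain2, "chain-2")
  vp <- norm_or_zero(msa_paired, "paired")
  n <- nrow(graph$nodes)
  cbind(neff_monomer = ifelse(graph$nodes$chain == 1L, v1, v2),
        neff_paired = rep(vp, n))
}
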