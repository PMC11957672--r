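#' Threshold probabilities into per-class binding calls
#'
#' A residue is called binding to class C iff its class-C probability is at
#' least the threshold (the comparison is inclusive, `>= 0.5` by default).
#' The rule is applied per class independently, so a residue may be called
#' for several ligand classes at once; it is non-binding only if all three
#' probabilities stay below the threshold.
#'
#' @param probs L x 3 probability matrix (metal, nucleic, small).
#' @param threshold call threshold in (0, 1); default 0.5.
#' @return L x 3 binary integer matrix.
#' @export
call_binding <- function(probs, threshold = 0.5) {
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  m <- matrix(as.integer(probs >= threshold), nrow(probs), ncol(probs))
  colnames(m) <- colnames(probs) %||% LIGAND_CLASSES
  m
}

#' Binary binding reduction
#'
#' A residue binds (binary task) iff any ligand class fires: the binary
#' call is the logical OR of the three class calls.
#'
#' @param calls L x 3 binary call matrix from [call_binding()].
#' @return integer vector of length L.
#' @export
to_binary <- function(calls) {
  as.integer(rowSums(calls) > 0)
}

#' Per-residue prediction reliability
#'
#' The reliability score of a residue is its maximum class probability;
#' higher scores correlate with higher precision (see
#' [reliability_table()]). The per-class probabilities themselves are also
#' available for class-specific reliability analyses.
#'
#' @param probs L x 3 probability matrix.
#' @return numeric vector of length L.
#' @export
reliability <- function(probs) {
  apply(probs, 1, max)
}

#' Predict binding probabilities for a set of proteins
#'
#' Deterministic inference pass (dropout off) of one model over prepared
#' inputs.
#'
#' @param model a `gnn_model`.
#' @param inputs named list of protein inputs (see [prepare_inputs()]).
#' @return named list of L x 3 probability matrices.
#' @export
predict_proteins <- function(model, inputs) {
  out <- lapply(inputs, function(x) {
    p <- forward_model(model, x$embedding, x$graph, x$dssp,
                       training = FALSE)$probs
    colnames(p) <- LIGAND_CLASSES
    p
  })
  stats::setNames(out, names(inputs))
}
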