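# Shared helpers: hand-built graphs, tiny PDB fixtures, brute-force oracles.

# residue_graph constructed directly from an edge list (i < j, 1-based).
manual_graph <- function(n, edges, weights, distances = NULL, threshold = NA) {
  edges <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  g <- list(n_nodes = n, edges = edges, weights = as.numeric(weights),
            distances = distances %||% rep(1, nrow(edges)),
            threshold = threshold)
  class(g) <- "residue_graph"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force O(L^2) graph construction, independent of build_graph().
brute_force_graph <- function(coords, threshold) {
  L <- nrow(coords)
  edges <- list(); weights <- numeric(0)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= threshold) {
        edges[[length(edges) + 1]] <- c(i, j)
        weights <- c(weights, max(1 - d / threshold, 1e-6))
      }
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
         matrix(integer(0), ncol = 2),
       weights = weights)
}

# Direct transcription of the five confusion-metric formulas (with the
# same zero-denominator conventions), independent of metrics().
direct_metrics <- function(tp, fp, tn, fn) {
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(
    mcc = if (den > 0) (tp * tn - fn * fp) / den else 0,
    precision = prec,
    recall = rec,
    accuracy = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else 0,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  )
}

# One-residue PDB file content (CA at 1,2,3 with B-factor 88.5).
single_residue_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 88.50           C",
    "TER", "END"), path)
  path
}

# Three-residue helix-like fixture with coordinates on the 3-decimal PDB grid.
helix_fixture <- function() {
  cs <- list(
    protein_id = "HLX",
    ca_coords = matrix(c(0.000, 0.000, 0.000,
                         2.300, 2.700, 1.500,
                         0.800, 5.200, 3.000), 3, 3, byrow = TRUE),
    plddt = c(90.25, 77.50, 61.75),
    sequence = "AGL",
    resno = 1:3)
  class(cs) <- "coordinate_set"
  cs
}

# Small prepared training set with a planted signal (fast: low embedding dim).
small_training_set <- function(n = 30, d = 8, signal = 3, seed = 5,
                               threshold = 17) {
  fx <- generate_fixture_set(fixture_spec(
    n_proteins = n, length_range = c(40, 60), d = d, signal = signal,
    seed = seed))
  list(fx = fx,
       inputs = prepare_inputs(fx$coord_sets, fx$embeddings, fx$labels,
                               threshold = threshold))
}
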