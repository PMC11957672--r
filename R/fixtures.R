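#' Synthetic fixture specification
#'
#' Declares the study conditions a generated dataset emulates: chain
#' geometry with realistic consecutive C-alpha spacing, per-residue
#' embeddings carrying a plantable class signal, DSSP-like records and
#' multi-label binding annotations with the strong class imbalance of real
#' binding data (roughly 10 % of residues binding under the defaults).
#'
#' @param n_proteins number of proteins (default 100).
#' @param length_range inclusive range of chain lengths L (default 80-120).
#' @param d embedding dimension (default 1024, the width of the pLM used by
#'   the final published model).
#' @param n_pockets pocket sites planted per protein (default 2).
#' @param pocket_radius Angstrom radius of a pocket: residues whose
#'   C-alpha lies within it get the pocket's class label (default 7, which lands total binding
#'   prevalence near 10 % on random-walk chains).
#' @param signal signal strength s >= 0 of the class direction added to the
#'   embeddings of labeled residues; 0 is the null model (default 3).
#' @param class_probs sampling probabilities of the pocket class
#'   (metal, nucleic, small); default (0.3, 0.3, 0.4).
#' @param seed master seed; everything downstream is derived from it.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 100, length_range = c(80, 120), d = 1024,
                         n_pockets = 2, pocket_radius = 7, signal = 3,
                         class_probs = c(metal = 0.3, nucleic = 0.3, small = 0.4),
                         seed = 1) {
  assert_that(signal >= 0, "signal strength must be >= 0")
  assert_that(d >= 3, "embedding dimension must be at least 3")
  structure(list(n_proteins = n_proteins, length_range = length_range, d = d,
                 n_pockets = n_pockets, pocket_radius = pocket_radius,
                 signal = signal, class_probs = class_probs, seed = seed),
            class = "fixture_spec")
}

#' Generate a self-avoiding random-walk C-alpha chain
#'
#' Consecutive C-alpha atoms are placed exactly 3.8 Angstrom apart (the
#' trans-peptide spacing); every non-adjacent pair is kept at least 4.5
#' Angstrom apart by rejection. Consequently a 4 Angstrom contact graph on
#' such a chain contains exactly the backbone edges (i, i+1). pLDDT is
#' drawn uniformly from \[50, 100\].
#'
#' @param L chain length.
#' @param seed RNG seed (same seed, same chain).
#' @return a `coordinate_set` (without sequence).
#' @export
generate_chain <- function(L, seed) {
  set.seed(seed)
  step <- 3.8
  min_sep <- 4.5
  for (attempt in 1:100) {
    coords <- matrix(0, L, 3)
    stuck <- FALSE
    i <- 2
    while (i <= L) {
      placed <- FALSE
      for (k in 1:300) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- coords[i - 1, ] + step * u
        clash <- i > 2 &&
          min(sqrt(colSums((t(coords[seq_len(i - 2), , drop = FALSE]) - cand)^2))) < min_sep
        if (!clash) {
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { stuck <- TRUE; break }
      i <- i + 1
    }
    if (!stuck) {
      out <- list(protein_id = NULL, ca_coords = coords,
                  plddt = stats::runif(L, 50, 100), resno = seq_len(L))
      class(out) <- "coordinate_set"
      return(out)
    }
  }
  stop("failed to grow a self-avoiding chain of length ", L)
}

#' Plant ligand-binding pockets on a chain
#'
#' Chooses pocket-center residues, assigns each pocket a ligand class drawn
#' from the spec's class probabilities, and labels every residue whose
#' C-alpha lies within the pocket radius of the center with that class.
#' Pockets may overlap, so a residue can end up multi-labeled -- as in real
#' annotations.
#'
#' @param coords L x 3 C-alpha coordinates.
#' @param spec a [fixture_spec()] (uses n_pockets, pocket_radius,
#'   class_probs).
#' @param seed RNG seed.
#' @return L x 3 binary label matrix (metal, nucleic, small).
#' @export
plant_sites <- function(coords, spec, seed) {
  set.seed(seed)
  L <- nrow(coords)
  labels <- matrix(0L, L, 3, dimnames = list(NULL, LIGAND_CLASSES))
  centers <- sample(L, min(spec$n_pockets, L))
  classes <- sample(1:3, length(centers), replace = TRUE, prob = spec$class_probs)
  for (p in seq_along(centers)) {
    d <- sqrt(colSums((t(coords) - coords[centers[p], ])^2))
    labels[d <= spec$pocket_radius, classes[p]] <- 1L
  }
  labels
}

#' Generate embeddings with a plantable class signal
#'
#' Each residue's embedding is unit Gaussian noise plus, for every class it
#' is labeled with, `s` times that class's direction. The class directions
#' are fixed orthogonal unit vectors (the first three coordinate axes), so
#' `s = 0` gives label-independent pure noise (the null model) and large
#' `s` makes the classes linearly separable.
#'
#' @param labels L x 3 binary label matrix.
#' @param d embedding dimension (>= 3).
#' @param s signal strength.
#' @param seed RNG seed.
#' @return L x d numeric matrix.
#' @export
generate_embeddings <- function(labels, d, s, seed) {
  set.seed(seed)
  L <- nrow(labels)
  mu <- matrix(0, 3, d)
  mu[cbind(1:3, 1:3)] <- 1
  s * (labels %*% mu) + matrix(stats::rnorm(L * d), L, d)
}

#' Generate DSSP-like per-residue records
#'
#' Emulates the fields a DSSP run would provide: persistent runs of
#' secondary-structure classes, backbone dihedrals on the 0.1-degree grid
#' (undefined at the termini, as DSSP reports), relative solvent
#' accessibility, and four H-bond (relative index, energy) pairs. Values
#' are draws with DSSP-like ranges, not a geometric recomputation from the
#' coordinates.
#'
#' @param coords L x 3 coordinates (fixes L).
#' @param seed RNG seed.
#' @param sequence optional one-letter sequence (random otherwise).
#' @return data.frame with the [parse_dssp()] columns.
#' @export
generate_dssp_like <- function(coords, seed, sequence = NULL) {
  set.seed(seed)
  L <- nrow(coords)
  aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aa <- if (is.null(sequence)) sample(aa_letters, L, replace = TRUE)
        else strsplit(sequence, "")[[1]]
  ss <- character(L)
  ss[1] <- sample(DSSP_SS_CLASSES, 1)
  for (i in seq_len(L)[-1]) {
    ss[i] <- if (stats::runif(1) < 0.8) ss[i - 1] else sample(DSSP_SS_CLASSES, 1)
  }
  grid <- function(x) round(x, 1)
  out <- data.frame(
    residue_index = seq_len(L), aa = aa, ss = ss,
    phi = c(NA, grid(stats::runif(L - 1, -180, 180))),
    psi = c(grid(stats::runif(L - 1, -180, 180)), NA),
    rsa = round(stats::runif(L), 2),
    stringsAsFactors = FALSE
  )
  for (k in 1:4) {
    out[[paste0("hb_relidx_", k)]] <- sample(-6:6, L, replace = TRUE)
    out[[paste0("hb_energy_", k)]] <- grid(stats::runif(L, -4, 0))
  }
  out
}

#' Generate a complete in-memory fixture set
#'
#' Produces every artifact the pipeline consumes, mutually consistent:
#' protein records, chains, labels, embeddings, DSSP records and a 5-fold
#' split assignment (round-robin). Fully deterministic under the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return list: `records` (data.frame), `coord_sets`, `labels`,
#'   `embeddings`, `dssp_records`, `dssp_features` (normalized L x 20),
#'   `splits`.
#' @export
generate_fixture_set <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                 spec$n_proteins, replace = TRUE)
  ids <- sprintf("SYN%04d", seq_len(spec$n_proteins))
  aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  coord_sets <- list(); labels <- list(); embeddings <- list()
  dssp_records <- list(); dssp_features <- list(); seqs <- character(spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    s0 <- derive_seed(spec$seed, 10 * i)
    cs <- generate_chain(lens[i], s0)
    cs$protein_id <- ids[i]
    set.seed(derive_seed(spec$seed, 10 * i + 1))
    seqs[i] <- paste(sample(aa_letters, lens[i], replace = TRUE), collapse = "")
    cs$sequence <- seqs[i]
    lab <- plant_sites(cs$ca_coords, spec, derive_seed(spec$seed, 10 * i + 2))
    emb <- generate_embeddings(lab, spec$d, spec$signal,
                               derive_seed(spec$seed, 10 * i + 3))
    dr <- generate_dssp_like(cs$ca_coords, derive_seed(spec$seed, 10 * i + 4),
                             sequence = seqs[i])
    coord_sets[[ids[i]]] <- cs
    labels[[ids[i]]] <- lab
    embeddings[[ids[i]]] <- emb
    dssp_records[[ids[i]]] <- dr
    dssp_features[[ids[i]]] <- normalize_features(dr, lens[i])
  }
  records <- data.frame(id = ids, sequence = seqs, length = lens,
                        stringsAsFactors = FALSE)
  splits <- stats::setNames(as.character(rep_len(1:5, spec$n_proteins)), ids)
  list(records = records, coord_sets = coord_sets, labels = labels,
       embeddings = embeddings, dssp_records = dssp_records,
       dssp_features = dssp_features, splits = splits, spec = spec)
}

#' Write a fixture set to disk in every pipeline format
#'
#' Emits `structures/<id>.pdb` (coordinates at PDB precision),
#' `sequences.fasta`, `embeddings/<id>.tsv`, `dssp/<id>.dssp`,
#' `labels.tsv` and `splits.tsv` under `outdir`. The emitted files pass
#' [validate_lengths()] with zero exclusions and drive the full pipeline
#' end-to-end.
#'
#' @param fixture a fixture set from [generate_fixture_set()] (or a
#'   [fixture_spec()], which is generated first).
#' @param outdir output directory (created if needed).
#' @return named list of the paths written.
#' @export
emit_fixture_set <- function(fixture, outdir) {
  if (inherits(fixture, "fixture_spec")) fixture <- generate_fixture_set(fixture)
  dir.create(file.path(outdir, "structures"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "dssp"), recursive = TRUE, showWarnings = FALSE)
  for (id in fixture$records$id) {
    cs <- fixture$coord_sets[[id]]
    cs$ca_coords <- round(cs$ca_coords, 3)
    cs$plddt <- round(cs$plddt, 2)
    write_structure(cs, file.path(outdir, "structures", paste0(id, ".pdb")))
    write_dssp(fixture$dssp_records[[id]],
               file.path(outdir, "dssp", paste0(id, ".dssp")))
  }
  write_fasta_records(fixture$records, file.path(outdir, "sequences.fasta"))
  write_embeddings(fixture$embeddings, file.path(outdir, "embeddings"))
  write_labels(fixture$labels, file.path(outdir, "labels.tsv"))
  write_splits(fixture$splits, file.path(outdir, "splits.tsv"))
  list(structures = file.path(outdir, "structures"),
       dssp = file.path(outdir, "dssp"),
       fasta = file.path(outdir, "sequences.fasta"),
       embeddings = file.path(outdir, "embeddings"),
       labels = file.path(outdir, "labels.tsv"),
       splits = file.path(outdir, "splits.tsv"))
}
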