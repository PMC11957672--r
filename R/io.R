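## Three-letter -> one-letter amino acid map; anything unknown becomes X so
## that non-standard residues keep the structure/sequence lengths in step.
aa_three_to_one <- function(resid) {
  one <- bio3d::aa321(resid)
  one[is.na(one) | !(one %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))] <- "X"
  one
}

#' Read a predicted protein structure (PDB or mmCIF)
#'
#' Extracts one C-alpha row per residue, in residue-number order, from a
#' single-chain predicted-structure file. Per-residue pLDDT confidence is
#' taken from the B-factor column, the convention of AlphaFold DB and
#' ColabFold output. Multi-model and multi-chain files are rejected rather
#' than silently truncated or concatenated; a residue without a C-alpha
#' atom is an error. Non-standard residues are kept (sequence letter `X`)
#' as long as they have a C-alpha, preserving length agreement with the
#' FASTA sequence.
#'
#' @param path a `.pdb` or `.cif`/`.mmcif` file.
#' @param protein_id identifier to attach; defaults to the file base name.
#' @return a `coordinate_set`: list with `protein_id`, `ca_coords`
#'   (L x 3 matrix, Angstrom), `plddt` (length L, 0-100), `sequence`
#'   (one-letter string) and `resno`.
#' @export
read_structure <- function(path, protein_id = NULL) {
  assert_that(file.exists(path), paste("no such file:", path))
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, multi = TRUE)),
    error = function(e) stop("unparseable structure file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.null(pdb$xyz) && is.matrix(unclass(pdb$xyz)) && nrow(pdb$xyz) > 1) {
    stop("multiple models in ", path, ": ambiguous input, supply a single-model file",
         call. = FALSE)
  }
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  assert_that(nrow(atoms) > 0, paste("no ATOM records in", path))
  chains <- unique(atoms$chain)
  assert_that(length(chains) == 1,
              paste0("multiple chains in ", path, " (",
                     paste(chains, collapse = ","), "); expected a single chain"))
  resno_all <- unique(atoms$resno)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(resno_all, ca$resno)
  assert_that(length(missing_ca) == 0,
              paste("residues missing a C-alpha atom in", path, ":",
                    paste(utils::head(missing_ca, 5), collapse = ",")))
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  coords <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  assert_that(all(is.finite(coords)), paste("non-finite coordinates in", path))
  out <- list(
    protein_id = protein_id %||% sub("\\.(pdb|cif|mmcif)$", "", basename(path),
                                     ignore.case = TRUE),
    ca_coords = coords,
    plddt = as.numeric(ca$b),
    sequence = paste(aa_three_to_one(ca$resid), collapse = ""),
    resno = ca$resno
  )
  class(out) <- "coordinate_set"
  out
}

#' Write a C-alpha trace as a single-chain PDB file
#'
#' Minimal ATOM-record writer for synthetic chains and round-trip tests:
#' one CA atom per residue, chain A, occupancy 1.00, pLDDT in the B-factor
#' column. Coordinates are written at PDB precision (3 decimals), pLDDT at
#' 2; inputs already on that grid round-trip bit-identically.
#'
#' @param coord_set a `coordinate_set` (needs `ca_coords`, `plddt` and
#'   optionally `sequence`).
#' @param path output `.pdb` path.
#' @export
write_structure <- function(coord_set, path) {
  xyz <- coord_set$ca_coords
  L <- nrow(xyz)
  seq1 <- if (!is.null(coord_set$sequence)) strsplit(coord_set$sequence, "")[[1]]
          else rep("A", L)
  three <- vapply(seq1, function(a) {
    r <- bio3d::aa123(a)
    if (is.na(r) || a == "X") "UNK" else r
  }, character(1))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(L), three, seq_len(L), xyz[, 1], xyz[, 2], xyz[, 3],
    1.00, coord_set$plddt
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return data.frame of protein records: `id`, `sequence`, `length`.
#' @export
read_fasta_records <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1)
  seqs <- as.character(aas)
  data.frame(id = ids, sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta_records
#' @param records data.frame with `id` and `sequence` columns.
#' @export
write_fasta_records <- function(records, path) {
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Cross-file length consistency check
#'
#' A protein is kept iff its sequence length, coordinate row count,
#' embedding row count and label row count all agree; proteins failing the
#' check are excluded and reported together with the offending source --
#' mirroring the dataset-construction rule that drops proteins whose
#' predicted structure does not match the sequence. A protein that appears
#' in the labels but not among the sequences is a hard error (corrupt
#' dataset), not an exclusion.
#'
#' @param records protein records data.frame (`id`, `sequence`, `length`).
#' @param coord_sets named list of `coordinate_set`s (NULL to skip).
#' @param embeddings named list of L x d matrices (NULL to skip).
#' @param labels named list of L x 3 label matrices (NULL to skip).
#' @return list with `kept` (character ids) and `excluded` (data.frame:
#'   id, source, expected, found).
#' @export
validate_lengths <- function(records, coord_sets = NULL, embeddings = NULL,
                             labels = NULL) {
  ids <- records$id
  if (!is.null(labels)) {
    orphan <- setdiff(names(labels), ids)
    assert_that(length(orphan) == 0,
                paste("labels reference unknown proteins:",
                      paste(utils::head(orphan, 5), collapse = ",")))
  }
  expect_len <- stats::setNames(records$length, ids)
  excl <- list()
  check <- function(xs, source, nrows) {
    for (id in intersect(names(xs), ids)) {
      found <- nrows(xs[[id]])
      if (found != expect_len[[id]]) {
        excl[[length(excl) + 1]] <<- data.frame(
          id = id, source = source,
          expected = unname(expect_len[[id]]), found = found)
      }
    }
  }
  if (!is.null(coord_sets)) check(coord_sets, "structure", function(x) nrow(x$ca_coords))
  if (!is.null(embeddings)) check(embeddings, "embeddings", nrow)
  if (!is.null(labels))     check(labels, "labels", nrow)
  excluded <- if (length(excl)) do.call(rbind, excl)
              else data.frame(id = character(0), source = character(0),
                              expected = integer(0), found = integer(0))
  list(kept = setdiff(ids, unique(excluded$id)), excluded = excluded)
}

#' Read per-residue binding labels from TSV
#'
#' Format: three columns `protein_id`, `residue_index` (1-based),
#' `class` (one of metal, nucleic, small), with a header line. Absence of
#' rows for a protein means non-binding everywhere; a residue may carry
#' several classes (one row each). Duplicate rows and out-of-range indices
#' are errors.
#'
#' @param path label TSV.
#' @param records protein records (provides ids and lengths).
#' @return named list of L x 3 binary matrices, columns (metal, nucleic,
#'   small), one entry for every protein in `records`.
#' @export
read_labels <- function(path, records) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  names(df) <- c("protein_id", "residue_index", "class")
  assert_that(all(df$class %in% LIGAND_CLASSES),
              paste("unknown ligand class:",
                    paste(setdiff(unique(df$class), LIGAND_CLASSES), collapse = ",")))
  orphan <- setdiff(unique(df$protein_id), records$id)
  assert_that(length(orphan) == 0,
              paste("labels reference unknown proteins:",
                    paste(utils::head(orphan, 5), collapse = ",")))
  key <- paste(df$protein_id, df$residue_index, df$class)
  assert_that(!anyDuplicated(key),
              paste("duplicate label rows, e.g.:", key[duplicated(key)][1]))
  out <- lapply(seq_len(nrow(records)), function(r) {
    L <- records$length[r]
    m <- matrix(0L, L, 3, dimnames = list(NULL, LIGAND_CLASSES))
    sub <- df[df$protein_id == records$id[r], , drop = FALSE]
    if (nrow(sub)) {
      bad <- sub$residue_index < 1 | sub$residue_index > L
      assert_that(!any(bad),
                  sprintf("label residue index out of range for %s (L=%d): %d",
                          records$id[r], L, sub$residue_index[bad][1]))
      m[cbind(sub$residue_index, match(sub$class, LIGAND_CLASSES))] <- 1L
    }
    m
  })
  stats::setNames(out, records$id)
}

#' @rdname read_labels
#' @param labels named list of L x 3 binary matrices.
#' @export
write_labels <- function(labels, path) {
  rows <- lapply(names(labels), function(id) {
    idx <- which(labels[[id]] == 1, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(protein_id = id, residue_index = idx[, 1],
               class = LIGAND_CLASSES[idx[, 2]])
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(protein_id = character(0), residue_index = integer(0),
               class = character(0)))))
  df <- df[order(df$protein_id, df$residue_index, df$class), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write per-protein embedding matrices
#'
#' Embeddings are consumed pre-computed. On disk they live in a directory
#' with one tab-separated text file per protein (`<id>.tsv`, L rows x d
#' numeric columns, no header), written at full precision so matrices
#' round-trip exactly.
#'
#' @param dir embeddings directory.
#' @param ids optional character vector restricting which proteins to read.
#' @return named list of L x d numeric matrices.
#' @export
read_embeddings <- function(dir, ids = NULL) {
  assert_that(dir.exists(dir), paste("no such directory:", dir))
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  fids <- sub("\\.tsv$", "", basename(files))
  if (!is.null(ids)) {
    missing <- setdiff(ids, fids)
    assert_that(length(missing) == 0,
                paste("no embedding file for:",
                      paste(utils::head(missing, 5), collapse = ",")))
    files <- files[match(ids, fids)]
    fids <- ids
  }
  out <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  })
  stats::setNames(out, fids)
}

#' @rdname read_embeddings
#' @param embeddings named list of L x d matrices.
#' @export
write_embeddings <- function(embeddings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(embeddings)) {
    m <- embeddings[[id]]
    txt <- apply(m, 1, function(row) paste(format_full(row), collapse = "\t"))
    writeLines(txt, file.path(dir, paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' Read a cross-validation split assignment
#'
#' TSV with header and columns `protein_id`, `fold`, where fold is `1`-`5`
#' for development proteins or `test`. Every development protein sits in
#' exactly one fold; test is disjoint by construction of the mapping.
#'
#' @param path split TSV.
#' @return named character vector protein_id -> fold.
#' @export
read_splits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  names(df) <- c("protein_id", "fold")
  assert_that(!anyDuplicated(df$protein_id),
              "a protein appears in more than one split row")
  ok <- df$fold %in% c(as.character(1:5), "test")
  assert_that(all(ok), paste("invalid fold value:",
                             paste(unique(df$fold[!ok]), collapse = ",")))
  stats::setNames(df$fold, df$protein_id)
}

#' @rdname read_splits
#' @param splits named character vector protein_id -> fold.
#' @export
write_splits <- function(splits, path) {
  utils::write.table(
    data.frame(protein_id = names(splits), fold = unname(splits)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read per-residue prediction tables
#'
#' TSV columns: `protein_id`, `residue_index` (1-based), `residue`
#' (one-letter), `p_metal`, `p_nucleic`, `p_small` (probabilities, 6
#' decimals) and `calls` (semicolon-joined class names, `-` when
#' non-binding). Probabilities round-trip to within 5e-7.
#'
#' @param probs named list of L x 3 probability matrices.
#' @param sequences named character vector of protein sequences.
#' @param path output TSV.
#' @param threshold per-class call threshold (default 0.5, inclusive).
#' @export
write_predictions <- function(probs, sequences, path, threshold = 0.5) {
  rows <- lapply(names(probs), function(id) {
    p <- probs[[id]]
    calls <- call_binding(p, threshold)
    call_str <- apply(calls, 1, function(cl) {
      if (!any(cl == 1)) "-" else paste(LIGAND_CLASSES[cl == 1], collapse = ";")
    })
    data.frame(protein_id = id, residue_index = seq_len(nrow(p)),
               residue = strsplit(sequences[[id]], "")[[1]],
               p_metal = sprintf("%.6f", p[, 1]),
               p_nucleic = sprintf("%.6f", p[, 2]),
               p_small = sprintf("%.6f", p[, 3]),
               calls = call_str)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$protein_id), function(sub) {
    sub <- sub[order(sub$residue_index), , drop = FALSE]
    m <- as.matrix(sub[, c("p_metal", "p_nucleic", "p_small")])
    dimnames(m) <- list(NULL, LIGAND_CLASSES)
    m
  })
  out
}
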