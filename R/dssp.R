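## DSSP secondary-structure classes, fixed one-hot order.
DSSP_SS_CLASSES <- c("H", "B", "E", "G", "I", "T", "S", "-")

## Maximal accessible surface area per residue (Sander & Rost 1994), used to
## turn DSSP's absolute ACC into relative solvent accessibility in [0,1] --
## the same convention the biopython DSSP wrapper applies. X falls back to
## the glycine-excluded mean-ish value 200.
MAX_ASA <- c(
  A = 106, R = 248, N = 157, D = 163, C = 135, Q = 198, E = 194, G = 84,
  H = 184, I = 169, L = 164, K = 205, M = 188, F = 197, P = 136, S = 130,
  T = 142, W = 227, Y = 222, V = 142, X = 200
)

#' Parse a classic DSSP output file
#'
#' Reads the fixed-column per-residue records of DSSP text output (tolerant
#' of mkdssp 3.x/4.x header variants: data lines are located by the
#' `#  RESIDUE` header). Extracts, per residue: secondary-structure class,
#' phi/psi backbone dihedrals, relative solvent accessibility (absolute ACC
#' divided by the residue's maximal ASA, capped at 1) and the four backbone
#' hydrogen-bond (relative index, energy) pairs.
#'
#' DSSP marks undefined dihedrals at chain termini with the sentinel 360.0;
#' these are returned as `NA`. A blank secondary-structure field is the
#' loop class `"-"`.
#'
#' @param path DSSP file.
#' @param L expected number of residues; a record-count mismatch is an error.
#' @return data.frame with one row per residue: `residue_index`, `aa`, `ss`,
#'   `phi`, `psi`, `rsa`, `hb_relidx_1..4`, `hb_energy_1..4`.
#' @export
parse_dssp <- function(path, L) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  assert_that(length(hdr) >= 1, paste0("not a DSSP file (no residue header): ", path))
  body <- lines[(hdr[1] + 1):length(lines)]
  # chain breaks are lines whose AA column is '!'
  body <- body[nzchar(trimws(body)) & substr(body, 14, 14) != "!"]
  assert_that(length(body) == L,
              sprintf("DSSP record count (%d) differs from expected length (%d)",
                      length(body), L))
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  parse_line <- function(ln) {
    aa <- substr(ln, 14, 14)
    ss <- substr(ln, 17, 17)
    if (ss == " ") ss <- "-"
    acc <- num(substr(ln, 35, 38))
    # four H-bond fields, 11 chars each from column 40: "%6d,%5.1f"
    hb <- lapply(0:3, function(k) {
      f <- substr(ln, 40 + 11 * k, 50 + 11 * k)
      parts <- strsplit(f, ",", fixed = TRUE)[[1]]
      c(num(parts[1]), num(parts[2]))
    })
    phi <- num(substr(ln, 104, 109))
    psi <- num(substr(ln, 110, 115))
    list(
      residue_index = as.integer(num(substr(ln, 6, 10))),
      aa = aa, ss = ss, phi = phi, psi = psi,
      rsa = min(acc / MAX_ASA[[if (aa %in% names(MAX_ASA)) aa else "X"]], 1),
      hb = hb
    )
  }
  recs <- lapply(body, parse_line)
  out <- data.frame(
    residue_index = vapply(recs, `[[`, integer(1), "residue_index"),
    aa = vapply(recs, `[[`, character(1), "aa"),
    ss = vapply(recs, `[[`, character(1), "ss"),
    phi = vapply(recs, `[[`, numeric(1), "phi"),
    psi = vapply(recs, `[[`, numeric(1), "psi"),
    rsa = vapply(recs, `[[`, numeric(1), "rsa"),
    stringsAsFactors = FALSE
  )
  for (k in 1:4) {
    out[[paste0("hb_relidx_", k)]] <- vapply(recs, function(r) r$hb[[k]][1], numeric(1))
    out[[paste0("hb_energy_", k)]] <- vapply(recs, function(r) r$hb[[k]][2], numeric(1))
  }
  # DSSP sentinel for undefined dihedrals
  out$phi[!is.na(out$phi) & abs(out$phi) >= 360] <- NA
  out$psi[!is.na(out$psi) & abs(out$psi) >= 360] <- NA
  bad <- out$ss %in% DSSP_SS_CLASSES
  assert_that(all(bad), paste("unknown secondary structure class:",
                              paste(unique(out$ss[!bad]), collapse = ", ")))
  out
}

## min-max to [0,1] within one protein; a constant column maps to all zeros.
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Normalize DSSP records into the 20-dimensional node feature matrix
#'
#' Column layout (fixed; width always 20):
#' relative position (1) | secondary-structure one-hot over H,B,E,G,I,T,S,-
#' (8) | phi (1) | psi (1) | rsa (1) | H-bond relative indices (4) | H-bond
#' energies (4).
#'
#' Normalizations: relative position is `i / L` with `i` 1-based; angles map
#' affinely from \[-180, 180\] degrees to \[0, 1\] via `(angle + 180) / 360`
#' (undefined dihedrals become 0); rsa is already relative; each of the
#' eight H-bond columns is min-max normalized within the protein (a
#' constant column becomes all zeros, which also makes the encoding
#' invariant to a per-protein constant shift of those fields).
#'
#' @param records data.frame from [parse_dssp()] (or the synthetic
#'   generator); must have exactly `L` rows in residue order.
#' @param L protein length.
#' @return numeric L x 20 matrix, all entries in \[0, 1\].
#' @export
normalize_features <- function(records, L) {
  assert_that(nrow(records) == L, "records must have exactly L rows")
  ss_onehot <- outer(records$ss, DSSP_SS_CLASSES, `==`) * 1
  angle01 <- function(a) {
    a01 <- (a + 180) / 360
    a01[is.na(a01)] <- 0
    pmin(pmax(a01, 0), 1)
  }
  hb_cols <- c(paste0("hb_relidx_", 1:4), paste0("hb_energy_", 1:4))
  hb <- vapply(hb_cols, function(cn) minmax01(records[[cn]]), numeric(L))
  if (L == 1) hb <- matrix(hb, nrow = 1)
  m <- cbind(
    seq_len(L) / L,
    ss_onehot,
    angle01(records$phi),
    angle01(records$psi),
    pmin(pmax(records$rsa, 0), 1),
    hb
  )
  colnames(m) <- c("relpos", paste0("ss_", DSSP_SS_CLASSES),
                   "phi", "psi", "rsa", hb_cols)
  stopifnot(ncol(m) == 20)
  m
}

#' Write per-residue records in classic DSSP text layout
#'
#' Emits a minimal but column-faithful DSSP file (header banner, residue
#' header line, fixed-column records) that [parse_dssp()] reads back.
#' Undefined dihedrals are written with DSSP's 360.0 sentinel. RSA is
#' converted back to absolute ACC with the same max-ASA table the parser
#' uses.
#'
#' @param records data.frame with the columns produced by [parse_dssp()].
#' @param path output file.
#' @export
write_dssp <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    sprintf("  %d  1  0  0  0 TOTAL NUMBER OF RESIDUES, NUMBER OF CHAINS", nrow(records)),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  ), con)
  ang <- function(a) ifelse(is.na(a), 360.0, a)
  for (r in seq_len(nrow(records))) {
    acc <- round(records$rsa[r] *
                 MAX_ASA[[if (records$aa[r] %in% names(MAX_ASA)) records$aa[r] else "X"]])
    # four 11-character H-bond fields starting at column 40
    hb <- paste0(vapply(1:4, function(k) {
      sprintf("%5d,%5.1f", as.integer(records[[paste0("hb_relidx_", k)]][r]),
              records[[paste0("hb_energy_", k)]][r])
    }, character(1)), collapse = "")
    # columns: 1-5 serial, 6-10 resnum, 12 chain, 14 aa, 17 ss, 26-33 bp,
    # 35-38 acc, 40-83 hbonds, 84-115 tco/kappa/alpha/phi/psi, 116+ CA xyz
    writeLines(sprintf(
      "%5d%5d A %s  %s%s%4d%4d %4d %s%8.3f%6.1f%6.1f%6.1f%6.1f%7.1f%7.1f%7.1f",
      r, records$residue_index[r], records$aa[r],
      if (records$ss[r] == "-") " " else records$ss[r],
      strrep(" ", 8), 0L, 0L, as.integer(acc), hb,
      0, 360, 360, ang(records$phi[r]), ang(records$psi[r]), 0, 0, 0), con)
  }
  invisible(path)
}
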