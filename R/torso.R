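## The HCDR3 torso: the first three (T1-T3) and last four (T4-T7) residues
## of the loop.  The central "head" residues between T3 and T4 are
## structurally diverse and are not part of the fragment, but the atoms
## flanking the torso (the C of the residue before T1, the N of the residue
## after T3, the C of the residue before T4, and the N/CA of the first
## framework-4 residue after T7) are retained so that all 14 phi/psi angles
## of the torso can be measured.

TORSO_POSITIONS <- paste0("T", 1:7)

#' Construct a torso fragment
#'
#' Usually produced by [extract_torso()]; the constructor is exported for
#' synthetic fixtures and tests.
#'
#' @param residues 7-row data.frame in T1..T7 order with the
#'   [chain_backbone()] coordinate columns plus `position`.
#' @param anchors Named list of xyz vectors (or NULL when unavailable):
#'   `c_prev` (C of the residue preceding T1), `n_after_t3` (N of the first
#'   head residue, or of T4 for the shortest loops), `c_before_t4` (C of the
#'   last head residue), `n_fr4` and `ca_fr4` (N and CA of the first
#'   framework-4 residue following T7).
#' @param source_id Identifier of the originating structure.
#' @return An object of class `torso_fragment`.
#' @export
torso_fragment <- function(residues, anchors = list(), source_id = NA_character_) {
  if (nrow(residues) != 7L)
    stop("a torso has exactly 7 residues (T1-T7)", call. = FALSE)
  residues$position <- TORSO_POSITIONS
  rownames(residues) <- TORSO_POSITIONS
  for (nm in c("c_prev", "n_after_t3", "c_before_t4", "n_fr4", "ca_fr4"))
    if (is.null(anchors[[nm]])) anchors[nm] <- list(NULL)
  structure(list(source_id = source_id, residues = residues, anchors = anchors,
                 sequence = paste(residues$aa, collapse = "")),
            class = "torso_fragment")
}

#' @export
print.torso_fragment <- function(x, ...) {
  cat(sprintf("torso_fragment [%s]: sequence %s\n", x$source_id, x$sequence))
  invisible(x)
}

#' Extract the torso from a chain given an HCDR3 definition
#'
#' @param chain A [chain_backbone()].
#' @param start,end 1-based inclusive sequential indices of the HCDR3.
#' @return A [torso_fragment()].
#' @details T1-T3 are HCDR3 residues `start..start+2`; T4-T7 are the last
#'   four HCDR3 residues `end-3..end`.  Errors if the HCDR3 is shorter than
#'   8 residues, if no residue precedes T1, or if the first framework-4
#'   residue (`end + 1`) is absent.
#' @export
extract_torso <- function(chain, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  len <- end - start + 1L
  if (len < 8L)
    stop("HCDR3 length ", len, " < 8: torso (7 residues) plus head required",
         call. = FALSE)
  n <- nrow(chain$residues)
  if (start <= 1L)
    stop("no residue precedes the HCDR3: phi(T1) unmeasurable", call. = FALSE)
  if (end + 1L > n)
    stop("first framework-4 residue (index ", end + 1L, ") absent from chain",
         call. = FALSE)
  idx <- c(start:(start + 2L), (end - 3L):end)
  residues <- chain$residues[idx, , drop = FALSE]
  anchors <- list(
    c_prev      = res_atom(chain, start - 1L, "C"),
    n_after_t3  = res_atom(chain, start + 3L, "N"),
    c_before_t4 = res_atom(chain, end - 4L, "C"),
    n_fr4       = res_atom(chain, end + 1L, "N"),
    ca_fr4      = res_atom(chain, end + 1L, "CA"))
  torso_fragment(residues, anchors, source_id = chain$source_id)
}

#' Measure the 14 torso dihedral angles
#'
#' phi and psi at each of T1..T7, in degrees.  phi(Ti) is the torsion over
#' C(i-1), N(i), CA(i), C(i); psi(Ti) over N(i), CA(i), C(i), N(i+1).  For
#' T3 the "next" nitrogen is that of the first head residue; for T7 it is
#' the first framework-4 nitrogen.
#'
#' @param frag A [torso_fragment()].
#' @return data.frame with columns `position` (T1..T7), `phi`, `psi`
#'   (degrees, in (-180, 180]).  An angle whose flanking atom is missing is
#'   reported as NA with a warning.
#' @export
torso_dihedrals <- function(frag) {
  res <- frag$residues
  at <- function(i, atom) res_atom(frag, i, atom)
  phi <- psi <- rep(NA_real_, 7L)
  missing_angles <- character(0)
  for (i in 1:7) {
    cprev <- switch(as.character(i),
                    "1" = frag$anchors$c_prev,
                    "4" = frag$anchors$c_before_t4,
                    at(i - 1L, "C"))
    nnext <- switch(as.character(i),
                    "3" = frag$anchors$n_after_t3,
                    "7" = frag$anchors$n_fr4,
                    at(i + 1L, "N"))
    if (is.null(cprev)) {
      missing_angles <- c(missing_angles, paste0("phi(T", i, ")"))
    } else {
      phi[i] <- dihedral_angle(cprev, at(i, "N"), at(i, "CA"), at(i, "C"))
    }
    if (is.null(nnext)) {
      missing_angles <- c(missing_angles, paste0("psi(T", i, ")"))
    } else {
      psi[i] <- dihedral_angle(at(i, "N"), at(i, "CA"), at(i, "C"), nnext)
    }
  }
  if (length(missing_angles))
    warning("unmeasurable (missing flanking atom): ",
            paste(missing_angles, collapse = ", "), call. = FALSE)
  data.frame(position = TORSO_POSITIONS, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Backbone coordinates of a torso fragment
#'
#' Concatenated T1-T3 + T4-T7 backbone coordinates in residue order, used
#' for superposition-RMSD clustering of torso conformations.
#'
#' @param frag A [torso_fragment()].
#' @param atoms Backbone atoms per residue; carbonyl O is included only if
#'   present in all seven residues.
#' @return n x 3 numeric matrix.
#' @export
fragment_coords <- function(frag, atoms = c("N", "CA", "C", "O")) {
  atoms <- match.arg(atoms, c("N", "CA", "C", "O"), several.ok = TRUE)
  if ("O" %in% atoms && any(is.na(frag$residues$o_x)))
    atoms <- setdiff(atoms, "O")
  rows <- list()
  for (i in 1:7)
    for (a in atoms)
      rows[[length(rows) + 1L]] <- res_atom(frag, i, a)
  out <- do.call(rbind, rows)
  colnames(out) <- c("x", "y", "z")
  out
}
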