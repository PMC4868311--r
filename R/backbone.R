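## chain_backbone: the ordered backbone (N, CA, C, optional O) of one chain,
## renumbered sequentially from 1.  The residue table is a plain data.frame
## so downstream code can subset it with base idioms.

#' Construct a chain backbone
#'
#' @param residues data.frame with columns `index` (1-based, consecutive),
#'   `aa` (one-letter code), and coordinates `n_x,n_y,n_z`, `ca_x,ca_y,ca_z`,
#'   `c_x,c_y,c_z`, and optionally `o_x,o_y,o_z` (NA when the carbonyl
#'   oxygen is absent).
#' @param source_id Identifier of the originating structure (e.g. file name).
#' @param chain_id Chain identifier.
#' @return An object of class `chain_backbone`.
#' @export
chain_backbone <- function(residues, source_id = NA_character_,
                           chain_id = NA_character_) {
  needed <- c("index", "aa",
              "n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
              "c_x", "c_y", "c_z")
  missing_cols <- setdiff(needed, names(residues))
  if (length(missing_cols))
    stop("residue table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(c("o_x", "o_y", "o_z") %in% names(residues)))
    residues[c("o_x", "o_y", "o_z")] <- NA_real_
  if (nrow(residues) == 0L)
    stop("chain has zero complete residues", call. = FALSE)
  if (any(is.na(residues[needed[-(1:2)]])))
    stop("N, CA and C must be present for every residue", call. = FALSE)
  residues$index <- as.integer(residues$index)
  if (!identical(residues$index, seq_len(nrow(residues))))
    stop("residue indices must be 1, 2, ... in order (renumber first)",
         call. = FALSE)
  rownames(residues) <- NULL
  structure(list(source_id = source_id, chain_id = chain_id,
                 residues = residues),
            class = "chain_backbone")
}

#' @export
print.chain_backbone <- function(x, ...) {
  cat(sprintf("chain_backbone: %s chain %s, %d residues\n",
              x$source_id, x$chain_id, nrow(x$residues)))
  cat(" sequence:", backbone_sequence(x), "\n")
  invisible(x)
}

#' @export
length.chain_backbone <- function(x) nrow(x$residues)

#' One-letter sequence of a chain backbone
#' @param chain A `chain_backbone`.
#' @return Character scalar.
#' @export
backbone_sequence <- function(chain) paste(chain$residues$aa, collapse = "")

# xyz of one backbone atom of residue at sequential index i, or NULL if absent
res_atom <- function(chain, i, atom = c("N", "CA", "C", "O")) {
  atom <- match.arg(atom)
  res <- chain$residues
  if (i < 1L || i > nrow(res)) return(NULL)
  pre <- c(N = "n", CA = "ca", C = "c", O = "o")[[atom]]
  p <- as.numeric(res[i, paste0(pre, c("_x", "_y", "_z"))])
  if (any(is.na(p))) NULL else p
}

# n x 3 matrix of one atom type over residue indices (error on missing)
res_atom_matrix <- function(chain, idx, atom = "CA") {
  out <- t(vapply(idx, function(i) {
    p <- res_atom(chain, i, atom)
    if (is.null(p))
      stop("missing ", atom, " atom at residue ", i, call. = FALSE)
    p
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

# peptide-bond continuity check used by validation and tests
peptide_bond_lengths <- function(chain) {
  n <- nrow(chain$residues)
  if (n < 2L) return(numeric(0))
  vapply(seq_len(n - 1L), function(i) {
    ci <- res_atom(chain, i, "C"); nn <- res_atom(chain, i + 1L, "N")
    sqrt(sum((ci - nn)^2))
  }, numeric(1))
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M")

aa3to1 <- function(resid) {
  out <- .AA3TO1[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}
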