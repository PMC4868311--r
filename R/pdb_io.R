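## PDB backbone reading and the HCDR3 definitions table.
##
## Parsing of the PDB format itself is delegated to bio3d; this layer
## applies the package's residue model: ATOM records only, altloc resolved
## by highest occupancy, insertion codes collapsed, residues missing any of
## N/CA/C dropped with a warning, and the survivors renumbered sequentially
## from 1 (matching the numbering convention of the definitions table).

#' Read one chain's backbone from a PDB file
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object.
#' @param chain_id Chain identifier to extract.
#' @return A [chain_backbone()] with residues renumbered from 1 in order of
#'   appearance.
#' @details Only ATOM records are used (HETATM ignored).  When alternate
#'   locations are present the highest-occupancy altloc is kept (ties: the
#'   first encountered).  Residues lacking any of N, CA or C are dropped
#'   with a warning; an error is raised if the chain is absent or no
#'   complete residue remains.
#' @export
read_backbone <- function(pdb, chain_id) {
  if (is.character(pdb)) {
    if (!file.exists(pdb)) stop("PDB file not found: ", pdb, call. = FALSE)
    src <- basename(pdb)
    pdb <- bio3d::read.pdb(pdb, rm.alt = FALSE, verbose = FALSE)
  } else {
    src <- NA_character_
  }
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$chain %in% chain_id, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("chain '", chain_id, "' not found in PDB input", call. = FALSE)

  # residue key in order of appearance; insertion codes collapse into the
  # sequential renumbering
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$resno, ins, sep = "|")
  key <- factor(key, levels = unique(key))

  rows <- lapply(split(seq_len(nrow(atoms)), key), function(ii) {
    res <- atoms[ii, , drop = FALSE]
    get_atom <- function(name) {
      cand <- res[res$elety == name, , drop = FALSE]
      if (nrow(cand) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      if (nrow(cand) > 1L) {
        occ <- cand$o
        occ[is.na(occ)] <- 1
        cand <- cand[which.max(occ), , drop = FALSE]  # ties -> first
      }
      c(cand$x, cand$y, cand$z)
    }
    n <- get_atom("N"); ca <- get_atom("CA"); cc <- get_atom("C"); o <- get_atom("O")
    data.frame(aa = aa3to1(res$resid[1L]),
               n_x = n[1], n_y = n[2], n_z = n[3],
               ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
               c_x = cc[1], c_y = cc[2], c_z = cc[3],
               o_x = o[1], o_y = o[2], o_z = o[3],
               stringsAsFactors = FALSE)
  })
  residues <- do.call(rbind, rows)
  complete <- !is.na(residues$n_x) & !is.na(residues$ca_x) & !is.na(residues$c_x)
  if (any(!complete))
    warning(sum(!complete), " residue(s) dropped from ", src, " chain ",
            chain_id, ": missing N/CA/C backbone atoms", call. = FALSE)
  residues <- residues[complete, , drop = FALSE]
  if (nrow(residues) == 0L)
    stop("chain '", chain_id, "' has zero complete backbone residues",
         call. = FALSE)
  residues$index <- seq_len(nrow(residues))
  chain_backbone(residues, source_id = src, chain_id = chain_id)
}

#' Read an HCDR3 definitions table
#'
#' Parses a comma-separated table with rows `pdb_file, chain_id, start, end`
#' where `start`/`end` are 1-based inclusive residue indices into the
#' sequentially renumbered chain.  A header line (non-integer start/end) is
#' skipped.
#'
#' @param path Path to the CSV file, or a character vector of lines.
#' @return data.frame with columns `pdb_file`, `chain_id`, `start`, `end`
#'   (one row per valid definition), with attribute `"errors"` holding
#'   per-row problem messages (row numbers refer to the input file).
#' @details A definition must satisfy `end - start + 1 >= 8` (the torso
#'   needs seven residues plus at least one head residue) and `start > 1`
#'   (phi of the first torso residue needs a preceding residue).  Invalid
#'   rows are reported, not silently dropped.
#' @export
read_definitions <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  rows <- which(keep)
  defs <- list(); errors <- character(0)
  for (i in rows) {
    fields <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1L]])
    if (length(fields) < 4L) {
      errors <- c(errors, sprintf("row %d: expected 4 comma-separated fields", i))
      next
    }
    start <- suppressWarnings(as.integer(fields[3L]))
    end <- suppressWarnings(as.integer(fields[4L]))
    if (is.na(start) || is.na(end)) {
      if (i == rows[1L]) next  # header line
      errors <- c(errors, sprintf("row %d: non-integer start/end", i))
      next
    }
    if (start >= end) {
      errors <- c(errors, sprintf("row %d: start (%d) must be < end (%d)",
                                  i, start, end))
      next
    }
    if (end - start + 1L < 8L) {
      errors <- c(errors, sprintf(
        "row %d: HCDR3 length %d < 8 (torso needs 7 residues + head)",
        i, end - start + 1L))
      next
    }
    if (start <= 1L) {
      errors <- c(errors, sprintf(
        "row %d: start must be > 1 (phi(T1) needs a preceding residue)", i))
      next
    }
    defs[[length(defs) + 1L]] <- data.frame(
      pdb_file = fields[1L], chain_id = fields[2L],
      start = start, end = end, stringsAsFactors = FALSE)
  }
  out <- if (length(defs)) do.call(rbind, defs) else
    data.frame(pdb_file = character(0), chain_id = character(0),
               start = integer(0), end = integer(0))
  attr(out, "errors") <- errors
  out
}

#' Locate the HCDR3 by its conserved sequence anchors
#'
#' Finds the HCDR3 from the IMGT junction anchors: the loop starts
#' immediately after the conserved V-gene cysteine (Cys104) and ends
#' immediately before the conserved J-gene tryptophan (Trp118) of the
#' Trp-Gly-x-Gly motif.  The anchor pair is identified in sequence as the
#' last Cys occurring before a downstream W-G-x-G motif.
#'
#' @param chain A [chain_backbone()].
#' @return A list with `start` and `end` (1-based sequential indices), or
#'   `NULL` (an explicit no-call) when the anchors are absent or ambiguous;
#'   callers must then supply an explicit definition.
#' @export
locate_hcdr3_imgt <- function(chain) {
  seq <- backbone_sequence(chain)
  motifs <- gregexpr("WG.G", seq)[[1L]]
  if (motifs[1L] == -1L) return(NULL)
  cys <- gregexpr("C", seq, fixed = TRUE)[[1L]]
  if (cys[1L] == -1L) return(NULL)
  for (w in as.integer(motifs)) {
    before <- cys[cys < w]
    if (!length(before)) next
    cpos <- max(before)          # last Cys before the motif
    start <- cpos + 1L
    end <- w - 1L
    if (end >= start) return(list(start = start, end = end))
  }
  NULL
}
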