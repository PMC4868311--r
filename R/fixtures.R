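## Synthetic fixtures with known ground truth.
##
## Backbones are built from internal coordinates (torsion-driven chain
## extension, the NeRF construction) using standard ideal backbone geometry,
## so that measuring phi/psi on the result recovers the specified angles to
## numerical precision.  This gives every measurement in the package a
## round-trip oracle and lets class-conditional torsos and decoy sets be
## generated without any structure download.  The fixtures aim at
## self-consistency, not crystallographic realism: no side chains, ideal
## bond lengths/angles, and decoy loops are not re-closed onto the
## framework.

# ideal backbone internal coordinates (Engh-Huber-style standard values)
.IDEAL <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,   # bond lengths, Angstrom
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7)  # bond angles, deg

# NeRF atom placement: position D such that |C-D| = bond, angle(B,C,D) =
# theta and dihedral(A,B,C,D) = torsion (degrees)
place_atom <- function(a, b, c, bond, theta, torsion) {
  th <- theta * pi / 180; to <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(to), bond * sin(th) * sin(to))
  c + cbind(bc, m, n) %*% d
}

#' Build a backbone chain from phi/psi/omega angles
#'
#' Sequentially places N, CA and C atoms from internal coordinates with
#' ideal bond lengths and angles.  Measuring the torsions of the result
#' returns the specified angles to better than 1e-6 degrees.
#'
#' @param spec data.frame with one row per residue: `aa` (one-letter code),
#'   `phi`, `psi` and optionally `omega` (degrees; omega defaults to 180).
#'   `phi` of the first residue and `psi`/`omega` of the last are unused.
#' @param source_id,chain_id Identifiers for the resulting chain.
#' @return A [chain_backbone()] (carbonyl oxygens are not built).
#' @export
build_backbone <- function(spec, source_id = "synthetic", chain_id = "H") {
  if (!all(c("aa", "phi", "psi") %in% names(spec)))
    stop("spec needs columns aa, phi, psi", call. = FALSE)
  n <- nrow(spec)
  if (n < 2L) stop("a chain needs at least 2 residues", call. = FALSE)
  if (is.null(spec$omega)) spec$omega <- 180
  spec$omega[is.na(spec$omega)] <- 180
  g <- .IDEAL
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                              g$b_c_n, g$a_ca_c_n, spec$psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                               g$b_n_ca, g$a_c_n_ca, spec$omega[i])
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                              g$b_ca_c, g$a_n_ca_c, spec$phi[i + 1L])
  }
  residues <- data.frame(
    index = seq_len(n), aa = as.character(spec$aa),
    n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
    ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
    c_x = C[, 1], c_y = C[, 2], c_z = C[, 3],
    stringsAsFactors = FALSE)
  chain_backbone(residues, source_id = source_id, chain_id = chain_id)
}

#' Measure all backbone torsions of a chain
#'
#' @param chain A [chain_backbone()].
#' @return data.frame with `index`, `phi`, `psi`, `omega` in degrees; NA
#'   where the flanking residue does not exist (phi of the first residue,
#'   psi/omega of the last).
#' @export
chain_dihedrals <- function(chain) {
  n <- nrow(chain$residues)
  at <- function(i, a) res_atom(chain, i, a)
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L)
      phi[i] <- dihedral_angle(at(i - 1L, "C"), at(i, "N"), at(i, "CA"), at(i, "C"))
    if (i < n) {
      psi[i] <- dihedral_angle(at(i, "N"), at(i, "CA"), at(i, "C"), at(i + 1L, "N"))
      omega[i] <- dihedral_angle(at(i, "CA"), at(i, "C"), at(i + 1L, "N"),
                                 at(i + 1L, "CA"))
    }
  }
  data.frame(index = seq_len(n), phi = phi, psi = psi, omega = omega)
}

# phi/psi used for framework and head residues: extended beta conformation
.EXTENDED <- c(phi = -140, psi = 135)

#' Sample class-conditional torso fragments
#'
#' Draws torso phi/psi angles from wrapped normals with a class profile's
#' (mean, sd), realizes each sample as a 3D backbone (one preceding
#' framework residue, T1-T3, `head_len` extended head residues, T4-T7, one
#' following framework-4 residue) and extracts the torso fragment.  The
#' excluded psi(T4) is drawn from an equal mixture of two modes 180 degrees
#' apart, reproducing its bimodality within both torso classes.
#'
#' @param profile A [torso_profile()].
#' @param n Number of fragments.
#' @param seed Optional integer seed for reproducibility.
#' @param head_len Number of head residues between T3 and T4; default 9
#'   (an HCDR3 of length 16, the repertoire-typical length).
#' @return List of `n` [torso_fragment()]s; each carries the generating
#'   angles as attribute `"truth"`.
#' @export
sample_class_torsos <- function(profile, n, seed = NULL, head_len = 9L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1L, head_len >= 1L)
  lapply(seq_len(n), function(k) {
    ang <- lapply(TORSO_POSITIONS, function(pos) {
      phi <- profile_angle(profile, pos, "phi")
      psi <- profile_angle(profile, pos, "psi")
      psi_mean <- psi$mean
      if (is_excluded(profile, pos, "psi"))
        psi_mean <- wrap180(psi_mean + sample(c(0, 180), 1L))
      c(phi = rwrappednorm(1L, phi$mean, phi$sd),
        psi = rwrappednorm(1L, psi_mean, psi$sd))
    })
    ang <- do.call(rbind, ang)
    len <- 3L + head_len + 4L
    chain_len <- len + 2L
    spec <- data.frame(aa = rep("A", chain_len),
                       phi = .EXTENDED[["phi"]], psi = .EXTENDED[["psi"]])
    t_rows <- c(2:4, (chain_len - 4L):(chain_len - 1L))
    spec$phi[t_rows] <- ang[, "phi"]
    spec$psi[t_rows] <- ang[, "psi"]
    chain <- build_backbone(spec, source_id = sprintf("%s-%03d", profile$label, k))
    frag <- extract_torso(chain, start = 2L, end = chain_len - 1L)
    attr(frag, "truth") <- data.frame(position = TORSO_POSITIONS,
                                      phi = ang[, "phi"], psi = ang[, "psi"])
    frag
  })
}

#' Generate a decoy set with controlled score-RMSD structure
#'
#' Perturbs the loop dihedrals of a native backbone with wrapped-normal
#' noise, rebuilds each decoy from internal coordinates, measures its loop
#' RMSD (after framework superposition) and RMSD16, and assigns a score of
#' `a * RMSD16 + b + N(0, score_noise_sd)` in REU.  The ground-truth
#' RMSD16 of every decoy is part of the returned records, so score-based
#' metrics can be checked against construction.
#'
#' @param native A [chain_backbone()].
#' @param loop_start,loop_end 1-based inclusive loop range.
#' @param n Number of decoys.
#' @param noise_sd Wrapped-normal dihedral noise in degrees.
#' @param score_a,score_b,score_noise_sd Score model parameters (REU).
#' @param seed Optional integer seed.
#' @return List with `records` (data.frame: `id`, `score`, `rmsd`,
#'   `rmsd16`, `L`) and `decoys` (named list of [chain_backbone()]s).
#' @export
make_decoy_set <- function(native, loop_start, loop_end, n = 100L,
                           noise_sd = 20, score_a = 2, score_b = -20,
                           score_noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1L)
  tor <- chain_dihedrals(native)
  L <- loop_end - loop_start + 1L
  loop <- loop_start:loop_end
  aa <- native$residues$aa
  decoys <- list()
  records <- vector("list", n)
  for (k in seq_len(n)) {
    spec <- data.frame(aa = aa, phi = tor$phi, psi = tor$psi, omega = tor$omega)
    spec$phi[1L] <- 0; spec$psi[nrow(spec)] <- 0; spec$omega[nrow(spec)] <- 180
    if (noise_sd > 0) {
      spec$phi[loop] <- wrap180(spec$phi[loop] + stats::rnorm(L, 0, noise_sd))
      spec$psi[loop] <- wrap180(spec$psi[loop] + stats::rnorm(L, 0, noise_sd))
    }
    id <- sprintf("decoy_%04d", k)
    decoy <- build_backbone(spec, source_id = id, chain_id = native$chain_id)
    r <- loop_rmsd(decoy, native, loop_start, loop_end)
    r16 <- rmsd16(r, L)
    records[[k]] <- data.frame(
      id = id, score = score_a * r16 + score_b + stats::rnorm(1L, 0, score_noise_sd),
      rmsd = r, rmsd16 = r16, L = L, stringsAsFactors = FALSE)
    decoys[[id]] <- decoy
  }
  list(records = do.call(rbind, records), decoys = decoys)
}

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
             X = "UNK")

#' Write a chain backbone as a PDB file
#'
#' @param chain A [chain_backbone()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(chain, path) {
  res <- chain$residues
  has_o <- !is.na(res$o_x)
  xyz <- c(); elety <- c(); resno <- c(); resid <- c()
  for (i in seq_len(nrow(res))) {
    atoms <- c("N", "CA", "C", if (has_o[i]) "O")
    for (a in atoms) {
      xyz <- c(xyz, res_atom(chain, i, a))
      elety <- c(elety, a)
      resno <- c(resno, res$index[i])
      resid <- c(resid, unname(.AA1TO3[res$aa[i]]))
    }
  }
  resid[is.na(resid)] <- "UNK"
  bio3d::write.pdb(file = path, xyz = xyz, elety = elety, resno = resno,
                   resid = resid,
                   chain = rep(chain$chain_id, length(elety)))
  invisible(path)
}

#' Read a two-column model score table
#'
#' Tab- or comma-separated `model_id, score` (REU) with an optional header.
#'
#' @param path File path.
#' @return data.frame with columns `id`, `score`.
#' @export
read_score_table <- function(path) {
  sep <- if (any(grepl("\t", readLines(path, n = 5L)))) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("score table needs 2 columns (id, score)", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L]))))
    tab <- tab[-1L, , drop = FALSE]  # header
  data.frame(id = as.character(tab[[1L]]), score = as.numeric(tab[[2L]]),
             stringsAsFactors = FALSE)
}
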