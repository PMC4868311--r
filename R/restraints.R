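## Circular-harmonic dihedral restraints in Rosetta constraint-file format.
##
## Each non-excluded (position, angle) of a torso profile becomes one
## restraint line; the penalty a conforming model pays is
## (circular deviation / sigma)^2, continuous across the +-180 branch cut,
## matching Rosetta's CIRCULARHARMONIC functional form so that emitted
## files are directly consumable by the external modeling engine.

#' Derive dihedral restraints from a torso profile
#'
#' Maps torso positions onto HCDR3 residue numbers (T1-T3 to the first
#' three, T4-T7 to the last four residues of the loop) and emits one
#' circular-harmonic restraint per non-excluded measurement.  For a profile
#' excluding only psi(T4), a valid derivation always contains exactly 13
#' restraints (7 phi + 6 psi).
#'
#' @param profile A [torso_profile()].
#' @param start 1-based index of the first HCDR3 residue in the target
#'   numbering.
#' @param length HCDR3 length in residues (>= 8).
#' @param min_sigma Floor for the restraint width in degrees (default 1);
#'   prevents degenerate zero-width restraints from tiny classes.
#' @return An object of class `restraint_set`: a list with `restraints`
#'   (data.frame with atom quadruples, `x0` and `sigma` in radians) and
#'   `provenance`.
#' @details Restraint order is T1 to T7, phi before psi within a residue.
#'   phi(r) restrains C(r-1), N(r), CA(r), C(r); psi(r) restrains N(r),
#'   CA(r), C(r), N(r+1).  The residue numbering is the caller's target
#'   numbering; `start` must leave room for a preceding residue and the
#'   following framework-4 residue.
#' @export
derive_restraints <- function(profile, start, length, min_sigma = 1) {
  start <- as.integer(start); length <- as.integer(length)
  if (length < 8L)
    stop("HCDR3 length ", length, " < 8", call. = FALSE)
  if (start < 2L)
    stop("start must be >= 2: phi(T1) references residue start - 1",
         call. = FALSE)
  resno <- c(start + 0:2, start + length - 4L + 0:3)
  names(resno) <- TORSO_POSITIONS
  rows <- list()
  for (pos in TORSO_POSITIONS) {
    r <- resno[[pos]]
    for (ang in c("phi", "psi")) {
      if (is_excluded(profile, pos, ang)) next
      ref <- profile_angle(profile, pos, ang)
      if (is.null(ref$mean) || is.na(ref$mean) || is.na(ref$sd))
        stop("profile lacks a summary for ", pos, " ", ang, call. = FALSE)
      atoms <- if (ang == "phi")
        list(a = c("C", "N", "CA", "C"), r = c(r - 1L, r, r, r))
      else
        list(a = c("N", "CA", "C", "N"), r = c(r, r, r, r + 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, angle = ang,
        a1 = atoms$a[1], r1 = atoms$r[1], a2 = atoms$a[2], r2 = atoms$r[2],
        a3 = atoms$a[3], r3 = atoms$r[3], a4 = atoms$a[4], r4 = atoms$r[4],
        x0 = wrap_pi(ref$mean * pi / 180),
        sigma = max(ref$sd, min_sigma) * pi / 180,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(restraints = do.call(rbind, rows),
                 provenance = list(profile = profile$label,
                                   start = start, length = length,
                                   min_sigma = min_sigma,
                                   date = format(Sys.Date()))),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d circular-harmonic dihedral restraints (profile '%s')\n",
              nrow(x$restraints), x$provenance$profile))
  invisible(x)
}

#' Serialize restraints in Rosetta constraint-file format
#'
#' One line per restraint:
#' `Dihedral <a1> <r1> <a2> <r2> <a3> <r3> <a4> <r4> CIRCULARHARMONIC <x0> <sigma>`
#' with the target angle and width in radians, 6 decimal places.
#'
#' @param rs A `restraint_set` from [derive_restraints()].
#' @param path Optional file path; when given the text is written there.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_rosetta_constraints <- function(rs, path = NULL) {
  df <- rs$restraints
  lines <- if (is.null(df) || nrow(df) == 0L) character(0) else
    sprintf("Dihedral %s %d %s %d %s %d %s %d CIRCULARHARMONIC %.6f %.6f",
            df$a1, df$r1, df$a2, df$r2, df$a3, df$r3, df$a4, df$r4,
            df$x0, df$sigma)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a Rosetta dihedral constraint file
#'
#' Reads back `Dihedral ... CIRCULARHARMONIC x0 sigma` lines written by
#' [write_rosetta_constraints()] (round-trip identity on atoms, residues,
#' target and width).  The torso position labels are not part of the format
#' and are reconstructed only as phi/psi from the atom template.
#'
#' @param x Path to a constraint file, or a character vector of lines.
#' @return A `restraint_set`.
#' @export
parse_rosetta_constraints <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[[:space:]]+")[[1L]]
    if (length(f) != 12L || f[1L] != "Dihedral")
      stop("line ", i, ": not a Dihedral constraint line", call. = FALSE)
    if (f[10L] != "CIRCULARHARMONIC")
      stop("line ", i, ": unsupported function type '", f[10L], "'",
           call. = FALSE)
    a <- f[c(2, 4, 6, 8)]; r <- as.integer(f[c(3, 5, 7, 9)])
    ang <- if (identical(a, c("C", "N", "CA", "C"))) "phi"
           else if (identical(a, c("N", "CA", "C", "N"))) "psi"
           else NA_character_
    data.frame(position = NA_character_, angle = ang,
               a1 = a[1], r1 = r[1], a2 = a[2], r2 = r[2],
               a3 = a[3], r3 = r[3], a4 = a[4], r4 = r[4],
               x0 = as.numeric(f[11L]), sigma = as.numeric(f[12L]),
               stringsAsFactors = FALSE)
  })
  structure(list(restraints = do.call(rbind, rows),
                 provenance = list(profile = NA_character_)),
            class = "restraint_set")
}

#' Evaluate the restraint penalty on measured dihedrals
#'
#' Sum over restraints of `(wrapped(measured - x0) / sigma)^2`, the
#' circular-harmonic penalty a scoring pass adds for deviation from the
#' knowledge-based torso geometry.  Zero when every restrained angle equals
#' its target.
#'
#' @param rs A `restraint_set`.
#' @param measured data.frame with columns `residue`, `angle`
#'   (`"phi"`/`"psi"`) and `value` (degrees).
#' @return Non-negative penalty (unitless multiples of sigma^2).
#' @export
restraint_penalty <- function(rs, measured) {
  df <- rs$restraints
  if (is.null(df) || nrow(df) == 0L) return(0)
  total <- 0
  missing <- character(0)
  for (k in seq_len(nrow(df))) {
    r <- df$r2[k]  # phi and psi templates both center on the second residue
    ang <- df$angle[k]
    hit <- measured$value[measured$residue == r & measured$angle == ang]
    if (length(hit) != 1L || is.na(hit)) {
      missing <- c(missing, sprintf("%s(%d)", ang, r))
      next
    }
    dev <- wrap_pi(hit * pi / 180 - df$x0[k])
    total <- total + (dev / df$sigma[k])^2
  }
  if (length(missing))
    stop("restrained angles not measurable: ",
         paste(missing, collapse = ", "), call. = FALSE)
  total
}

#' Torso dihedrals as a residue-numbered angle table
#'
#' Maps a [torso_dihedrals()] table onto HCDR3 residue numbers so it can be
#' scored by [restraint_penalty()].
#'
#' @param dihedrals 7-row table from [torso_dihedrals()].
#' @param start,length HCDR3 start index and length in the target numbering.
#' @return data.frame with columns `residue`, `angle`, `value`.
#' @export
torso_angle_table <- function(dihedrals, start, length) {
  resno <- c(start + 0:2, start + length - 4L + 0:3)
  out <- rbind(
    data.frame(residue = resno, angle = "phi", value = dihedrals$phi),
    data.frame(residue = resno, angle = "psi", value = dihedrals$psi))
  out[!is.na(out$value), , drop = FALSE]
}
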