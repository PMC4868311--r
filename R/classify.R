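## Torso classification and base geometry.
##
## The two torso classes are separated structurally by clustering; for a
## single new structure this package additionally offers a closed-form
## classifier (an extension beyond the clustering route): the standardized
## circular RMS deviation of the measured torso dihedrals from each class
## profile, gated on psi(T6), the measurement that actually discriminates
## bulged from non-bulged torsos.

#' Classify a torso against bulged / non-bulged profiles
#'
#' For each class, the distance is the root-mean-square over all measured,
#' non-excluded angles of the circular deviation from the class mean
#' divided by the class standard deviation.  The torso is assigned to the
#' nearer class, provided its psi(T6) lies within `sigma_mult` standard
#' deviations of that class's psi(T6) mean; otherwise the call is
#' `"indeterminate"`.
#'
#' @param dihedrals 7-row table from [torso_dihedrals()].
#' @param profile_a,profile_b The two class [torso_profile()]s (typically
#'   [reference_torso_profile()] for bulged and non-bulged).
#' @param sigma_mult Width of the psi(T6) gate in class standard
#'   deviations; default 3.
#' @return List with `label` (one of the two profile labels or
#'   `"indeterminate"`), `distances` (named per-class scores) and `reason`
#'   (for indeterminate calls).
#' @export
classify_torso <- function(dihedrals, profile_a, profile_b, sigma_mult = 3) {
  psi_t6 <- dihedrals$psi[dihedrals$position == "T6"]
  if (length(psi_t6) != 1L || is.na(psi_t6)) {
    return(list(label = "indeterminate",
                distances = c(NA_real_, NA_real_),
                reason = "psi(T6) not measured"))
  }
  profiles <- list(profile_a, profile_b)
  labels <- vapply(profiles, `[[`, character(1), "label")
  dist <- vapply(profiles, function(p) .profile_distance(dihedrals, p),
                 numeric(1))
  names(dist) <- labels
  best <- which.min(dist)
  gate <- profile_angle(profiles[[best]], "T6", "psi")
  dev <- abs(wrap180(psi_t6 - gate$mean))
  if (dev > sigma_mult * gate$sd) {
    return(list(label = "indeterminate", distances = dist,
                reason = sprintf(
                  "psi(T6) = %.1f deg is %.1f sd from the %s class mean",
                  psi_t6, dev / gate$sd, labels[best])))
  }
  list(label = labels[best], distances = dist, reason = NA_character_)
}

.profile_distance <- function(dihedrals, profile) {
  devs <- c()
  for (pos in TORSO_POSITIONS) {
    for (ang in c("phi", "psi")) {
      if (is_excluded(profile, pos, ang)) next
      x <- dihedrals[[ang]][dihedrals$position == pos]
      if (is.na(x)) next
      ref <- profile_angle(profile, pos, ang)
      devs <- c(devs, wrap180(x - ref$mean) / ref$sd)
    }
  }
  if (!length(devs))
    stop("no measurable non-excluded angle to compare", call. = FALSE)
  sqrt(mean(devs^2))
}

#' Torso-base pseudo-angles
#'
#' The pseudodihedral alpha101 over the C-alpha atoms of T5, T6, T7 and the
#' first framework-4 residue, and the planar pseudo-bond angle tau101 over
#' the C-alpha atoms of T6, T7 and the first framework-4 residue.  These
#' base angles characterize the kinked (bulged) torso conformation.
#'
#' @param frag A [torso_fragment()] with the framework-4 C-alpha anchor.
#' @return List with `alpha101` in (-180, 180] and `tau101` in [0, 180]
#'   (degrees).
#' @export
base_geometry <- function(frag) {
  ca_fr4 <- frag$anchors$ca_fr4
  if (is.null(ca_fr4))
    stop("framework-4 C-alpha anchor missing: base geometry unmeasurable",
         call. = FALSE)
  ca <- lapply(5:7, function(i) res_atom(frag, i, "CA"))
  # a perfectly straight base leaves the pseudodihedral undefined while the
  # pseudo-bond angle is still meaningful (180)
  alpha <- tryCatch(dihedral_angle(ca[[1]], ca[[2]], ca[[3]], ca_fr4),
                    error = function(e) {
                      warning("alpha101 undefined: ", conditionMessage(e),
                              call. = FALSE)
                      NA_real_
                    })
  list(alpha101 = alpha,
       tau101 = planar_angle(ca[[2]], ca[[3]], ca_fr4))
}

#' Test torso-base geometry against a bulged reference window
#'
#' Checks whether both tau101 and alpha101 fall within
#' `mean +/- multiplier * sigma` of an externally supplied reference window
#' (closed interval; the alpha101 comparison is circular).  The reference
#' means and sigmas for the bulged torso window come from prior published
#' measurements and must be given explicitly; the package supplies no
#' default.
#'
#' @param geometry Output of [base_geometry()].
#' @param window List with `tau101_mean`, `tau101_sd`, `alpha101_mean`,
#'   `alpha101_sd` (degrees).
#' @param multiplier Window half-width in standard deviations; default 3.
#' @return TRUE/FALSE.
#' @export
in_bulged_window <- function(geometry, window, multiplier = 3) {
  needed <- c("tau101_mean", "tau101_sd", "alpha101_mean", "alpha101_sd")
  if (is.null(window) || !all(needed %in% names(window)))
    stop("explicit reference window required (",
         paste(needed, collapse = ", "), ")", call. = FALSE)
  tau_ok <- abs(geometry$tau101 - window$tau101_mean) <=
    multiplier * window$tau101_sd
  alpha_ok <- abs(wrap180(geometry$alpha101 - window$alpha101_mean)) <=
    multiplier * window$alpha101_sd
  tau_ok && alpha_ok
}

#' Torso sequence motif statistics
#'
#' Position-frequency matrix over the seven torso positions and the
#' bulged-torso salt-bridge motif fractions: Arg or Lys at T2, Asp at T6,
#' and both together (the T2/T6 motif that stabilizes the bulge).
#'
#' @param sequences Character vector of 7-letter torso sequences (standard
#'   amino-acid alphabet; `X` permitted and excluded from denominators).
#' @return List with `pfm` (20 x 7 matrix of per-position fractions over
#'   observed residues), `frac_t2_rk`, `frac_t6_d`, `frac_both`, and `n`.
#' @export
motif_stats <- function(sequences) {
  if (!length(sequences))
    stop("no torso sequences supplied", call. = FALSE)
  bad <- nchar(sequences) != 7L
  if (any(bad))
    stop("torso sequences must be exactly 7 letters; offending: ",
         paste(utils::head(sequences[bad], 3), collapse = ", "), call. = FALSE)
  aa <- sort(unname(unique(.AA3TO1)))
  mat <- t(vapply(strsplit(toupper(sequences), ""), identity, character(7)))
  pfm <- vapply(1:7, function(j) {
    col <- mat[, j]
    col <- col[col != "X"]
    tab <- table(factor(col, levels = aa))
    if (sum(tab) == 0) rep(0, length(aa)) else as.numeric(tab) / sum(tab)
  }, numeric(length(aa)))
  dimnames(pfm) <- list(aa, TORSO_POSITIONS)
  t2 <- mat[, 2L]; t6 <- mat[, 6L]
  n2 <- sum(t2 != "X"); n6 <- sum(t6 != "X")
  nb <- sum(t2 != "X" & t6 != "X")
  list(pfm = pfm,
       frac_t2_rk = if (n2) sum(t2 %in% c("R", "K")) / n2 else NA_real_,
       frac_t6_d = if (n6) sum(t6 == "D") / n6 else NA_real_,
       frac_both = if (nb) sum(t2 %in% c("R", "K") & t6 == "D") / nb else NA_real_,
       n = length(sequences))
}
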