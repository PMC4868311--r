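# Shared fixture builders and independent oracles.  Oracles deliberately
# avoid the package's computation path: brute-force rotation search instead
# of Kabsch, bio3d instead of the package kernel, plain re-sorts instead of
# the metric functions.

# chain whose torso positions carry the given 7x2 angle matrix (phi, psi),
# embedded in an extended-strand context: 1 framework residue, T1-T3,
# head_len head residues, T4-T7, 1 framework-4 residue
torso_chain <- function(phi, psi, head_len = 9L, aa = NULL) {
  n <- 2L + 7L + head_len
  spec <- data.frame(aa = if (is.null(aa)) rep("A", n) else aa,
                     phi = -140, psi = 135)
  tr <- c(2:4, (n - 4L):(n - 1L))
  spec$phi[tr] <- phi
  spec$psi[tr] <- psi
  build_backbone(spec)
}

torso_chain_from_profile <- function(profile, head_len = 9L) {
  torso_chain(profile$summaries$phi_mean, profile$summaries$psi_mean,
              head_len = head_len)
}

# torso fragment with angles set to a profile's means
mean_fragment <- function(profile, head_len = 9L) {
  ch <- torso_chain_from_profile(profile, head_len)
  extract_torso(ch, 2L, nrow(ch$residues) - 1L)
}

# random rigid transform applied to an n x 3 matrix
random_rigid <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(m %*% t(R), 2, stats::rnorm(3, sd = 5), `+`)
}

# independent superposition-RMSD oracle: coarse search over rotations (unit
# quaternions) refined by Nelder-Mead on Euler angles; no Kabsch involved
oracle_superpose_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  rot_euler <- function(e) {
    cz <- cos(e[1]); sz <- sin(e[1])
    cy <- cos(e[2]); sy <- sin(e[2])
    cx <- cos(e[3]); sx <- sin(e[3])
    matrix(c(cz * cy, sz * cy, -sy,
             cz * sy * sx - sz * cx, sz * sy * sx + cz * cx, cy * sx,
             cz * sy * cx + sz * sx, sz * sy * cx - cz * sx, cy * cx), 3, 3)
  }
  f <- function(e) sqrt(mean(rowSums((a0 - b0 %*% t(rot_euler(e)))^2)))
  grid <- seq(0, 2 * pi - 0.4, by = 0.4)
  best <- Inf; best_e <- c(0, 0, 0)
  for (z in grid) for (y in grid) for (x in grid) {
    v <- f(c(z, y, x))
    if (v < best) { best <- v; best_e <- c(z, y, x) }
  }
  opt <- stats::optim(best_e, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# independent greedy clustering oracle: pairwise RMSDs via bio3d, then the
# most-neighbors rule written as a direct loop
oracle_greedy_cluster <- function(items, radius) {
  n <- length(items)
  dm <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dm[i, j] <- dm[j, i] <- bio3d::rmsd(c(t(items[[i]])), c(t(items[[j]])),
                                        fit = TRUE)
  }
  remaining <- 1:n
  out <- list()
  while (length(remaining)) {
    counts <- sapply(remaining, function(i) sum(dm[i, remaining] <= radius))
    ctr <- remaining[which.max(counts)]
    mem <- remaining[dm[ctr, remaining] <= radius]
    out[[length(out) + 1]] <- sort(mem)
    remaining <- setdiff(remaining, mem)
  }
  out[order(sapply(out, length), decreasing = TRUE)]
}

# small cloud of distinct 3D points
point_cloud <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 3), n, 3)
}

# profile variant for cluster-separation fixtures: concentrated within-class
# dispersion and no bimodal psi(T4) flip, so class geometry stays within the
# 2 A cluster radius while the between-class difference is untouched
tight_profile <- function(profile, sd_cap = 8) {
  profile$summaries$phi_sd <- pmin(profile$summaries$phi_sd, sd_cap)
  profile$summaries$psi_sd <- pmin(profile$summaries$psi_sd, sd_cap)
  profile$excluded <- character(0)
  profile
}

# native chain for decoy experiments: extended framework padding around a
# 16-residue loop so the framework fit has plenty of CA atoms
padded_native <- function(pad = 7L, loop_len = 16L) {
  n <- 2L * pad + loop_len
  ch <- build_backbone(data.frame(aa = rep("A", n), phi = -120, psi = 130))
  list(chain = ch, loop_start = pad + 1L, loop_end = pad + loop_len)
}
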