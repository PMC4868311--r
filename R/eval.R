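## Decoy-set evaluation: length-normalized loop RMSD (RMSD16), sampling and
## score-based recovery metrics, funnel labeling, and cluster reports.
##
## Scores are in Rosetta Energy Units (REU); lower is better.  All rank
## computations sort ascending by score with ties broken by model id.

#' Length-normalized loop RMSD (RMSD16)
#'
#' Normalizes a loop C-alpha RMSD to a reference loop length of 16 residues
#' using the Carugo-Pongor logarithmic length correction rescaled to
#' reference length 16: `rmsd / (1 + ln(sqrt(L / 16)))`.  RMSDs of loops of
#' different lengths become comparable; the normalization is the identity
#' at L = 16 and inflates the RMSD of shorter loops.
#'
#' @param rmsd Loop C-alpha RMSD in Angstrom (>= 0).
#' @param L Loop length in residues (>= 4; the correction diverges for very
#'   short segments).
#' @return RMSD16 in Angstrom.
#' @export
rmsd16 <- function(rmsd, L) {
  stopifnot(all(rmsd >= 0))
  if (any(L < 4))
    stop("length normalization undefined for loops shorter than 4 residues",
         call. = FALSE)
  rmsd / (1 + log(sqrt(L / 16)))
}

#' Loop C-alpha RMSD after framework superposition
#'
#' Superposes the model onto the native on the C-alpha atoms of all
#' residues outside the loop (the framework), then computes the C-alpha
#' RMSD over the loop residues without re-fitting.  A rigid motion of the
#' whole model therefore contributes nothing; only loop displacement
#' relative to the framework is measured.
#'
#' @param model,native [chain_backbone()]s with identical residue counts.
#' @param loop_start,loop_end 1-based inclusive loop range.
#' @return RMSD in Angstrom.
#' @export
loop_rmsd <- function(model, native, loop_start, loop_end) {
  n <- nrow(native$residues)
  if (nrow(model$residues) != n)
    stop("model and native differ in residue count", call. = FALSE)
  loop <- loop_start:loop_end
  frame <- setdiff(seq_len(n), loop)
  if (length(frame) < 3L)
    stop("framework too small to superpose on", call. = FALSE)
  nat_frame <- res_atom_matrix(native, frame, "CA")
  mod_frame <- res_atom_matrix(model, frame, "CA")
  fit <- superpose(nat_frame, mod_frame)
  mod_loop <- res_atom_matrix(model, loop, "CA")
  # apply the framework transform to the loop atoms
  mod_loop <- sweep(sweep(mod_loop, 2L, colMeans(mod_frame)) %*% t(fit$rotation),
                    2L, fit$translation, `+`)
  nat_loop <- res_atom_matrix(native, loop, "CA")
  coord_rmsd(nat_loop, mod_loop)
}

#' Sampling metrics of a decoy set
#'
#' How well the conformational sampling covered the native basin: the
#' number of models strictly below 2 Angstrom RMSD16, the best RMSD16
#' sampled, and the mean RMSD16 of the 10 best models ranked by RMSD16
#' (all models when fewer than 10).
#'
#' @param decoys data.frame with at least columns `id` and `rmsd16`.
#' @param cutoff Native-likeness cutoff in Angstrom; default 2.
#' @return List with `n_below`, `best_rmsd16`, `avg_rmsd16_best10`.
#' @export
sampling_metrics <- function(decoys, cutoff = 2.0) {
  if (!nrow(decoys)) stop("empty decoy set", call. = FALSE)
  r <- decoys$rmsd16
  list(n_below = sum(r < cutoff),
       best_rmsd16 = min(r),
       avg_rmsd16_best10 = mean(utils::head(sort(r), 10L)))
}

#' Score-based recovery metrics of a decoy set
#'
#' How well the score identifies native-like models: the RMSD16 of the
#' top-scoring model, the mean RMSD16 of the 10 best-scoring models, and
#' the 1-based rank (by score) of the first model strictly below the
#' cutoff (NA when none is).
#'
#' @param decoys data.frame with columns `id`, `score` (REU, lower is
#'   better) and `rmsd16`.
#' @param cutoff Native-likeness cutoff in Angstrom; default 2.
#' @return List with `rmsd16_top_scoring`, `avg_rmsd16_top10_by_score`,
#'   `rank_first_below`.
#' @export
scoring_metrics <- function(decoys, cutoff = 2.0) {
  if (!nrow(decoys)) stop("empty decoy set", call. = FALSE)
  ord <- order(decoys$score, decoys$id)
  r <- decoys$rmsd16[ord]
  hit <- which(r < cutoff)
  list(rmsd16_top_scoring = r[1L],
       avg_rmsd16_top10_by_score = mean(utils::head(r, 10L)),
       rank_first_below = if (length(hit)) hit[1L] else NA_integer_)
}

#' Funnel labels for a score-vs-RMSD16 decoy plot
#'
#' `"blue"`: score ranked in the top 10 percent and RMSD16 <= 2 Angstrom
#' (native-like and recognized); `"red"`: score ranked below the top 10
#' percent and RMSD16 > 2 (non-native and correctly penalized); `"gray"`
#' otherwise.  The top-10-percent cut keeps `ceiling(0.10 * N)` models,
#' with score ties at the cut broken by model id; labels depend on score
#' only through ranks and are invariant under monotone score transforms.
#'
#' @inheritParams scoring_metrics
#' @param top_fraction Fraction of models counted as top-scoring;
#'   default 0.10.
#' @return Character vector of labels aligned with `decoys` rows.
#' @export
label_models <- function(decoys, cutoff = 2.0, top_fraction = 0.10) {
  n <- nrow(decoys)
  if (!n) stop("empty decoy set", call. = FALSE)
  ord <- order(decoys$score, decoys$id)
  rank <- integer(n); rank[ord] <- seq_len(n)
  top <- rank <= ceiling(top_fraction * n)
  native <- decoys$rmsd16 <= cutoff
  ifelse(top & native, "blue",
         ifelse(!top & !native, "red", "gray"))
}

#' Cluster report for a decoy set
#'
#' Per surviving cluster: size, dense size rank (1 = largest), average
#' score, average RMSD16 and dense RMSD16 rank (1 = lowest).  The cluster
#' with the lowest average score is flagged as the "correct" cluster --
#' the selection a blind modeling run would make, since the native
#' structure is unknown outside benchmarks.  When only one cluster
#' survives its ranks carry a `single_cluster` flag (reported as "1*");
#' with no survivors the report is marked not available.
#'
#' @param decoys data.frame with columns `id`, `score`, `rmsd16`.
#' @param clusters Output of [cluster_decoys()] whose member ids all appear
#'   in `decoys$id`.
#' @return List with `available`, `single_cluster`, `table` (one row per
#'   cluster) and `correct` (the flagged row, or NULL).
#' @export
cluster_report <- function(decoys, clusters) {
  if (!length(clusters))
    return(list(available = FALSE, single_cluster = FALSE,
                table = NULL, correct = NULL))
  rows <- lapply(clusters, function(cl) {
    hit <- match(cl$members, decoys$id)
    if (anyNA(hit))
      stop("cluster member(s) without decoy record: ",
           paste(cl$members[is.na(hit)], collapse = ", "), call. = FALSE)
    data.frame(representative = cl$representative, size = cl$size,
               avg_score = mean(decoys$score[hit]),
               avg_rmsd16 = mean(decoys$rmsd16[hit]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$size_rank <- .dense_rank(-tab$size)
  tab$rmsd_rank <- .dense_rank(tab$avg_rmsd16)
  tab$correct <- seq_len(nrow(tab)) == which.min(tab$avg_score)
  list(available = TRUE, single_cluster = nrow(tab) == 1L,
       table = tab, correct = tab[tab$correct, , drop = FALSE])
}

# dense rank: 1 = smallest value; equal values share a rank
.dense_rank <- function(x) match(x, sort(unique(x)))
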