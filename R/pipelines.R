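## The two end-to-end workflows: deriving knowledge-based torso restraints
## from a set of antibody structures, and evaluating a decoy set produced
## by an external loop-modeling engine.  The modeling engine itself (which
## consumes the constraint file and produces the decoys/scores) sits
## between the two pipelines and is not part of this package.

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

.log <- function(quiet, fmt, ...) if (!quiet) message(sprintf(fmt, ...))

#' Derive torso restraints from antibody structures
#'
#' Reads the HCDR3 definitions table, extracts a torso fragment from each
#' structure, separates torso conformations by greedy RMSD clustering,
#' summarizes each of the two largest clusters into a dihedral profile with
#' circular statistics, derives circular-harmonic restraints from the
#' bulged-labeled (or largest) profile and reports the T2/T6 sequence-motif
#' statistics of that cluster.
#'
#' @param pdb_dir Directory holding the PDB files named in the definitions.
#' @param definitions Path to the definitions CSV
#'   (`pdb_file, chain_id, start, end`), or its parsed data.frame.
#' @param out_dir Optional output directory; when given, profile CSVs, the
#'   constraint file, the motif report and a provenance JSON are written.
#' @param radius Fragment cluster radius in Angstrom; default 2.
#' @param min_sigma Restraint width floor in degrees; default 1.
#' @param reference Optional reference [torso_profile()] used to label
#'   clusters: a cluster whose mean psi(T6) lies within 3 reference
#'   standard deviations of the reference bulged psi(T6) is labeled
#'   bulged, otherwise non-bulged.  Without a reference, clusters are
#'   labeled cluster-1, cluster-2 by size.
#' @param restraint_start,restraint_length Target numbering for the
#'   emitted restraints; default to the first definition row.
#' @param quiet Suppress per-stage progress messages.
#' @return List with `fragments`, `clusters`, `profiles`, `restraints`,
#'   `motif` and `counts`.
#' @export
run_derive_pipeline <- function(pdb_dir, definitions, out_dir = NULL,
                                radius = 2.0, min_sigma = 1,
                                reference = NULL,
                                restraint_start = NULL,
                                restraint_length = NULL,
                                quiet = FALSE) {
  stopifnot(radius > 0, min_sigma > 0)
  defs <- .stage("read_definitions", {
    d <- if (is.data.frame(definitions)) definitions else read_definitions(definitions)
    if (!nrow(d)) stop("no valid HCDR3 definitions")
    d
  })
  .log(quiet, "read_definitions: %d definitions", nrow(defs))

  fragments <- .stage("extract_torsos", {
    frags <- lapply(seq_len(nrow(defs)), function(i) {
      chain <- read_backbone(file.path(pdb_dir, defs$pdb_file[i]),
                             defs$chain_id[i])
      extract_torso(chain, defs$start[i], defs$end[i])
    })
    names(frags) <- make.unique(defs$pdb_file)
    frags
  })
  .log(quiet, "extract_torsos: %d torso fragments", length(fragments))

  clusters <- .stage("cluster_fragments",
    greedy_cluster(lapply(fragments, fragment_coords), radius = radius))
  .log(quiet, "cluster_fragments: %d clusters, sizes %s", length(clusters),
       paste(vapply(clusters, `[[`, integer(1), "size"), collapse = "/"))

  profiles <- .stage("profile_clusters", {
    top <- utils::head(clusters, 2L)
    lapply(seq_along(top), function(ci) {
      members <- fragments[top[[ci]]$members]
      dihedrals <- suppressWarnings(lapply(members, torso_dihedrals))
      prof <- profile_from_dihedrals(dihedrals, label = paste0("cluster-", ci))
      if (!is.null(reference)) {
        ref_t6 <- profile_angle(reference, "T6", "psi")
        t6 <- profile_angle(prof, "T6", "psi")
        bulged <- abs(wrap180(t6$mean - ref_t6$mean)) <= 3 * ref_t6$sd
        prof$label <- if (bulged) "bulged" else "non-bulged"
      }
      prof
    })
  })
  .log(quiet, "profile_clusters: %s",
       paste(vapply(profiles, `[[`, character(1), "label"), collapse = ", "))

  target <- profiles[[1L]]
  if (!is.null(reference)) {
    hit <- which(vapply(profiles, `[[`, character(1), "label") == "bulged")
    if (length(hit)) target <- profiles[[hit[1L]]]
  }
  if (is.null(restraint_start)) restraint_start <- defs$start[1L]
  if (is.null(restraint_length))
    restraint_length <- defs$end[1L] - defs$start[1L] + 1L
  restraints <- .stage("derive_restraints",
    derive_restraints(target, start = restraint_start,
                      length = restraint_length, min_sigma = min_sigma))
  .log(quiet, "derive_restraints: %d restraints from profile '%s'",
       nrow(restraints$restraints), target$label)

  target_members <- clusters[[
    which(vapply(profiles, `[[`, character(1), "label") == target$label)[1L]]]$members
  motif <- .stage("motif_stats",
    motif_stats(vapply(fragments[target_members], `[[`, character(1),
                       "sequence")))
  .log(quiet, "motif_stats: T2 R/K %.2f, T6 D %.2f, both %.2f over n = %d",
       motif$frac_t2_rk, motif$frac_t6_d, motif$frac_both, motif$n)

  result <- list(fragments = fragments, clusters = clusters,
                 profiles = profiles, restraints = restraints, motif = motif,
                 counts = list(definitions = nrow(defs),
                               fragments = length(fragments),
                               cluster_sizes = vapply(clusters, `[[`,
                                                      integer(1), "size")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in profiles)
      write_profile_csv(p, file.path(out_dir, paste0("profile_", p$label, ".csv")))
    write_rosetta_constraints(restraints, file.path(out_dir, "hcdr3.cst"))
    utils::write.csv(
      data.frame(metric = c("frac_t2_rk", "frac_t6_d", "frac_both", "n"),
                 value = c(motif$frac_t2_rk, motif$frac_t6_d,
                           motif$frac_both, motif$n)),
      file.path(out_dir, "motif.csv"), row.names = FALSE, quote = FALSE)
    .write_provenance(file.path(out_dir, "provenance.json"),
                      pipeline = "derive",
                      inputs = list(pdb_dir = pdb_dir),
                      parameters = list(radius = radius, min_sigma = min_sigma,
                                        restraint_start = restraint_start,
                                        restraint_length = restraint_length))
  }
  result
}

#' Evaluate a decoy set against its native structure
#'
#' Computes loop RMSD after framework superposition and RMSD16 for every
#' decoy, joins the external scores, and produces the sampling metrics,
#' score-based recovery metrics, funnel labels and Calibur-style cluster
#' report.
#'
#' @param native A [chain_backbone()], or a PDB path (then `chain_id` is
#'   required).
#' @param decoys Named list of [chain_backbone()]s, or a directory of decoy
#'   PDB files (model id = file name without extension).
#' @param scores data.frame with columns `id`, `score` (REU), or a path
#'   readable by [read_score_table()].
#' @param loop_start,loop_end 1-based inclusive HCDR3 range.
#' @param chain_id Chain to read when `native`/`decoys` are paths.
#' @param threshold Decoy cluster radius in Angstrom; default 2.
#' @param min_fraction Minimum cluster fraction; default 0.01.
#' @param out_dir Optional output directory for the report CSVs, the
#'   per-model scatter data and a provenance JSON.
#' @param quiet Suppress progress messages.
#' @return List with `records` (per-model table including labels),
#'   `sampling`, `scoring`, `clusters` and `cluster_report`.
#' @export
run_evaluate_pipeline <- function(native, decoys, scores, loop_start, loop_end,
                                  chain_id = "H", threshold = 2.0,
                                  min_fraction = 0.01, out_dir = NULL,
                                  quiet = FALSE) {
  stopifnot(threshold > 0)
  native <- .stage("read_native",
    if (is.character(native)) read_backbone(native, chain_id) else native)
  decoys <- .stage("read_decoys", {
    if (is.character(decoys)) {
      files <- sort(list.files(decoys, pattern = "\\.pdb$", full.names = TRUE))
      if (!length(files)) stop("no decoy PDB files in ", decoys)
      out <- lapply(files, read_backbone, chain_id = chain_id)
      names(out) <- sub("\\.pdb$", "", basename(files))
      out
    } else decoys
  })
  scores <- .stage("read_scores",
    if (is.character(scores)) read_score_table(scores) else scores)
  .log(quiet, "read: native + %d decoys, %d scores", length(decoys),
       nrow(scores))

  records <- .stage("measure_rmsd", {
    L <- loop_end - loop_start + 1L
    ids <- names(decoys)
    missing <- setdiff(ids, scores$id)
    if (length(missing))
      stop("decoys without score: ", paste(missing, collapse = ", "))
    r <- vapply(decoys, loop_rmsd, numeric(1), native = native,
                loop_start = loop_start, loop_end = loop_end)
    data.frame(id = ids, score = scores$score[match(ids, scores$id)],
               rmsd = unname(r), rmsd16 = rmsd16(unname(r), L), L = L,
               stringsAsFactors = FALSE)
  })
  records$label <- label_models(records)
  sampling <- sampling_metrics(records)
  scoring <- scoring_metrics(records)
  .log(quiet,
       "metrics: %d below 2 A RMSD16, best %.2f A, top-scoring %.2f A",
       sampling$n_below, sampling$best_rmsd16, scoring$rmsd16_top_scoring)

  clusters <- .stage("cluster_decoys", {
    coords <- lapply(decoys, function(d)
      res_atom_matrix(d, loop_start:loop_end, "CA"))
    cluster_decoys(coords, threshold = threshold, min_fraction = min_fraction)
  })
  report <- .stage("cluster_report", cluster_report(records, clusters))
  .log(quiet, "clusters: %s",
       if (!report$available) "N/A (no cluster above the size floor)"
       else sprintf("%d surviving; correct cluster size %d (rank %d%s)",
                    nrow(report$table), report$correct$size,
                    report$correct$size_rank,
                    if (report$single_cluster) "*" else ""))

  result <- list(records = records, sampling = sampling, scoring = scoring,
                 clusters = clusters, cluster_report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "models.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(metric = c("n_below_2A", "best_rmsd16", "avg_rmsd16_best10",
                            "rmsd16_top_scoring", "avg_rmsd16_top10_by_score",
                            "rank_first_below_2A"),
                 value = c(sampling$n_below, sampling$best_rmsd16,
                           sampling$avg_rmsd16_best10,
                           scoring$rmsd16_top_scoring,
                           scoring$avg_rmsd16_top10_by_score,
                           scoring$rank_first_below)),
      file.path(out_dir, "metrics.csv"), row.names = FALSE, quote = FALSE)
    if (report$available)
      utils::write.csv(report$table, file.path(out_dir, "clusters.csv"),
                       row.names = FALSE, quote = FALSE)
    .write_provenance(file.path(out_dir, "provenance.json"),
                      pipeline = "evaluate",
                      inputs = list(loop_start = loop_start,
                                    loop_end = loop_end),
                      parameters = list(threshold = threshold,
                                        min_fraction = min_fraction))
  }
  result
}

.write_provenance <- function(path, pipeline, inputs, parameters) {
  jsonlite::write_json(
    list(pipeline = pipeline, inputs = inputs, parameters = parameters,
         package = "cdr3torso",
         version = as.character(utils::packageVersion("cdr3torso")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE)
}
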