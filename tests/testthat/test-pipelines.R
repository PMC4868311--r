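# End-to-end pipelines on synthetic structures written to disk as PDB.

bulged <- reference_torso_profile("bulged")
nonbulged <- reference_torso_profile("non-bulged")

# structures drawn tightly around the class means: the fixture probes the
# cluster -> profile -> restraint mechanics, not dispersion robustness
make_structure_set <- function(dir, n_bulged = 20, n_nonbulged = 5, seed = 101) {
  dir.create(dir, showWarnings = FALSE)
  frag_sets <- sample_class_torsos(tight_profile(bulged), n_bulged,
                                   seed = seed)
  if (n_nonbulged > 0)
    frag_sets <- c(frag_sets,
                   sample_class_torsos(tight_profile(nonbulged), n_nonbulged,
                                       seed = seed + 1))
  lines <- c("pdb_file,chain_id,start,end")
  for (i in seq_along(frag_sets)) {
    truth <- attr(frag_sets[[i]], "truth")
    ch <- torso_chain(truth$phi, truth$psi)
    file <- sprintf("ab%03d.pdb", i)
    write_backbone_pdb(ch, file.path(dir, file))
    lines <- c(lines, sprintf("%s,H,2,17", file))
  }
  defs <- file.path(dir, "defs.csv")
  writeLines(lines, defs)
  list(dir = dir, defs = defs, n = length(frag_sets))
}

test_that("the derive pipeline separates classes and recovers generator means", {
  setd <- make_structure_set(tempfile("derive"))
  out_dir <- tempfile("out")
  res <- run_derive_pipeline(setd$dir, setd$defs, out_dir = out_dir,
                             reference = bulged, quiet = TRUE)
  expect_equal(res$counts$fragments, 25L)
  expect_equal(res$counts$cluster_sizes[1:2], c(20L, 5L))
  labels <- vapply(res$profiles, `[[`, character(1), "label")
  expect_setequal(labels, c("bulged", "non-bulged"))
  prof_b <- res$profiles[[which(labels == "bulged")]]
  for (pos in paste0("T", 1:7)) {
    i <- match(pos, prof_b$summaries$position)
    expect_lt(abs(wrap180(prof_b$summaries$phi_mean[i] -
                          bulged$summaries$phi_mean[i])), 5)
    if (pos != "T4")
      expect_lt(abs(wrap180(prof_b$summaries$psi_mean[i] -
                            bulged$summaries$psi_mean[i])), 5)
  }
  expect_equal(nrow(res$restraints$restraints), 13L)
  expect_true(file.exists(file.path(out_dir, "hcdr3.cst")))
  expect_true(file.exists(file.path(out_dir, "profile_bulged.csv")))
  expect_true(file.exists(file.path(out_dir, "provenance.json")))
  # profile CSV round-trips
  back <- read_profile_csv(file.path(out_dir, "profile_bulged.csv"))
  expect_equal(back$summaries$phi_mean, prof_b$summaries$phi_mean,
               tolerance = 1e-9)
})

test_that("derive pipeline reports stage names on failure and floors sigma", {
  expect_error(run_derive_pipeline(tempdir(), c("pdb_file,chain_id,start,end"),
                                   quiet = TRUE),
               "\\[read_definitions\\]")
  # single structure: one singleton cluster, sd floored in the restraints
  setd <- make_structure_set(tempfile("single"), n_bulged = 1, n_nonbulged = 0)
  res <- run_derive_pipeline(setd$dir, setd$defs, quiet = TRUE)
  expect_equal(res$counts$cluster_sizes, 1L)
  expect_true(all(res$restraints$restraints$sigma >= pi / 180 - 1e-12))
})

test_that("the evaluate pipeline matches per-metric recomputation on a fixture", {
  nat <- padded_native()
  ds <- make_decoy_set(nat$chain, nat$loop_start, nat$loop_end, n = 60,
                       noise_sd = 15, score_a = 2, score_noise_sd = 0.5,
                       seed = 7)
  decoy_dir <- tempfile("decoys")
  dir.create(decoy_dir)
  for (id in names(ds$decoys))
    write_backbone_pdb(ds$decoys[[id]], file.path(decoy_dir, paste0(id, ".pdb")))
  native_pdb <- tempfile(fileext = ".pdb")
  write_backbone_pdb(nat$chain, native_pdb)
  scores <- tempfile(fileext = ".tsv")
  write.table(ds$records[, c("id", "score")], scores, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  out_dir <- tempfile("eval")
  res <- run_evaluate_pipeline(native_pdb, decoy_dir, scores,
                               loop_start = nat$loop_start,
                               loop_end = nat$loop_end,
                               out_dir = out_dir, quiet = TRUE)
  # PDB serialization quantizes coordinates; ground truth survives to ~1e-2
  expect_equal(res$records$rmsd16[order(res$records$id)],
               ds$records$rmsd16[order(ds$records$id)], tolerance = 1e-2)
  expect_equal(res$sampling$n_below, sum(res$records$rmsd16 < 2))
  expect_equal(res$scoring$rmsd16_top_scoring,
               res$records$rmsd16[which.min(res$records$score)])
  expect_true(file.exists(file.path(out_dir, "models.csv")))
  expect_true(file.exists(file.path(out_dir, "metrics.csv")))
  # missing scores are reported by id
  bad <- ds$records[-1, c("id", "score")]
  expect_error(run_evaluate_pipeline(nat$chain, ds$decoys, bad,
                                     nat$loop_start, nat$loop_end,
                                     quiet = TRUE),
               "decoy_0001")
})

test_that("identical decoys give a single flagged cluster and perfect sampling", {
  nat <- padded_native()
  decoys <- setNames(rep(list(nat$chain), 20), sprintf("copy_%02d", 1:20))
  set.seed(8)
  scores <- data.frame(id = names(decoys), score = stats::rnorm(20, -10))
  res <- run_evaluate_pipeline(nat$chain, decoys, scores,
                               nat$loop_start, nat$loop_end, quiet = TRUE)
  expect_equal(res$sampling$n_below, 20L)
  expect_equal(res$sampling$best_rmsd16, 0, tolerance = 1e-9)
  expect_true(res$cluster_report$single_cluster)
  expect_equal(res$cluster_report$correct$size, 20L)
})

test_that("shuffling scores changes labels but not sampling metrics", {
  nat <- padded_native()
  ds <- make_decoy_set(nat$chain, nat$loop_start, nat$loop_end, n = 40,
                       noise_sd = 15, seed = 13)
  rec1 <- ds$records
  set.seed(5)
  rec2 <- rec1
  rec2$score <- sample(rec2$score)
  expect_identical(sampling_metrics(rec1), sampling_metrics(rec2))
  expect_false(identical(label_models(rec1), label_models(rec2)))
})
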