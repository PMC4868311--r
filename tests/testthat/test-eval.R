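# RMSD16, loop RMSD, sampling/scoring metrics, funnel labels, cluster report.

test_that("rmsd16 has its fixed point at L = 16 and follows the log correction", {
  expect_equal(rmsd16(2.0, 16), 2.0)
  expect_equal(rmsd16(0, 11), 0)
  expect_equal(rmsd16(2.0, 26), 2 / (1 + 0.5 * log(26 / 16)))
  expect_equal(rmsd16(2.0, 26), 1.60933, tolerance = 1e-5)
  # strictly increasing in rmsd at fixed L; inflates short loops
  r <- seq(0, 5, by = 0.5)
  expect_true(all(diff(rmsd16(r, 11)) > 0))
  expect_gt(rmsd16(1, 11), 1)
  expect_lt(rmsd16(1, 26), 1)
  expect_error(rmsd16(1, 3), "shorter than 4")
})

test_that("loop RMSD is measured after framework superposition", {
  native <- build_backbone(data.frame(aa = rep("A", 30), phi = -120, psi = 130))
  expect_equal(loop_rmsd(native, native, 10, 20), 0, tolerance = 1e-9)
  # a rigid motion of the whole model is removed by the framework fit
  rot <- native
  m <- as.matrix(rot$residues[, 3:11])
  moved <- random_rigid(rbind(m[, 1:3], m[, 4:6], m[, 7:9]), seed = 4)
  n <- nrow(m)
  rot$residues[, 3:5] <- moved[1:n, ]
  rot$residues[, 6:8] <- moved[n + 1:n, ]
  rot$residues[, 9:11] <- moved[2 * n + 1:n, ]
  expect_equal(loop_rmsd(rot, native, 10, 20), 0, tolerance = 1e-9)
  # displacing the loop CA atoms by 1 A (leaving the framework) gives 1 A
  shifted <- native
  shifted$residues$ca_z[10:20] <- shifted$residues$ca_z[10:20] + 1
  expect_equal(loop_rmsd(shifted, native, 10, 20), 1, tolerance = 1e-9)
})

test_that("sampling metrics use a strict below-2A count and best-10 average", {
  d <- data.frame(id = letters[1:4], rmsd16 = c(0.5, 1.5, 2.5, 3.0))
  m <- sampling_metrics(d)
  expect_equal(m$n_below, 2L)
  expect_equal(m$best_rmsd16, 0.5)
  expect_equal(m$avg_rmsd16_best10, 1.875)  # all four used when fewer than 10
  one <- sampling_metrics(data.frame(id = "a", rmsd16 = 1.0))
  expect_equal(unlist(one), c(n_below = 1, best_rmsd16 = 1, avg_rmsd16_best10 = 1))
  expect_equal(sampling_metrics(data.frame(id = "a", rmsd16 = c(2, 2.4)))$n_below, 0L)
  expect_error(sampling_metrics(data.frame(id = character(0),
                                           rmsd16 = numeric(0))), "empty")
})

test_that("scoring metrics rank by score with ties broken by id", {
  d <- data.frame(id = c("m1", "m2", "m3"), score = c(-10, -9, -8),
                  rmsd16 = c(3.0, 1.0, 0.5))
  m <- scoring_metrics(d)
  expect_equal(m$rmsd16_top_scoring, 3.0)
  expect_equal(m$rank_first_below, 2L)
  expect_equal(m$avg_rmsd16_top10_by_score, mean(c(3, 1, 0.5)))
  all_native <- data.frame(id = c("a", "b"), score = c(1, 2), rmsd16 = c(1, 1))
  expect_equal(scoring_metrics(all_native)$rank_first_below, 1L)
  none <- data.frame(id = c("a", "b"), score = c(1, 2), rmsd16 = c(3, 4))
  expect_true(is.na(scoring_metrics(none)$rank_first_below))
})

test_that("labels partition blue/red/gray by top-10% score and the 2A cutoff", {
  d <- data.frame(id = sprintf("m%02d", 1:10), score = 1:10,
                  rmsd16 = c(1, 3, 3, 3, 3, 1, 1, 3, 3, 3))
  lab <- label_models(d)
  expect_equal(lab[1], "blue")    # best score, native-like
  expect_equal(lab[10], "red")    # worst score, non-native
  expect_equal(lab[6], "gray")    # native-like but not top-scoring
  d2 <- d; d2$rmsd16[1] <- 3
  expect_equal(label_models(d2)[1], "gray")  # top score but non-native
  expect_false(any(lab == "blue" & lab == "red"))
  # rank-based: monotone score transforms leave labels unchanged
  d3 <- d; d3$score <- exp(d$score / 2) - 50
  expect_identical(label_models(d3), lab)
})

test_that("metrics and labels agree with a brute-force re-sort oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(12:60, 1)
    d <- data.frame(id = sprintf("m%03d", sample(n)),
                    score = round(stats::rnorm(n, -15, 5), 2),
                    rmsd16 = round(stats::rexp(n, 1 / 2), 3))
    # oracle: explicit sorts, no shared code with the implementation
    ord <- order(d$score, d$id)
    sm <- sampling_metrics(d); sc <- scoring_metrics(d)
    expect_equal(sm$n_below, sum(d$rmsd16 < 2))
    expect_equal(sm$best_rmsd16, sort(d$rmsd16)[1])
    expect_equal(sm$avg_rmsd16_best10, mean(sort(d$rmsd16)[1:min(10, n)]))
    expect_equal(sc$rmsd16_top_scoring, d$rmsd16[ord][1])
    expect_equal(sc$avg_rmsd16_top10_by_score,
                 mean(d$rmsd16[ord][1:min(10, n)]))
    below <- which(d$rmsd16[ord] < 2)
    expect_equal(sc$rank_first_below,
                 if (length(below)) below[1] else NA_integer_)
    lab <- label_models(d)
    cut <- ceiling(0.1 * n)
    top_ids <- d$id[ord][1:cut]
    expect_identical(lab, ifelse(d$id %in% top_ids & d$rmsd16 <= 2, "blue",
                          ifelse(!(d$id %in% top_ids) & d$rmsd16 > 2, "red",
                                 "gray")))
  }
})

test_that("the correct cluster is the lowest-average-score cluster with dense ranks", {
  d <- data.frame(id = sprintf("m%03d", 1:100),
                  score = c(rep(-12, 60), rep(-8, 40)) + seq(0, 0.99, 0.01),
                  rmsd16 = c(rep(1.2, 60), rep(3.5, 40)))
  clusters <- list(
    list(representative = "m001", members = d$id[1:60], size = 60L,
         avg_rmsd = 0.4),
    list(representative = "m061", members = d$id[61:100], size = 40L,
         avg_rmsd = 0.5))
  rep_ <- cluster_report(d, clusters)
  expect_true(rep_$available)
  expect_false(rep_$single_cluster)
  expect_equal(rep_$correct$representative, "m001")
  expect_equal(rep_$correct$size_rank, 1L)
  expect_equal(rep_$correct$rmsd_rank, 1L)
  # single surviving cluster -> flagged
  rep1 <- cluster_report(d, clusters[1])
  expect_true(rep1$single_cluster)
  expect_equal(rep1$correct$size_rank, 1L)
  # no survivors -> not available
  rep0 <- cluster_report(d, list())
  expect_false(rep0$available)
  expect_null(rep0$table)
  # member without record -> error
  bad <- clusters
  bad[[1]]$members[1] <- "ghost"
  expect_error(cluster_report(d, bad), "ghost")
})

test_that("correct-cluster RMSD rank improves as score noise vanishes", {
  # score = rmsd16 + noise: with less noise the lowest-score cluster is
  # increasingly the lowest-RMSD cluster
  set.seed(12)
  base_rmsd <- c(0.8, 2.5, 4.0)
  ranks <- vapply(c(3, 0.5, 0), function(noise) {
    set.seed(99)
    d <- data.frame(id = sprintf("m%03d", 1:90),
                    rmsd16 = rep(base_rmsd, each = 30) +
                      stats::runif(90, 0, 0.1))
    d$score <- d$rmsd16 + stats::rnorm(90, 0, noise)
    clusters <- lapply(0:2, function(g)
      list(representative = d$id[30 * g + 1],
           members = d$id[30 * g + 1:30], size = 30L, avg_rmsd = 0.1))
    cluster_report(d, clusters)$correct$rmsd_rank
  }, integer(1))
  expect_true(all(diff(ranks) <= 0))
  expect_equal(ranks[3], 1L)
})
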