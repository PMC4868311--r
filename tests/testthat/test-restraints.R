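# Restraint derivation, Rosetta constraint-file serialization and the
# circular-harmonic penalty.

bulged <- reference_torso_profile("bulged")

test_that("a bulged derivation yields 13 restraints and skips psi(T4)", {
  rs <- derive_restraints(bulged, start = 100, length = 16)
  df <- rs$restraints
  expect_equal(nrow(df), 13L)
  expect_equal(sum(df$angle == "phi"), 7L)
  expect_equal(sum(df$angle == "psi"), 6L)
  # T4 maps to residue 112 for start 100, length 16; no psi restraint there
  expect_false(any(df$angle == "psi" & df$r2 == 112))
  expect_true(any(df$angle == "phi" & df$r2 == 112))
  # order: T1..T7, phi before psi within a residue
  expect_equal(df$position,
               c("T1", "T1", "T2", "T2", "T3", "T3", "T4",
                 "T5", "T5", "T6", "T6", "T7", "T7"))
  # the invariant holds across lengths and starts
  for (L in c(8, 11, 16, 26)) {
    rs2 <- derive_restraints(bulged, start = 95, length = L)
    expect_equal(nrow(rs2$restraints), 13L)
  }
  expect_error(derive_restraints(bulged, start = 100, length = 7), "< 8")
  expect_error(derive_restraints(bulged, start = 1, length = 16), ">= 2")
})

test_that("shortest loops map T4-T7 contiguously after the single head residue", {
  rs <- derive_restraints(bulged, start = 10, length = 8)
  phi_res <- rs$restraints$r2[rs$restraints$angle == "phi"]
  expect_equal(phi_res, c(10:12, 14:17))
})

test_that("constraint lines carry radians at 6 decimals in the Rosetta dialect", {
  rs <- derive_restraints(bulged, start = 100, length = 16)
  lines <- write_rosetta_constraints(rs)
  expect_equal(lines[1],
               "Dihedral C 99 N 100 CA 100 C 100 CIRCULARHARMONIC -2.530727 0.157080")
  expect_equal(length(lines), 13L)
  expect_true(all(grepl(
    "^Dihedral( (N|CA|C) \\d+){4} CIRCULARHARMONIC -?\\d+\\.\\d{6} \\d+\\.\\d{6}$",
    lines)))
  # empty set -> empty output
  rs0 <- rs; rs0$restraints <- rs$restraints[0, ]
  expect_length(write_rosetta_constraints(rs0), 0L)
})

test_that("write/parse round-trips the constraint file", {
  rs <- derive_restraints(bulged, start = 100, length = 16)
  f <- tempfile(fileext = ".cst")
  write_rosetta_constraints(rs, f)
  back <- parse_rosetta_constraints(f)
  cols <- c("a1", "r1", "a2", "r2", "a3", "r3", "a4", "r4")
  expect_equal(back$restraints[cols], rs$restraints[cols],
               ignore_attr = TRUE)
  expect_equal(back$restraints$x0, rs$restraints$x0, tolerance = 1e-6)
  expect_equal(back$restraints$angle, rs$restraints$angle)
  expect_identical(write_rosetta_constraints(back),
                   write_rosetta_constraints(rs))
  expect_error(parse_rosetta_constraints("Atom 1 2 3"), "not a Dihedral")
})

test_that("sigma is floored to avoid zero-width restraints", {
  prof <- bulged
  prof$summaries$phi_sd[1] <- 0
  rs <- derive_restraints(prof, start = 100, length = 16, min_sigma = 1)
  expect_equal(rs$restraints$sigma[1], pi / 180, tolerance = 1e-12)
})

test_that("the penalty is zero at the target, unit at one sigma, and circular", {
  rs <- derive_restraints(bulged, start = 100, length = 16)
  at_means <- torso_angle_table(
    torso_dihedrals(mean_fragment(bulged)), start = 100, length = 16)
  expect_equal(restraint_penalty(rs, at_means), 0, tolerance = 1e-12)
  # one angle off by exactly one sigma -> penalty 1
  off <- at_means
  k <- which(off$residue == 100 & off$angle == "phi")
  off$value[k] <- off$value[k] + bulged$summaries$phi_sd[1]
  expect_equal(restraint_penalty(rs, off), 1, tolerance = 1e-9)
  # antipodal deviations are identical by wrap symmetry
  plus <- at_means; plus$value[k] <- wrap180(plus$value[k] + 180)
  minus <- at_means; minus$value[k] <- wrap180(minus$value[k] - 180)
  expect_equal(restraint_penalty(rs, plus), restraint_penalty(rs, minus),
               tolerance = 1e-9)
  # missing angle -> informative error
  gone <- at_means[-k, ]
  expect_error(restraint_penalty(rs, gone), "phi\\(100\\)")
})

test_that("the penalty is continuous across the branch cut", {
  rs <- derive_restraints(bulged, start = 2, length = 16)
  rs$restraints <- rs$restraints[rs$restraints$position == "T1" &
                                 rs$restraints$angle == "phi", ]
  base <- torso_angle_table(torso_dihedrals(mean_fragment(bulged)),
                            start = 2, length = 16)
  k <- which(base$residue == 2 & base$angle == "phi")
  grid <- seq(179.9, 180.1, by = 0.002)
  pen <- vapply(c(grid, -grid), function(v) {
    m <- base; m$value[k] <- wrap180(v)
    restraint_penalty(rs, m)
  }, numeric(1))
  expect_lt(max(abs(diff(pen[seq_along(grid)]))), 0.05)
  expect_true(all(is.finite(pen)))
})

test_that("bulged restraints penalize non-bulged torsos more", {
  nonbulged <- reference_torso_profile("non-bulged")
  rs <- derive_restraints(bulged, start = 2, length = 16)
  pen_of <- function(frags) vapply(frags, function(f)
    restraint_penalty(rs, torso_angle_table(torso_dihedrals(f),
                                            start = 2, length = 16)),
    numeric(1))
  pb <- pen_of(sample_class_torsos(bulged, n = 60, seed = 5))
  pn <- pen_of(sample_class_torsos(nonbulged, n = 60, seed = 6))
  expect_lt(stats::median(pb), stats::median(pn))
  expect_lt(stats::wilcox.test(pb, pn, alternative = "less")$p.value, 1e-6)
})
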