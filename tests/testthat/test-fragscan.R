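# Fragment docking score aggregation, core-region calling, pose
# classification, backend contract.

NLS1 <- peptide_sequence("AKKKSTGSSTWPLDPGVEVTLTMKVAS", 58, "acetyl",
                         "amide")

test_that("per-residue aggregation equals brute-force window membership", {
  frags <- make_fragments(NLS1)
  scores <- c(-6, -6, -6, -7, -8, -8, -7, -6, -6, -6, -6)
  prof <- aggregate_per_residue(fragment_scores(frags, scores))
  expect_equal(prof$residue_number, 58:84)
  brute <- oracle_residue_means(frags$start_number, 7L, scores, 58:84)
  expect_equal(prof$mean_score, brute)
  # random scores on random fragmentations
  set.seed(13)
  for (i in 1:10) {
    L <- sample(10:30, 1); W <- sample(3:7, 1); S <- sample(1:3, 1)
    if (W > L) next
    s <- paste(sample(names(bindlab:::AA_AVERAGE_MASS), L, TRUE),
               collapse = "")
    p <- peptide_sequence(s, start_number = sample(1:500, 1))
    fr <- suppressWarnings(make_fragments(p, W, S))
    sc <- rnorm(nrow(fr), -7)
    prof_i <- aggregate_per_residue(fragment_scores(fr, sc))
    brute_i <- oracle_residue_means(fr$start_number, W, sc,
                                    prof_i$residue_number)
    expect_equal(prof_i$mean_score, brute_i)
  }
})

test_that("uniform scores give a uniform profile; termini are flagged", {
  frags <- make_fragments(NLS1)
  prof <- aggregate_per_residue(fragment_scores(frags, rep(-7, 11)))
  expect_true(all(prof$mean_score == -7))
  # window 7 / step 2: interior residues covered by 4 fragments, chain ends
  # by exactly 1
  expect_equal(max(prof$n_fragments), 4L)
  expect_equal(prof$n_fragments[1], 1L)
  expect_equal(prof$n_fragments[nrow(prof)], 1L)
  expect_true(prof$terminal_flag[1])
  expect_false(prof$terminal_flag[prof$residue_number == 70])
})

test_that("a single scored fragment scores exactly its own residues", {
  p <- peptide_sequence("AKKKSTG", 58)
  fr <- make_fragments(p, 7, 2)
  prof <- aggregate_per_residue(fragment_scores(fr, -6.5))
  expect_equal(prof$residue_number, 58:64)
  expect_true(all(prof$mean_score == -6.5))
})

test_that("fragments that are not windows of the parent are rejected", {
  frags <- make_fragments(NLS1)
  bad <- as.data.frame(frags)
  bad$sequence[3] <- "WWWWWWW"
  bad$score_kcal_mol <- rep(-7, nrow(bad))
  class(bad) <- c("fragment_scores", "data.frame")
  attr(bad, "parent") <- NLS1
  expect_error(aggregate_per_residue(bad), "not a window")
})

test_that("core region call finds a parabolic dip and respects the margin", {
  sim <- gen_affinity_landscape(noise_sd = 0, core_center = 68, seed = 1)
  prof <- aggregate_per_residue(sim$scores)
  core <- call_core_region(prof)
  expect_true(core$start <= 68 && 68 <= core$end)
  # the called region is a compact window around the dip
  expect_lte(core$end - core$start + 1, 11)
  expect_gte(core$end - core$start + 1, 3)
})

test_that("core region call is shift-invariant and renumbering-equivariant", {
  sim <- gen_affinity_landscape(noise_sd = 0.1, seed = 5)
  prof <- aggregate_per_residue(sim$scores)
  core <- call_core_region(prof)
  # adding a constant changes nothing
  prof2 <- prof
  prof2$mean_score <- prof$mean_score + 3.7
  core2 <- call_core_region(prof2)
  expect_equal(c(core2$start, core2$end), c(core$start, core$end))
  # renumbering the parent shifts the call by the same offset
  sim3 <- gen_affinity_landscape(noise_sd = 0.1, seed = 5,
                                 start_number = 158L, core_center = 168L)
  core3 <- call_core_region(aggregate_per_residue(sim3$scores))
  expect_equal(c(core3$start, core3$end) - 100L,
               c(core$start, core$end))
})

test_that("flat and terminus-clipped profiles are handled", {
  frags <- make_fragments(NLS1)
  flat <- aggregate_per_residue(fragment_scores(frags, rep(-7, 11)))
  expect_warning(core <- call_core_region(flat), "degenerate")
  expect_true(core$degenerate)
  # minimum at the N-terminal fragment: region clipped at the terminus
  scores <- seq(-8, -6, length.out = 11)
  prof <- aggregate_per_residue(fragment_scores(frags, scores))
  expect_message(core2 <- call_core_region(prof), "terminus")
  expect_equal(core2$start, 58)
  expect_true(core2$clipped)
})

test_that("pose classification uses minimum backbone distance to references", {
  ref <- matrix(rnorm(30, sd = 5), ncol = 3)
  # identical pose: major at distance zero
  hit <- classify_pose_site(ref, major_ref = ref)
  expect_equal(hit$site, "major")
  expect_equal(hit$distance, 0)
  # pose translated far away: other
  far <- classify_pose_site(ref + 100, major_ref = ref)
  expect_equal(far$site, "other")
  expect_gt(far$distance, 5)
  # pose jittered within 3 A: major
  near <- classify_pose_site(ref + matrix(runif(30, -1, 1), ncol = 3),
                             major_ref = ref)
  expect_equal(near$site, "major")
  # closer to the minor reference: minor
  minor <- classify_pose_site(ref + 100,
                              major_ref = ref, minor_ref = ref + 100)
  expect_equal(minor$site, "minor")
  expect_warning(none <- classify_pose_site(ref), "other")
  expect_equal(none$site, "other")
})

test_that("backend adapter builds profiles and honors its cache", {
  frags <- make_fragments(NLS1)
  calls <- new.env(); calls$n <- 0L
  mock <- function(fragment_row, config) {
    calls$n <- calls$n + 1L
    list(score = -6 - 0.1 * fragment_row$fragment_id)
  }
  cfg <- docking_config()
  cache <- tempfile(fileext = ".csv")
  sc <- run_backend(frags, cfg, backend = mock, cache_path = cache)
  expect_equal(calls$n, 11L)
  expect_s3_class(aggregate_per_residue(sc), "residue_affinity_profile")
  # cached: backend not invoked again, identical scores
  sc2 <- run_backend(frags, cfg, backend = mock, cache_path = cache)
  expect_equal(calls$n, 11L)
  expect_equal(sc2$score_kcal_mol, sc$score_kcal_mol)
  expect_error(docking_config(box_size = c(-1, 9, 9)), "positive")
})
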