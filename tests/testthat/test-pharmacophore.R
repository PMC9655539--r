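test_that("feature perception follows the structural definitions", {
  path <- write_pose_sdf(benzene_molfile(), ethanol_molfile(),
                         piperazinium_molfile())
  poses <- read_poses(path)

  benz <- perceive_features(poses[[1]])
  expect_equal(benz$feature_type, "aromatic_hydrophobic")
  expect_equal(c(benz$x, benz$y, benz$z), c(0, 0, 0), tolerance = 1e-6)

  eth <- perceive_features(poses[[2]])
  expect_setequal(eth$feature_type, c("hbond_donor", "hbond_acceptor"))
  # both features sit on the oxygen
  expect_equal(unique(eth$x), 2.2)
  expect_equal(unique(eth$y), 1.2)

  pipz <- perceive_features(poses[[3]])
  # protonated N: positive_ionizable at that nitrogen, not a donor/acceptor
  pi_feat <- pipz[pipz$feature_type == "positive_ionizable", ]
  expect_equal(nrow(pi_feat), 1L)
  expect_equal(c(pi_feat$x, pi_feat$y), c(0, 0))
  # the neutral ring nitrogen (no explicit H) remains an acceptor
  expect_true("hbond_acceptor" %in% pipz$feature_type)
  expect_false("hbond_donor" %in% pipz$feature_type)

  expect_error(perceive_features(list()), "no pose")
})

test_that("consensus building recovers archetypes and handles boundaries", {
  arch <- archetype_features()
  # N identical copies: consensus equals the archetype with full support
  sets <- generate_pose_features(8, arch, jitter_sd = 0, seed = 2)
  m <- build_consensus(sets)
  expect_equal(nrow(m$features), 3L)
  expect_equal(m$features$support, rep(8L, 3))
  got <- m$features[order(match(m$features$feature_type, arch$feature_type)), ]
  expect_equal(got$x, arch$x, tolerance = 1e-12)
  expect_equal(got$y, arch$y, tolerance = 1e-12)

  # two ligands 1.0 A apart: one merged feature at the midpoint, support 2
  s2 <- list(L1 = data.frame(feature_type = "hbond_donor", x = 0, y = 0, z = 0),
             L2 = data.frame(feature_type = "hbond_donor", x = 1, y = 0, z = 0))
  f2 <- build_consensus(s2)$features
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$x, 0.5)
  expect_equal(f2$support, 2L)

  # 2.0 A apart: two singleton clusters, each 1/2 = 50% => both retained
  s3 <- list(L1 = data.frame(feature_type = "hbond_donor", x = 0, y = 0, z = 0),
             L2 = data.frame(feature_type = "hbond_donor", x = 2, y = 0, z = 0))
  f3 <- build_consensus(s3, support_threshold = 0.5)$features
  expect_equal(nrow(f3), 2L)
  expect_equal(f3$support, c(1L, 1L))
  # ... and a stricter threshold drops both (support monotonicity)
  expect_equal(nrow(build_consensus(s3, support_threshold = 0.6)$features), 0L)

  expect_error(build_consensus(list()), "empty input")
})

test_that("cluster members always lie within tolerance of the final centroid", {
  arch <- archetype_features()
  set.seed(33)
  for (jit in c(0.2, 0.5)) {
    sets <- generate_pose_features(12, arch, jitter_sd = jit,
                                   seed = round(jit * 100))
    m <- build_consensus(sets)
    pool <- do.call(rbind, sets)
    for (i in seq_len(nrow(m$features))) {
      f <- m$features[i, ]
      same <- pool[pool$feature_type == f$feature_type, ]
      d <- sqrt((same$x - f$x)^2 + (same$y - f$y)^2 + (same$z - f$z)^2)
      # at least `support` same-type points within tolerance of centroid
      expect_true(sum(d <= m$tolerance_A) >= f$support)
    }
  }
})

test_that("match-all rule is self-consistent and tolerance-monotone", {
  arch <- archetype_features()
  sets <- generate_pose_features(6, arch, jitter_sd = 0.3, seed = 41)
  m <- build_consensus(sets)
  # every seeding ligand matches its own model (0.3 << 1.45 regime)
  expect_true(all(vapply(sets, match_all_features, TRUE, model = m)))
  # removing a required feature breaks the match
  crippled <- sets[[1]][-1, ]
  expect_false(match_all_features(crippled, m))
  # increasing tolerance never turns a match into a non-match
  for (lig in sets) {
    tols <- c(0.5, 1.0, 1.45, 2.5)
    ok <- vapply(tols, function(t) match_all_features(lig, m, t), TRUE)
    expect_true(all(diff(ok) >= 0))
  }
  # hbond_either in a model is satisfied by a donor or an acceptor
  me <- m
  me$features$feature_type[me$features$feature_type == "hbond_donor"] <-
    "hbond_either"
  expect_true(all(vapply(sets, match_all_features, TRUE, model = me)))
})

test_that("multi-target filter keeps only compounds matching all models", {
  arch <- archetype_features()
  targets <- c("AChE", "HDAC2", "MAOB")
  sets <- lapply(targets, function(t)
    generate_pose_features(5, arch, jitter_sd = 0.2,
                           seed = match(t, targets)))
  names(sets) <- targets
  for (t in targets) names(sets[[t]]) <- paste0("c", 1:5)
  models <- lapply(targets, function(t)
    build_consensus(sets[[t]], target = t))
  names(models) <- targets
  res <- multi_target_pharmacophore_filter(sets, models)
  expect_setequal(res$kept, paste0("c", 1:5))

  # break compound c3 on one target only: it must drop out
  sets$HDAC2$c3 <- sets$HDAC2$c3[-1, ]
  res2 <- multi_target_pharmacophore_filter(sets, models)
  expect_setequal(res2$kept, paste0("c", c(1, 2, 4, 5)))
  expect_match(res2$removed$reason, "HDAC2")

  # a compound with no pose for one target is removed, with reason
  sets$MAOB$c1 <- NULL
  res3 <- multi_target_pharmacophore_filter(sets, models)
  expect_false("c1" %in% res3$kept)
  expect_match(res3$removed$reason[res3$removed$compound_id == "c1"],
               "no_pose")
})
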