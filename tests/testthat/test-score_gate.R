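test_that("thresholds equal the best (most negative) reference pose score", {
  # flexible re-docking profile spanning -8.52 .. -6.29 => threshold -8.52
  prof <- reference_profile("AChE", "flexible",
                            c(-8.52, -7.9, -7.4, -7.0, -6.29))
  expect_equal(derive_threshold(prof), -8.52)
  expect_equal(derive_threshold(-5.5), -5.5)  # single-score profile
  expect_error(derive_threshold(numeric()), "empty")
  # brute-force minimum oracle on random profiles
  set.seed(101)
  for (i in 1:20) {
    scores <- round(rnorm(10, -10, 2), 3)
    oracle <- Reduce(function(a, b) if (b < a) b else a, scores)
    expect_equal(derive_threshold(scores), oracle)
  }
})

test_that("bundled reference thresholds match the re-docking ranges", {
  expect_equal(reference_thresholds("flexible"),
               c(AChE = -8.52, HDAC2 = -7.68, MAOB = -8.34))
  expect_equal(reference_thresholds("rigid"),
               c(AChE = -14.71, HDAC2 = -13.01, MAOB = -13.56))
})

test_that("closed-interval overlap matches the binding-site compatibility calls", {
  # safinamide cross-docked in HDAC2 (rigid) vs the HDAC2 reference range
  expect_true(ranges_overlap(score_interval(-11.72, -10.42),
                             score_interval(-13.01, -11.30)))
  expect_false(ranges_overlap(score_interval(-5, -4), score_interval(-3, -2)))
  # touching endpoints count as overlap (closed intervals)
  expect_true(ranges_overlap(score_interval(-5, -4), score_interval(-4, -3)))
  expect_error(score_interval(-4, -5), "invalid interval")
  # symmetry on random interval pairs
  set.seed(7)
  for (i in 1:50) {
    a <- score_interval(min(x <- rnorm(2)), max(x))
    b <- score_interval(min(y <- rnorm(2)), max(y))
    expect_identical(ranges_overlap(a, b), ranges_overlap(b, a))
  }
  # under the flexible protocol every cross-docking range overlaps the
  # target's own re-docking range (full binding-site compatibility)
  rr <- reference_score_ranges()
  flex <- rr[rr$protocol == "flexible", ]
  for (tg in unique(flex$target)) {
    ref <- flex[flex$target == tg & flex$is_reference, ]
    for (i in which(flex$target == tg & !flex$is_reference)) {
      expect_true(ranges_overlap(
        score_interval(flex$score_low[i], flex$score_high[i]),
        score_interval(ref$score_low, ref$score_high)))
    }
  }
})

test_that("triple-activity filter keeps exactly the all-target beaters", {
  thr <- c(AChE = -8.52, HDAC2 = -7.68, MAOB = -8.34)
  sc <- data.frame(
    compound_id = rep(c("good", "edge", "onefail"), each = 3),
    target = rep(names(thr), 3),
    flexible_score = c(-20, -20, -20,     # well below all thresholds
                       -8.52, -9, -9,     # exactly at the AChE threshold
                       -9, -7.0, -9))     # fails HDAC2
  res <- triple_activity_filter(sc, thr, protocol = "flexible")
  expect_equal(res$kept, "good")
  expect_equal(sort(res$removed$compound_id), c("edge", "onefail"))
  expect_equal(res$removed$failed_targets[res$removed$compound_id == "edge"],
               "AChE")  # boundary score is removed: strict inequality

  # a compound missing a target score is excluded and logged, not dropped
  sc2 <- sc[-2, ]
  res2 <- triple_activity_filter(sc2, thr, protocol = "flexible")
  expect_false("good" %in% res2$kept)
  expect_equal(res2$removed$reason[res2$removed$compound_id == "good"],
               "missing_target_score")
})

test_that("filter equals exhaustive per-compound evaluation at scale", {
  lib <- generate_library(sim_params(n_compounds = 10000, seed = 17))
  thr <- lib$params$thresholds$rigid
  res <- triple_activity_filter(lib$scores, thr, protocol = "rigid")
  # independent oracle: plain per-compound evaluation of the score table
  byid <- split(lib$scores[, c("target", "rigid_score")],
                lib$scores$compound_id)
  oracle <- vapply(byid, function(rows) {
    all(names(thr) %in% rows$target) &&
      all(rows$rigid_score[match(names(thr), rows$target)] < thr)
  }, logical(1))
  expect_setequal(res$kept, names(oracle)[oracle])
  expect_equal(length(res$kept) + nrow(res$removed), 10000L)
  expect_true(all(lib$planted %in% res$kept))
})

test_that("score gating is monotone in thresholds and idempotent", {
  lib <- generate_library(sim_params(n_compounds = 800, seed = 23))
  thr <- lib$params$thresholds$flexible
  res <- triple_activity_filter(lib$scores, thr, protocol = "flexible")
  loose <- triple_activity_filter(lib$scores, thr + 1.5, protocol = "flexible")
  expect_true(all(res$kept %in% loose$kept))  # loosening never shrinks
  again <- triple_activity_filter(
    lib$scores[lib$scores$compound_id %in% res$kept, ], thr,
    protocol = "flexible")
  expect_identical(again$kept, res$kept)      # idempotence
  expect_equal(nrow(again$removed), 0L)
})
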