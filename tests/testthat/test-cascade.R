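test_that("bundled hit set passes the affinity stage 16 in, 16 out", {
  fx <- hit_fixture()
  scores <- data.frame(compound_id = fx$affinities$compound_id,
                       target = fx$affinities$target,
                       rigid_score = NA_real_, flexible_score = NA_real_,
                       ki_lower_nM = fx$affinities$ki_nM,
                       ki_upper_nM = fx$affinities$ki_nM)
  rep <- run_cascade(cascade_config(fx$records, scores,
                                    stages = "affinity_gate"))
  expect_equal(rep$stages$n_in, 16L)
  expect_equal(rep$stages$n_out, 16L)
  expect_equal(rep$hits$rank, 1:16)
})

test_that("bundled BBB labels pass the consensus stage 4 in, 3 out", {
  recs <- hit_fixture()$records
  four <- recs[recs$compound_id %in% bbb_fixture()$name, ]
  rep <- run_cascade(cascade_config(four, stages = "bbb",
                                    bbb_labels = bbb_fixture_labels()))
  expect_equal(rep$stages$n_in, 4L)
  expect_equal(rep$stages$n_out, 3L)
  expect_equal(rep$removals$compound_id, "Asinex BAS 07211091")
  expect_equal(rep$removals$reason, "bbb_non_penetrant")
})

test_that("stage counts are non-increasing and removals sum to library size", {
  lib <- generate_library(sim_params(n_compounds = 600, seed = 29,
                                     q_pains = 0.1))
  cfg <- cascade_config(lib$library, lib$scores,
                        stages = c("score_gate_rigid", "score_gate_flexible",
                                   "substructure", "affinity_gate"))
  rep <- run_cascade(cfg)
  expect_true(all(rep$stages$n_out <= rep$stages$n_in))
  # chaining: stage k+1 sees exactly stage k's survivors
  expect_equal(rep$stages$n_in[-1], head(rep$stages$n_out, -1))
  # attribution: every removal in exactly one stage, all accounted for
  expect_equal(nrow(rep$removals) + nrow(rep$hits), 600L)
  expect_false(anyDuplicated(rep$removals$compound_id) > 0)
  # planted actives are clean by construction and survive everything
  expect_setequal(rep$hits$compound_id, lib$planted)
})

test_that("the full cascade including pharmacophore, BBB and toxicity runs end to end", {
  lib <- generate_library(sim_params(n_compounds = 400, seed = 57))
  arch <- archetype_features()
  targets <- unique(lib$scores$target)
  # survivors of the affinity stages are known planted ids; give every
  # planted compound a pose per target, with one compound degraded
  pre <- run_cascade(cascade_config(lib$library, lib$scores,
                                    stages = c("score_gate_rigid",
                                               "score_gate_flexible",
                                               "substructure",
                                               "affinity_gate")))
  ids <- pre$hits$compound_id
  expect_gt(length(ids), 2)
  pose_features <- lapply(seq_along(targets), function(i) {
    sets <- generate_pose_features(length(ids), arch, jitter_sd = 0.25,
                                   seed = 100 + i)
    names(sets) <- ids
    sets
  })
  names(pose_features) <- targets
  pose_features[[1]][[ids[1]]] <-
    pose_features[[1]][[ids[1]]][-1, ]  # strip a required feature
  bbb <- data.frame(compound_id = rep(ids, 2),
                    model = rep(c("m1", "m2"), each = length(ids)),
                    label = "penetrant", stringsAsFactors = FALSE)
  bbb$label[bbb$compound_id == ids[2]] <- "weak_penetrant"
  tox <- data.frame(compound_id = ids[3], endpoint = "hepatotoxicity",
                    likelihood = "plausible")

  rep <- run_cascade(cascade_config(
    lib$library, lib$scores, pose_features = pose_features,
    bbb_labels = bbb, tox_annotations = tox))
  expect_equal(rep$stages$stage[1], "score_gate_rigid")
  # compound 1 lost at pharmacophore, compound 2 at BBB; compound 3 is
  # flagged but retained (annotate action)
  expect_false(ids[1] %in% rep$hits$compound_id)
  expect_false(ids[2] %in% rep$hits$compound_id)
  expect_true(ids[3] %in% rep$hits$compound_id)
  expect_equal(rep$flagged, ids[3])
  expect_equal(nrow(rep$removals) + nrow(rep$hits), 400L)
  ph <- rep$removals[rep$removals$stage == "pharmacophore", ]
  expect_equal(ph$compound_id, ids[1])
  # final hits keep their affinity ranking order
  expect_equal(rep$hits$rank, seq_len(nrow(rep$hits)))
})

test_that("identical config and seed give byte-identical outputs", {
  run_once <- function() {
    lib <- generate_library(sim_params(n_compounds = 300, seed = 77,
                                       q_pains = 0.08))
    rep <- run_cascade(cascade_config(lib$library, lib$scores,
                                      stages = c("score_gate_rigid",
                                                 "score_gate_flexible",
                                                 "substructure",
                                                 "affinity_gate"),
                                      seed = 77))
    path <- tempfile(fileext = ".csv")
    write.csv(rep$hits, path, row.names = FALSE)
    path
  }
  p1 <- run_once(); p2 <- run_once()
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("misconfigured cascades abort before any stage runs", {
  lib <- generate_library(sim_params(n_compounds = 10, seed = 1))
  expect_error(cascade_config(lib$library, scores = NULL,
                              stages = "score_gate_rigid"),
               "score_gate_rigid")
  expect_error(cascade_config(lib$library, stages = "pharmacophore"),
               "pharmacophore")
  expect_error(cascade_config(lib$library, stages = "bbb"), "bbb")
  expect_error(cascade_config(lib$library, stages = "warp_drive"),
               "unknown stage")
})

test_that("reports serialize to text and csv", {
  lib <- generate_library(sim_params(n_compounds = 120, seed = 8))
  rep <- run_cascade(cascade_config(lib$library, lib$scores,
                                    stages = c("score_gate_rigid",
                                               "affinity_gate")))
  txt <- tempfile(fileext = ".txt")
  write_report(rep, txt, format = "text")
  expect_true(any(grepl("score_gate_rigid", readLines(txt))))
  csv <- tempfile(fileext = ".csv")
  write_report(rep, csv, format = "csv")
  stages <- read.csv(csv)
  expect_equal(stages$n_in, rep$stages$n_in)
  expect_true(file.exists(sub("\\.csv$", "_removals.csv", csv)))
})

test_that("stage subcommands compose via files to the same final table", {
  cli <- system.file("scripts", "mtscreen-cli.R", package = "mtscreen")
  expect_true(nzchar(cli))
  dir <- tempfile("cli"); dir.create(dir)
  lib <- generate_library(sim_params(n_compounds = 150, seed = 91,
                                     q_pains = 0.1))
  write_library(lib, dir)
  library_csv <- file.path(dir, "library.csv")
  scores_csv <- file.path(dir, "scores.csv")

  # direct: one run_cascade over the same files (the grammar produces
  # duplicate structures at this size; ingest collapses them, warning)
  lib_in <- suppressWarnings(read_molecule_table(library_csv))
  sc_in <- read_score_table(scores_csv)
  direct <- run_cascade(cascade_config(lib_in, sc_in,
                                       stages = c("score_gate_rigid",
                                                  "score_gate_flexible",
                                                  "substructure",
                                                  "affinity_gate")))
  direct_csv <- file.path(dir, "direct.csv")
  write.csv(direct$hits, direct_csv, row.names = FALSE)

  # chained: the same stages as subcommands over intermediate files
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run_cli <- function(...) {
    status <- system2(rscript, c(cli, ...), env = env,
                      stdout = FALSE, stderr = FALSE)
    expect_equal(status, 0L)
  }
  s1 <- file.path(dir, "s1.csv"); s2 <- file.path(dir, "s2.csv")
  s3 <- file.path(dir, "s3.csv"); final <- file.path(dir, "final.csv")
  log <- file.path(dir, "stages.csv")
  run_cli("score-gate", "--library", library_csv, "--scores", scores_csv,
          "--protocol", "rigid", "--out", s1, "--log", log)
  run_cli("score-gate", "--library", s1, "--scores", scores_csv,
          "--protocol", "flexible", "--out", s2, "--log", log)
  run_cli("substructure", "--library", s2, "--out", s3, "--log", log)
  run_cli("rank", "--library", s3, "--scores", scores_csv,
          "--out", final, "--log", log)
  expect_identical(unname(tools::md5sum(final)),
                   unname(tools::md5sum(direct_csv)))
  stage_log <- read.csv(log)
  expect_equal(stage_log$n_in, direct$stages$n_in)
  expect_equal(stage_log$n_out, direct$stages$n_out)

  # report subcommand renders the accumulated log
  rpt <- file.path(dir, "report.txt")
  run_cli("report", "--log", log, "--out", rpt)
  expect_true(any(grepl("substructure", readLines(rpt))))
})
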