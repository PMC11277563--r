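# Synthetic-data generator: determinism, planted-signal separation,
# and recovery metrics.

sim_panel <- function() builtin_panels()$early_invasion_up

test_that("simulation is a pure function of its seed", {
  cfg <- simulation_config(60, sim_panel(), seed = 99)
  a <- simulate_truth(cfg)
  b <- simulate_truth(cfg)
  expect_identical(a$interactions, b$interactions)
  expect_identical(as.data.frame(a$dysregulation),
                   as.data.frame(b$dysregulation))
  expect_identical(a$truth, b$truth)
  c <- simulate_truth(simulation_config(60, sim_panel(), seed = 100))
  expect_false(identical(a$interactions, c$interactions))
})

test_that("simulate_truth does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- stats::runif(1)
  set.seed(7)
  invisible(simulate_truth(simulation_config(30, sim_panel(), seed = 1)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("infeasible configs are rejected", {
  expect_error(simulation_config(10, sim_panel(), n_planted = 6,
                                 n_decoy_score = 3, n_decoy_direction = 3),
               "exceeds n_mirnas")
  expect_error(simulation_config(30, sim_panel(), edge_probability = 1.5),
               "edge_probability")
  expect_error(simulation_config(30, sim_panel(),
                                 rule = threshold_rule(1, strict = TRUE)),
               "no miRNA can pass")
})

test_that("a null world yields an empty candidate set downstream", {
  cfg <- simulation_config(20, sim_panel(), edge_probability = 0,
                           n_planted = 0, n_decoy_score = 0,
                           n_decoy_direction = 0, seed = 3)
  truth <- simulate_truth(cfg)
  res <- run_stage(truth$panel$stage, list(truth$panel),
                   truth$interactions, truth$dysregulation)
  expect_identical(nrow(res$candidates), 0L)
})

test_that("the pipeline recovers exactly the planted miRNAs", {
  cfg <- simulation_config(100, sim_panel(), n_planted = 5,
                           n_decoy_score = 5, n_decoy_direction = 5,
                           seed = 2024)
  truth <- simulate_truth(cfg)
  res <- run_stage(truth$panel$stage, list(truth$panel),
                   truth$interactions, truth$dysregulation)
  planted <- truth$truth$mirna_id[truth$truth$role == "planted"]
  expect_setequal(candidate_mirnas(res, "DOWN"), planted)
  m <- recovery_metrics(res, truth)
  expect_identical(m$precision, 1)
  expect_identical(m$recall, 1)
})

test_that("planted coverage is exactly k and direction decoys sit at k-1", {
  truth <- simulate_truth(simulation_config(40, sim_panel(), seed = 8))
  net <- panel_subnetwork(truth$interactions, truth$panel)
  for (role in c("planted", "decoy_score", "decoy_direction")) {
    ids <- truth$truth$mirna_id[truth$truth$role == role]
    counts <- vapply(ids, function(m) {
      compute_target_score(net, m)$count
    }, integer(1))
    expected <- if (role == "decoy_direction") truth$k - 1L else truth$k
    expect_true(all(counts == expected))
  }
})

test_that("recovery metric degenerate cases", {
  truth <- simulate_truth(simulation_config(30, sim_panel(), seed = 4))
  res <- run_stage(truth$panel$stage, list(truth$panel),
                   truth$interactions, truth$dysregulation)
  # strip all evidence: no candidates, recall 0, precision defined as 1
  empty_db <- dysregulation_db(data.frame(
    mirna_id = "miR-9999-5p", direction = "up", source = "blood",
    reference = "r"))
  res0 <- run_stage(truth$panel$stage, list(truth$panel),
                    truth$interactions, empty_db)
  m0 <- recovery_metrics(res0, truth)
  expect_identical(m0$recall, 0)
  expect_identical(m0$precision, 1)
  m1 <- recovery_metrics(res, truth)
  expect_identical(m1$precision, 1)
  expect_identical(m1$recall, 1)
})

test_that("simulated files round trip through the pipeline readers", {
  truth <- simulate_truth(simulation_config(25, sim_panel(), seed = 12))
  dir <- withr::local_tempdir()
  paths <- simulate_to_files(truth, dir)
  expect_true(all(file.exists(paths)))
  tab <- load_interactions(paths[["interactions"]], quiet = TRUE)
  db <- load_dysregulation(paths[["dysregulation"]], quiet = TRUE)
  panels <- load_panels(paths[["panels"]])
  expect_identical(as.data.frame(tab), as.data.frame(truth$interactions))
  expect_identical(as.data.frame(db), as.data.frame(truth$dysregulation))
  expect_identical(panels[[1]]$genes, truth$panel$genes)
  labels <- utils::read.delim(paths[["truth"]])
  expect_identical(nrow(labels), 25L)
})
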