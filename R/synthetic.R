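# Synthetic bipartite interaction networks and dysregulation tables
# with planted true candidates and two decoy classes, for
# download-free testing and planted-signal recovery checks.

#' Configuration for a synthetic network simulation
#'
#' The generated world contains four miRNA classes against one stage
#' panel: `planted` true candidates (coverage at the threshold count
#' and reverse-direction tissue/saliva evidence), `decoy_score`
#' (threshold-passing coverage but wrong-direction or absent
#' evidence), `decoy_direction` (correct evidence but coverage one
#' below threshold), and background miRNAs whose edges to panel genes
#' are independent Bernoulli draws with `edge_probability` and who
#' carry no dysregulation records.
#'
#' @param n_mirnas Total miRNAs.
#' @param panel A [stage_panel()] the simulation is built around.
#' @param n_background_genes Extra non-panel genes receiving random
#'   edges (noise in the table; never affects panel coverage).
#' @param edge_probability Bernoulli probability of each background
#'   miRNA-gene edge, in \[0, 1\].
#' @param n_planted,n_decoy_score,n_decoy_direction Class sizes; their
#'   sum must not exceed `n_mirnas`.
#' @param rule [threshold_rule()] defining the threshold count.
#' @param seed Integer RNG seed; the simulation is a pure function of
#'   the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_mirnas, panel, n_background_genes = 20,
                              edge_probability = 0.05, n_planted = 5,
                              n_decoy_score = 5, n_decoy_direction = 5,
                              rule = threshold_rule(), seed = 1) {
  stopifnot(inherits(panel, "stage_panel"), inherits(rule, "threshold_rule"))
  counts <- c(n_mirnas, n_background_genes, n_planted, n_decoy_score,
              n_decoy_direction)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (n_planted + n_decoy_score + n_decoy_direction > n_mirnas) {
    stop("n_planted + n_decoy_score + n_decoy_direction exceeds n_mirnas")
  }
  if (edge_probability < 0 || edge_probability > 1) {
    stop("edge_probability must be in [0, 1]")
  }
  k <- min_required_count(length(panel$genes), rule)
  if (k > length(panel$genes)) {
    stop("threshold count ", k, " exceeds panel size; no miRNA can pass")
  }
  structure(list(n_mirnas = n_mirnas, panel = panel,
                 n_background_genes = n_background_genes,
                 edge_probability = edge_probability,
                 n_planted = n_planted, n_decoy_score = n_decoy_score,
                 n_decoy_direction = n_decoy_direction,
                 rule = rule, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a network + evidence world with known truth
#'
#' Deterministic given the config seed. Planted and score-decoy miRNAs
#' receive exactly the threshold count of panel genes (sampled without
#' replacement); direction-decoys receive one fewer. Planted miRNAs
#' get a reverse-direction tissue/saliva record; score-decoys
#' alternate between a wrong-direction record and no record;
#' direction-decoys get a reverse-direction record. By construction
#' exactly the planted miRNAs satisfy both filters.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_truth` list: `config`, `truth` (data frame
#'   `mirna_id`, `role`), `interactions`, `dysregulation`, `panel`,
#'   `k` (threshold count).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_mirnas
  ids <- sprintf("hsa-miR-9%04d-5p", seq_len(n))
  roles <- rep("background", n)
  idx <- 0
  take <- function(count) {
    sel <- idx + seq_len(count)
    idx <<- idx + count
    sel
  }
  planted <- take(config$n_planted)
  decoy_score <- take(config$n_decoy_score)
  decoy_dir <- take(config$n_decoy_direction)
  roles[planted] <- "planted"
  roles[decoy_score] <- "decoy_score"
  roles[decoy_dir] <- "decoy_direction"

  panel_genes <- config$panel$genes
  k <- min_required_count(length(panel_genes), config$rule)
  bg_genes <- if (config$n_background_genes > 0)
    sprintf("BGGENE%03d", seq_len(config$n_background_genes)) else character(0)

  edge_mirna <- character(0)
  edge_gene <- character(0)
  add_edges <- function(m, g) {
    edge_mirna <<- c(edge_mirna, rep(m, length(g)))
    edge_gene <<- c(edge_gene, g)
  }
  for (i in seq_len(n)) {
    if (roles[i] %in% c("planted", "decoy_score")) {
      add_edges(ids[i], sample(panel_genes, k))
    } else if (roles[i] == "decoy_direction" && k > 1) {
      add_edges(ids[i], sample(panel_genes, k - 1))
    } else if (roles[i] == "background") {
      hit <- stats::runif(length(panel_genes)) < config$edge_probability
      if (any(hit)) add_edges(ids[i], panel_genes[hit])
    }
    if (length(bg_genes)) {
      hit <- stats::runif(length(bg_genes)) < config$edge_probability
      if (any(hit)) add_edges(ids[i], bg_genes[hit])
    }
  }
  if (length(edge_mirna) == 0) {
    # degenerate null world: keep the table type valid with one
    # self-documenting inert edge to a background gene
    add_edges(ids[1], "BGNULL")
  }
  interactions <- interaction_table(data.frame(
    mirna_id = edge_mirna, gene = edge_gene, source_db = "sim",
    stringsAsFactors = FALSE))

  need <- required_direction(config$panel$direction)
  wrong <- config$panel$direction
  rec <- list()
  add_rec <- function(m, d, s) {
    rec[[length(rec) + 1L]] <<- data.frame(
      mirna_id = m, direction = d, source = s, reference = "sim",
      stringsAsFactors = FALSE)
  }
  for (i in planted) add_rec(ids[i], need, sample(c("tissue", "saliva"), 1))
  for (j in seq_along(decoy_score)) {
    if (j %% 2 == 1) add_rec(ids[decoy_score[j]], wrong,
                             sample(c("tissue", "saliva"), 1))
    # even-indexed score decoys get no record at all
  }
  for (i in decoy_dir) add_rec(ids[i], need, sample(c("tissue", "saliva"), 1))
  dysregulation <- if (length(rec))
    dysregulation_db(do.call(rbind, rec))
  else dysregulation_db(data.frame(
    mirna_id = "hsa-miR-0-5p", direction = "down", source = "tissue",
    reference = "sim-placeholder"))

  structure(list(config = config,
                 truth = data.frame(mirna_id = ids, role = roles,
                                    stringsAsFactors = FALSE),
                 interactions = interactions,
                 dysregulation = dysregulation,
                 panel = config$panel, k = k),
            class = "simulated_truth")
}

#' Precision and recall of a stage result against simulated truth
#'
#' Candidates (for the simulated panel's miRNA direction) are compared
#' with the planted set. Precision with zero candidates is defined as
#' 1 (no false positives were made); recall with zero planted is 1.
#'
#' @param result A [run_stage()] result from the simulated world.
#' @param truth A [simulate_truth()] result.
#' @return List with `precision`, `recall`, `n_candidates`, `n_planted`.
#' @export
recovery_metrics <- function(result, truth) {
  stopifnot(inherits(result, "stage_result"),
            inherits(truth, "simulated_truth"))
  need <- required_direction(truth$panel$direction)
  cand <- candidate_mirnas(result, need)
  planted <- truth$truth$mirna_id[truth$truth$role == "planted"]
  tp <- length(intersect(cand, planted))
  list(
    precision = if (length(cand)) tp / length(cand) else 1,
    recall = if (length(planted)) tp / length(planted) else 1,
    n_candidates = length(cand),
    n_planted = length(planted)
  )
}

#' Write a simulated world to pipeline-readable files
#'
#' Emits the same TSV formats the main pipeline reads
#' (`interactions.tsv`, `dysregulation.tsv`), a `panels.json` config,
#' and `truth_labels.tsv`.
#'
#' @param truth A [simulate_truth()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of paths, invisibly.
#' @export
simulate_to_files <- function(truth, dir) {
  stopifnot(inherits(truth, "simulated_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(interactions = file.path(dir, "interactions.tsv"),
             dysregulation = file.path(dir, "dysregulation.tsv"),
             panels = file.path(dir, "panels.json"),
             truth = file.path(dir, "truth_labels.tsv"))
  write_interactions(truth$interactions, paths[["interactions"]])
  write_dysregulation(truth$dysregulation, paths[["dysregulation"]])
  jsonlite::write_json(
    list(list(stage = truth$panel$stage, direction = truth$panel$direction,
              genes = truth$panel$genes)),
    paths[["panels"]], auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(truth$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
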