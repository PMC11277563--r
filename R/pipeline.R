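# End-to-end pipeline runner and report writer: interactions + panels
# + dysregulation evidence in, per-stage candidate tables, network
# exports, a cross-stage comparison and a filter-chain log out.

#' Path to a packaged fixture file
#'
#' Shipped fixtures: `paper_edges.tsv` (the in-study interaction edge
#' set), `paper_directions.tsv` (dysregulation evidence for the
#' pipeline miRNAs), `table1_update.tsv` (the 2023-2024 literature
#' update records), `builtin_panels.json` (the default panel config).
#'
#' @param name Fixture file name.
#' @return Absolute path.
#' @export
stagemir_fixture <- function(name) {
  path <- system.file("extdata", name, package = "stagemiR")
  if (!nzchar(path)) stop("no packaged fixture named ", name)
  path
}

as_interactions <- function(x, quiet = TRUE) {
  if (inherits(x, "interaction_table")) x else load_interactions(x, quiet)
}

as_dysregulation <- function(x, quiet = TRUE) {
  if (inherits(x, "dysregulation_db")) x else load_dysregulation(x, quiet)
}

as_panels <- function(x) {
  if (is.character(x)) return(load_panels(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "stage_panel"))) {
    return(x)
  }
  stop("panels must be a config path or a list of stage_panel objects")
}

#' Run the full stage-specific prioritization pipeline
#'
#' Executes [run_stage()] for every stage present in the panel set (in
#' the canonical order hyperplasia, dysplasia, early invasion) and,
#' when two or more stages are available, [compare_stages()]. With
#' `out_dir` set, writes per-stage candidate/rejected TSVs, the
#' comparison report (TSV/Markdown/JSON), one GraphML export per
#' panel, and a `filter_log.tsv` recording the count at every filter
#' step. Repeated runs on the same inputs produce byte-identical
#' outputs; the pipeline contains no randomness.
#'
#' @param interactions An [interaction_table()] or TSV path.
#' @param panels A panel list ([builtin_panels()], the default) or a
#'   JSON config path.
#' @param dysregulation A [dysregulation_db()] or TSV path.
#' @param rule A [threshold_rule()].
#' @param allowed_sources Evidence sources for the direction filter.
#' @param disease_list Disease-level reference set for the comparison.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return A `stagemir_run` list: `stages` (named [run_stage()]
#'   results), `comparison` (or `NULL` for a single stage), `log`
#'   (combined filter-chain counts), and `paths` of written files.
#' @export
run_pipeline <- function(interactions = stagemir_fixture("paper_edges.tsv"),
                         panels = builtin_panels(),
                         dysregulation = stagemir_fixture("paper_directions.tsv"),
                         rule = threshold_rule(),
                         allowed_sources = c("TISSUE", "SALIVA"),
                         disease_list = disease_specific_mirnas(),
                         out_dir = NULL, quiet = FALSE) {
  table <- as_interactions(interactions, quiet = quiet)
  db <- as_dysregulation(dysregulation, quiet = quiet)
  panel_set <- as_panels(panels)
  stages <- intersect(OSCC_STAGES,
                      vapply(panel_set, function(p) p$stage, character(1)))
  if (length(stages) == 0) stop("panel set contains no known stage")

  results <- lapply(stages, run_stage, panels = panel_set, table = table,
                    db = db, rule = rule, allowed_sources = allowed_sources)
  names(results) <- stages
  log <- do.call(rbind, lapply(results, function(r) {
    cbind(data.frame(stage = r$stage, stringsAsFactors = FALSE), r$log)
  }))
  rownames(log) <- NULL
  if (!quiet) {
    for (i in seq_len(nrow(log))) {
      message(sprintf("%-25s network %4d -> score %3d -> direction %3d",
                      log$panel[i], log$n_network_mirnas[i],
                      log$n_score_pass[i], log$n_direction_pass[i]))
    }
  }
  comparison <- if (length(results) >= 2) {
    compare_stages(results, disease_list)
  } else NULL

  paths <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (st in stages) {
      base <- tolower(st)
      p1 <- file.path(out_dir, paste0(base, "_candidates.tsv"))
      p2 <- file.path(out_dir, paste0(base, "_rejected.tsv"))
      utils::write.table(results[[st]]$candidates, p1, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(results[[st]]$rejected, p2, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, p1, p2)
    }
    for (key in names(panel_set)) {
      net <- panel_subnetwork(table, panel_set[[key]])
      pg <- file.path(out_dir, paste0(key, "_network.graphml"))
      export_network(net, pg, "graphml")
      paths <- c(paths, pg)
    }
    plog <- file.path(out_dir, "filter_log.tsv")
    utils::write.table(log, plog, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, plog)
    if (!is.null(comparison)) {
      paths <- c(paths, write_comparison(comparison, out_dir))
    }
    pj <- file.path(out_dir, "stage_results.json")
    jsonlite::write_json(
      lapply(results, function(r) {
        list(stage = r$stage,
             down_candidates = candidate_mirnas(r, "DOWN"),
             up_candidates = candidate_mirnas(r, "UP"),
             rejected = sort(unique(r$rejected$mirna_id)))
      }),
      pj, auto_unbox = FALSE, pretty = TRUE)
    paths <- c(paths, pj)
  }

  structure(list(stages = results, comparison = comparison, log = log,
                 paths = paths),
            class = "stagemir_run")
}

#' @export
print.stagemir_run <- function(x, ...) {
  cat("<stagemir_run>\n")
  print(x$log, row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
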