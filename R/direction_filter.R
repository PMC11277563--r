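# The reverse-expression consistency filter: a candidate miRNA must be
# dysregulated in the direction OPPOSITE to its target panel (a
# repressor of upregulated genes should itself be down, and vice
# versa), with tissue/saliva evidence. Assembles per-stage results.

#' Direction a candidate miRNA must show, given its panel's direction
#'
#' Repression logic: genes up in a stage implicate miRNAs that are
#' down, and genes down implicate miRNAs that are up. The map is an
#' involution.
#'
#' @param panel_direction `"UP"` or `"DOWN"`.
#' @return The opposite direction.
#' @export
required_direction <- function(panel_direction) {
  panel_direction <- match_enum(panel_direction, MIRNA_DIRECTIONS, "direction")
  unname(c(UP = "DOWN", DOWN = "UP")[panel_direction])
}

#' Run the full filter chain for one stage
#'
#' For every panel of the stage: build the panel subnetwork, keep
#' miRNAs whose simultaneous coverage clears the threshold rule, then
#' require dysregulation evidence in the reverse direction within the
#' allowed sample sources. Score-passing miRNAs that fail the
#' direction check are retained in a `rejected` table with reasons, so
#' `candidates` and `rejected` partition the score-passing set.
#'
#' @param stage Stage name.
#' @param panels Named list of [stage_panel()] objects (any stages; the
#'   relevant ones are selected).
#' @param table An [interaction_table()].
#' @param db A [dysregulation_db()].
#' @param rule A [threshold_rule()].
#' @param allowed_sources Sample sources accepted as direction
#'   evidence; default tissue + saliva.
#' @return A `stage_result` list: `stage`, `candidates` (data frame
#'   with score and verdict columns), `rejected` (same shape plus
#'   `reason`), and `log` (per-panel counts along the filter chain:
#'   network miRNAs -> score-passing -> direction-passing).
#' @export
run_stage <- function(stage, panels, table, db, rule = threshold_rule(),
                      allowed_sources = c("TISSUE", "SALIVA")) {
  stage <- match_enum(stage, OSCC_STAGES, "stage")
  stage_panels <- panels_for_stage(panels, stage)
  cand_rows <- list()
  rej_rows <- list()
  log_rows <- list()
  for (panel in stage_panels) {
    net <- panel_subnetwork(table, panel)
    scored <- filter_by_score(net, rule)
    need <- required_direction(panel$direction)
    n_pass <- 0L
    for (i in seq_len(nrow(scored))) {
      verdict <- query_direction(db, scored$mirna_id[i], need,
                                 allowed_sources)
      row <- cbind(
        scored[i, , drop = FALSE],
        data.frame(
          required_mirna_direction = need,
          direction_passes = verdict$passes,
          qualifier = verdict$qualifier,
          supporting_sources = paste(verdict$supporting_sources,
                                     collapse = SOURCES_SEP),
          n_support = verdict$n_support,
          n_oppose = verdict$n_oppose,
          stringsAsFactors = FALSE
        )
      )
      if (verdict$passes) {
        n_pass <- n_pass + 1L
        cand_rows[[length(cand_rows) + 1L]] <- row
      } else {
        row$reason <- sprintf(
          "no %s evidence in allowed sources (%s)", need,
          paste(allowed_sources, collapse = "/"))
        rej_rows[[length(rej_rows) + 1L]] <- row
      }
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      panel = panel_key(panel),
      panel_size = length(panel$genes),
      min_count = min_required_count(length(panel$genes), rule),
      n_network_mirnas = length(net$mirnas),
      n_score_pass = nrow(scored),
      n_direction_pass = n_pass,
      stringsAsFactors = FALSE
    )
  }
  empty_cand <- data.frame(
    mirna_id = character(0), stage = character(0),
    panel_direction = character(0), targeted_genes = character(0),
    count = integer(0), panel_size = integer(0), fraction = numeric(0),
    percent = numeric(0), required_mirna_direction = character(0),
    direction_passes = logical(0), qualifier = character(0),
    supporting_sources = character(0), n_support = integer(0),
    n_oppose = integer(0), stringsAsFactors = FALSE)
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else empty_cand
  rejected <- if (length(rej_rows)) do.call(rbind, rej_rows) else
    cbind(empty_cand, data.frame(reason = character(0)))
  rownames(candidates) <- rownames(rejected) <- NULL
  structure(list(stage = stage, candidates = candidates,
                 rejected = rejected, log = do.call(rbind, log_rows)),
            class = "stage_result")
}

#' Candidate miRNA ids of a stage result
#'
#' Convenience accessor; `mirna_direction` filters by the miRNA's own
#' dysregulation direction (`"DOWN"` candidates come from UP panels).
#'
#' @param result A [run_stage()] result.
#' @param mirna_direction Optional `"UP"` or `"DOWN"`.
#' @return Sorted character vector of miRNA ids.
#' @export
candidate_mirnas <- function(result, mirna_direction = NULL) {
  stopifnot(inherits(result, "stage_result"))
  d <- result$candidates
  if (!is.null(mirna_direction)) {
    d <- d[d$required_mirna_direction == mirna_direction, , drop = FALSE]
  }
  sort(unique(d$mirna_id))
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("<stage_result> %s: %d candidate(s), %d rejected\n",
              x$stage, nrow(x$candidates), nrow(x$rejected)))
  print(x$log, row.names = FALSE)
  invisible(x)
}
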