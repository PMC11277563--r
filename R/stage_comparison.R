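# Cross-stage set algebra: the shared downregulated core, the sets
# that distinguish each stage from its predecessors, and the overlap
# with a disease-level (whole-OSCC) miRNA list.

#' Default disease-level miRNA list for whole-OSCC
#'
#' The five molecules previously identified as the most OSCC-specific
#' across the whole disease, with their majority dysregulation
#' direction. Used as the default reference set for the disease-level
#' overlap; override with any (miRNA, direction) table.
#'
#' @return Data frame with columns `mirna_id`, `direction`.
#' @export
disease_specific_mirnas <- function() {
  data.frame(
    mirna_id = normalize_mirna_id(c("miR-34a-5p", "miR-155-5p",
                                    "miR-124-3p", "miR-1-3p",
                                    "miR-16-5p")),
    direction = c("DOWN", "UP", "DOWN", "DOWN", "DOWN"),
    stringsAsFactors = FALSE
  )
}

#' Compare stage results along the oncogenesis sequence
#'
#' Given stage results ordered hyperplasia -> dysplasia -> early
#' invasion, computes: the shared core (miRNAs downregulated in every
#' stage); per-stage distinguishing sets (`added_down`, `added_up`:
#' candidates absent from every earlier stage with the same miRNA
#' direction; for the first stage, its down-candidates beyond the
#' shared core); `dropped_down`/`dropped_up` audit sets (present
#' earlier, absent now — empty when candidate sets are nested); and
#' the overlap of all stage candidates with a disease-level list. A
#' miRNA appearing UP in one stage and DOWN in another is tracked as
#' two distinct (miRNA, direction) elements.
#'
#' @param results List of >= 2 [run_stage()] results in stage order.
#' @param disease_list Data frame with `mirna_id`, `direction`;
#'   defaults to [disease_specific_mirnas()].
#' @return A `comparison_report` list: `stages`, `shared_core`,
#'   `distinguishing`, `disease_overlap`, and `table` (long-format
#'   per-stage candidate listing with qualifiers).
#' @export
compare_stages <- function(results, disease_list = disease_specific_mirnas()) {
  if (length(results) < 2) stop("need at least two stage results to compare")
  if (!all(vapply(results, inherits, logical(1), "stage_result"))) {
    stop("results must be a list of stage_result objects")
  }
  stages <- vapply(results, function(r) r$stage, character(1))
  if (anyDuplicated(stages)) stop("duplicate stages in results")
  down_sets <- lapply(results, candidate_mirnas, mirna_direction = "DOWN")
  up_sets <- lapply(results, candidate_mirnas, mirna_direction = "UP")
  shared_core <- Reduce(intersect, down_sets)

  distinguishing <- vector("list", length(results))
  names(distinguishing) <- stages
  for (i in seq_along(results)) {
    earlier_down <- unique(c(shared_core,
                             unlist(down_sets[seq_len(i - 1)])))
    earlier_up <- unique(unlist(up_sets[seq_len(i - 1)]))
    dropped_down <- if (i > 1)
      setdiff(unique(unlist(down_sets[seq_len(i - 1)])), down_sets[[i]])
      else character(0)
    dropped_up <- if (i > 1)
      setdiff(unique(unlist(up_sets[seq_len(i - 1)])), up_sets[[i]])
      else character(0)
    distinguishing[[i]] <- list(
      added_down = setdiff(down_sets[[i]], earlier_down),
      added_up = setdiff(up_sets[[i]], earlier_up),
      dropped_down = dropped_down,
      dropped_up = dropped_up
    )
  }

  pair_key <- function(m, d) paste(m, d, sep = "|")
  stage_pairs <- unique(unlist(lapply(results, function(r) {
    pair_key(r$candidates$mirna_id, r$candidates$required_mirna_direction)
  })))
  disease_pairs <- pair_key(normalize_mirna_id(disease_list$mirna_id),
                            match_enum(disease_list$direction,
                                       MIRNA_DIRECTIONS, "direction"))
  hit <- disease_pairs %in% stage_pairs
  disease_overlap <- data.frame(
    mirna_id = normalize_mirna_id(disease_list$mirna_id)[hit],
    direction = match_enum(disease_list$direction,
                           MIRNA_DIRECTIONS, "direction")[hit],
    stringsAsFactors = FALSE
  )

  long <- do.call(rbind, lapply(results, function(r) {
    d <- r$candidates
    data.frame(stage = r$stage, mirna_id = d$mirna_id,
               mirna_direction = d$required_mirna_direction,
               qualifier = d$qualifier, stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL

  structure(list(stages = stages, shared_core = shared_core,
                 distinguishing = distinguishing,
                 disease_overlap = disease_overlap,
                 down_sets = stats::setNames(down_sets, stages),
                 up_sets = stats::setNames(up_sets, stages),
                 table = long),
            class = "comparison_report")
}

#' Render a comparison report as Markdown
#'
#' @param report A [compare_stages()] result.
#' @return Character vector of Markdown lines.
#' @export
render_comparison_md <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  arrow <- c(DOWN = "down", UP = "up")
  lines <- c("# Stage comparison", "",
             paste0("Shared downregulated core: ",
                    paste(report$shared_core, collapse = ", ")), "")
  for (st in report$stages) {
    d <- report$table[report$table$stage == st, , drop = FALSE]
    lines <- c(lines, paste0("## ", st), "",
               "| miRNA | direction | qualifier |",
               "|---|---|---|",
               sprintf("| %s | %s | %s |", d$mirna_id,
                       arrow[d$mirna_direction], tolower(d$qualifier)),
               "")
    dist <- report$distinguishing[[st]]
    added <- c(
      if (length(dist$added_down))
        paste0(dist$added_down, " (down)"),
      if (length(dist$added_up)) paste0(dist$added_up, " (up)"))
    lines <- c(lines,
               paste0("Distinguishing additions: ",
                      if (length(added)) paste(added, collapse = ", ")
                      else "none"), "")
  }
  lines
}

#' Write a comparison report to disk
#'
#' Emits three renderings: a long-format TSV, a Markdown summary, and
#' a JSON document with the full set decomposition.
#'
#' @param report A [compare_stages()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_comparison <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tsv = file.path(dir, "stage_comparison.tsv"),
             md = file.path(dir, "stage_comparison.md"),
             json = file.path(dir, "stage_comparison.json"))
  utils::write.table(report$table, paths[["tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(render_comparison_md(report), paths[["md"]])
  jsonlite::write_json(
    list(stages = report$stages, shared_core = report$shared_core,
         distinguishing = report$distinguishing,
         disease_overlap = report$disease_overlap,
         down_sets = report$down_sets, up_sets = report$up_sets),
    paths[["json"]], auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  shared downregulated core:",
      paste(x$shared_core, collapse = ", "), "\n")
  for (st in x$stages) {
    d <- x$distinguishing[[st]]
    cat(sprintf("  %s adds: down {%s} up {%s}\n", st,
                paste(d$added_down, collapse = ", "),
                paste(d$added_up, collapse = ", ")))
  }
  invisible(x)
}
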