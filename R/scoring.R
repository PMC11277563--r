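# Target-coverage scoring: how many of a panel's genes a single miRNA
# simultaneously targets, and the strict >75% threshold that a
# stage-specific candidate must clear.

#' Threshold rule for the target-score filter
#'
#' The default rule requires a miRNA to target strictly more than 75%
#' of the panel's genes. Strictness matters: on an 8-gene panel 6/8 is
#' exactly 75% and is excluded, so the minimum passing count is 7.
#'
#' @param min_fraction Required fraction of panel genes, in (0, 1].
#' @param strict If `TRUE` (default), the coverage fraction must exceed
#'   `min_fraction`; if `FALSE`, reaching it is enough.
#' @return A `threshold_rule` list.
#' @export
threshold_rule <- function(min_fraction = 0.75, strict = TRUE) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      is.na(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be a single number in (0, 1]")
  }
  stopifnot(is.logical(strict), length(strict) == 1, !is.na(strict))
  structure(list(min_fraction = min_fraction, strict = strict),
            class = "threshold_rule")
}

#' Minimum target count needed to pass the threshold
#'
#' Smallest integer `k` with `k > min_fraction * panel_size` (strict
#' rule) or `k >= min_fraction * panel_size` (non-strict). Under the
#' default strict >75% rule this gives 7 of 8, 7 of 9, 4 of 5, 3 of 3
#' and 2 of 2.
#'
#' @param panel_size Number of genes in the panel (>= 1).
#' @param rule A [threshold_rule()].
#' @return Integer count. A strict rule with `min_fraction = 1` returns
#'   `panel_size + 1`, i.e. unsatisfiable, which is the faithful reading.
#' @export
min_required_count <- function(panel_size, rule = threshold_rule()) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (!is.numeric(panel_size) || length(panel_size) != 1 ||
      panel_size < 1 || panel_size != floor(panel_size)) {
    stop("panel_size must be a single positive integer")
  }
  target <- rule$min_fraction * panel_size
  eps <- 1e-9
  k <- if (rule$strict) floor(target + eps) + 1 else ceiling(target - eps)
  as.integer(max(k, 1))
}

#' Target score of one miRNA against a panel network
#'
#' @param net A [panel_subnetwork()] result.
#' @param mirna miRNA name (normalized internally). A miRNA absent from
#'   the network scores 0.
#' @return A `target_score` list: `mirna_id`, `stage`,
#'   `panel_direction`, `targeted_genes`, `count`, `panel_size`,
#'   `fraction` (exact), `percent` (rounded to one decimal for display).
#' @export
compute_target_score <- function(net, mirna) {
  stopifnot(inherits(net, "panel_network"))
  id <- normalize_mirna_id(mirna)
  targeted <- sort(unique(net$edges$gene[net$edges$mirna_id == id]))
  n <- length(net$panel$genes)
  score <- list(
    mirna_id = id,
    stage = net$panel$stage,
    panel_direction = net$panel$direction,
    targeted_genes = targeted,
    count = length(targeted),
    panel_size = n,
    fraction = length(targeted) / n,
    percent = round(100 * length(targeted) / n, 1)
  )
  class(score) <- "target_score"
  score
}

#' Score every miRNA in a panel network and keep threshold passers
#'
#' Computes each distinct miRNA's simultaneous coverage of the panel
#' and returns those meeting [min_required_count()], sorted by
#' descending count then miRNA id (lexicographic tie-break).
#'
#' @param net A [panel_subnetwork()] result.
#' @param rule A [threshold_rule()].
#' @return Data frame with columns `mirna_id`, `stage`,
#'   `panel_direction`, `targeted_genes` (semicolon-joined), `count`,
#'   `panel_size`, `fraction`, `percent`; zero rows when nothing passes.
#' @export
filter_by_score <- function(net, rule = threshold_rule()) {
  stopifnot(inherits(net, "panel_network"))
  k <- min_required_count(length(net$panel$genes), rule)
  scores <- score_all_mirnas(net)
  out <- scores[scores$count >= k, , drop = FALSE]
  out <- out[order(-out$count, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# coverage table for every miRNA in the network (no threshold)
score_all_mirnas <- function(net) {
  n <- length(net$panel$genes)
  if (length(net$mirnas) == 0) {
    return(data.frame(mirna_id = character(0), stage = character(0),
                      panel_direction = character(0),
                      targeted_genes = character(0),
                      count = integer(0), panel_size = integer(0),
                      fraction = numeric(0), percent = numeric(0)))
  }
  by_mirna <- split(net$edges$gene, net$edges$mirna_id)
  ids <- sort(names(by_mirna))
  genes <- lapply(by_mirna[ids], function(g) sort(unique(g)))
  counts <- lengths(genes)
  data.frame(
    mirna_id = ids,
    stage = net$panel$stage,
    panel_direction = net$panel$direction,
    targeted_genes = vapply(genes, paste, character(1), collapse = SOURCES_SEP),
    count = as.integer(counts),
    panel_size = n,
    fraction = counts / n,
    percent = round(100 * counts / n, 1),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' @export
print.target_score <- function(x, ...) {
  cat(sprintf("<target_score> %s vs %s/%s: %d/%d (%s%%) [%s]\n",
              x$mirna_id, x$stage, x$panel_direction, x$count,
              x$panel_size, format(x$percent),
              paste(x$targeted_genes, collapse = ", ")))
  invisible(x)
}
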