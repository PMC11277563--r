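# Stage-specific directional gene panels: the expression signature of
# each early histological stage of oral oncogenesis, reduced to
# direction (up/down) and human gene symbols.

OSCC_STAGES <- c("HYPERPLASIA", "DYSPLASIA", "EARLY_INVASION")

# common protein-name aliases seen in the immunohistochemistry literature
GENE_ALIASES <- c(
  "KI-67" = "MKI67", "KI67" = "MKI67",
  "P16" = "CDKN2A", "P53" = "TP53", "C-FOS" = "FOS"
)

resolve_gene_symbols <- function(genes) {
  g <- toupper(trimws(as.character(genes)))
  hit <- g %in% names(GENE_ALIASES)
  g[hit] <- GENE_ALIASES[g[hit]]
  g
}

#' Construct a stage panel
#'
#' A panel is the set of genes whose expression is characteristically
#' up- or downregulated in one histological stage. Gene identity is by
#' human symbol; a small alias table maps protein names (Ki-67, p16,
#' p53) onto symbols (MKI67, CDKN2A, TP53).
#'
#' @param stage One of `"HYPERPLASIA"`, `"DYSPLASIA"`, `"EARLY_INVASION"`.
#' @param direction `"UP"` or `"DOWN"` — the genes' direction in the stage.
#' @param genes Character vector of gene symbols, non-empty, no duplicates.
#' @return A `stage_panel` list with elements `stage`, `direction`, `genes`.
#' @export
stage_panel <- function(stage, direction, genes) {
  stage <- match_enum(stage, OSCC_STAGES, "stage")
  direction <- match_enum(direction, MIRNA_DIRECTIONS, "direction")
  genes <- resolve_gene_symbols(genes)
  if (length(genes) == 0) stop("panel gene list is empty")
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene symbol(s) in ", stage, "/", direction,
         " panel: ", paste(unique(dup), collapse = ", "))
  }
  structure(list(stage = stage, direction = direction, genes = genes),
            class = "stage_panel")
}

panel_key <- function(panel) {
  paste0(tolower(panel$stage), "_", tolower(panel$direction))
}

#' Built-in gene panels for the three early stages
#'
#' The default panels encode the per-stage expression signature of the
#' hamster model of sequential oral oncogenesis, expressed as human
#' gene symbols. Hyperplasia has no downregulated genes, so only five
#' panels exist: hyperplasia up (8 genes), dysplasia up (9) and down
#' (3), early invasion up (5) and down (2).
#'
#' @return Named list of [stage_panel()] objects, keyed
#'   `"<stage>_<direction>"` in stage order.
#' @export
builtin_panels <- function() {
  panels <- list(
    stage_panel("HYPERPLASIA", "UP",
                c("EGFR", "ERBB2", "JUN", "ETS1", "MYC", "MKI67",
                  "CDKN2A", "TP53")),
    stage_panel("DYSPLASIA", "UP",
                c("EGFR", "ERBB2", "FGFR2", "FGFR3", "ETS1", "JUN",
                  "MYC", "MKI67", "TP53")),
    stage_panel("DYSPLASIA", "DOWN", c("CDKN2A", "NRAS", "BCL2")),
    stage_panel("EARLY_INVASION", "UP",
                c("EGFR", "FGFR2", "FGFR3", "ETS1", "JUN")),
    stage_panel("EARLY_INVASION", "DOWN", c("CDKN2A", "BCL2"))
  )
  names(panels) <- vapply(panels, panel_key, character(1))
  panels
}

#' Load stage panels from a JSON config file
#'
#' The config is a JSON array of objects with fields `stage`,
#' `direction` and `genes`. Symbols are uppercased and alias-resolved;
#' duplicate symbols within a panel and repeated (stage, direction)
#' pairs are rejected.
#'
#' @param path Path to the JSON config.
#' @return Named list of [stage_panel()] objects.
#' @seealso [builtin_panels()]; the shipped default config
#'   `system.file("extdata", "builtin_panels.json", package = "stagemiR")`
#'   reproduces it.
#' @export
load_panels <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(cfg) || length(cfg) == 0) stop("no panels in config: ", path)
  panels <- lapply(cfg, function(entry) {
    for (field in c("stage", "direction", "genes")) {
      if (is.null(entry[[field]])) {
        stop("panel entry missing field '", field, "' in ", path)
      }
    }
    stage_panel(entry$stage, entry$direction, unlist(entry$genes))
  })
  keys <- vapply(panels, panel_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (stage, direction) panel(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  names(panels) <- keys
  panels
}

#' Select the panels belonging to one stage
#'
#' @param panels Named list of `stage_panel` objects.
#' @param stage Stage name.
#' @return Sublist of panels for that stage (possibly of length 1).
#' @export
panels_for_stage <- function(panels, stage) {
  stage <- match_enum(stage, OSCC_STAGES, "stage")
  hit <- Filter(function(p) p$stage == stage, panels)
  if (length(hit) == 0) stop("no panels defined for stage ", stage)
  hit
}

#' @export
print.stage_panel <- function(x, ...) {
  cat(sprintf("<stage_panel> %s/%s: %d genes (%s)\n",
              x$stage, x$direction, length(x$genes),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}
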