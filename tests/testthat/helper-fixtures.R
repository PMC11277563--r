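# Shared test data. The per-table target-gene enumerations below are
# transcribed independently of the packaged fixture files and serve as
# the oracle the fixtures are checked against.

tab2_targets <- list( # hyperplasia UP panel (8 genes)
  "hsa-miR-34a-5p" = c("EGFR", "ERBB2", "JUN", "ETS1", "MYC", "MKI67",
                       "TP53", "CDKN2A"),
  "hsa-miR-124-3p" = c("EGFR", "ERBB2", "JUN", "ETS1", "MYC", "MKI67",
                       "CDKN2A"),
  "hsa-miR-125b-5p" = c("EGFR", "ERBB2", "JUN", "ETS1", "MKI67", "TP53",
                        "CDKN2A")
)

tab3_targets <- list( # dysplasia UP panel (9 genes)
  "hsa-miR-34a-5p" = c("EGFR", "ERBB2", "FGFR2", "FGFR3", "ETS1", "MYC",
                       "JUN", "TP53", "MKI67"),
  "hsa-miR-124-3p" = c("EGFR", "ERBB2", "FGFR3", "ETS1", "MYC", "JUN",
                       "MKI67"),
  "hsa-miR-125b-5p" = c("EGFR", "ERBB2", "FGFR2", "ETS1", "JUN", "TP53",
                        "MKI67"),
  "hsa-miR-1-3p" = c("EGFR", "FGFR2", "ETS1", "MYC", "JUN", "TP53",
                     "MKI67")
)

tab4_up_targets <- list( # early invasion UP panel (5 genes)
  "hsa-miR-34a-5p" = c("EGFR", "FGFR2", "FGFR3", "ETS1", "JUN"),
  "hsa-miR-124-3p" = c("EGFR", "FGFR3", "ETS1", "JUN"),
  "hsa-miR-125b-5p" = c("EGFR", "FGFR2", "ETS1", "JUN"),
  "hsa-miR-1-3p" = c("EGFR", "FGFR2", "ETS1", "JUN"),
  "hsa-miR-147a" = c("EGFR", "FGFR2", "ETS1", "JUN")
)

tab4_down_targets <- list( # early invasion DOWN panel (2 genes)
  "hsa-miR-155-5p" = c("CDKN2A", "BCL2"),
  "hsa-miR-423-3p" = c("CDKN2A", "BCL2"),
  "hsa-miR-34a-5p" = c("CDKN2A", "BCL2")
)

# unique (miRNA, gene) pairs across all four table enumerations
expected_fixture_pairs <- function() {
  all_lists <- c(tab2_targets, tab3_targets, tab4_up_targets,
                 tab4_down_targets)
  # iterate entries positionally: the concatenation repeats miRNA names
  # across tables, and the union must cover every table's list
  pairs <- unique(do.call(rbind, mapply(function(m, g) {
    data.frame(mirna_id = m, gene = g, stringsAsFactors = FALSE)
  }, names(all_lists), all_lists, SIMPLIFY = FALSE)))
  pairs[order(pairs$mirna_id, pairs$gene), , drop = FALSE]
}

paper_edges <- function() {
  load_interactions(stagemir_fixture("paper_edges.tsv"), quiet = TRUE)
}

paper_db <- function() {
  load_dysregulation(stagemir_fixture("paper_directions.tsv"), quiet = TRUE)
}

# random bipartite edge table; returns NULL when no edge was drawn
random_edge_df <- function(mirnas, genes, p) {
  grid <- expand.grid(mirna_id = mirnas, gene = genes,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < p
  if (!any(keep)) return(NULL)
  cbind(grid[keep, , drop = FALSE], source_db = "rand")
}

rand_mirna_ids <- function(n) sprintf("hsa-miR-8%03d-3p", seq_len(n))
rand_gene_ids <- function(n) sprintf("GENE%02d", seq_len(n))

# brute-force oracle: per-miRNA panel coverage by direct row scanning
brute_force_coverage <- function(edge_df, panel_genes) {
  edge_df <- unique(edge_df[, c("mirna_id", "gene")])
  hits <- edge_df[edge_df$gene %in% panel_genes, , drop = FALSE]
  counts <- table(hits$mirna_id)
  stats::setNames(as.integer(counts), names(counts))
}
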