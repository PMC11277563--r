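# Bipartite miRNA-gene interaction tables: loading, deduplication,
# per-panel subnetworks, and lossless GraphML / node-link JSON export.

SOURCES_SEP <- ";"

join_sources <- function(tags) {
  # radix sort = C-locale collation, so files are byte-stable across locales
  paste(sort(unique(tags[nzchar(tags)]), method = "radix"),
        collapse = SOURCES_SEP)
}

split_sources <- function(x) strsplit(x, SOURCES_SEP, fixed = TRUE)

#' Construct an interaction table
#'
#' The bipartite edge set miRNA -> target gene. Duplicate
#' (miRNA, gene) rows are merged and their source-database tags
#' unioned; ids are normalized and gene symbols uppercased, so loading
#' is idempotent under file self-concatenation.
#'
#' @param edges Data frame with columns `mirna_id`, `gene` and
#'   optionally `source_db` (free-text provenance tag).
#' @return An `interaction_table` (data frame with columns `mirna_id`,
#'   `gene`, `sources` — semicolon-joined sorted unique tags).
#' @export
interaction_table <- function(edges) {
  missing <- setdiff(c("mirna_id", "gene"), names(edges))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(edges) == 0) stop("no interaction edges supplied")
  src <- if ("source_db" %in% names(edges)) as.character(edges$source_db)
         else if ("sources" %in% names(edges)) as.character(edges$sources)
         else rep("", nrow(edges))
  src[is.na(src)] <- ""
  df <- data.frame(
    mirna_id = normalize_mirna_id(edges$mirna_id),
    gene = resolve_gene_symbols(edges$gene),
    src = src,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(df$gene))) stop("empty gene symbol in interaction table")
  key <- paste(df$mirna_id, df$gene, sep = "\r")
  tags <- unlist(split_sources(df$src))
  grp <- rep(key, lengths(split_sources(df$src)))
  merged <- tapply(tags, factor(grp, levels = unique(key)), join_sources)
  first <- !duplicated(key)
  out <- data.frame(
    mirna_id = df$mirna_id[first],
    gene = df$gene[first],
    sources = as.character(merged[key[first]]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mirna_id, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Load a miRNA-gene interaction table from TSV
#'
#' @param path TSV with header columns `mirna_id`, `gene`, `source_db`
#'   (miRTarBase/TarBase-style edge dump).
#' @param quiet Suppress the count message.
#' @return An [interaction_table()].
#' @export
load_interactions <- function(path, quiet = FALSE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0) stop("empty interaction file: ", path)
  tab <- tryCatch(interaction_table(raw), error = function(e) {
    stop("while parsing ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf(
      "loaded %d rows -> %d unique edges (%d miRNAs, %d genes)",
      nrow(raw), nrow(tab), length(unique(tab$mirna_id)),
      length(unique(tab$gene))))
  }
  tab
}

#' Write an interaction table to TSV
#'
#' @param table An `interaction_table`.
#' @param path Output path.
#' @export
write_interactions <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  out <- data.frame(mirna_id = table$mirna_id, gene = table$gene,
                    source_db = table$sources)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an interaction table to one panel's genes
#'
#' The per-panel regulatory network: every edge into a panel gene, and
#' the set of distinct miRNAs holding at least one such edge.
#'
#' @param table An [interaction_table()].
#' @param panel A [stage_panel()].
#' @return A `panel_network` list with elements `panel`, `edges`
#'   (interaction-table subset) and `mirnas`. An empty intersection
#'   yields a valid empty network.
#' @export
panel_subnetwork <- function(table, panel) {
  stopifnot(inherits(table, "interaction_table"),
            inherits(panel, "stage_panel"))
  edges <- table[table$gene %in% panel$genes, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(panel = panel, edges = edges,
                 mirnas = sort(unique(edges$mirna_id))),
            class = "panel_network")
}

#' Export a panel network as GraphML or node-link JSON
#'
#' Nodes carry a `role` attribute (`"mirna"` or `"gene"`), edges carry
#' the semicolon-joined `sources` tag. [import_network()] reads either
#' format back losslessly.
#'
#' @param net A [panel_subnetwork()] result.
#' @param path Output file path.
#' @param format `"graphml"` or `"node_link_json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "node_link_json")) {
  stopifnot(inherits(net, "panel_network"))
  format <- match.arg(format)
  mirnas <- net$mirnas
  genes <- sort(unique(c(net$panel$genes, net$edges$gene)))
  nodes <- data.frame(
    name = c(mirnas, genes),
    role = c(rep("mirna", length(mirnas)), rep("gene", length(genes))),
    stringsAsFactors = FALSE
  )
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = net$edges$mirna_id, to = net$edges$gene,
                     sources = net$edges$sources),
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    payload <- list(
      nodes = nodes,
      links = data.frame(source = net$edges$mirna_id,
                         target = net$edges$gene,
                         sources = net$edges$sources,
                         stringsAsFactors = FALSE)
    )
    jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path File written by [export_network()].
#' @param format `"graphml"` or `"node_link_json"`.
#' @return List with `edges` (data frame `mirna_id`, `gene`, `sources`),
#'   `mirnas` and `genes` character vectors.
#' @export
import_network <- function(path, format = c("graphml", "node_link_json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    roles <- igraph::vertex_attr(g, "role")
    vnames <- igraph::vertex_attr(g, "name")
    el <- igraph::as_edgelist(g)
    srcs <- if (igraph::ecount(g) > 0) igraph::edge_attr(g, "sources")
            else character(0)
    if (nrow(el) > 0) {
      # orient each edge miRNA -> gene regardless of storage order
      from_is_mirna <- roles[match(el[, 1], vnames)] == "mirna"
      edges <- data.frame(
        mirna_id = ifelse(from_is_mirna, el[, 1], el[, 2]),
        gene = ifelse(from_is_mirna, el[, 2], el[, 1]),
        sources = srcs, stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(mirna_id = character(0), gene = character(0),
                          sources = character(0))
    }
  } else {
    payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    vnames <- payload$nodes$name
    roles <- payload$nodes$role
    if (length(payload$links) && NROW(payload$links) > 0) {
      edges <- data.frame(mirna_id = payload$links$source,
                          gene = payload$links$target,
                          sources = payload$links$sources,
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(mirna_id = character(0), gene = character(0),
                          sources = character(0))
    }
  }
  edges <- edges[order(edges$mirna_id, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges,
       mirnas = sort(vnames[roles == "mirna"]),
       genes = sort(vnames[roles == "gene"]))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d edges, %d miRNAs, %d genes\n",
              nrow(x), length(unique(x$mirna_id)), length(unique(x$gene))))
  NextMethod()
}

#' @export
print.panel_network <- function(x, ...) {
  cat(sprintf("<panel_network> %s/%s: %d edges, %d miRNAs over %d panel genes\n",
              x$panel$stage, x$panel$direction, nrow(x$edges),
              length(x$mirnas), length(x$panel$genes)))
  invisible(x)
}
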