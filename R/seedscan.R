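# Canonical miRNA seed-site detection in 3'UTR sequences. The seed is
# miRNA nucleotides 2-8 (5' end); a site on the UTR sense strand is
# the reverse complement of (part of) the seed, optionally followed by
# an adenosine opposite miRNA position 1:
#   8mer     revcomp(nt 2-8) + A    (8 nt, most specific)
#   7mer-m8  revcomp(nt 2-8)        (7 nt)
#   7mer-A1  revcomp(nt 2-7) + A    (7 nt)
#   6mer     revcomp(nt 2-7)        (6 nt, least specific)
# Strict Watson-Crick pairing only (no G:U wobble); overlapping
# matches are reported at their most specific type only.

SITE_TYPES <- c("SITE_8MER", "SITE_7MER_M8", "SITE_7MER_A1", "SITE_6MER")
SITE_SPECIFICITY <- stats::setNames(seq(4, 1), SITE_TYPES)

clean_rna <- function(x, what) {
  s <- toupper(gsub("\\s+", "", x))
  s <- chartr("T", "U", s)
  if (!nzchar(s)) stop(what, " sequence is empty")
  if (grepl("[^ACGU]", s)) {
    stop(what, " sequence contains characters outside {A,C,G,U/T}")
  }
  s
}

rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

#' Find canonical seed-match sites of one miRNA in one 3'UTR
#'
#' Scans the UTR on the given sense strand (5'->3') for reverse
#' complements of the miRNA seed. Coordinates are 0-based half-open on
#' the UTR. `T` is treated as `U`, so DNA and RNA UTRs are both
#' accepted.
#'
#' @param mirna_sequence Mature miRNA sequence, 5'->3', length >= 8.
#' @param utr_sequence 3'UTR sequence, 5'->3'.
#' @param mirna_id,gene Optional labels carried onto the sites.
#' @return Data frame with columns `mirna_id`, `gene`, `start`, `end`
#'   (0-based half-open), `site_type`; zero rows when no site exists.
#' @export
find_seed_sites <- function(mirna_sequence, utr_sequence,
                            mirna_id = "mirna", gene = "gene") {
  mir <- clean_rna(mirna_sequence, "miRNA")
  utr <- clean_rna(utr_sequence, "UTR")
  if (nchar(mir) < 8) stop("miRNA sequence shorter than 8 nt")
  core6 <- rna_revcomp(substr(mir, 2, 7))          # last 6 nt of the 7mer-m8
  m8_base <- rna_revcomp(substr(mir, 8, 8))        # complement of nt 8

  empty <- data.frame(mirna_id = character(0), gene = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (nchar(utr) < 6) return(empty)
  # exhaustive scan: fixed-string gregexpr would miss overlapping
  # occurrences of the 6mer core in low-complexity repeats
  starts1 <- which(vapply(seq_len(nchar(utr) - 5), function(i) {
    substr(utr, i, i + 5) == core6
  }, logical(1)))
  if (length(starts1) == 0) return(empty)

  rows <- lapply(starts1, function(i) {
    p <- i - 1L                         # 0-based start of the 6mer core
    has_m8 <- p >= 1 && substr(utr, i - 1, i - 1) == m8_base
    has_a1 <- p + 6 < nchar(utr) && substr(utr, i + 6, i + 6) == "A"
    if (has_m8 && has_a1) {
      data.frame(start = p - 1L, end = p + 7L, site_type = "SITE_8MER")
    } else if (has_m8) {
      data.frame(start = p - 1L, end = p + 6L, site_type = "SITE_7MER_M8")
    } else if (has_a1) {
      data.frame(start = p, end = p + 7L, site_type = "SITE_7MER_A1")
    } else {
      data.frame(start = p, end = p + 6L, site_type = "SITE_6MER")
    }
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(mirna_id = mirna_id, gene = gene,
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Collapse seed sites into interaction edges
#'
#' One edge per (miRNA, gene) pair holding at least one site of at
#' least the requested specificity, in the ordering
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer. Edges carry the source tag
#' `"seedscan"`, making the output a drop-in interaction table for the
#' network module.
#'
#' @param sites Data frame as returned by [find_seed_sites()] (rows
#'   from several scans may be concatenated).
#' @param min_type Least specific site class that still counts;
#'   default `"SITE_7MER_A1"`.
#' @return An [interaction_table()], or a zero-row data frame when no
#'   site qualifies.
#' @export
sites_to_edges <- function(sites, min_type = "SITE_7MER_A1") {
  min_type <- match.arg(min_type, SITE_TYPES)
  stopifnot(all(sites$site_type %in% SITE_TYPES))
  keep <- SITE_SPECIFICITY[sites$site_type] >= SITE_SPECIFICITY[[min_type]]
  d <- sites[keep, , drop = FALSE]
  if (nrow(d) == 0) {
    return(structure(
      data.frame(mirna_id = character(0), gene = character(0),
                 sources = character(0), stringsAsFactors = FALSE),
      class = c("interaction_table", "data.frame")))
  }
  interaction_table(data.frame(mirna_id = d$mirna_id, gene = d$gene,
                               source_db = "seedscan",
                               stringsAsFactors = FALSE))
}

#' Scan FASTA files of miRNAs and 3'UTRs for seed sites
#'
#' Headers of the miRNA FASTA are taken as miRNA ids and headers of
#' the UTR FASTA as gene symbols. Every (miRNA, UTR) pair is scanned.
#' Requires the Biostrings package for FASTA parsing.
#'
#' @param mirna_fasta,utr_fasta Paths to FASTA files.
#' @param min_type Passed to [sites_to_edges()].
#' @return List with `sites` (all detected sites) and `edges` (the
#'   collapsed [interaction_table()]).
#' @export
scan_fasta_seed_sites <- function(mirna_fasta, utr_fasta,
                                  min_type = "SITE_7MER_A1") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("scan_fasta_seed_sites requires the Biostrings package")
  }
  mirs <- Biostrings::readBStringSet(mirna_fasta)
  utrs <- Biostrings::readBStringSet(utr_fasta)
  site_list <- list()
  for (m in seq_along(mirs)) {
    for (u in seq_along(utrs)) {
      s <- find_seed_sites(as.character(mirs[[m]]), as.character(utrs[[u]]),
                           mirna_id = names(mirs)[m], gene = names(utrs)[u])
      if (nrow(s)) site_list[[length(site_list) + 1L]] <- s
    }
  }
  sites <- if (length(site_list)) do.call(rbind, site_list) else
    data.frame(mirna_id = character(0), gene = character(0),
               start = integer(0), end = integer(0),
               site_type = character(0), stringsAsFactors = FALSE)
  list(sites = sites, edges = sites_to_edges(sites, min_type))
}
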