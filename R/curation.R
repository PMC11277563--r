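# Curation of experimentally reported miRNA dysregulation evidence in
# OSCC biospecimens: identifier normalization, the evidence database,
# and directional queries against it.

MIRNA_DIRECTIONS <- c("UP", "DOWN")
MIRNA_SOURCES <- c("TISSUE", "SALIVA", "BLOOD", "CELL_LINE")
VERDICT_QUALIFIERS <- c("CONSISTENT", "MOSTLY", "RARELY", "NONE")

# input tokens accepted in TSV files; saliva_exosome maps to SALIVA with
# an exosome flag so that exosomal saliva studies count as saliva evidence
SOURCE_TOKENS <- c(
  tissue = "TISSUE", saliva = "SALIVA", blood = "BLOOD",
  cell_line = "CELL_LINE", saliva_exosome = "SALIVA"
)

#' Normalize a miRNA identifier to canonical form
#'
#' Published reports mix spellings of the same mature miRNA:
#' `"miR124-3p"`, `"miR-124-3p"`, `"hsa-miR-124-3p"`, `"MIR-124-3P"` all
#' denote one molecule. This routine unifies them to the canonical
#' human miRBase-style name (`"hsa-miR-124-3p"`). The `let-7` family
#' keeps its historical `let` stem. Arm suffixes (`-3p`/`-5p`) and any
#' trailing qualifiers are preserved verbatim. Normalization is
#' idempotent: applying it to an already-canonical name is a no-op.
#'
#' @param raw Character vector of miRNA names.
#' @return Character vector of canonical names, same length as `raw`.
#' @examples
#' normalize_mirna_id(c("miR124-3p", "hsa-miR-34a-5p", "let-7g-5p"))
#' @export
normalize_mirna_id <- function(raw) {
  if (!is.character(raw)) stop("miRNA ids must be character")
  vapply(raw, normalize_one_mirna, character(1), USE.NAMES = FALSE)
}

normalize_one_mirna <- function(x) {
  tok <- gsub("\\s+", "", x)
  if (is.na(tok) || !nzchar(tok)) {
    stop("empty miRNA identifier (raw token: ", deparse(x), ")")
  }
  body <- sub("^hsa-", "", tok, ignore.case = TRUE)
  if (grepl("^let-?7", body, ignore.case = TRUE)) {
    rest <- sub("^let-?", "", body, ignore.case = TRUE)
    return(paste0("hsa-let-", rest))
  }
  if (grepl("^mir-?[0-9]", body, ignore.case = TRUE)) {
    rest <- sub("^mir-?", "", body, ignore.case = TRUE)
    return(paste0("hsa-miR-", rest))
  }
  stop("not a recognizable miRNA identifier: ", deparse(x))
}

match_enum <- function(x, allowed, what) {
  up <- toupper(trimws(x))
  bad <- !(up %in% allowed)
  if (any(bad)) {
    stop("unknown ", what, " token(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  up
}

#' Construct a dysregulation evidence database
#'
#' One row per evidence record: a miRNA reported significantly up- or
#' downregulated in one OSCC sample source, with a citation tag. Rows
#' are validated, miRNA ids normalized, and exact duplicate records
#' collapsed. A miRNA may legitimately carry evidence in both
#' directions (the conflicted miR-34a-5p pattern).
#'
#' @param records Data frame with columns `mirna_id`, `direction`
#'   (`up`/`down`), `source` (`tissue`, `saliva`, `blood`, `cell_line`,
#'   `saliva_exosome`), `reference`.
#' @return A `dysregulation_db` (data frame with columns `mirna_id`,
#'   `direction`, `source`, `exosome`, `reference`).
#' @export
dysregulation_db <- function(records) {
  needed <- c("mirna_id", "direction", "source", "reference")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0) stop("no evidence records supplied")
  src_tok <- tolower(trimws(records$source))
  bad <- !(src_tok %in% names(SOURCE_TOKENS))
  if (any(bad)) {
    stop("unknown source token(s) at row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(records$source[bad]), collapse = ", "))
  }
  db <- data.frame(
    mirna_id = normalize_mirna_id(records$mirna_id),
    direction = match_enum(records$direction, MIRNA_DIRECTIONS, "direction"),
    source = unname(SOURCE_TOKENS[src_tok]),
    exosome = src_tok == "saliva_exosome",
    reference = as.character(records$reference),
    stringsAsFactors = FALSE
  )
  db <- unique(db)
  db <- db[order(db$mirna_id, db$direction, db$source, db$reference), ]
  rownames(db) <- NULL
  class(db) <- c("dysregulation_db", "data.frame")
  db
}

#' Load a dysregulation database from a tab-separated file
#'
#' @param path Path to a UTF-8 TSV with header
#'   `mirna_id  direction  source  reference`.
#' @param quiet Suppress the row-count message.
#' @return A [dysregulation_db()].
#' @export
load_dysregulation <- function(path, quiet = FALSE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0) stop("empty dysregulation file: ", path)
  db <- tryCatch(dysregulation_db(raw), error = function(e) {
    stop("while parsing ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("loaded %d evidence rows (%d after dedup) for %d miRNAs",
                    nrow(raw), nrow(db), length(unique(db$mirna_id))))
  }
  db
}

#' Write a dysregulation database back to TSV
#'
#' Inverse of [load_dysregulation()]: reloading the written file yields
#' an identical record set.
#'
#' @param db A `dysregulation_db`.
#' @param path Output path.
#' @export
write_dysregulation <- function(db, path) {
  stopifnot(inherits(db, "dysregulation_db"))
  token <- tolower(db$source)
  token[db$exosome] <- "saliva_exosome"
  out <- data.frame(mirna_id = db$mirna_id,
                    direction = tolower(db$direction),
                    source = token,
                    reference = db$reference)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-direction index of a dysregulation database
#'
#' @param db A `dysregulation_db`.
#' @return Named list: for each miRNA, a list with `UP` and `DOWN`
#'   data frames of its evidence records.
#' @export
direction_index <- function(db) {
  stopifnot(inherits(db, "dysregulation_db"))
  lapply(split(as.data.frame(db), db$mirna_id), function(d) {
    list(UP = d[d$direction == "UP", , drop = FALSE],
         DOWN = d[d$direction == "DOWN", , drop = FALSE])
  })
}

#' Query directional evidence for one miRNA
#'
#' Decides whether a miRNA has at least one evidence record in the
#' required direction within the allowed sample sources (the filter the
#' stage pipeline applies), and qualifies the verdict by majority:
#' `CONSISTENT` when no opposing record exists, `MOSTLY` when
#' supporting records are at least as many as opposing ones, `RARELY`
#' when opposing records outnumber supporting ones, `NONE` when no
#' supporting record exists. Evidence outside `allowed_sources` never
#' affects `passes` but is reported in `other_sources`.
#'
#' @param db A `dysregulation_db`.
#' @param mirna miRNA name (normalized internally).
#' @param required `"UP"` or `"DOWN"`.
#' @param allowed_sources Subset of
#'   `c("TISSUE","SALIVA","BLOOD","CELL_LINE")`; default tissue+saliva,
#'   the restriction used for biomarker filtering.
#' @return A `direction_verdict` list with elements `mirna_id`,
#'   `direction_required`, `passes`, `qualifier`, `n_support`,
#'   `n_oppose`, `supporting_sources`, `other_sources`.
#' @export
query_direction <- function(db, mirna, required,
                            allowed_sources = c("TISSUE", "SALIVA")) {
  stopifnot(inherits(db, "dysregulation_db"))
  required <- match_enum(required, MIRNA_DIRECTIONS, "direction")
  allowed_sources <- match_enum(allowed_sources, MIRNA_SOURCES, "source")
  if (!length(allowed_sources)) stop("allowed_sources must be non-empty")
  id <- normalize_mirna_id(mirna)
  rows <- db[db$mirna_id == id, , drop = FALSE]
  inset <- rows$source %in% allowed_sources
  support <- rows$direction == required & inset
  oppose <- rows$direction != required & inset
  n_support <- sum(support)
  n_oppose <- sum(oppose)
  qualifier <- if (n_support == 0) "NONE"
    else if (n_oppose == 0) "CONSISTENT"
    else if (n_support >= n_oppose) "MOSTLY"
    else "RARELY"
  verdict <- list(
    mirna_id = id,
    direction_required = required,
    passes = n_support >= 1,
    qualifier = qualifier,
    n_support = n_support,
    n_oppose = n_oppose,
    supporting_sources = sort(unique(rows$source[support])),
    other_sources = sort(unique(rows$source[rows$direction == required & !inset]))
  )
  class(verdict) <- "direction_verdict"
  verdict
}

#' @export
print.direction_verdict <- function(x, ...) {
  cat(sprintf("<direction_verdict> %s required %s: %s (%s; %d for / %d against)\n",
              x$mirna_id, x$direction_required,
              if (x$passes) "PASS" else "FAIL",
              x$qualifier, x$n_support, x$n_oppose))
  invisible(x)
}

#' @export
print.dysregulation_db <- function(x, ...) {
  cat(sprintf("<dysregulation_db> %d records, %d miRNAs\n",
              nrow(x), length(unique(x$mirna_id))))
  NextMethod()
}
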