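# Curation module: identifier normalization, the evidence database,
# and directional queries.

test_that("normalize_mirna_id canonicalizes the spellings seen in print", {
  cases <- c(
    "miR124-3p" = "hsa-miR-124-3p",
    "hsa-miR-34a-5p" = "hsa-miR-34a-5p",
    "let-7g-5p" = "hsa-let-7g-5p",
    "miR-16-1-3p" = "hsa-miR-16-1-3p",
    "MIR-155-5P" = "hsa-miR-155-5P",
    "mir 423-3p" = "hsa-miR-423-3p",
    "hsa-let-7g-5p" = "hsa-let-7g-5p",
    "miR-3928" = "hsa-miR-3928"
  )
  expect_identical(normalize_mirna_id(names(cases)), unname(cases))
})

test_that("normalization is idempotent over many raw variants", {
  variants <- c("miR124-3p", "miR-34a-5p", "hsa-mir-1-3p", "let-7g-5p",
                "LET-7a", "mir147a", "hsa-miR-155-5p", "miR-16-1-3p")
  once <- normalize_mirna_id(variants)
  expect_identical(normalize_mirna_id(once), once)
})

test_that("non-miRNA tokens are rejected by name", {
  expect_error(normalize_mirna_id(""), "empty")
  expect_error(normalize_mirna_id("EGFR"), "EGFR")
  expect_error(normalize_mirna_id("miR-"), "miR-")
})

test_that("the literature-update fixture yields 7 up and 10 down miRNAs", {
  db <- load_dysregulation(stagemir_fixture("table1_update.tsv"),
                           quiet = TRUE)
  up <- unique(db$mirna_id[db$direction == "UP"])
  down <- unique(db$mirna_id[db$direction == "DOWN"])
  expect_length(up, 7)
  expect_length(down, 10)
  expect_length(intersect(up, down), 0)
  # exosomal saliva rows count as saliva with the flag set
  exo <- db[db$mirna_id == "hsa-miR-1307-5p", ]
  expect_identical(exo$source, "SALIVA")
  expect_true(exo$exosome)
})

test_that("duplicate rows collapse and unknown tokens fail loudly", {
  rec <- data.frame(mirna_id = "miR-1-3p", direction = "down",
                    source = "tissue", reference = "r1")
  expect_identical(nrow(dysregulation_db(rbind(rec, rec))), 1L)
  bad_src <- transform(rec, source = "plasma")
  expect_error(dysregulation_db(bad_src), "plasma")
  bad_dir <- transform(rec, direction = "sideways")
  expect_error(dysregulation_db(bad_dir), "sideways")
  expect_error(dysregulation_db(rec[0, ]), "no evidence")
})

test_that("a conflicted miRNA is indexed under both directions", {
  idx <- direction_index(paper_db())
  m34 <- idx[["hsa-miR-34a-5p"]]
  expect_gt(nrow(m34$UP), 0)
  expect_gt(nrow(m34$DOWN), 0)
  # every record is reachable from the index
  total <- sum(vapply(idx, function(d) nrow(d$UP) + nrow(d$DOWN), numeric(1)))
  expect_identical(total, as.numeric(nrow(paper_db())))
})

test_that("TSV round trip preserves the record set", {
  db <- load_dysregulation(stagemir_fixture("table1_update.tsv"),
                           quiet = TRUE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_dysregulation(db, tmp)
  again <- load_dysregulation(tmp, quiet = TRUE)
  expect_identical(as.data.frame(db), as.data.frame(again))
})

test_that("query_direction reproduces the printed verdicts", {
  db <- paper_db()
  v_down <- query_direction(db, "miR-34a-5p", "DOWN")
  expect_true(v_down$passes)
  expect_identical(v_down$qualifier, "MOSTLY")
  v_up <- query_direction(db, "miR-34a-5p", "UP")
  expect_true(v_up$passes)
  expect_identical(v_up$qualifier, "RARELY")
  v124 <- query_direction(db, "miR-124-3p", "DOWN")
  expect_identical(v124$qualifier, "CONSISTENT")
  expect_setequal(v124$supporting_sources, c("TISSUE", "SALIVA"))
  v_absent <- query_direction(db, "miR-9999-5p", "UP")
  expect_false(v_absent$passes)
  expect_identical(v_absent$qualifier, "NONE")
})

test_that("evidence outside allowed sources never affects passes", {
  rec <- data.frame(
    mirna_id = c("miR-10-5p", "miR-10-5p"),
    direction = c("up", "up"),
    source = c("blood", "cell_line"),
    reference = c("r1", "r2"))
  db <- dysregulation_db(rec)
  v <- query_direction(db, "miR-10-5p", "UP", c("TISSUE", "SALIVA"))
  expect_false(v$passes)
  expect_setequal(v$other_sources, c("BLOOD", "CELL_LINE"))
  v2 <- query_direction(db, "miR-10-5p", "UP",
                        c("TISSUE", "SALIVA", "BLOOD"))
  expect_true(v2$passes)
})

test_that("passes is monotone in allowed_sources (property)", {
  set.seed(41)
  sources <- c("tissue", "saliva", "blood", "cell_line")
  source_sets <- list(c("TISSUE"), c("SALIVA"), c("TISSUE", "SALIVA"),
                      c("TISSUE", "SALIVA", "BLOOD"),
                      c("TISSUE", "SALIVA", "BLOOD", "CELL_LINE"))
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    db <- dysregulation_db(data.frame(
      mirna_id = sprintf("miR-%d-5p", sample(1:5, n, replace = TRUE)),
      direction = sample(c("up", "down"), n, replace = TRUE),
      source = sample(sources, n, replace = TRUE),
      reference = sprintf("r%d", seq_len(n))))
    for (m in unique(db$mirna_id)) {
      for (d in c("UP", "DOWN")) {
        passes <- vapply(source_sets, function(s) {
          query_direction(db, m, d, s)$passes
        }, logical(1))
        # enlarging the nested source sets never flips TRUE -> FALSE
        expect_true(all(diff(passes[c(1, 3, 4, 5)]) >= 0))
        expect_true(all(diff(passes[c(2, 3, 4, 5)]) >= 0))
      }
    }
  }
})

test_that("single-direction miRNAs pass exactly one required direction", {
  db <- paper_db()
  idx <- direction_index(db)
  for (m in names(idx)) {
    one_dir <- xor(nrow(idx[[m]]$UP) > 0, nrow(idx[[m]]$DOWN) > 0)
    if (!one_dir) next
    p_up <- query_direction(db, m, "UP",
                            c("TISSUE", "SALIVA", "BLOOD", "CELL_LINE"))$passes
    p_down <- query_direction(db, m, "DOWN",
                              c("TISSUE", "SALIVA", "BLOOD", "CELL_LINE"))$passes
    expect_true(xor(p_up, p_down))
  }
})
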