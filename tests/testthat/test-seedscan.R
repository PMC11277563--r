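# Seed-site scanner: canonical site grammar on constructed UTRs.
#
# Worked construction used throughout: miRNA 5'-UACGUACGUACGUACGUACGU-3'
# has seed (nt 2-8) ACGUACG; the sense-strand site core (revcomp of
# nt 2-7) is GUACGU, the m8-matching base is C, so the full site
# classes read CGUACGUA (8mer), CGUACGU (7mer-m8), GUACGUA (7mer-A1),
# GUACGU (6mer).

mir21 <- "UACGUACGUACGUACGUACGU"

test_that("a UTR without seed complements yields no sites", {
  expect_identical(nrow(find_seed_sites(mir21, "UUUUUUUUUUUU")), 0L)
  expect_identical(nrow(find_seed_sites(mir21, "ACG")), 0L) # shorter than 6
})

test_that("the constructed 8mer is found at the expected offset", {
  utr <- paste0("UUUU", "CGUACGUA", "UUUU")
  sites <- find_seed_sites(mir21, utr, mirna_id = "hsa-miR-77-5p",
                           gene = "GENEX")
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$site_type, "SITE_8MER")
  expect_identical(sites$start, 4L)
  expect_identical(sites$end, 12L)
  expect_identical(substr(utr, sites$start + 1, sites$end), "CGUACGUA")
})

test_that("concatenating two site-bearing UTRs translates the second site", {
  utr1 <- paste0("UUUU", "CGUACGUA", "UUUU")
  both <- find_seed_sites(mir21, paste0(utr1, utr1))
  expect_identical(nrow(both), 2L)
  expect_identical(both$start[2] - both$start[1], nchar(utr1))
  expect_identical(unique(both$site_type), "SITE_8MER")
})

test_that("each site class is reported at its most specific type only", {
  # m8 match, no A1 adenosine -> 7mer-m8
  s <- find_seed_sites(mir21, "UUCGUACGUUUU")
  expect_identical(s$site_type, "SITE_7MER_M8")
  expect_identical(s$end - s$start, 7L)
  # A1 adenosine, no m8 match -> 7mer-A1
  s <- find_seed_sites(mir21, "UUGGUACGUAUU")
  expect_identical(s$site_type, "SITE_7MER_A1")
  expect_identical(s$end - s$start, 7L)
  # neither -> 6mer
  s <- find_seed_sites(mir21, "UUGGUACGUUUU")
  expect_identical(s$site_type, "SITE_6MER")
  expect_identical(s$end - s$start, 6L)
  # DNA input is accepted (T == U)
  s <- find_seed_sites(mir21, "TTTTCGTACGTATTTT")
  expect_identical(s$site_type, "SITE_8MER")
})

test_that("boundary sites lacking room for m8/A1 degrade gracefully", {
  # core at the very 5' end: no position for the m8 base
  s <- find_seed_sites(mir21, "GUACGUAUUU")
  expect_identical(s$site_type, "SITE_7MER_A1")
  expect_identical(s$start, 0L)
  # core at the very 3' end: no position for the A1 adenosine
  s <- find_seed_sites(mir21, "UUUCGUACGU")
  expect_identical(s$site_type, "SITE_7MER_M8")
})

test_that("the scanner respects the given sense strand", {
  utr <- paste0("UUUU", "CGUACGUA", "UUUU")
  rc <- paste(rev(strsplit(chartr("ACGU", "UGCA", utr), "")[[1]]),
              collapse = "")
  expect_identical(nrow(find_seed_sites(mir21, rc)), 0L)
})

test_that("invalid sequences are rejected", {
  expect_error(find_seed_sites("ACGUACG", "ACGUACGU"), "8 nt")
  expect_error(find_seed_sites("ACGUACGN", "ACGUACGU"), "characters outside")
  expect_error(find_seed_sites(mir21, "ACGUXACG"), "characters outside")
  expect_error(find_seed_sites(mir21, ""), "empty")
})

test_that("sites_to_edges applies the specificity ordering", {
  sites <- rbind(
    find_seed_sites(mir21, "UUGGUACGUUUU",          # 6mer
                    mirna_id = "hsa-miR-77-5p", gene = "GENEA"),
    find_seed_sites(mir21, "UUUUCGUACGUAUUUU",      # 8mer
                    mirna_id = "hsa-miR-77-5p", gene = "GENEB"),
    find_seed_sites(mir21, "UUGGUACGUAUU",          # 7mer-A1
                    mirna_id = "hsa-miR-78-5p", gene = "GENEA"))
  low <- sites_to_edges(sites, min_type = "SITE_6MER")
  expect_identical(nrow(low), 3L)
  default <- sites_to_edges(sites)                  # >= 7mer-A1
  expect_identical(nrow(default), 2L)
  strict <- sites_to_edges(sites, min_type = "SITE_8MER")
  expect_identical(nrow(strict), 1L)
  expect_identical(strict$gene, "GENEB")
  expect_true(all(default$sources == "seedscan"))
  # brute-force grouping oracle: one edge per qualifying (miRNA, gene)
  keep <- sites$site_type %in% c("SITE_8MER", "SITE_7MER_M8", "SITE_7MER_A1")
  expect_identical(nrow(default),
                   nrow(unique(sites[keep, c("mirna_id", "gene")])))
  none <- sites_to_edges(sites[sites$site_type == "SITE_6MER", ],
                         min_type = "SITE_7MER_A1")
  expect_identical(nrow(none), 0L)
})

test_that("FASTA scanning produces pipeline-compatible edges", {
  skip_if_not_installed("Biostrings")
  dir <- withr::local_tempdir()
  mirs <- file.path(dir, "mirs.fa")
  utrs <- file.path(dir, "utrs.fa")
  writeLines(c(">hsa-miR-77-5p", mir21), mirs)
  writeLines(c(">GENEA", "UUUUCGUACGUAUUUU",
               ">GENEB", "UUUUUUUUUUUU"), utrs)
  out <- scan_fasta_seed_sites(mirs, utrs)
  expect_identical(nrow(out$sites), 1L)
  expect_identical(out$edges$gene, "GENEA")
  expect_s3_class(out$edges, "interaction_table")
})
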