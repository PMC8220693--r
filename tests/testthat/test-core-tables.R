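test_that("count tables read, validate and round-trip through TSV and BIOM", {
  tbl <- tiny_table()
  expect_equal(unname(rowSums(tbl)), c(5, 3, 7))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tbl, tsv)
  expect_equal(unclass(read_count_table(tsv)), unclass(tbl))

  biom <- withr::local_tempfile(fileext = ".biom")
  write_count_table(tbl, biom)
  back <- read_count_table(biom)
  expect_equal(unclass(back)[asv_ids(tbl), sample_ids(tbl)], unclass(tbl))

  # degenerate and malformed inputs
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("asv_id\ts1\ts2", empty)
  expect_error(read_count_table(empty), "no ASVs")
  expect_error(asv_table(matrix(-1, 1, 1, dimnames = list("a", "s"))),
               "negative")
  expect_error(asv_table(matrix(1.5, 1, 1, dimnames = list("a", "s"))),
               "non-integer")
  expect_error(asv_table(matrix(1, 2, 1, dimnames = list(c("a", "a"), "s"))),
               "duplicate")
})

test_that("study design validates sample types, nesting and replicate groups", {
  df <- data.frame(sample_id = paste0("s", 1:6),
                   sample_type = c(rep("plasma", 4), rep("plasma_denc", 2)),
                   extraction_batch = "A", stringsAsFactors = FALSE)
  d <- study_design(df)
  expect_equal(sum(d$sample_type == "plasma_denc"), 2)

  expect_error(study_design(data.frame(sample_id = "s1", sample_type = "serum")),
               "unknown sample_type")
  # a day cannot belong to two batches
  bad <- data.frame(sample_id = c("s1", "s2"), sample_type = "plasma",
                    extraction_batch = c("A", "B"), extraction_day = "d1")
  expect_error(study_design(bad), "nesting")
  # replicate group spanning two patients
  bad2 <- data.frame(sample_id = c("s1", "s2"), sample_type = "plasma",
                     patient_id = c("p1", "p2"),
                     extraction_batch = c("A", "B"), replicate_group = "g1")
  expect_error(study_design(bad2), "patient")
  # design round-trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, tsv)
  expect_equal(read_design(tsv)$sample_id, d$sample_id)
})

test_that("non-target lineages are removed at any rank, case-insensitively", {
  tbl <- asv_table(matrix(1, 5, 2, dimnames = list(paste0("a", 1:5),
                                                   c("s1", "s2"))))
  tax <- tiny_taxonomy(asv_ids(tbl))
  tax$family[3] <- "Mitochondria"
  out <- filter_nontarget_taxa(tbl, tax)
  expect_equal(nrow(out), 4)
  expect_false("a3" %in% asv_ids(out))
  # identity when nothing matches
  expect_equal(asv_ids(filter_nontarget_taxa(tbl, tiny_taxonomy(asv_ids(tbl)))),
               asv_ids(tbl))
  # all matching: empty with warning
  tax$domain <- "Eukaryota"
  expect_warning(res <- filter_nontarget_taxa(tbl, tax), "all ASVs")
  expect_equal(nrow(res), 0)
  # missing taxonomy errors
  expect_error(filter_nontarget_taxa(tbl, tiny_taxonomy("a1")), "missing taxonomy")
})

test_that("technical replicates merge by summing and conserve reads", {
  m <- matrix(c(3, 0, 2, 5, 1, 1), nrow = 2,
              dimnames = list(c("a1", "a2"), c("r1", "r2", "r3")))
  tbl <- asv_table(m)
  des <- tiny_design(c("r1", "r2", "r3"))
  des$replicate_group <- NULL
  des$bio <- c("x", "x", "y")
  out <- merge_technical_replicates(tbl, des, "bio")
  expect_equal(unname(unclass(out$table)[, "x"]), c(5, 5))
  expect_equal(sum(out$table), sum(tbl))
  expect_equal(ncol(out$table), 2)
  # singleton groups: unchanged up to relabelling
  des$bio <- c("u", "v", "w")
  out2 <- merge_technical_replicates(tbl, des, "bio")
  expect_equal(unname(unclass(out2$table)), unname(m))
  # groups may not mix sample types
  des$sample_type <- c("plasma", "stool", "plasma")
  des$bio <- c("x", "x", "y")
  expect_error(merge_technical_replicates(tbl, study_design(des), "bio"),
               "mixes sample types")
})

test_that("abundance floor removes per-stratum below-threshold ASVs strictly", {
  # asv2 has 1 read of a 100000-read plasma stratum: 0.001% < 0.01%
  m <- matrix(c(90000, 9989, 1, 10), nrow = 4,
              dimnames = list(paste0("a", 1:4), "s1"))
  tbl <- asv_table(m)
  des <- tiny_design("s1")
  out <- filter_low_abundance(tbl, des, floor_pct = 0.01)
  expect_false("a3" %in% asv_ids(out))
  expect_equal(unname(unclass(out)[, 1]), c(90000, 9989, 10))
  # exactly at the floor: retained (removal is strictly below)
  m2 <- matrix(c(99990, 10), nrow = 2, dimnames = list(c("big", "edge"), "s1"))
  out2 <- filter_low_abundance(asv_table(m2), tiny_design("s1"), 0.01)
  expect_true("edge" %in% asv_ids(out2))
  # floor 0 is the identity
  expect_equal(unclass(filter_low_abundance(tbl, des, 0)), unclass(tbl))
  # stratum independence: removal in plasma does not affect stool
  m3 <- matrix(c(1, 100000, 5000, 5000), nrow = 2,
               dimnames = list(c("x", "y"), c("p1", "st1")))
  des3 <- study_design(data.frame(sample_id = c("p1", "st1"),
                                  sample_type = c("plasma", "stool")))
  out3 <- filter_low_abundance(asv_table(m3), des3, 0.01)
  expect_equal(unname(unclass(out3)["x", ]), c(0, 5000))
  # idempotence
  expect_equal(unclass(filter_low_abundance(out, des, 0.01)), unclass(out))
})

test_that("rarefaction is an exact-depth, seeded, order-independent subsample", {
  tbl <- random_table(n_asv = 30, n_samp = 5, lambda = 40, seed = 3)
  out <- rarefy(tbl, depth = 500, seed = 42)
  expect_true(all(colSums(out) == 500))
  expect_true(all(unclass(out) <= unclass(tbl)))
  # determinism and seed sensitivity
  expect_identical(unclass(rarefy(tbl, 500, seed = 42)), unclass(out))
  expect_false(identical(unclass(rarefy(tbl, 500, seed = 43)), unclass(out)))
  # per-sample draws do not depend on column order
  perm <- c(3, 1, 5, 2, 4)
  shuffled <- asv_table(unclass(tbl)[, perm])
  out_sh <- rarefy(shuffled, 500, seed = 42)
  expect_equal(unclass(out_sh)[, sample_ids(out)], unclass(out))
  # depth == column sum leaves the column unchanged
  depths <- colSums(tbl)
  out_id <- rarefy(tbl, min(depths), seed = 1)
  j <- which.min(depths)
  expect_equal(unclass(out_id)[, j], unclass(tbl)[, j])
  # shallow samples are dropped with a warning
  expect_warning(r2 <- rarefy(tbl, max(depths) - 1, seed = 1), "dropped")
  expect_lt(ncol(r2), ncol(tbl))
  expect_error(rarefy(tbl, 0), "positive")
  # richness never increases under rarefaction
  expect_true(all(apply(unclass(out), 2, richness) <=
                    apply(unclass(tbl)[, sample_ids(out)], 2, richness)))
})

test_that("count transforms match their closed forms", {
  m <- matrix(c(2, 2, 4), 3, 1, dimnames = list(paste0("a", 1:3), "s1"))
  tbl <- asv_table(m)
  expect_equal(unname(transform_counts(tbl, "relative")[, 1]),
               c(0.25, 0.25, 0.5))
  expect_equal(unname(transform_counts(tbl, "sqrt")[, 1]),
               sqrt(c(0.25, 0.25, 0.5)))
  # clr of a constant column is zero, and clr components always sum to 0
  const <- asv_table(matrix(5, 4, 1, dimnames = list(paste0("a", 1:4), "s")))
  expect_equal(unname(transform_counts(const, "clr")[, 1]), rep(0, 4))
  z <- transform_counts(random_table(seed = 5), "clr")
  expect_true(all(abs(colSums(z)) < 1e-9))
  # log-CPM closed form
  lc <- transform_counts(tbl, "log_cpm", prior_cpm = 0.5)
  expect_equal(lc[1, 1], log2((2 + 0.5) / (8 + 1) * 1e6))
  expect_error(transform_counts(tbl, "clr", offset = 0), "positive")
})
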