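test_that("count_table validates invariants and names offenders", {
  m <- matrix(c(3, 1, 0, 2), nrow = 2,
              dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
  ct <- count_table(m)
  expect_s3_class(ct, "count_table")
  expect_equal(unclass(ct)[, ], m)

  m_neg <- m; m_neg[2, 1] <- -1
  expect_error(count_table(m_neg), "OTU2.*S1")
  m_frac <- m; m_frac[1, 2] <- 1.5
  expect_error(count_table(m_frac), "non-negative integer")
  expect_error(count_table(m, otu_ids = c("A", "A")), "duplicate OTU")
  expect_error(count_table(m, sample_ids = c("S", "S")), "duplicate sample")
})

test_that("TSV and BIOM JSON round-trips are cell-for-cell exact", {
  set.seed(101)
  for (k in 1:20) {
    ct <- random_count_table(sample(2:12, 1), sample(2:8, 1))
    for (fmt in c("tsv", "biom_json")) {
      f <- withr::local_tempfile(fileext = if (fmt == "tsv") ".tsv" else ".json")
      write_count_table(ct, f, format = fmt)
      back <- read_count_table(f, format = fmt)
      expect_identical(rownames(back), rownames(ct))
      expect_identical(colnames(back), colnames(ct))
      expect_equal(unclass(back), unclass(ct), ignore_attr = FALSE)
    }
  }
})

test_that("reading a table with a negative cell names OTU and sample", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1\tS2", "OTU1\t3\t0", "OTU2\t-1\t2"), f)
  expect_error(read_count_table(f), "OTU2.*S1")
})

test_that("metadata reader types, validates enums, keeps extra columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  md <- toy_metadata(4)
  md$mystery_covariate <- seq_len(nrow(md))
  write_metadata(md, f)
  back <- read_metadata(f)
  expect_s3_class(back, "sample_metadata")
  expect_equal(nrow(back), 8)
  expect_true("mystery_covariate" %in% names(back))
  expect_identical(back$treatment[1], "intact")

  bad <- md; bad$treatment[1] <- "sieved"
  write_metadata(bad, f)
  expect_error(read_metadata(f), "sieved")
  bad <- md; bad$habitat[1] <- "summit"
  write_metadata(bad, f)
  expect_error(read_metadata(f), "summit")
  bad <- md; bad$elevation <- NULL
  write_metadata(bad, f)
  expect_error(read_metadata(f), "elevation")
})

test_that("generator output survives the metadata round-trip", {
  ds <- simulate_dataset(simulation_params(seed = 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(ds$metadata, f)
  back <- read_metadata(f)
  expect_equal(nrow(back), 60)
  expect_identical(back$sample_id, ds$metadata$sample_id)
  expect_identical(paired_design(back), ds$design)
})

test_that("standardize_depth hits the target exactly, per column", {
  # forced outcome: single OTU carries the whole column
  ct <- count_table(matrix(c(50000L, 0L), nrow = 2),
                    otu_ids = c("A", "B"), sample_ids = "S1")
  std <- standardize_depth(ct, depth = 10000, seed = 1)
  expect_equal(unclass(std)[, 1], c(A = 10000, B = 0))

  set.seed(7)
  ct <- random_count_table(15, 6, max_count = 3000)
  std <- standardize_depth(ct, depth = 10000, seed = 42)
  expect_true(all(colSums(std) == 10000))
  expect_true(all(unclass(std) <= unclass(ct)))  # without replacement
  # bit-identical under the same seed
  expect_identical(unclass(standardize_depth(ct, depth = 10000, seed = 42)),
                   unclass(std))
})

test_that("resampled counts match the hypergeometric expectation", {
  ct <- count_table(matrix(c(9000L, 3000L), nrow = 2),
                    otu_ids = c("A", "B"), sample_ids = "S1")
  means <- vapply(1:400, function(s) {
    unclass(standardize_depth(ct, depth = 10000, seed = s))[1, 1]
  }, numeric(1))
  # E[X] = depth * 9000/12000 = 7500; hypergeometric sd ~ 18, so the mean
  # of 400 draws is within ~4 * 18/sqrt(400) of 7500
  expect_equal(mean(means), 7500, tolerance = 4 * 18 / sqrt(400) / 7500)
})

test_that("shortfall policy aborts by default and drops on request", {
  ct <- count_table(matrix(c(5L, 2L, 20000L, 1L), nrow = 2),
                    otu_ids = c("A", "B"), sample_ids = c("low", "ok"))
  expect_error(standardize_depth(ct, depth = 10000, seed = 1),
               "low.*total 7")
  expect_warning(std <- standardize_depth(ct, depth = 10000, seed = 1,
                                          shortfall = "drop"),
                 "dropping")
  expect_identical(colnames(std), "ok")
})

test_that("combine_paired sums pairs, preserves reads, detects orphans", {
  md <- toy_metadata(3)
  design <- paired_design(md)
  m <- matrix(c(2, 0, 1,  0, 0, 3,  1, 1, 0,  4, 0, 0,  0, 2, 2,  1, 1, 1),
              nrow = 3)
  ct <- count_table(m, otu_ids = c("a", "b", "c"),
                    sample_ids = md$sample_id)
  comb <- combine_paired(ct, design)
  expect_identical(colnames(comb), design$plant_id)
  expect_equal(unclass(comb)[, 1], c(a = 2, b = 0, c = 4))
  expect_equal(sum(comb), sum(ct))
  # richness of the union bounds each member (set-union property)
  for (i in seq_len(nrow(design))) {
    expect_gte(otu_richness(comb[, i]),
               otu_richness(unclass(ct)[, design$intact[i]]))
    expect_gte(otu_richness(comb[, i]),
               otu_richness(unclass(ct)[, design$disturbed[i]]))
  }
  orphaned <- count_table(unclass(ct)[, 1:5])
  expect_error(combine_paired(orphaned, design), "P03_D")
})

test_that("presence_absence is binary, idempotent, richness-consistent", {
  ct <- count_table(matrix(c(0L, 1L, 37L), nrow = 3),
                    otu_ids = c("a", "b", "c"), sample_ids = "S1")
  pa <- presence_absence(ct)
  expect_equal(unname(unclass(pa)[, 1]), c(0, 1, 1))
  expect_equal(unclass(presence_absence(pa)), unclass(pa))
  set.seed(12)
  ct <- random_count_table(10, 5)
  expect_equal(unname(colSums(presence_absence(ct))),
               unname(apply(unclass(ct), 2, otu_richness)))
})

test_that("paired design rejects malformed pairings", {
  md <- toy_metadata(3)
  dup <- as.data.frame(md)
  dup$treatment[2] <- "intact"  # plant P01 now has two intact samples
  expect_error(paired_design(sample_metadata(dup)), "P01")
  mism <- as.data.frame(md)
  mism$elevation[2] <- 999
  expect_error(paired_design(sample_metadata(mism)), "disagree")
})
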