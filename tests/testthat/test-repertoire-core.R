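test_that("clone-table parsing merges duplicates and recomputes frequencies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_airr_fixture(path,
    v = c("TRBV5-1", "TRBV5-1*01"), j = c("TRBJ2-7", "TRBJ2-7"),
    cdr3 = c("CASSLF", "CASSLF"), count = c(10, 5))
  clones <- read_clone_table(path)
  expect_equal(nrow(clones), 1)
  expect_equal(clones$count, 15)
  expect_equal(clones$frequency, 1.0)
  expect_equal(clones$v_gene, "TRBV5-1") # allele stripped for the key

  write_airr_fixture(path,
    v = "TRBV5-1", j = "TRBJ2-7", cdr3 = c("CASSLF", "CASSLY"), count = c(3, 1))
  clones <- read_clone_table(path)
  expect_equal(clones$frequency, c(0.75, 0.25))
})

test_that("invalid rows are dropped with a logged count", {
  # 20-row fixture, 2 invalid CDR3s (lowercase normalizes fine, so use a stop
  # character and an empty junction) -> 18 clones retained
  path <- withr::local_tempfile(fileext = ".tsv")
  cdr3 <- paste0("CASS", strrep("G", 1:20), "F")
  cdr3[7] <- "CASS*RF"
  cdr3[13] <- ""
  write_airr_fixture(path, v = paste0("TRBV", 1:20), j = "TRBJ1-1",
                     cdr3 = cdr3, count = rep(2, 20))
  expect_message(clones <- read_clone_table(path), "dropped 2 of 20")
  expect_equal(nrow(clones), 18)
  expect_equal(sum(clones$frequency), 1, tolerance = 1e-12)

  # all rows invalid -> empty-repertoire error
  write_airr_fixture(path, v = "TRBV1", j = "TRBJ1-1", cdr3 = "CAS*S", count = 1)
  expect_error(suppressMessages(read_clone_table(path)), "no valid clones")
})

test_that("missing required columns are reported by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(v_call = "TRBV1", j_call = "TRBJ1-1", junction_aa = "CASF"),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clone_table(path), "duplicate_count")
})

test_that("write/read round trip preserves keys, counts and frequencies", {
  set.seed(21)
  spec <- cohort_spec(n_clones = 150, read_depth = 20000, seed = 21)
  r <- generate_repertoire(spec, meta = list(
    sample_id = "s", patient_id = "p", treatment = "AHSCT",
    subpopulation = "CD4_memory", timepoint = "t0"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(r, path)
  back <- read_clone_table(path)
  ord <- function(df) df[order(df$v_gene, df$j_gene, df$cdr3_aa), ]
  a <- ord(r$clones); b <- ord(back)
  expect_identical(a$cdr3_aa, b$cdr3_aa)
  expect_identical(as.numeric(a$count), as.numeric(b$count))
  expect_equal(a$frequency, b$frequency, tolerance = 1e-12)
  expect_equal(sum(back$frequency), 1, tolerance = 1e-9)
})

test_that("cohort loading round-trips metadata and enforces contracts", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(n_patients = c(AHSCT = 1, NTZ = 1),
                    subpopulations = list(AHSCT = "CD4_naive", NTZ = "CD8_naive"))
  co <- write_cohort(co, dir)
  loaded <- load_cohort(file.path(dir, "metadata.tsv"), dir)
  expect_s3_class(loaded, "tcr_cohort")
  expect_identical(loaded$metadata$sample_id, co$metadata$sample_id)
  for (id in co$metadata$sample_id) {
    expect_setequal(repertoire_keys(loaded$repertoires[[id]]),
                    repertoire_keys(co$repertoires[[id]]))
  }

  # missing clone table -> error naming the sample
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  md$file_name[1] <- "absent.tsv"
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "metadata.tsv"), dir), md$sample_id[1])

  # invalid treatment -> validation error
  md$file_name[1] <- paste0(md$sample_id[1], ".tsv")
  md$treatment[1] <- "PLACEBO"
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "metadata.tsv"), dir), "treatment")

  # duplicate sample_id -> error
  md$treatment[1] <- "AHSCT"
  md <- rbind(md, md[1, ])
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "metadata.tsv"), dir), "duplicate sample_id")
})

test_that("repertoire summaries count reads and clones and are order invariant", {
  r <- make_repertoire(c(3, 1), cdr3 = c("CASSLF", "CASSLY"))
  s <- summarize_repertoire(r)
  expect_equal(s$n_reads, 4)
  expect_equal(s$n_clones, 2)

  r10 <- make_repertoire(rep(5, 10))
  expect_equal(summarize_repertoire(r10)$shannon_evenness, 1.0)

  rp <- make_freq_repertoire(c(0.7, 0.1, 0.1, 0.1))
  expect_equal(summarize_repertoire(rp)$shannon_evenness, 0.64028212947178464,
               tolerance = 1e-9)

  # permutation invariance of n_reads (and every other summary field)
  set.seed(5)
  counts <- sample(1:50, 20)
  perm <- sample(20)
  cdr3 <- paste0("CAS", strrep("W", 1:20), "F")
  s1 <- summarize_repertoire(make_repertoire(counts, cdr3 = cdr3))
  s2 <- summarize_repertoire(make_repertoire(counts[perm], cdr3 = cdr3[perm]))
  expect_equal(s1[, -1], s2[, -1])
})

test_that("correlate_stats matches the textbook Pearson formula", {
  df <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 4, 6, 8, 10))
  expect_equal(correlate_stats(df, "x", "y"), 1.0)
  df$y <- -df$x
  expect_equal(correlate_stats(df, "x", "y"), -1.0)

  df <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  expect_equal(correlate_stats(df, "x", "y"), 0.6, tolerance = 1e-12)

  set.seed(9)
  df <- data.frame(x = rnorm(25), y = rnorm(25))
  expect_equal(correlate_stats(df, "x", "y"), pearson_oracle(df$x, df$y),
               tolerance = 1e-12)

  # zero variance -> NA with warning, not a crash; NA pairs excluded
  df <- data.frame(x = rep(1, 5), y = 1:5)
  expect_warning(r <- correlate_stats(df, "x", "y"), "zero variance")
  expect_true(is.na(r))
  df <- data.frame(x = c(1, 2, NA, 4), y = c(1, NA, 3, 4))
  expect_warning(correlate_stats(df, "x", "y"), "fewer than 3")
})

test_that("gene usage sums to one under both weightings", {
  r <- make_repertoire(c(3, 1), cdr3 = c("CASSLF", "CASSLY"),
                       v = c("TRBV5-1", "TRBV9"))
  expect_equal(gene_usage(r, "V", weighted = TRUE)$frequency, c(0.75, 0.25))
  expect_equal(gene_usage(r, "V", weighted = FALSE)$frequency, c(0.5, 0.5))
  expect_equal(gene_usage(r, "J")$frequency, 1.0) # single J gene
  set.seed(2)
  rr <- make_repertoire(sample(1:20, 12), cdr3 = paste0("CA", strrep("D", 1:12), "F"),
                        v = sample(c("TRBV1", "TRBV2", "TRBV3"), 12, replace = TRUE))
  expect_equal(sum(gene_usage(rr, "V", weighted = TRUE)$frequency), 1, tolerance = 1e-12)
  expect_equal(sum(gene_usage(rr, "V", weighted = FALSE)$frequency), 1, tolerance = 1e-12)
})
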