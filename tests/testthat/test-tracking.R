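test_that("clonal persistence follows |A∩B| / mean(|A|,|B|) and is symmetric", {
  a <- make_repertoire(rep(1, 10), cdr3 = paste0("CAAA", strrep("G", 1:10), "F"),
                       sample_id = "a")
  expect_equal(clonal_persistence(a, a)$persistence_pct, 100)

  b <- make_repertoire(rep(1, 20), cdr3 = paste0("CTTT", strrep("W", 1:20), "F"),
                       sample_id = "b")
  expect_equal(clonal_persistence(a, b)$persistence_pct, 0)

  # |A| = 10, |B| = 20, 3 shared -> 100 * 3 / 15 = 20
  b3 <- make_repertoire(rep(1, 20),
                        cdr3 = c(paste0("CAAA", strrep("G", 1:3), "F"),
                                 paste0("CTTT", strrep("W", 1:17), "F")),
                        sample_id = "b3")
  res <- clonal_persistence(a, b3)
  expect_equal(res$n_shared, 3)
  expect_equal(res$persistence_pct, 20.0)
  rev <- clonal_persistence(b3, a)
  expect_identical(res$persistence_pct, rev$persistence_pct)
  expect_identical(res$n_shared, rev$n_shared)

  # different V gene breaks the clone key even with identical CDR3s
  a2 <- make_repertoire(rep(1, 10), cdr3 = paste0("CAAA", strrep("G", 1:10), "F"),
                        v = "TRBV9", sample_id = "a2")
  expect_equal(clonal_persistence(a, a2)$persistence_pct, 0)
})

test_that("persistence tables pair t0 with t24 per patient and skip incomplete patients", {
  co <- tiny_cohort()
  tbl <- persistence_table(co)
  # 4 patients x (2 subpops x 2 subpops) pairings
  expect_equal(nrow(tbl), 16)
  expect_true(all(tbl$persistence_pct >= 0 & tbl$persistence_pct <= 100))
  matched <- persistence_table(co, "matched_subpopulation")
  expect_equal(nrow(matched), 8)
  # generator injects rho = 0.2 exactly on the matched diagonal
  expect_equal(matched$persistence_pct, rep(20, 8))

  # drop one patient's t24 samples -> rows skipped with a log entry
  keep <- !(co$metadata$patient_id == "MS01" & co$metadata$timepoint == "t24")
  co2 <- as_cohort(co$repertoires[co$metadata$sample_id[keep]])
  expect_message(tbl2 <- persistence_table(co2), "MS01")
  expect_equal(nrow(tbl2), 12)

  # invariant to sample ordering
  co3 <- as_cohort(rev(co$repertoires))
  tbl3 <- persistence_table(co3)
  key <- function(t) t[order(t$sample_a, t$sample_b), "persistence_pct"]
  expect_equal(key(tbl3), key(tbl))
})

test_that("publicity classification applies the >= 2 repertoires rule", {
  r1 <- make_repertoire(c(1, 1), cdr3 = c("CASSLF", "CAAAGF"), sample_id = "s1",
                        patient_id = "p1")
  r2 <- make_repertoire(c(1, 1), cdr3 = c("CASSLF", "CTTTWF"), sample_id = "s2",
                        patient_id = "p2")
  r3 <- make_repertoire(1, cdr3 = "CWWWPF", sample_id = "s3", patient_id = "p1")
  co <- as_cohort(list(r1, r2, r3))
  pub <- classify_publicity(co)
  expect_identical(pub$publicity[pub$cdr3_aa == "CASSLF"], "public")
  expect_identical(pub$publicity[pub$cdr3_aa == "CAAAGF"], "private")
  expect_identical(pub$publicity, ifelse(pub$n_sharing >= 2, "public", "private"))

  # patient-level sharing: two samples of one patient stay private
  r4 <- make_repertoire(1, cdr3 = "CWWWPF", sample_id = "s4", patient_id = "p1")
  co2 <- as_cohort(list(r1, r2, r3, r4))
  by_sample <- classify_publicity(co2, "sample")
  by_patient <- classify_publicity(co2, "patient")
  expect_identical(by_sample$publicity[by_sample$cdr3_aa == "CWWWPF"], "public")
  expect_identical(by_patient$publicity[by_patient$cdr3_aa == "CWWWPF"], "private")
})

test_that("per-sample public-clone stats cover the degenerate cohorts", {
  cdr3 <- paste0("CASS", strrep("A", 1:5), "F")
  same <- lapply(1:3, function(i) {
    make_repertoire(rep(1, 5), cdr3 = cdr3, sample_id = paste0("s", i),
                    patient_id = paste0("p", i))
  })
  st <- public_clone_stats(as_cohort(same))
  expect_equal(st$pct_public, rep(100, 3))

  disjoint <- lapply(1:3, function(i) {
    make_repertoire(rep(1, 5), cdr3 = paste0("C", strrep(c("A", "G", "W")[i], 3),
                                             strrep("G", 1:5), "F"),
                    sample_id = paste0("s", i), patient_id = paste0("p", i))
  })
  st2 <- public_clone_stats(as_cohort(disjoint))
  expect_equal(st2$pct_public, rep(0, 3))

  # one clone shared by samples 1 and 2 only -> sample 3 has zero public clones
  mixed <- disjoint
  mixed[[1]] <- make_repertoire(rep(1, 5), cdr3 = c("CASSLF", paste0("CAAA", strrep("G", 1:4), "F")),
                                sample_id = "s1", patient_id = "p1")
  mixed[[2]] <- make_repertoire(rep(1, 5), cdr3 = c("CASSLF", paste0("CTTT", strrep("G", 1:4), "F")),
                                sample_id = "s2", patient_id = "p2")
  st3 <- public_clone_stats(as_cohort(mixed))
  expect_equal(st3$n_public[st3$sample_id == "s1"], 1)
  expect_equal(st3$n_public[st3$sample_id == "s3"], 0)

  # publicity classes partition each sample's clones
  co <- tiny_cohort()
  pub <- classify_publicity(co)
  st4 <- public_clone_stats(co, publicity = pub)
  pub_keys <- with(pub, paste(v_gene, j_gene, cdr3_aa, sep = "|"))[pub$publicity == "public"]
  for (id in st4$sample_id[1:4]) {
    keys <- repertoire_keys(co$repertoires[[id]])
    n_private <- sum(!(keys %in% pub_keys))
    expect_equal(n_private + st4$n_public[st4$sample_id == id],
                 st4$n_clones[st4$sample_id == id])
  }
})

test_that("highly shared clones respect the threshold monotonically", {
  co <- tiny_cohort()  # 16 samples, pool injected cyclically
  hs_all <- highly_shared_clones(co, min_samples = 2)
  expect_true(all(hs_all$records$n_sharing >= 2))
  expect_equal(unname(rowSums(hs_all$presence)),
               unname(vapply(strsplit(hs_all$records$sample_ids, ","), length, integer(1))))

  hs_hi <- highly_shared_clones(co, min_samples = 5)
  keyify <- function(rec) paste(rec$v_gene, rec$j_gene, rec$cdr3_aa)
  expect_true(all(keyify(hs_hi$records) %in% keyify(hs_all$records)))

  hs_none <- highly_shared_clones(co, min_samples = nrow(co$metadata) + 1)
  expect_equal(nrow(hs_none$records), 0)
})
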