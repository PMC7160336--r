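mcpas_fixture <- function(path) {
  df <- data.frame(
    CDR3.beta.aa = c("CASSLF", "CASSLF", "CASSQETQYF", "CSARDRTGNGYTF", "cassx!"),
    Pathology = c("Influenza", "Epstein Barr virus (EBV)", "Multiple sclerosis (MS)",
                  "Cytomegalovirus (CMV)", "Influenza"),
    TRBV = c("TRBV5-1", "TRBV5-1", "TRBV6-5*01", "TRBV20-1", "TRBV9"),
    TRBJ = c("TRBJ2-7", "TRBJ2-7", "TRBJ2-5", "TRBJ1-2", "TRBJ1-1"),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("database loading collapses duplicates and unions categories", {
  # 5-row fixture: one duplicate CDR3 under two categories, one invalid CDR3
  path <- withr::local_tempfile(fileext = ".csv")
  mcpas_fixture(path)
  expect_message(db <- load_db(path, "mcpas"), "dropped 1 of 5")
  expect_equal(nrow(db), 3)
  dup <- db[db$cdr3_aa == "CASSLF", ]
  expect_equal(strsplit(dup$category, ";")[[1]],
               sort(c("Influenza", "Epstein Barr virus (EBV)")))
  expect_identical(db$j_gene[db$cdr3_aa == "CASSQETQYF"], "TRBJ2-5")
  expect_identical(db$v_gene[db$cdr3_aa == "CASSQETQYF"], "TRBV6-5") # allele stripped

  # vdjdb layout with TRB filtering
  vpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("TRB", "TRA", "TRB"),
                         cdr3 = c("CASSLF", "CAVRDF", "CSARDF"),
                         antigen.species = c("CMV", "CMV", "EBV"),
                         v.segm = c("TRBV5-1*01", "TRAV1", "TRBV20-1"),
                         j.segm = c("TRBJ2-7", "TRAJ3", "TRBJ1-2")),
              vpath, sep = "\t", quote = FALSE, row.names = FALSE)
  vdb <- load_db(vpath, "vdjdb")
  expect_equal(nrow(vdb), 2)
  expect_true(all(grepl("^TRBV", vdb$v_gene)))

  # bare CDR3 list with a supplied category
  lpath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CASSLF", "CWWWGF", "CASSLF"), lpath)
  ldb <- load_db(lpath, "cdr3_list", category = "MS_literature")
  expect_equal(nrow(ldb), 2)
  expect_identical(unique(ldb$category), "MS_literature")

  # zero valid records -> error
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("x1", "??"), bad)
  expect_error(suppressMessages(load_db(bad, "cdr3_list")), "no valid")
})

test_that("repertoire-database overlap counts distinct matched clones", {
  path <- withr::local_tempfile(fileext = ".csv")
  mcpas_fixture(path)
  db <- suppressMessages(load_db(path, "mcpas"))

  # 10-clone repertoire with 3 CDR3s planted in the db -> 30%
  cdr3 <- c("CASSLF", "CASSQETQYF", "CSARDRTGNGYTF",
            paste0("CAAA", strrep("G", 1:7), "F"))
  r <- make_repertoire(rep(2, 10), cdr3 = cdr3)
  ov <- match_repertoire(r, db)
  expect_equal(ov$summary$n_overlap, 3)
  expect_equal(ov$summary$pct_overlap, 30.0)
  expect_setequal(ov$per_category$category,
                  c("Influenza", "Epstein Barr virus (EBV)",
                    "Multiple sclerosis (MS)", "Cytomegalovirus (CMV)"))

  # subset / disjoint limits
  rsub <- make_repertoire(c(1, 1), cdr3 = c("CASSLF", "CASSQETQYF"))
  expect_equal(match_repertoire(rsub, db)$summary$pct_overlap, 100.0)
  rnone <- make_repertoire(c(1, 1), cdr3 = c("CTTTWF", "CPPPPF"))
  expect_equal(match_repertoire(rnone, db)$summary$n_overlap, 0)

  # strict V-CDR3-J matching is at most as permissive as CDR3 matching
  rv <- make_repertoire(c(1, 1), cdr3 = c("CASSLF", "CASSQETQYF"), v = "TRBV14")
  expect_equal(match_repertoire(rv, db, match_on = "v_cdr3_j")$summary$n_overlap, 0)
  expect_equal(match_repertoire(rv, db, match_on = "cdr3")$summary$n_overlap, 2)

  # overlap never exceeds species richness; duplicate db rows change nothing
  db2 <- suppressMessages(load_db(path, "mcpas"))
  expect_identical(match_repertoire(r, rbind(db2, db2))$summary$n_overlap,
                   ov$summary$n_overlap)
})

test_that("per-category cohort tables plant explicit zeros and ignore row order", {
  co <- tiny_cohort()
  planted <- "CASSTEVPLANTF"
  # plant an EBV-labelled CDR3 into half the samples via a fresh cohort copy
  reps <- co$repertoires
  hit <- names(reps)[seq(1, length(reps), by = 2)]
  for (id in hit) {
    cl <- reps[[id]]$clones
    cl <- rbind(cl[, c("v_gene", "j_gene", "cdr3_aa", "count")],
                data.frame(v_gene = "TRBV9", j_gene = "TRBJ1-1",
                           cdr3_aa = planted, count = 1))
    reps[[id]] <- repertoire(cl, reps[[id]]$sample_id, reps[[id]]$patient_id,
                             reps[[id]]$treatment, reps[[id]]$subpopulation,
                             reps[[id]]$timepoint)
  }
  co2 <- as_cohort(reps)
  dbpath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(CDR3.beta.aa = c(planted, "CNOMATCHF"),
                       Pathology = c("EBV", "CMV"),
                       TRBV = "TRBV9", TRBJ = "TRBJ1-1"),
            dbpath, row.names = FALSE, quote = FALSE)
  db <- load_db(dbpath, "mcpas")
  tbl <- overlap_by_category(co2, db)
  ebv <- tbl[tbl$category == "EBV", ]
  expect_equal(sort(ebv$sample_id[ebv$n == 1]), sort(hit))
  expect_true(all(ebv$n[!(ebv$sample_id %in% hit)] == 0))
  expect_true(all(tbl$n[tbl$category == "CMV"] == 0))

  # invariance to db row order
  tbl2 <- overlap_by_category(co2, db[rev(seq_len(nrow(db))), ])
  expect_equal(tbl[order(tbl$sample_id, tbl$category), "n"],
               tbl2[order(tbl2$sample_id, tbl2$category), "n"])
})
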