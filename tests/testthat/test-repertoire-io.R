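test_that("AIRR TSV reads one record per contig row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- rbind(good_cell("c1"), good_cell("c2"))
  utils::write.table(
    data.frame(cell_id = df$cell_id, locus = df$locus,
               sequence_aa = df$sequence_aa, germline_alignment_aa = df$germline_aa,
               v_call = df$v_call, c_call = df$c_call, cdr3_aa = df$cdr3_aa,
               cdr3_start = df$cdr3_start, cdr3_end = df$cdr3_end),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_repertoire(f, "airr_tsv")
  expect_equal(nrow(rec), 4)
  expect_setequal(rec$locus, c("heavy", "light"))
})

test_that("contig CSV 1-based inclusive spans convert to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".csv")
  # CDR3 "DEF" sits at 1-based inclusive positions 3..5 of "ACDEFGHIKL",
  # i.e. 0-based half-open [2, 5)
  utils::write.csv(
    data.frame(barcode = "b1", chain = "IGH", sequence_aa = "ACDEFGHIKL",
               germline_aa = "ACDEFGHIKL", v_gene = "IGHV1-1*01",
               c_gene = "IGHM", cdr3 = "DEF", cdr3_start = 3, cdr3_end = 5),
    f, row.names = FALSE)
  rec <- read_repertoire(f, "contig_csv")
  expect_equal(rec$cdr3_start, 2L)
  expect_equal(rec$cdr3_end, 5L)
  expect_equal(substr(rec$sequence_aa, rec$cdr3_start + 1, rec$cdr3_end), "DEF")
})

test_that("empty file with header gives an empty record set", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("cell_id", "locus", "sequence_aa", "germline_alignment_aa",
                     "v_call", "c_call", "cdr3_aa"), collapse = "\t"), f)
  expect_equal(nrow(read_repertoire(f, "airr_tsv")), 0)
})

test_that("missing required columns are a hard error naming the column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cell_id\tlocus", f)
  expect_error(read_repertoire(f, "airr_tsv"), "sequence_aa")
})

test_that("non-canonical sequences and bad CDR3 coordinates are skipped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    cell_id = c("c1", "c2", "c3"), locus = "IGH",
    sequence_aa = c("ACDEFGHIKL", "ACDXFGHIKL", "ACDEFGHIKL"),
    germline_alignment_aa = "ACDEFGHIKL", v_call = "IGHV1-1*01",
    c_call = "IGHM", cdr3_aa = c("DEF", "DEF", "WWW"),
    cdr3_start = 2, cdr3_end = 5)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(rec <- read_repertoire(f, "airr_tsv"), "skipped")
  expect_equal(rec$cell_id, "c1")
  expect_equal(attr(rec, "dropped")[["non_canonical"]], 1L)
  expect_equal(attr(rec, "dropped")[["cdr3_mismatch"]], 1L)
})

test_that("filter rules remove the right cells and the log reconciles", {
  rep <- filter_cells(filter_fixture())
  log <- rep$filter_log
  expect_equal(unname(log["multi_transcript"]), 1L)
  expect_equal(unname(log["incomplete"]), 1L)
  expect_equal(unname(log["no_germline"]), 1L)
  expect_equal(unname(log["no_heavy_cgene"]), 1L)
  expect_equal(unname(log["duplicated_barcode"]), 2L)
  expect_equal(attr(log, "n_input"), 12L)
  expect_equal(attr(log, "n_retained"), 6L)
  expect_equal(sum(log) + attr(log, "n_retained"), attr(log, "n_input"))
  expect_setequal(rep$cells$cell_id, sprintf("c%02d", 1:6))
  # isotypes collapse subclasses
  expect_setequal(unique(rep$cells$isotype), c("IgM", "IgG", "IgA"))
})

test_that("an all-filtered repertoire is valid and empty", {
  rep <- filter_cells(chain_row("only", "heavy"))
  expect_equal(nrow(rep$cells), 0)
  expect_equal(unname(rep$filter_log["incomplete"]), 1L)
})

test_that("clonotyping groups by V family and CDR3 identity, or trusts input", {
  rows <- rbind(good_cell("a", seq_h = "ACDEFGHIKL"),
                good_cell("b", seq_h = "ACDEFGHIKL"),
                good_cell("d", seq_h = "ACWWWGHIKL"))
  rep <- filter_cells(rows)
  cl <- rep$cells$clone_id
  expect_equal(cl[1], cl[2])   # identical CDR3 -> same clone
  expect_false(cl[1] == cl[3]) # mutated CDR3 -> split
  rows$clone_id <- "truth1"
  rep2 <- filter_cells(rows, clonotype = "input_clone_id")
  expect_true(all(rep2$cells$clone_id == "truth1"))
  rows$clone_id <- NULL
  expect_error(filter_cells(rows, clonotype = "input_clone_id"), "clone_id")
})

test_that("hamming_shm counts mismatches and excludes indel cells", {
  expect_equal(hamming_shm("ACDE", "ACDE"), 0L)
  expect_equal(hamming_shm("ACDE", "ACDY"), 1L)
  expect_true(is.na(hamming_shm("ACDE", "ACD")))
  # symmetry and identity on random pairs
  set.seed(55)
  for (i in 1:20) {
    a <- paste(sample(aa_alphabet(), 15, replace = TRUE), collapse = "")
    b <- paste(sample(aa_alphabet(), 15, replace = TRUE), collapse = "")
    expect_equal(hamming_shm(a, b), hamming_shm(b, a))
    expect_equal(hamming_shm(a, a), 0L)
  }
})

test_that("simulated SHM equals the truth count when no position mutated twice", {
  sim <- quick_sim(n_cells = 100, seed = 59)
  hv <- sim$chains[sim$chains$locus == "heavy", ]
  ev <- sim$truth$substitutions
  shm <- hamming_shm(hv$sequence_aa, hv$germline_aa)
  for (i in seq_len(nrow(hv))) {
    e <- ev[ev$cell_id == hv$cell_id[i] & ev$locus == "heavy", ]
    if (!anyDuplicated(e$position)) expect_equal(shm[i], nrow(e))
  }
})

test_that("v_family parses families and flags unknowns", {
  expect_equal(v_family("IGHV1-26*01"), "IGHV1")
  expect_equal(v_family("IGHV7"), "IGHV7")
  expect_equal(v_family("IGKV10-96*02"), "IGKV10")
  expect_equal(v_family("foo"), "unknown")
})

test_that("normalized expansion sums to one over clones", {
  sim <- quick_sim(n_cells = 100, seed = 61)
  rep <- filter_cells(sim$chains, clonotype = "input_clone_id")
  ex <- normalized_expansion(rep)
  expect_equal(sum(ex), 1)
  expect_true(all(ex > 0 & ex <= 1))
  # forced arithmetic: a 5-cell clone in a 100-cell sample
  sizes <- table(rep$cells$clone_id)
  expect_equal(unname(ex[names(sizes)[1]]), unname(sizes[1]) / 100)
  empty <- structure(list(cells = data.frame()), class = "bcr_repertoire")
  expect_error(normalized_expansion(empty), "empty")
})

test_that("filtered repertoires round-trip through the AIRR writer", {
  sim <- quick_sim(n_cells = 20, seed = 67)
  rep <- filter_cells(sim$chains)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(rep, f)
  back <- filter_cells(read_repertoire(f, "airr_tsv"))
  expect_equal(nrow(back$cells), nrow(rep$cells))
  expect_setequal(back$chains$sequence_aa, rep$chains$sequence_aa)
  j <- withr::local_tempfile(fileext = ".json")
  write_filter_report(rep, j)
  rpt <- jsonlite::read_json(j)
  expect_equal(rpt$n_retained, nrow(rep$cells))
})
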