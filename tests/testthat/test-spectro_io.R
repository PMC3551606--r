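test_that("read_trace parses, sorts and infers units by kind", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# a comment", "4,-5.1", "6,-5.0", "8,-4.9", "10,-4.8",
               "12,-4.7"), f)
  tr <- read_trace(f, "melt")
  expect_equal(tr$x, c(4, 6, 8, 10, 12))
  expect_equal(tr$x_unit, "degC")
  expect_equal(tr$y_unit, "mdeg")

  # shuffled rows come back sorted by x
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("12,-4.7", "4,-5.1", "8,-4.9", "6,-5.0", "10,-4.8"), f2)
  tr2 <- read_trace(f2, "melt")
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$y, tr$y)

  # tab-delimited with a header line parses identically
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tsignal", "0\t1", "10\t2", "20\t3", "30\t4", "40\t5",
               ""), f3)
  tr3 <- read_trace(f3, "progress")
  expect_equal(tr3$x, seq(0, 40, 10))
  expect_equal(tr3$x_unit, "s")
})

test_that("read_trace rejects malformed tables with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "2,3", "3,oops", "4,5", "5,6"), f)
  expect_error(read_trace(f, "melt"), "row 3")
  writeLines(c("1,2", "2,3", "2,4", "4,5", "5,6"), f)
  expect_error(read_trace(f, "melt"), "duplicate")
  writeLines(c("1,2", "2,3", "3,4"), f)
  expect_error(read_trace(f, "melt"), "fewer than 5")
  expect_error(read_trace(file.path(tempdir(), "nope.csv"), "melt"),
               "not found")
})

test_that("trace write/read round-trip is lossless to 1e-9", {
  curve <- gen_melt(dH = 40, Tm_c = 58, noise_frac = 0.03, seed = 2)
  tr <- structure(list(x = curve$temperature_c, y = curve$signal,
                       x_unit = "degC", y_unit = "mdeg"), class = "raw_trace")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f, "melt")
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(back$y, tr$y, tolerance = 1e-9)
})

test_that("FASTA reading matches an independent line-concatenation parse", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "WAAYAAAF", ">s2", "mkv", "lqw"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("s1", "s2"))
  expect_equal(recs$sequence[1], "WAAYAAAF")
  # independent parse: concatenate body lines, upper-case
  lines <- readLines(f)
  expect_equal(recs$sequence[2], toupper(paste0(lines[4], lines[5])))
  expect_false(any(recs$has_gaps))

  g <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">aln", "WA-AY*"), g)
  expect_true(read_fasta(g)$has_gaps)

  e <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), e)
  expect_error(read_fasta(e), "empty|parse")
  b <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "WA1Y"), b)
  expect_error(read_fasta(b), "bad")
})

test_that("FASTA write/read round-trip preserves records", {
  seqs <- gen_sequences(5, 120, seed = 31)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back$id, seqs$id)
  expect_equal(back$sequence, seqs$sequence)
})

test_that("variant names parse into mutation records", {
  v <- variant_record("C72S/W9A", background = "C72S")
  expect_equal(v$mutations$pos, c(72L, 9L))
  expect_equal(v$mutations$wt, c("C", "W"))
  expect_equal(v$mutations$mut, c("S", "A"))
  expect_equal(nrow(variant_record("WT")$mutations), 0)
  expect_error(variant_record("C72S/C72A"), "duplicate")
  expect_error(variant_record("C72"), "malformed")
  expect_error(variant_record(""), "non-empty")
})

test_that("results table writes the declared schema and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # empty input: header-only file
  write_results_table(data.frame(), f)
  expect_equal(length(readLines(f)), 1L)
  hdr <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(hdr[1:3], c("variant", "pH4_helicity_note", "Tm_C"))

  row <- data.frame(variant = "C72S", Tm_C = 58.012345, MEWD_nm = 10,
                    residual_activity_pct = 14.7)
  write_results_table(row, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  back <- read_results_table(f)
  expect_equal(back$Tm_C, 58.012345)
  expect_equal(back$MEWD_nm, 10)
  expect_equal(back$residual_activity_pct, 14.7)
  expect_true(is.na(back$lambda_max_pH4))  # missing fields written as NA
})
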