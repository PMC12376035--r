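test_that("output names follow the label-joining convention", {
  sch <- default_scheme()
  labs <- c("D05", "C12", "B01", "A20")
  cl <- classify_read(paste0(make_string(sch, labs), strrep("T", 60)), sch)
  expect_identical(output_name(cl, "run"), "D05_C12_B01_A20.fastq")
  clp <- classify_read(paste0(make_string(sch, c(labs[1:3], NA)),
                              strrep("T", 60)), sch)
  expect_identical(output_name(clp, "run"), "D05_C12_B01____.fastq")
  clb <- classify_read(strrep("T", 80), sch)
  expect_identical(output_name(clb, "run"), "run_0_1.fastq")
})

test_that("trim_read removes the detected string(s) exactly", {
  sch <- default_scheme()
  labs <- c("D05", "C12", "B01", "A20")
  s <- make_string(sch, labs)          # 44 nt
  mk <- function(seq) list(id = "r", seq = seq,
                           qual = strrep("I", nchar(seq)))
  # direct string ends at 44 in a 100 nt read -> positions 45..100 remain
  r1 <- paste0(s, strrep("T", 56))
  t1 <- trim_read(mk(r1), classify_read(r1, sch))
  expect_identical(nchar(t1$seq), 56L)
  expect_identical(t1$seq, strrep("T", 56))
  expect_identical(nchar(t1$qual), 56L)
  # strings on both ends of a 100 nt read -> 100 - 44 - 44 = 12 remain
  r2 <- paste0(s, strrep("T", 12), reverse_complement(s))
  t2 <- trim_read(mk(r2), classify_read(r2, sch))
  expect_identical(nchar(t2$seq), 12L)
  # bulk reads are untouched
  r3 <- strrep("T", 80)
  t3 <- trim_read(mk(r3), classify_read(r3, sch))
  expect_identical(t3$seq, r3)
  # adapter residue before the string is removed by default, kept on demand
  r4 <- paste0(strrep("G", 10), s, strrep("T", 46))
  cl4 <- classify_read(r4, sch)
  expect_identical(trim_read(mk(r4), cl4)$seq, strrep("T", 46))
  expect_identical(trim_read(mk(r4), cl4, keep_adapter_residue = TRUE)$seq,
                   paste0(strrep("G", 10), strrep("T", 46)))
  # degenerate trim (string covers the whole read) is refused
  t5 <- trim_read(mk(s), classify_read(s, sch))
  expect_true(t5$degenerate)
  expect_identical(t5$seq, s)
})

test_that("the 6-read fixture routes 2+1+1 named, 1 combined, 2 bulk", {
  dir <- withr::local_tempdir()
  fx <- six_read_fixture(dir)
  out <- file.path(dir, "out")
  res <- demultiplex(fx$path, fx$scheme, out)
  a <- res$accounting
  expect_identical(a$total_reads, 6L)
  expect_identical(sum(a$per_category_counts), 6L)
  expect_identical(a$per_category_counts[["complete"]], 3L)
  expect_identical(a$per_category_counts[["partial_3"]], 1L)
  expect_identical(a$per_category_counts[["bulk_0_1"]], 2L)
  expect_identical(a$conflict_count, 1L)
  named <- setdiff(names(a$per_file_counts),
                   c("fixture6_0_1.fastq"))
  expect_length(named, 3L)
  expect_identical(a$per_file_counts[[fx$complete_name]], 2L)
  expect_identical(a$per_file_counts[[fx$conflict_name]], 1L)
  expect_identical(a$per_file_counts[[fx$partial_name]], 1L)
  expect_identical(a$per_file_counts[["fixture6_0_1.fastq"]], 2L)
  # combined partial file holds the one partial read
  comb <- read_fastq_file(file.path(out, "fixture6_3_2.fastq"))
  expect_identical(comb$id, "fix4")
  # written records keep ids and matched seq/qual lengths
  for (f in names(a$per_file_counts)) {
    rec <- read_fastq_file(file.path(out, f))
    expect_identical(nchar(rec$seq), nchar(rec$qual))
  }
})

test_that("empty FASTQ gives empty accounting and no files", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "empty.fastq")
  file.create(fq)
  out <- file.path(dir, "out")
  res <- demultiplex(fq, default_scheme(), out)
  expect_identical(res$accounting$total_reads, 0L)
  expect_length(res$accounting$per_file_counts, 0L)
  expect_length(list.files(out), 0L)
})

test_that("truncated and malformed FASTQ records report the record index", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  expect_error(demultiplex(fq, default_scheme(), file.path(dir, "o")),
               "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)  # qual length mismatch
  expect_error(demultiplex(fq, default_scheme(), file.path(dir, "o")),
               "record 1")
})

test_that("error-free complete reads over 10 combinations land in 10 files", {
  sch <- default_scheme()
  set.seed(5)
  combos <- replicate(10, vapply(1:4, function(i)
    sample(sch$sets[[i]]$well, 1), ""), simplify = FALSE)
  n <- 1000L
  pick <- sample(10, n, replace = TRUE)
  seqs <- vapply(pick, function(k)
    paste0(make_string(sch, combos[[k]]), strrep("T", 60)), "")
  dir <- withr::local_tempdir()
  fq <- write_fastq_file(file.path(dir, "runs.fastq"),
                         sprintf("r%04d", 1:n), seqs)
  res <- demultiplex(fq, sch, file.path(dir, "out"))
  pf <- res$accounting$per_file_counts
  expect_length(pf, 10L)
  expect_identical(sum(pf), n)
  expect_identical(res$accounting$per_category_counts[["complete"]], n)
  for (k in 1:10) {
    f <- paste0(paste(combos[[k]], collapse = "_"), ".fastq")
    expect_identical(pf[[f]], sum(pick == k))
  }
})

test_that("conservation and trim consistency hold on a synthetic run", {
  sch <- default_scheme()
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "mix.fastq")
  sim <- simulate_reads(sim_config(sch, n_reads = 400, seed = 99), fq)
  out <- file.path(dir, "out")
  res <- demultiplex(fq, sch, out)
  a <- res$accounting
  expect_identical(a$total_reads, 400L)
  expect_identical(sum(a$per_category_counts), 400L)
  # conservation: named + bulk file record counts equal the input count
  files <- setdiff(list.files(out, pattern = "\\.fastq$"), "mix_3_2.fastq")
  recs <- lapply(file.path(out, files), read_fastq_file)
  ids <- unlist(lapply(recs, `[[`, "id"))
  expect_length(ids, 400L)
  expect_false(anyDuplicated(ids) > 0)   # no read duplicated across/within
  # per-file counts match what is on disk
  on_disk <- vapply(recs, function(r) length(r$id), integer(1))
  expect_identical(stats::setNames(on_disk, files)[names(a$per_file_counts)],
                   a$per_file_counts)
  # trim consistency: trimmed + removed == original, for every read
  orig <- read_fastq_file(fq)
  orig_len <- stats::setNames(nchar(orig$seq), orig$id)
  for (r in recs) {
    stopifnot(length(r$id) > 0)
    expect_true(all(nchar(r$seq) <= orig_len[r$id]))
    expect_identical(nchar(r$seq), nchar(r$qual))
  }
  dg <- res$reads
  trimmed_len <- orig_len[dg$read_id] -
    ifelse(is.na(dg$direct_last_end) | dg$category == "bulk_0_1" |
             dg$direct_n < 2, 0L, dg$direct_last_end) -
    ifelse(is.na(dg$reverse_last_end) | dg$category == "bulk_0_1" |
             dg$reverse_n < 2, 0L, dg$reverse_last_end)
  disk_len <- stats::setNames(unlist(lapply(recs, function(r) nchar(r$seq))),
                              ids)
  expect_identical(unname(disk_len[dg$read_id]), unname(trimmed_len))
})

test_that("gzip input and output round-trip", {
  sch <- default_scheme()
  labs <- c("D02", "C03", "B04", "A05")
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "in.fastq.gz")
  con <- gzfile(fq, "wt")
  writeLines(c("@g1", paste0(make_string(sch, labs), strrep("T", 30)),
               "+", strrep("I", 74)), con)
  close(con)
  out <- file.path(dir, "out")
  res <- demultiplex(fq, sch, out, gzip_output = TRUE)
  expect_identical(res$stem, "in")
  f <- file.path(out, paste0(paste(labs, collapse = "_"), ".fastq.gz"))
  expect_true(file.exists(f))
  rec <- read_fastq_file(f)
  expect_identical(rec$id, "g1")
  expect_identical(rec$seq, strrep("T", 30))
})

test_that("dry run classifies without writing per-cell files", {
  dir <- withr::local_tempdir()
  fx <- six_read_fixture(dir)
  out <- file.path(dir, "dry")
  res <- demultiplex(fx$path, fx$scheme, out, dry_run = TRUE)
  expect_identical(res$accounting$total_reads, 6L)
  expect_false(dir.exists(out))
})
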