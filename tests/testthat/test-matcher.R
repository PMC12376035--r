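test_that("reverse_complement handles ACGTN and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement("GATTN"), "NAATC")
  expect_identical(reverse_complement(""), "")
  expect_error(reverse_complement("ACGU"), "non-ACGTN")
  set.seed(11)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                 replace = TRUE), collapse = ""), "")
  expect_identical(reverse_complement(reverse_complement(seqs)), seqs)
  # against the Biostrings reference (N-free; oracle route)
  seqs2 <- gsub("N", "A", seqs)
  expect_identical(reverse_complement(seqs2),
                   vapply(seqs2, o_revcomp, "", USE.NAMES = FALSE))
})

test_that("find_nearest_match returns the smallest in-window start", {
  sch <- two_set_scheme()
  D <- sch$sets$D
  # spec coordinates are 0-based [0,12); here 1-based window 1..12
  m <- find_nearest_match("TTAAAAAAAATT", D, 1, 12)
  expect_equal(m[c("well_label", "start", "end")],
               list(well_label = "D1", start = 3L, end = 10L))
  expect_null(find_nearest_match("GGGGGGGG", D, 1, 8))
  m2 <- find_nearest_match("CCCCCCCCAAAAAAAA", D, 1, 16)
  expect_equal(m2$well_label, "D2")   # nearest wins over D1 at 9
  expect_equal(m2$start, 1L)
  # bound excludes matches that do not fit
  expect_null(find_nearest_match("TTAAAAAAAATT", D, 1, 9))
  expect_null(find_nearest_match("TTAAAAAAAATT", D, 4, 12))
})

test_that("scan_end builds chained strings with linkers and categories", {
  sch <- two_set_scheme()
  # complete: D1 + 4 nt linker + A1 + padding
  r <- paste0("AAAAAAAA", "TTTT", "GGGGGGGG", strrep("C", 20))
  bs <- scan_end(r, sch)
  expect_identical(bs$category, "complete")
  expect_identical(bs$linkers, 4L)
  expect_identical(bs$last_end, 20L)
  expect_identical(bs$labels, c("D1", "A1"))
  # empty (no 8-mer of the scheme present)
  expect_identical(scan_end(strrep("AG", 20), sch)$category, "empty")
  # reads shorter than one barcode are empty
  expect_identical(scan_end("ACG", sch)$category, "empty")
  # 3 nt shrunken linker is detected and reported
  r3 <- paste0("AAAAAAAA", "TTT", "GGGGGGGG", strrep("C", 20))
  expect_identical(scan_end(r3, sch)$linkers, 3L)
  # 1 nt overlap via default slack: linker -1 (barcodes share the C at pos 4)
  sov <- barcode_scheme(
    list(D = data.frame(well = "D1", sequence = "AACC"),
         A = data.frame(well = "A1", sequence = "CGGT")),
    barcodes_per_set = 1, barcode_length = 4, linker_length = 4,
    search_window = 16)
  rov <- paste0("AACCGGT", strrep("A", 12))
  bov <- scan_end(rov, sov)
  expect_identical(bov$linkers, -1L)
  expect_identical(bov$category, "complete")
  # slack 0 forbids the overlap
  expect_identical(scan_end(rov, sov, overlap_slack = 0)$n_found, 1L)
})

test_that("scan_end skip and restart behaviour on a 4-set scheme", {
  sch <- default_scheme()
  labs <- c("D01", "C05", "B09", "A13")
  # interior set C absent -> skipped with skipped_sets = 2
  s <- make_string(sch, c(labs[1], NA, labs[3], labs[4]))
  b <- scan_end(paste0(s, strrep("T", 50)), sch)
  expect_identical(b$category, "skipped")
  expect_identical(b$skipped_sets, 2L)
  expect_identical(b$n_found, 3L)
  # leading set D absent -> restart with C: sequential C-B-A
  s2 <- make_string(sch, c(NA, labs[2], labs[3], labs[4]))
  b2 <- scan_end(paste0(s2, strrep("T", 50)), sch)
  expect_identical(b2$category, "incomplete_sequential")
  expect_identical(b2$labels, c(NA, labs[2:4]))
  # mixed linkers 3,4,4 -> complete, string ends at 43
  s3 <- make_string(sch, labs, linkers = c(3, 4, 4))
  b3 <- scan_end(paste0(s3, strrep("T", 50)), sch)
  expect_identical(b3$category, "complete")
  expect_identical(b3$linkers, c(3L, 4L, 4L))
  expect_identical(b3$last_end, 43L)
  # exactness: one substitution in every D occurrence -> no set-1 match
  d_mut <- sub("^.", ifelse(substr(bc_of(sch, 1, "D01"), 1, 1) == "A",
                            "C", "A"), bc_of(sch, 1, "D01"))
  b4 <- scan_end(paste0(d_mut, strrep("T", 60)), sch)
  expect_true(is.null(b4$slots[[1]]))
})

test_that("classify_read merges both ends by the priority ladder", {
  sch <- default_scheme()
  labX <- c("D01", "C02", "B03", "A04")
  labY <- c("D05", "C06", "B07", "A08")
  ins <- strrep("T", 60)
  sX <- make_string(sch, labX)
  # complete on the direct end only
  cl <- classify_read(paste0(sX, ins), sch)
  expect_identical(cl$category, "complete")
  expect_identical(cl$origin, "direct")
  expect_identical(cl$naming_labels, labX)
  expect_identical(cl$reverse$category, "empty")
  expect_false(cl$conflict)
  # identical complete strings on both ends: assigned once, no conflict
  cl2 <- classify_read(paste0(sX, ins, reverse_complement(sX)), sch)
  expect_identical(cl2$naming_labels, labX)
  expect_false(cl2$conflict)
  expect_identical(cl2$trim_prefix_end, 44L)
  expect_identical(cl2$trim_suffix_start, nchar(paste0(sX, ins)) + 1L)
  # conflicting complete ends: direct names the read, conflict flagged
  sY <- make_string(sch, labY)
  cl3 <- classify_read(paste0(sX, ins, reverse_complement(sY)), sch)
  expect_identical(cl3$naming_labels, labX)
  expect_true(cl3$conflict)
  # direct partial vs reverse complete: the complete end wins
  sP <- make_string(sch, c(labX[1:3], NA))
  cl4 <- classify_read(paste0(sP, ins, reverse_complement(sY)), sch)
  expect_identical(cl4$category, "complete")
  expect_identical(cl4$origin, "reverse")
  expect_identical(cl4$naming_labels, labY)
  # single barcode never names a read
  cl5 <- classify_read(paste0(bc_of(sch, 1, "D01"), ins), sch)
  expect_identical(cl5$category, "bulk_0_1")
  expect_null(cl5$naming_labels)
  # reverse-complemented complete read is recovered through the reverse scan
  cl6 <- classify_read(reverse_complement(paste0(sX, ins)), sch)
  expect_identical(cl6$category, "complete")
  expect_identical(cl6$origin, "reverse")
  expect_identical(cl6$naming_labels, labX)
})

test_that("classification is deterministic", {
  sch <- tiny_scheme()
  set.seed(42)
  reads <- replicate(50, random_oracle_read(sch))
  a <- lapply(reads, classify_read, scheme = sch)
  b <- lapply(reads, classify_read, scheme = sch)
  expect_identical(a, b)
})

test_that("classify_read agrees with the brute-force oracle", {
  sch <- tiny_scheme()
  set.seed(20240817)
  n_cases <- 2500   # plus the 10k acceptance sweep in test-acceptance.R
  bad <- character(0)
  for (i in seq_len(n_cases)) {
    rd <- random_oracle_read(sch)
    got <- classify_read(rd, sch)
    want <- o_classify(rd, sch)
    same <- identical(got$category, want$category) &&
      identical(got$origin, want$origin) &&
      identical(got$conflict, want$conflict) &&
      (is.null(want$naming) || identical(got$naming_labels, want$naming)) &&
      identical(got$trim_prefix_end, want$trim_prefix_end) &&
      identical(got$trim_suffix_start, want$trim_suffix_start)
    if (!same) bad <- c(bad, rd)
  }
  expect_identical(bad, character(0))
})

test_that("barcode string positions increase and respect the slack bound", {
  sch <- tiny_scheme()
  set.seed(7)
  for (i in 1:400) {
    rd <- random_oracle_read(sch)
    b <- scan_end(rd, sch)
    found <- Filter(Negate(is.null), b$slots)
    if (length(found) >= 2) {
      starts <- vapply(found, `[[`, integer(1), "start")
      expect_true(all(diff(starts) > 0))
      expect_true(all(b$linkers >= -1L))
    }
  }
})
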