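# Shared fixtures, built in code.

# 2 sets x 2 barcodes of 4 nt, deliberately chosen so that reverse
# complements and homopolymer overlaps collide across sets/orientations
# (worst case for the chained search).
tiny_scheme <- function(l = 16L) {
  barcode_scheme(
    list(D = data.frame(well = c("D1", "D2"),
                        sequence = c("AAAA", "CCCC")),
         A = data.frame(well = c("A1", "A2"),
                        sequence = c("GGGG", "TTTT"))),
    barcodes_per_set = 2L, barcode_length = 4L,
    linker_length = 4L, search_window = l)
}

# 2 sets x 2 barcodes of 8 nt (homopolymers), 4 nt linker, window 40.
two_set_scheme <- function(l = 40L) {
  barcode_scheme(
    list(D = data.frame(well = c("D1", "D2"),
                        sequence = c("AAAAAAAA", "CCCCCCCC")),
         A = data.frame(well = c("A1", "A2"),
                        sequence = c("GGGGGGGG", "TTTTTTTT"))),
    barcodes_per_set = 2L, barcode_length = 8L,
    linker_length = 4L, search_window = l)
}

# the bundled synthetic 4 x 24 x 8 nt plate
default_scheme <- function(l = 88L) {
  read_barcode_scheme(
    system.file("extdata", "barcodes_atrandi_synthetic.tsv",
                package = "splitpool"),
    barcodes_per_set = 24L, barcode_length = 8L, linker_length = 4L,
    search_window = l)
}

# barcode sequence for a well label
bc_of <- function(scheme, set, well) {
  s <- scheme$sets[[set]]
  s$sequence[match(well, s$well)]
}

# assemble a barcode string from labels (NA = set absent), with given
# linker lengths between consecutive present barcodes (recycled)
make_string <- function(scheme, labels, linkers = scheme$linker_length,
                        fill = "T") {
  present <- which(!is.na(labels))
  linkers <- rep_len(linkers, max(length(present) - 1L, 1L))
  out <- ""
  for (j in seq_along(present)) {
    i <- present[j]
    if (j > 1L) out <- paste0(out, strrep(fill, linkers[j - 1L]))
    out <- paste0(out, bc_of(scheme, i, labels[i]))
  }
  out
}

write_fastq_file <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), strrep, "", x = "I")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  invisible(path)
}

read_fastq_file <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  stopifnot(length(lines) %% 4L == 0L)
  list(id = sub("^@", "", lines[seq(1, length(lines), 4)]),
       seq = lines[seq(2, length(lines), 4)],
       qual = lines[seq(4, length(lines), 4)])
}

# The hand-verified 6-read fixture: 2 complete reads with the same
# combination, 1 complete read whose two ends disagree (conflict), 1
# sequential 3-barcode read, 1 single-barcode read, 1 read with no
# barcodes. Returns the FASTQ path and the expectations.
six_read_fixture <- function(dir, scheme = default_scheme()) {
  labA <- c("D01", "C02", "B03", "A04")
  labB <- c("D05", "C06", "B07", "A08")
  labC <- c("D13", "C14", "B15", "A16")
  labP <- c("D09", "C10", "B11", NA)
  ins <- function(n) strrep("T", n)
  s_complete <- make_string(scheme, labA)
  r1 <- paste0(s_complete, ins(60))
  r2 <- paste0(strrep("G", 10), s_complete, ins(60))
  # direct end labC, 3' end labB: conflicting complete strings
  r3 <- paste0(make_string(scheme, labC), ins(60),
               as.character(reverse_complement(make_string(scheme, labB))))
  r4 <- paste0(make_string(scheme, labP), ins(60))
  r5 <- paste0(bc_of(scheme, 1, "D12"), ins(60))
  r6 <- ins(80)
  path <- file.path(dir, "fixture6.fastq")
  write_fastq_file(path, paste0("fix", 1:6), c(r1, r2, r3, r4, r5, r6))
  list(path = path, scheme = scheme, stem = "fixture6",
       complete_name = paste0(paste(labA, collapse = "_"), ".fastq"),
       conflict_name = paste0(paste(labC, collapse = "_"), ".fastq"),
       partial_name = paste0(paste(c(labP[1:3], "___"), collapse = "_"),
                             ".fastq"))
}
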