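# FASTQ streaming, trimming and routing of reads to per-cell output
# files. Processing is strictly sequential (single writer): each read's
# destination depends only on its own content, but appends to the shared
# output files must never interleave. Files are opened, appended and
# closed per flush, so the number of simultaneously open handles stays
# bounded no matter how many barcode combinations appear.

fastq_connection <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Read up to `n` FASTQ records from an open text connection. Returns a
# list(id, seq, qual) of equal-length character vectors, or NULL at EOF.
# `offset` is the number of records already consumed (for error indices).
read_fastq_chunk <- function(con, n, offset = 0L) {
  lines <- readLines(con, n = 4L * n, warn = FALSE)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at record ",
         offset + length(lines) %/% 4L + 1L)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(substr(ids, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+" |
                 nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record at record ", offset + bad[1L])
  list(id = sub("^@", "", ids), seq = seqs, qual = quals)
}

append_fastq_records <- function(path, ids, seqs, quals, gz = FALSE) {
  con <- if (gz) gzfile(path, "ab") else file(path, "ab")
  on.exit(close(con))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", quals, "\n")
  writeLines(rec, con, sep = "")
  invisible(path)
}

#' Output filename for a classified read
#'
#' Complete strings name their file by joining the well labels in read
#' order (`D05_C12_B01_A20.fastq`); partial and skipped strings use the
#' same convention with each missing set's label replaced by the
#' placeholder (`D05_C12_B01____.fastq` for placeholder `"___"`); reads
#' with one or no barcodes go to the bulk file `<stem>_0_1.fastq`.
#' Partial/skipped reads are additionally appended to the combined file
#' `<stem>_3_2.fastq` (see [demultiplex()]).
#'
#' @param classification A [classify_read()] result.
#' @param stem Filename stem used for the bulk and combined files
#'   (typically the input filename without extension).
#' @return The primary output filename (no directory).
#' @export
output_name <- function(classification, stem) {
  if (classification$category == "bulk_0_1")
    paste0(stem, "_0_1.fastq")
  else
    paste0(paste(classification$naming_labels, collapse = "_"), ".fastq")
}

combined_partial_name <- function(stem) paste0(stem, "_3_2.fastq")

#' Trim the detected barcode string(s) off a read
#'
#' Removes the 5' prefix through the last base of the direct-end string
#' (adapter residue included, unless `keep_adapter_residue`) when the
#' direct end carries a string with two or more barcodes, and symmetrically
#' the 3' suffix when the reverse end does. Bulk (one-or-no-barcode) reads
#' are returned unmodified. Trimming that would leave an empty sequence is
#' refused: the read is returned untrimmed with `degenerate = TRUE` so the
#' caller can route it to the bulk file.
#'
#' @param read A list with `id`, `seq`, `qual` (equal-length `seq`/`qual`).
#' @param classification The [classify_read()] result for `read$seq`.
#' @param keep_adapter_residue If `TRUE`, the bases preceding the first
#'   detected barcode on a trimmed end are kept (only the barcode string
#'   itself is excised); by default everything from the read start through
#'   the string is removed, since untrimmed adapter residue is not
#'   biological sequence.
#' @return The trimmed read (same structure), with attribute-free logical
#'   element `degenerate` added.
#' @export
trim_read <- function(read, classification, keep_adapter_residue = FALSE) {
  cl <- classification
  L <- nchar(read$seq)
  p_end <- cl$trim_prefix_end      # last base removed from the 5' side
  s_start <- cl$trim_suffix_start  # first base removed on the 3' side
  if (is.na(p_end) && is.na(s_start)) {
    read$degenerate <- FALSE
    return(read)
  }
  lo <- if (is.na(p_end)) 1L else p_end + 1L
  hi <- if (is.na(s_start)) L else s_start - 1L
  if (lo > hi) {
    read$degenerate <- TRUE
    return(read)
  }
  if (keep_adapter_residue) {
    pre <- if (!is.na(p_end) && cl$direct$first_start > 1L)
      cl$direct$first_start - 1L else 0L
    post <- if (!is.na(s_start)) {
      r_res_start <- L - cl$reverse$first_start + 2L
      if (r_res_start <= L) c(r_res_start, L) else NULL
    } else NULL
    seq <- paste0(if (pre) substr(read$seq, 1L, pre) else "",
                  substr(read$seq, lo, hi),
                  if (!is.null(post)) substr(read$seq, post[1L], post[2L]) else "")
    qual <- paste0(if (pre) substr(read$qual, 1L, pre) else "",
                   substr(read$qual, lo, hi),
                   if (!is.null(post)) substr(read$qual, post[1L], post[2L]) else "")
    read$seq <- seq
    read$qual <- qual
  } else {
    read$seq <- substr(read$seq, lo, hi)
    read$qual <- substr(read$qual, lo, hi)
  }
  read$degenerate <- FALSE
  read
}

#' Demultiplex a FASTQ file into per-cell files
#'
#' Streams `fastq_in` (plain or gzip), classifies every read with
#' [classify_read()], trims detected strings with [trim_read()], and
#' appends each read to exactly one primary output file (plus, for
#' partial/skipped reads, one copy in the combined `<stem>_3_2.fastq`).
#' Output files are created lazily on first use. Reads whose trimming
#' would leave an empty sequence are routed untrimmed to the bulk file
#' with a warning.
#'
#' @param fastq_in Input FASTQ path (`.gz` accepted).
#' @param scheme A [barcode_scheme()].
#' @param out_dir Output directory (created if missing).
#' @param stem Stem for the bulk/combined/statistics files; defaults to
#'   the input filename without its (compressed) extension.
#' @param placeholder Missing-set label placeholder (default `"___"`).
#' @param keep_adapter_residue,overlap_slack See [trim_read()],
#'   [scan_end()].
#' @param gzip_output Write per-cell files gzip-compressed.
#' @param dry_run Classify and account only; write no per-cell files.
#' @param chunk_size Reads per streamed chunk.
#' @return An object of class `demux_result`: list with
#'   \describe{
#'     \item{accounting}{`total_reads`, `per_category_counts`,
#'       `per_file_counts` (primary file only), `conflict_count`,
#'       `degenerate_trim_count`}
#'     \item{reads}{per-read data.frame digest (id, file, category,
#'       per-end labels/linkers/positions) consumed by the statistics
#'       functions}
#'     \item{scheme, stem, out_dir, elapsed_sec}{run metadata}
#'   }
#' @export
demultiplex <- function(fastq_in, scheme, out_dir, stem = NULL,
                        placeholder = "___", keep_adapter_residue = FALSE,
                        overlap_slack = 1L, gzip_output = FALSE,
                        dry_run = FALSE, chunk_size = 2000L) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (!file.exists(fastq_in)) stop("input FASTQ not found: ", fastq_in)
  if (is.null(stem))
    stem <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_in))
  if (!dry_run && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]

  con <- fastq_connection(fastq_in)
  on.exit(close(con))
  ext <- if (gzip_output) ".gz" else ""
  categories <- c("complete", "partial_3", "partial_2", "skipped", "bulk_0_1")
  cat_counts <- stats::setNames(integer(length(categories)), categories)
  file_counts <- new.env(parent = emptyenv())
  conflict_count <- 0L
  degenerate_count <- 0L
  total <- 0L
  digests <- list()

  repeat {
    chunk <- read_fastq_chunk(con, chunk_size, offset = total)
    if (is.null(chunk)) break
    nr <- length(chunk$id)
    cls <- lapply(seq_len(nr), function(i)
      classify_read(toupper(chunk$seq[i]), scheme,
                    placeholder = placeholder,
                    overlap_slack = overlap_slack))

    files <- character(nr)
    trimmed_seq <- character(nr)
    trimmed_qual <- character(nr)
    partial <- logical(nr)
    for (i in seq_len(nr)) {
      cl <- cls[[i]]
      rd <- trim_read(list(id = chunk$id[i], seq = chunk$seq[i],
                           qual = chunk$qual[i]),
                      cl, keep_adapter_residue)
      if (isTRUE(rd$degenerate)) {
        degenerate_count <- degenerate_count + 1L
        warning("read ", chunk$id[i],
                ": trimming would empty the sequence; routed to bulk untrimmed",
                call. = FALSE)
        cl$category <- "bulk_0_1"
        cl$naming_labels <- NULL
        cls[[i]] <- cl
        rd$seq <- chunk$seq[i]
        rd$qual <- chunk$qual[i]
      }
      files[i] <- output_name(cl, stem)
      trimmed_seq[i] <- rd$seq
      trimmed_qual[i] <- rd$qual
      partial[i] <- cl$category %in% c("partial_3", "partial_2", "skipped")
      cat_counts[cl$category] <- cat_counts[cl$category] + 1L
      if (isTRUE(cl$conflict)) conflict_count <- conflict_count + 1L
    }
    if (!dry_run) {
      for (f in unique(files)) {
        idx <- which(files == f)
        append_fastq_records(file.path(out_dir, paste0(f, ext)),
                             chunk$id[idx], trimmed_seq[idx],
                             trimmed_qual[idx], gz = gzip_output)
      }
      if (any(partial)) {
        idx <- which(partial)
        append_fastq_records(file.path(out_dir,
                                       paste0(combined_partial_name(stem), ext)),
                             chunk$id[idx], trimmed_seq[idx],
                             trimmed_qual[idx], gz = gzip_output)
      }
    }
    for (f in files) {
      cur <- if (is.null(file_counts[[f]])) 0L else file_counts[[f]]
      file_counts[[f]] <- cur + 1L
    }
    digests[[length(digests) + 1L]] <-
      classification_digest(chunk$id, cls, files, scheme)
    total <- total + nr
  }

  per_file <- unlist(as.list(file_counts))
  if (is.null(per_file)) per_file <- stats::setNames(integer(0L), character(0L))
  reads <- if (length(digests)) do.call(rbind, digests) else
    classification_digest(character(0L), list(), character(0L), scheme)
  structure(
    list(accounting = list(total_reads = total,
                           per_category_counts = cat_counts,
                           per_file_counts = per_file[order(names(per_file))],
                           conflict_count = conflict_count,
                           degenerate_trim_count = degenerate_count),
         reads = reads,
         scheme = scheme, stem = stem,
         out_dir = if (dry_run) NA_character_ else out_dir,
         placeholder = placeholder,
         gzip_output = gzip_output, dry_run = dry_run,
         elapsed_sec = proc.time()[["elapsed"]] - t0),
    class = "demux_result")
}

# Flat per-read record of everything the statistics module needs.
classification_digest <- function(ids, cls, files, scheme) {
  n <- length(ids)
  g <- function(f) vapply(cls, f, character(1L))
  gi <- function(f) vapply(cls, f, integer(1L))
  lab_str <- function(bstr) paste(ifelse(is.na(bstr$labels), "", bstr$labels),
                                  collapse = ";")
  lk_str <- function(bstr) paste(bstr$linkers, collapse = ",")
  if (n == 0L) {
    return(data.frame(read_id = character(0L), file = character(0L),
                      category = character(0L), origin = character(0L),
                      conflict = logical(0L),
                      naming = character(0L),
                      direct_labels = character(0L),
                      reverse_labels = character(0L),
                      direct_n = integer(0L), reverse_n = integer(0L),
                      direct_last_end = integer(0L),
                      reverse_last_end = integer(0L),
                      direct_linkers = character(0L),
                      reverse_linkers = character(0L),
                      last_barcode_end = integer(0L),
                      linkers = character(0L),
                      stringsAsFactors = FALSE))
  }
  winner_field <- function(cl, fld, default) {
    if (is.na(cl$origin)) return(default)
    b <- if (cl$origin == "direct") cl$direct else cl$reverse
    fld(b)
  }
  data.frame(
    read_id = ids,
    file = files,
    category = g(function(cl) cl$category),
    origin = g(function(cl) if (is.na(cl$origin)) "" else cl$origin),
    conflict = vapply(cls, function(cl) isTRUE(cl$conflict), logical(1L)),
    naming = g(function(cl) if (is.null(cl$naming_labels)) ""
               else paste(cl$naming_labels, collapse = ";")),
    direct_labels = g(function(cl) lab_str(cl$direct)),
    reverse_labels = g(function(cl) lab_str(cl$reverse)),
    direct_n = gi(function(cl) cl$direct$n_found),
    reverse_n = gi(function(cl) cl$reverse$n_found),
    direct_last_end = gi(function(cl)
      if (is.na(cl$direct$last_end)) NA_integer_ else cl$direct$last_end),
    reverse_last_end = gi(function(cl)
      if (is.na(cl$reverse$last_end)) NA_integer_ else cl$reverse$last_end),
    direct_linkers = g(function(cl) lk_str(cl$direct)),
    reverse_linkers = g(function(cl) lk_str(cl$reverse)),
    last_barcode_end = gi(function(cl)
      winner_field(cl, function(b) b$last_end, NA_integer_)),
    linkers = g(function(cl)
      winner_field(cl, function(b) paste(b$linkers, collapse = ","), "")),
    stringsAsFactors = FALSE)
}

#' @export
print.demux_result <- function(x, ...) {
  a <- x$accounting
  cat("Demultiplexing of ", a$total_reads, " reads",
      if (x$dry_run) " (dry run)", "\n", sep = "")
  pc <- a$per_category_counts
  pct <- if (a$total_reads) 100 * pc / a$total_reads else pc * 0
  for (k in names(pc))
    cat(sprintf("  %-10s %8d  (%.2f%%)\n", k, pc[[k]], pct[[k]]))
  cat("  conflicting complete ends: ", a$conflict_count, "\n", sep = "")
  cat("  distinct output files: ", length(a$per_file_counts), "\n", sep = "")
  invisible(x)
}
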