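# Per-read and aggregate diagnostics: the tab-separated summary and stats
# files, and the aggregate report (category fractions, linker-length
# histogram by string end position, per-well usage) used to optimize
# laboratory barcoding workflows.

split_labels <- function(x, n_sets, placeholder) {
  parts <- strsplit(x, ";", fixed = TRUE)
  t(vapply(parts, function(p) {
    p <- c(p, rep("", n_sets - length(p)))[seq_len(n_sets)]
    ifelse(nzchar(p), p, placeholder)
  }, character(n_sets)))
}

#' Per-read summary table (barcodes found on both ends)
#'
#' One row per read, in input order: the well labels detected on the
#' direct end and on the reverse-complement end, one column per set and
#' orientation, with the placeholder for missing sets.
#'
#' @param result A [demultiplex()] result.
#' @return A data.frame with columns `read_id`,
#'   `direct_<set>`... and `reverse_<set>`...
#' @export
summary_table <- function(result) {
  stopifnot(inherits(result, "demux_result"))
  scheme <- result$scheme
  ph <- result$placeholder
  n <- scheme$n_sets
  d <- split_labels(result$reads$direct_labels, n, ph)
  r <- split_labels(result$reads$reverse_labels, n, ph)
  out <- data.frame(read_id = result$reads$read_id, stringsAsFactors = FALSE)
  for (i in seq_len(n))
    out[[paste0("direct_", names(scheme$sets)[i])]] <- d[, i]
  for (i in seq_len(n))
    out[[paste0("reverse_", names(scheme$sets)[i])]] <- r[, i]
  out
}

#' Per-read storage statistics table
#'
#' One row per read, in input order: the output file the read was stored
#' in, the 1-based position of the last base of the last detected barcode
#' of the naming string (empty for bulk reads), and the comma-joined
#' linker lengths between its consecutive detected barcodes.
#'
#' @param result A [demultiplex()] result.
#' @return A data.frame with columns `read_id`, `stored_file`,
#'   `last_barcode_end`, `linker_lengths`.
#' @export
stats_table <- function(result) {
  stopifnot(inherits(result, "demux_result"))
  data.frame(read_id = result$reads$read_id,
             stored_file = result$reads$file,
             last_barcode_end = result$reads$last_barcode_end,
             linker_lengths = result$reads$linkers,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Write the per-read summary file
#'
#' Writes `<stem>_summary.txt`: tab-separated, one header line, one row
#' per input read (see [summary_table()]).
#'
#' @param result A [demultiplex()] result.
#' @param path Output path; defaults to `<out_dir>/<stem>_summary.txt`.
#' @return The path, invisibly.
#' @export
write_summary <- function(result, path = NULL) {
  if (is.null(path))
    path <- file.path(result$out_dir, paste0(result$stem, "_summary.txt"))
  write_tsv(summary_table(result), path)
}

#' Write the per-read stats file
#'
#' Writes `<stem>_stats.txt`: tab-separated, one header line, one row per
#' input read (see [stats_table()]).
#'
#' @inheritParams write_summary
#' @return The path, invisibly.
#' @export
write_stats <- function(result, path = NULL) {
  if (is.null(path))
    path <- file.path(result$out_dir, paste0(result$stem, "_stats.txt"))
  write_tsv(stats_table(result), path)
}

parse_int_csv <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(p) as.integer(p[nzchar(p)]))
}

#' Aggregate run diagnostics
#'
#' Computes, over a whole demultiplexing run:
#' \itemize{
#'   \item category fractions (complete / partial_3 / partial_2 / skipped
#'     / bulk_0_1) as percentages of total reads;
#'   \item the linker-length histogram, counting every gap between
#'     consecutive detected barcodes on **both** ends, cross-tabulated
#'     with the end position of that end's string (10 nt bins) and
#'     classed against the scheme's nominal linker length
#'     (`<nominal` / `nominal` / `>nominal`);
#'   \item per-well read counts per set, from the naming string (a
#'     complete string increments one well in each of the `n_sets` sets);
#'   \item the number of reads with strings of two or more barcodes
#'     confirmed on both ends;
#'   \item the conflicting-ends fraction among complete-string reads.
#' }
#'
#' @param result A [demultiplex()] result.
#' @param position_bin Width (nt) of the string-end-position bins in the
#'   linker histogram.
#' @return An object of class `aggregate_report`.
#' @export
aggregate_report <- function(result, position_bin = 10L) {
  stopifnot(inherits(result, "demux_result"))
  scheme <- result$scheme
  reads <- result$reads
  total <- nrow(reads)
  categories <- c("complete", "partial_3", "partial_2", "skipped", "bulk_0_1")
  cat_counts <- stats::setNames(
    vapply(categories, function(k) sum(reads$category == k), integer(1L)),
    categories)
  cat_frac <- if (total) round(100 * cat_counts / total, 2L) else cat_counts * 0

  # linker observations from both ends, tagged with that end's string end
  collect <- function(linkers_col, end_col) {
    lk <- parse_int_csv(linkers_col)
    nlk <- lengths(lk)
    if (sum(nlk) == 0L)
      return(data.frame(length = integer(0L), end_pos = integer(0L)))
    data.frame(length = unlist(lk[nlk > 0L]),
               end_pos = rep(end_col[nlk > 0L], nlk[nlk > 0L]))
  }
  obs <- rbind(collect(reads$direct_linkers, reads$direct_last_end),
               collect(reads$reverse_linkers, reads$reverse_last_end))
  nominal <- scheme$linker_length
  if (nrow(obs)) {
    obs$pos_bin <- position_bin * ((pmax(obs$end_pos, 1L) - 1L) %/% position_bin) + 1L
    obs$class <- ifelse(obs$length < nominal, "<nominal",
                        ifelse(obs$length > nominal, ">nominal", "nominal"))
    linker_hist <- as.data.frame(
      table(length = obs$length, pos_bin = obs$pos_bin),
      stringsAsFactors = FALSE)
    linker_hist <- linker_hist[linker_hist$Freq > 0L, ]
    linker_hist$length <- as.integer(linker_hist$length)
    linker_hist$pos_bin <- as.integer(linker_hist$pos_bin)
    names(linker_hist)[3L] <- "count"
    rownames(linker_hist) <- NULL
    linker_counts <- table(factor(obs$length))
    linker_class_counts <- table(factor(obs$class,
                                        levels = c("<nominal", "nominal", ">nominal")))
  } else {
    linker_hist <- data.frame(length = integer(0L), pos_bin = integer(0L),
                              count = integer(0L))
    linker_counts <- table(factor(integer(0L)))
    linker_class_counts <- table(factor(character(0L),
                                        levels = c("<nominal", "nominal", ">nominal")))
  }

  # per-well counts from naming strings (placeholders skipped)
  wells <- lapply(scheme$sets, function(s)
    stats::setNames(integer(length(s$well)), s$well))
  named <- reads$naming[nzchar(reads$naming)]
  if (length(named)) {
    labm <- split_labels(named, scheme$n_sets, result$placeholder)
    for (i in seq_len(scheme$n_sets)) {
      tab <- table(labm[, i])
      tab <- tab[names(tab) %in% names(wells[[i]])]
      wells[[i]][names(tab)] <- wells[[i]][names(tab)] + as.integer(tab)
    }
  }
  both_end_confirmed <- sum(reads$direct_n >= 2L & reads$reverse_n >= 2L)
  n_complete <- cat_counts[["complete"]]
  conflict_fraction <- if (n_complete)
    round(100 * sum(reads$conflict) / n_complete, 2L) else NA_real_

  structure(
    list(total_reads = total,
         category_counts = cat_counts,
         category_fractions = cat_frac,
         linker_hist = linker_hist,
         linker_counts = linker_counts,
         linker_class_counts = linker_class_counts,
         nominal_linker = nominal,
         per_well_counts = wells,
         both_end_confirmed = both_end_confirmed,
         conflict_count = sum(reads$conflict),
         conflict_fraction = conflict_fraction),
    class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("Aggregate barcoding report (", x$total_reads, " reads)\n", sep = "")
  for (k in names(x$category_fractions))
    cat(sprintf("  %-10s %8d  (%.2f%%)\n", k, x$category_counts[[k]],
                x$category_fractions[[k]]))
  tot <- sum(x$linker_counts)
  cat("  linkers observed: ", tot, "\n", sep = "")
  if (tot) {
    pct <- round(100 * x$linker_class_counts / tot, 2L)
    cat(sprintf("    <%d nt: %.2f%%   %d nt: %.2f%%   >%d nt: %.2f%%\n",
                x$nominal_linker, pct[["<nominal"]],
                x$nominal_linker, pct[["nominal"]],
                x$nominal_linker, pct[[">nominal"]]))
  }
  cat("  strings confirmed on both ends: ", x$both_end_confirmed, "\n",
      sep = "")
  if (!is.na(x$conflict_fraction))
    cat(sprintf("  conflicting ends among complete reads: %.2f%%\n",
                x$conflict_fraction))
  invisible(x)
}

#' Write the aggregate report
#'
#' Writes `<stem>_report.txt` with key-value and table sections, plus a
#' machine-readable JSON companion `<stem>_report.json`.
#'
#' @param report An [aggregate_report()].
#' @param path Output path for the text report; the JSON companion is
#'   written next to it.
#' @return The text path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "aggregate_report"))
  con <- file(path, "wt")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("# aggregate barcoding report")
  w("total_reads\t", report$total_reads)
  w("")
  w("## category fractions (%)")
  for (k in names(report$category_fractions))
    w(k, "\t", report$category_counts[[k]], "\t",
      sprintf("%.2f", report$category_fractions[[k]]))
  w("")
  w("## linker length x string end position (bin start)")
  w("length\tpos_bin\tcount")
  for (i in seq_len(nrow(report$linker_hist)))
    w(report$linker_hist$length[i], "\t", report$linker_hist$pos_bin[i],
      "\t", report$linker_hist$count[i])
  w("")
  w("## per-well read counts")
  w("set\twell\tcount")
  for (s in names(report$per_well_counts)) {
    wc <- report$per_well_counts[[s]]
    for (j in seq_along(wc)) w(s, "\t", names(wc)[j], "\t", wc[[j]])
  }
  w("")
  w("both_end_confirmed\t", report$both_end_confirmed)
  w("conflict_count\t", report$conflict_count)
  w("conflict_fraction_pct\t",
    if (is.na(report$conflict_fraction)) "" else
      sprintf("%.2f", report$conflict_fraction))

  json_path <- sub("\\.txt$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(total_reads = report$total_reads,
         category_counts = as.list(report$category_counts),
         category_fractions = as.list(report$category_fractions),
         linker_counts = as.list(stats::setNames(
           as.integer(report$linker_counts), names(report$linker_counts))),
         linker_class_counts = as.list(stats::setNames(
           as.integer(report$linker_class_counts),
           names(report$linker_class_counts))),
         both_end_confirmed = report$both_end_confirmed,
         conflict_count = report$conflict_count,
         conflict_fraction = report$conflict_fraction),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
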