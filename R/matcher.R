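# Core detection: ordered, skip-tolerant chains of exact barcode matches
# inside a bounded window at each read end, in both orientations.
#
# Matching is strictly exact (no mismatches, no indels): a barcode carrying
# a sequencing or ligation error is indistinguishable from an absent one,
# which is what the downstream category taxonomy encodes. All coordinates
# are 1-based inclusive.

#' Reverse complement of DNA sequences
#'
#' Vectorized over `seqs`. Accepts A/C/G/T/N in either case; `N` maps to
#' `N`. Any other character is an error (matching is exact over ACGT, so
#' IUPAC ambiguity codes are not meaningful here).
#'
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of reverse complements (uppercased input is
#'   returned uppercased; case is preserved per base via `chartr`).
#' @export
reverse_complement <- function(seqs) {
  if (!is.character(seqs)) stop("'seqs' must be a character vector")
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seqs)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad))
    stop("non-ACGTN character in sequence(s): ",
         paste(which(bad), collapse = ", "))
  vapply(comp, function(s) {
    if (nchar(s) == 0L) return(s)
    intToUtf8(rev(utf8ToInt(s)))
  }, "", USE.NAMES = FALSE)
}

#' Nearest exact occurrence of any barcode of one set
#'
#' Scans `seq` for exact occurrences of any sequence of one barcode set
#' whose start lies in `[search_start, search_end - barcode_length + 1]`
#' (so the whole match fits inside position `search_end`), and returns the
#' occurrence with the smallest start -- the match "at the closest distance
#' from the preceding barcode".
#'
#' @param seq A single DNA sequence (character scalar).
#' @param set One element of `scheme$sets`: a list with `set_label`,
#'   `well`, `sequence`.
#' @param search_start First allowed match start (1-based).
#' @param search_end Last position (1-based, inclusive) a match may occupy.
#' @return A list with `well_label`, `start`, `end`, or `NULL` when no
#'   occurrence exists (a valid outcome, not an error).
#' @export
find_nearest_match <- function(seq, set, search_start = 1L,
                               search_end = nchar(seq)) {
  bs <- nchar(set$sequence[1L])
  search_start <- max(1L, as.integer(search_start))
  search_end <- min(nchar(seq), as.integer(search_end))
  last_start <- search_end - bs + 1L
  if (last_start < search_start) return(NULL)
  starts <- search_start:last_start
  kmers <- substring(seq, starts, starts + bs - 1L)
  m <- match(kmers, set$sequence)
  hit <- which(!is.na(m))
  if (length(hit) == 0L) return(NULL)
  i <- hit[1L]
  list(well_label = set$well[m[i]],
       start = starts[i], end = starts[i] + bs - 1L)
}

#' Scan one read end for a chained barcode string
#'
#' Implements the chained positional search: set 1 (outermost) is searched
#' in the window `[1, min(search_window, read length)]`; after a match of
#' set *k* ending at position *e*, set *k+1* is searched from the lower
#' bound `e + 1 - overlap_slack` (slack 1 permits a 1 nt overlap, reported
#' as a linker of -1 nt) up to the same global window bound. When set *k*
#' is not found the search falls through to set *k+1* from the same
#' anchor; this single rule yields both the restart-with-inner-sets
#' behaviour when leading sets are absent and the detection of skipped
#' interior sets.
#'
#' @param seq A single DNA sequence: the read itself (direct scan) or its
#'   reverse complement (reverse scan).
#' @param scheme A [barcode_scheme()].
#' @param overlap_slack Non-negative integer; how far a match may reach
#'   back over the previous barcode's last base (default 1 nt).
#' @return An object of class `barcode_string`: a list with
#'   \describe{
#'     \item{slots}{list of per-set matches (`NULL` when missing); each
#'       match has `set_index`, `well_label`, `start`, `end`,
#'       `linker_before` (`NA` for the first found set)}
#'     \item{labels}{character vector of well labels, `NA` when missing}
#'     \item{n_found}{number of detected barcodes}
#'     \item{category}{one of `complete`, `incomplete_sequential`,
#'       `skipped`, `single`, `empty`}
#'     \item{last_end}{1-based position of the final detected barcode's
#'       last base, `NA` if none}
#'     \item{linkers}{integer vector of gaps between consecutive found
#'       barcodes}
#'     \item{skipped_sets}{indices of sets missing strictly between found
#'       ones}
#'   }
#' @export
scan_end <- function(seq, scheme, overlap_slack = 1L) {
  n <- scheme$n_sets
  bs <- scheme$barcode_length
  slots <- vector("list", n)
  w <- min(scheme$search_window, nchar(seq))
  if (w >= bs) {
    starts <- seq_len(w - bs + 1L)
    kmers <- substring(seq, starts, starts + bs - 1L)
    lower <- 1L
    prev_end <- NA_integer_
    for (i in seq_len(n)) {
      m <- match(kmers, scheme$sets[[i]]$sequence)
      hit <- which(!is.na(m))
      if (length(hit)) hit <- hit[hit >= lower]
      if (length(hit)) {
        s <- hit[1L]
        e <- s + bs - 1L
        slots[[i]] <- list(
          set_index = i,
          well_label = scheme$sets[[i]]$well[m[s]],
          start = s, end = e,
          linker_before = if (is.na(prev_end)) NA_integer_
                          else s - prev_end - 1L)
        prev_end <- e
        lower <- e + 1L - as.integer(overlap_slack)
      }
    }
  }
  new_barcode_string(slots, n)
}

new_barcode_string <- function(slots, n_sets) {
  found <- which(!vapply(slots, is.null, logical(1L)))
  n_found <- length(found)
  skipped_sets <- integer(0L)
  if (n_found >= 2L) {
    span <- found[1L]:found[n_found]
    skipped_sets <- setdiff(span, found)
  }
  category <-
    if (n_found == n_sets) "complete"
    else if (n_found == 0L) "empty"
    else if (n_found == 1L) "single"
    else if (length(skipped_sets)) "skipped"
    else "incomplete_sequential"
  labels <- rep(NA_character_, n_sets)
  labels[found] <- vapply(slots[found], `[[`, "", "well_label")
  linkers <- if (n_found >= 2L)
    vapply(slots[found[-1L]], `[[`, integer(1L), "linker_before")
  else integer(0L)
  structure(
    list(slots = slots, labels = labels, n_found = n_found,
         category = category,
         last_end = if (n_found) slots[[found[n_found]]]$end else NA_integer_,
         first_start = if (n_found) slots[[found[1L]]]$start else NA_integer_,
         linkers = linkers, skipped_sets = skipped_sets),
    class = "barcode_string")
}

#' @export
print.barcode_string <- function(x, ...) {
  cat("<barcode_string> category=", x$category, ", found=", x$n_found, "\n",
      sep = "")
  if (x$n_found) {
    cat("  labels:", paste(ifelse(is.na(x$labels), "-", x$labels),
                           collapse = " "), "\n")
    cat("  last_end:", x$last_end,
        if (length(x$linkers)) paste0(" linkers: ",
                                      paste(x$linkers, collapse = ",")),
        "\n")
  }
  invisible(x)
}

# Merge priority of a barcode_string: complete beats any partial; >=2
# found beats <2; direct beats reverse at equal tier.
string_tier <- function(bstr) {
  if (bstr$category == "complete") 2L
  else if (bstr$n_found >= 2L) 1L
  else 0L
}

#' Classify a read by its barcode strings on both ends
#'
#' Runs [scan_end()] on the read and on its reverse complement, then
#' merges the two results by the priority ladder: direct complete >
#' reverse complete > direct partial (2+ barcodes) > reverse partial >
#' one-or-no-barcode bulk. When both ends carry complete strings with
#' identical labels the read is assigned once to that name; when both are
#' complete but disagree, the direct end names the read and the conflict
#' is flagged. Single-barcode strings never name a read (any short k-mer
#' occurs by chance in natural DNA); such reads fall to the bulk
#' category.
#'
#' @param read_seq A single DNA sequence (non-empty).
#' @param scheme A [barcode_scheme()].
#' @param placeholder Label substituted for a missing set in the naming
#'   string (default `"___"`).
#' @param overlap_slack Passed to [scan_end()].
#' @return An object of class `read_classification`: list with
#'   `direct` and `reverse` (`barcode_string`s), `category` (one of
#'   `complete`, `partial_3`, `partial_2`, `skipped`, `bulk_0_1`),
#'   `origin` (`"direct"`, `"reverse"` or `NA`), `naming_labels`
#'   (length-`n_sets` character vector with placeholders, or `NULL` for
#'   bulk), `conflict` flag, and 1-based trim coordinates
#'   `trim_prefix_end` (last base of the direct-end string, `NA` if that
#'   end is not trimmed) and `trim_suffix_start` (first base of the
#'   3'-end string in read coordinates, `NA` if absent).
#' @export
classify_read <- function(read_seq, scheme, placeholder = "___",
                          overlap_slack = 1L) {
  stopifnot(is.character(read_seq), length(read_seq) == 1L,
            nchar(read_seq) > 0L)
  d <- scan_end(read_seq, scheme, overlap_slack)
  r <- scan_end(reverse_complement(read_seq), scheme, overlap_slack)
  merge_classification(d, r, nchar(read_seq), scheme, placeholder)
}

merge_classification <- function(d, r, read_len, scheme, placeholder) {
  td <- string_tier(d)
  tr <- string_tier(r)
  origin <- if (td == 0L && tr == 0L) NA_character_
            else if (td >= tr) "direct" else "reverse"
  winner <- if (is.na(origin)) NULL else if (origin == "direct") d else r
  conflict <- d$category == "complete" && r$category == "complete" &&
    !identical(d$labels, r$labels)
  category <-
    if (is.null(winner)) "bulk_0_1"
    else switch(winner$category,
                complete = "complete",
                skipped = "skipped",
                incomplete_sequential = paste0("partial_", winner$n_found),
                "bulk_0_1")
  naming_labels <- if (is.null(winner)) NULL else {
    lab <- winner$labels
    lab[is.na(lab)] <- placeholder
    lab
  }
  trim_prefix_end <- if (category != "bulk_0_1" && d$n_found >= 2L)
    d$last_end else NA_integer_
  trim_suffix_start <- if (category != "bulk_0_1" && r$n_found >= 2L)
    read_len - r$last_end + 1L else NA_integer_
  structure(
    list(direct = d, reverse = r, category = category, origin = origin,
         naming_labels = naming_labels, conflict = conflict,
         trim_prefix_end = trim_prefix_end,
         trim_suffix_start = trim_suffix_start,
         read_length = read_len),
    class = "read_classification")
}

#' @export
print.read_classification <- function(x, ...) {
  cat("<read_classification> ", x$category,
      if (isTRUE(x$conflict)) " (conflicting ends)", "\n", sep = "")
  if (!is.null(x$naming_labels))
    cat("  name: ", paste(x$naming_labels, collapse = "_"), "\n", sep = "")
  cat("  direct: ", x$direct$category, " (", x$direct$n_found,
      "), reverse: ", x$reverse$category, " (", x$reverse$n_found, ")\n",
      sep = "")
  invisible(x)
}
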