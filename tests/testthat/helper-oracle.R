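# Independent brute-force oracle for the matcher contract. Written
# deliberately naively: every start position is tested with substr()
# against every barcode, chains are built by literal application of the
# stated rules, and the two ends are merged by the stated priority
# ladder. Shares no code with the package implementation.

o_revcomp <- function(seq) {
  # Biostrings as the independent reverse-complement reference
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# every (start, well) occurrence of any barcode of one set in seq:
# every start position is compared against every barcode
o_find_all <- function(seq, set, bs) {
  out <- list()
  if (nchar(seq) < bs) return(out)
  starts <- 1:(nchar(seq) - bs + 1L)
  for (k in seq_along(set$sequence)) {
    bc <- set$sequence[k]
    for (s in starts[substring(seq, starts, starts + bs - 1L) == bc])
      out[[length(out) + 1L]] <- list(start = s, well = set$well[k])
  }
  out
}

o_scan <- function(seq, scheme, slack = 1L) {
  bs <- scheme$barcode_length
  w <- min(scheme$search_window, nchar(seq))
  region <- substr(seq, 1L, w)
  n <- scheme$n_sets
  found <- list()
  lower <- 1L
  prev_end <- NA
  for (i in seq_len(n)) {
    occ <- o_find_all(region, scheme$sets[[i]], bs)
    occ <- Filter(function(o) o$start >= lower, occ)
    if (length(occ)) {
      starts <- vapply(occ, function(o) o$start, integer(1L))
      best <- occ[[which.min(starts)]]
      found[[as.character(i)]] <- list(
        set = i, well = best$well, start = best$start,
        end = best$start + bs - 1L,
        linker = if (is.na(prev_end)) NA_integer_
                 else best$start - prev_end - 1L)
      prev_end <- best$start + bs - 1L
      lower <- prev_end + 1L - slack
    }
  }
  nf <- length(found)
  idx <- as.integer(names(found))
  cat <- if (nf == n) "complete"
         else if (nf == 0L) "empty"
         else if (nf == 1L) "single"
         else if (length(setdiff(min(idx):max(idx), idx))) "skipped"
         else "incomplete_sequential"
  labels <- rep(NA_character_, n)
  for (f in found) labels[f$set] <- f$well
  list(found = found, n_found = nf, category = cat, labels = labels,
       last_end = if (nf) found[[nf]]$end else NA_integer_,
       linkers = if (nf >= 2L)
         vapply(found[-1L], function(f) f$linker, integer(1L))
       else integer(0L))
}

o_classify <- function(seq, scheme, placeholder = "___", slack = 1L) {
  d <- o_scan(seq, scheme, slack)
  r <- o_scan(o_revcomp(seq), scheme, slack)
  tier <- function(x) if (x$category == "complete") 2L
                      else if (x$n_found >= 2L) 1L else 0L
  origin <- if (tier(d) == 0L && tier(r) == 0L) NA_character_
            else if (tier(d) >= tier(r)) "direct" else "reverse"
  win <- if (is.na(origin)) NULL else if (origin == "direct") d else r
  category <- if (is.null(win)) "bulk_0_1"
              else if (win$category == "complete") "complete"
              else if (win$category == "skipped") "skipped"
              else paste0("partial_", win$n_found)
  naming <- if (is.null(win)) NULL else {
    x <- win$labels; x[is.na(x)] <- placeholder; x
  }
  L <- nchar(seq)
  list(category = category, origin = origin, naming = naming,
       conflict = d$category == "complete" && r$category == "complete" &&
         !identical(d$labels, r$labels),
       direct_n = d$n_found, reverse_n = r$n_found,
       direct_linkers = d$linkers, reverse_linkers = r$linkers,
       trim_prefix_end = if (category != "bulk_0_1" && d$n_found >= 2L)
         d$last_end else NA_integer_,
       trim_suffix_start = if (category != "bulk_0_1" && r$n_found >= 2L)
         L - r$last_end + 1L else NA_integer_)
}

# random read mixing pure noise with implanted barcode fragments
random_oracle_read <- function(scheme) {
  bases <- c("A", "C", "G", "T")
  if (stats::runif(1) < 0.5) {
    paste(sample(bases, sample(10:50, 1), replace = TRUE), collapse = "")
  } else {
    pieces <- character(0)
    for (p in seq_len(sample(2:6, 1))) {
      pieces <- c(pieces, if (stats::runif(1) < 0.5) {
        set <- sample(scheme$n_sets, 1)
        sample(scheme$sets[[set]]$sequence, 1)
      } else {
        paste(sample(bases, sample(0:6, 1), replace = TRUE), collapse = "")
      })
    }
    s <- paste(pieces, collapse = "")
    if (nchar(s) < 5) s <- paste0(s, strrep("A", 5))
    s
  }
}
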