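# Synthetic barcoded-read generator with ground truth. Emulates the
# error structure of a split-and-pool long-read library: variable
# adapter residue before the string, linker shrink/growth, incomplete
# and skipped-set strings, a reverse-complement string on the 3' end,
# conflicting end combinations, and global read orientation.

#' Simulation configuration
#'
#' Bundles a [barcode_scheme()] with the generative parameters of the
#' synthetic library. Defaults reproduce the error structure reported for
#' a PacBio HiFi split-and-pool run: 11.20% complete strings, 13.62%
#' three-barcode and 3.82% two-barcode sequential strings, rare skipped
#' strings, 70.7% one-or-no-barcode reads; linkers of nominal length
#' 98.48% of the time (3 nt 0.65%, 5 nt 0.54%, other lengths 0.33%); and
#' an adapter-residue length peaked at 10 nt, so complete strings end
#' near position 54 rather than the nominal 44.
#'
#' @param scheme A [barcode_scheme()].
#' @param n_reads Number of reads to generate.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param category_mix Named probabilities over
#'   `complete`, `partial_3`, `partial_2`, `skipped`, `single`, `none`
#'   (must sum to 1). For schemes with fewer than 4 sets, categories
#'   requiring more sets than available must have probability 0.
#' @param linker_dist Named probabilities over linker lengths (names are
#'   lengths in nt).
#' @param adapter_prefix_dist Named probabilities over adapter-residue
#'   lengths (nt) prepended before each string. The maximum residue plus
#'   the longest possible string must fit inside the search window.
#' @param both_ends_prob Probability that a read with a 2+ barcode string
#'   also carries a reverse-complement string at its 3' end.
#' @param conflict_prob Probability, given a complete-string read with
#'   strings on both ends, that the two ends carry different well
#'   combinations.
#' @param insert_length Length-2 vector `c(min, max)` of the uniform
#'   biological-insert length (nt). The default 150--400 nt is
#'   deliberately shorter than real whole-genome-amplified fragments
#'   (several kb); only the windows at the read ends are ever scanned, so
#'   insert length affects runtime but no measured quantity.
#' @param orientation_prob Probability the whole read is emitted
#'   reverse-complemented.
#' @param prefix_run_prob Probability that a sequential partial string is
#'   the leading run of sets (e.g. D-C-B rather than C-B-A); the
#'   complementary mass is spread uniformly over the other contiguous
#'   runs. Three-barcode leading runs dominate two-barcode trailing runs
#'   in real data, so the two partial categories use `prefix_run_prob`
#'   and `1 - prefix_run_prob` respectively.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scheme, n_reads, seed = 1L,
                       category_mix = c(complete = 0.1120,
                                        partial_3 = 0.1362,
                                        partial_2 = 0.0382,
                                        skipped = 0.0063,
                                        single = 0.2000,
                                        none = 0.5073),
                       linker_dist = c("2" = 0.00165, "3" = 0.0065,
                                       "4" = 0.9848, "5" = 0.0054,
                                       "6" = 0.00165),
                       adapter_prefix_dist = NULL,
                       both_ends_prob = 0.5,
                       conflict_prob = 0.008,
                       insert_length = c(150L, 400L),
                       orientation_prob = 0.5,
                       prefix_run_prob = 0.9) {
  stopifnot(inherits(scheme, "barcode_scheme"), n_reads > 0L)
  if (is.null(adapter_prefix_dist)) {
    len <- 0:30
    p <- stats::dpois(len, 10)
    adapter_prefix_dist <- stats::setNames(p / sum(p), len)
  }
  req <- c("complete", "partial_3", "partial_2", "skipped", "single", "none")
  if (!all(req %in% names(category_mix)))
    stop("category_mix must name all of: ", paste(req, collapse = ", "))
  category_mix <- category_mix[req]
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop("category_mix probabilities must sum to 1")
  if (abs(sum(linker_dist) - 1) > 1e-8)
    stop("linker_dist probabilities must sum to 1")
  if (abs(sum(adapter_prefix_dist) - 1) > 1e-8)
    stop("adapter_prefix_dist probabilities must sum to 1")
  n <- scheme$n_sets
  if (category_mix[["partial_3"]] > 0 && n < 4L)
    stop("category partial_3 requires at least 4 barcode sets")
  if (category_mix[["partial_2"]] > 0 && n < 3L)
    stop("category partial_2 requires at least 3 barcode sets")
  if (category_mix[["skipped"]] > 0 && n < 3L)
    stop("category skipped requires at least 3 barcode sets")
  max_res <- max(as.integer(names(adapter_prefix_dist)[adapter_prefix_dist > 0]))
  max_lk <- max(as.integer(names(linker_dist)[linker_dist > 0]))
  max_string <- n * scheme$barcode_length + (n - 1L) * max_lk
  if (max_res + max_string > scheme$search_window)
    stop("adapter residue (max ", max_res, ") plus longest string (",
         max_string, ") exceeds the search window (",
         scheme$search_window, ")")
  structure(list(scheme = scheme, n_reads = as.integer(n_reads),
                 seed = as.integer(seed), category_mix = category_mix,
                 linker_dist = linker_dist,
                 adapter_prefix_dist = adapter_prefix_dist,
                 both_ends_prob = both_ends_prob,
                 conflict_prob = conflict_prob,
                 insert_length = as.integer(insert_length),
                 orientation_prob = orientation_prob,
                 prefix_run_prob = prefix_run_prob),
            class = "sim_config")
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sample_len <- function(dist, n = 1L) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

# Which sets (indices, outermost first) are present for a sampled category.
sample_present_sets <- function(category, n_sets, prefix_run_prob) {
  run_of <- function(k, prefer_prefix) {
    starts <- seq_len(n_sets - k + 1L)
    preferred <- if (prefer_prefix) 1L else n_sets - k + 1L
    others <- setdiff(starts, preferred)
    s <- if (length(others) == 0L || stats::runif(1L) < prefix_run_prob)
      preferred else sample(others, 1L)
    s:(s + k - 1L)
  }
  switch(category,
         complete = seq_len(n_sets),
         partial_3 = run_of(3L, prefer_prefix = TRUE),
         partial_2 = run_of(2L, prefer_prefix = FALSE),
         skipped = {
           interior <- 2:(n_sets - 1L)
           drop <- if (length(interior) > 1L && stats::runif(1L) < 0.1)
             sample(interior, 2L) else
               interior[sample.int(length(interior), 1L)]
           setdiff(seq_len(n_sets), drop)
         },
         single = sample.int(n_sets, 1L),
         none = integer(0L))
}

# Assemble one barcode-string block: residue + barcodes joined by random
# linker fill. Returns the block string plus intended per-set labels.
build_block <- function(present, labels, residue_len, linker_lens, scheme) {
  if (length(present) == 0L)
    return(list(seq = random_dna(residue_len), labels = rep(NA_character_,
                                                            scheme$n_sets)))
  pieces <- character(0L)
  lab <- rep(NA_character_, scheme$n_sets)
  for (j in seq_along(present)) {
    i <- present[j]
    set <- scheme$sets[[i]]
    bc <- set$sequence[match(labels[i], set$well)]
    lab[i] <- labels[i]
    if (j > 1L) pieces <- c(pieces, random_dna(linker_lens[j - 1L]))
    pieces <- c(pieces, bc)
  }
  list(seq = paste0(random_dna(residue_len), paste(pieces, collapse = "")),
       labels = lab)
}

# All exact occurrences (starts) of any barcode of set i inside region.
region_hits <- function(region, set, bs) {
  w <- nchar(region)
  if (w < bs) return(list(start = integer(0L), label = character(0L)))
  starts <- seq_len(w - bs + 1L)
  m <- match(substring(region, starts, starts + bs - 1L), set$sequence)
  hit <- which(!is.na(m))
  list(start = hit, label = set$well[m[hit]])
}

# TRUE when each scan region contains exactly the intended barcodes of
# each set (right labels, right multiplicity) and nothing else.
read_is_clean <- function(read, scheme, direct_labels, reverse_labels) {
  w <- scheme$search_window
  regions <- list(substr(read, 1L, min(w, nchar(read))),
                  substr(reverse_complement(read), 1L, min(w, nchar(read))))
  intended <- list(direct_labels, reverse_labels)
  for (k in 1:2) {
    for (i in seq_len(scheme$n_sets)) {
      hits <- region_hits(regions[[k]], scheme$sets[[i]],
                          scheme$barcode_length)
      want <- intended[[k]][i]
      if (is.na(want)) {
        if (length(hits$start)) return(FALSE)
      } else {
        if (length(hits$start) != 1L || hits$label != want) return(FALSE)
      }
    }
  }
  TRUE
}

#' Generate synthetic barcoded reads with ground truth
#'
#' Emits `config$n_reads` FASTQ records plus a tab-separated truth table.
#' Each read is assembled as `[adapter residue][barcode string][insert]`
#' and, with probability `both_ends_prob`, a reverse-complement string
#' (with its own residue and linkers) at the 3' end; the whole read may
#' then be globally reverse-complemented. Any read whose scan windows
#' contain an unintended exact barcode occurrence (a chance collision in
#' random sequence, which would make the truth ambiguous) is resampled;
#' chance hits beyond the windows are left in place. Quality strings are
#' constant high quality; matching ignores quality. Deterministic for a
#' given `config$seed`; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @param fastq_path Output FASTQ path.
#' @param truth_path Output truth-table path (TSV); defaults to
#'   `fastq_path` with a `_truth.tsv` suffix.
#' @return Invisibly, a list with `fastq`, `truth` (paths) and the truth
#'   `data.frame`. Truth columns include the per-set true labels, the
#'   sampled category, which ends carry strings, the injected linker
#'   lengths, orientation, conflict flag, and the expected output
#'   category/file under the classification rules.
#' @export
simulate_reads <- function(config, fastq_path, truth_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth_path))
    truth_path <- paste0(sub("\\.(fastq|fq)(\\.gz)?$", "", fastq_path),
                         "_truth.tsv")
  scheme <- config$scheme
  n_sets <- scheme$n_sets
  local_rng(config$seed, {
    n <- config$n_reads
    cats <- sample(names(config$category_mix), n, replace = TRUE,
                   prob = config$category_mix)
    ids <- sprintf("sim_%07d_%s", seq_len(n), cats)
    recs <- vector("list", n)
    truth <- vector("list", n)
    for (ri in seq_len(n)) {
      category <- cats[ri]
      present <- sample_present_sets(category, n_sets,
                                     config$prefix_run_prob)
      labels <- rep(NA_character_, n_sets)
      for (i in present)
        labels[i] <- scheme$sets[[i]]$well[
          sample.int(scheme$barcodes_per_set, 1L)]
      multi <- length(present) >= 2L
      both <- multi && stats::runif(1L) < config$both_ends_prob
      conflict <- category == "complete" && both &&
        stats::runif(1L) < config$conflict_prob
      labels2 <- labels
      if (conflict) {
        repeat {
          for (i in present)
            labels2[i] <- scheme$sets[[i]]$well[
              sample.int(scheme$barcodes_per_set, 1L)]
          if (!identical(labels2, labels)) break
        }
      }
      flipped <- stats::runif(1L) < config$orientation_prob

      ok <- FALSE
      for (attempt in seq_len(60L)) {
        lk5 <- if (length(present) >= 2L)
          sample_len(config$linker_dist, length(present) - 1L) else integer(0L)
        lk3 <- if (both)
          sample_len(config$linker_dist, length(present) - 1L) else integer(0L)
        res5 <- sample_len(config$adapter_prefix_dist)
        res3 <- if (both) sample_len(config$adapter_prefix_dist) else 0L
        ins <- sample(config$insert_length[1L]:config$insert_length[2L], 1L)
        b5 <- build_block(present, labels, res5, lk5, scheme)
        read <- paste0(b5$seq, random_dna(ins))
        rev_labels <- rep(NA_character_, n_sets)
        if (both) {
          b3 <- build_block(present, labels2, res3, lk3, scheme)
          read <- paste0(read, reverse_complement(b3$seq))
          rev_labels <- b3$labels
        }
        dir_labels <- b5$labels
        if (flipped) {
          read <- reverse_complement(read)
          tmp <- dir_labels; dir_labels <- rev_labels; rev_labels <- tmp
          tmp <- lk5; lk5 <- lk3; lk3 <- tmp
        }
        if (read_is_clean(read, scheme, dir_labels, rev_labels)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("failed to generate a collision-free read after 60 attempts ",
             "(read ", ri, "); scheme may be too dense for its window")

      # expected classification under the merge rules: direct end wins
      expected_labels <-
        if (category %in% c("single", "none")) rep(NA_character_, n_sets)
        else if (all(is.na(dir_labels))) rev_labels
        else dir_labels
      expected_category <- switch(category,
                                  single = "bulk_0_1", none = "bulk_0_1",
                                  category)
      recs[[ri]] <- paste0("@", ids[ri], "\n", read, "\n+\n",
                           strrep("I", nchar(read)), "\n")
      truth[[ri]] <- data.frame(
        read_id = ids[ri], category = category,
        t(stats::setNames(labels, paste0("label_", names(scheme$sets)))),
        ends = if (both) "both" else if (category == "none") "none" else "one",
        conflict = conflict, flipped = flipped,
        linkers_direct = paste(lk5, collapse = ","),
        linkers_reverse = paste(lk3, collapse = ","),
        expected_category = expected_category,
        expected_labels = paste(ifelse(is.na(expected_labels), "",
                                       expected_labels), collapse = ";"),
        stringsAsFactors = FALSE)
    }
    con <- fastq_connection(fastq_path, "wb")
    writeLines(unlist(recs), con, sep = "")
    close(con)
    truth_df <- do.call(rbind, truth)
    write_tsv(truth_df, truth_path)
    invisible(list(fastq = fastq_path, truth = truth_path,
                   truth_table = truth_df))
  })
}

#' Score a demultiplexing run against simulation ground truth
#'
#' Joins a [demultiplex()] result with the truth table written by
#' [simulate_reads()] (by read id) and reports, per truth category, the
#' fraction of reads whose assigned category and naming labels match the
#' expected ones, plus a truth-by-observed confusion table.
#'
#' @param result A [demultiplex()] result (the run on the simulated
#'   FASTQ).
#' @param truth The truth `data.frame`, or the path to the truth TSV.
#' @return A list with `per_category` (data.frame: category, n, accuracy),
#'   `overall_accuracy`, and `confusion` (table of truth expected category
#'   vs observed category).
#' @export
score_against_truth <- function(result, truth) {
  stopifnot(inherits(result, "demux_result"))
  if (is.character(truth))
    truth <- utils::read.delim(truth, stringsAsFactors = FALSE,
                               colClasses = "character")
  reads <- result$reads
  if (nrow(reads) != nrow(truth) ||
      !setequal(reads$read_id, truth$read_id))
    stop("read ids of result and truth table do not match")
  truth <- truth[match(reads$read_id, truth$read_id), ]
  exp_lab <- as.character(truth$expected_labels)
  obs_lab <- reads$naming
  correct <- reads$category == truth$expected_category &
    (truth$expected_category == "bulk_0_1" |
       vapply(seq_len(nrow(reads)), function(i) {
         # compare only the label slots the truth expects to be recovered
         e <- strsplit(exp_lab[i], ";", fixed = TRUE)[[1L]]
         o <- strsplit(obs_lab[i], ";", fixed = TRUE)[[1L]]
         length(o) >= length(e) &&
           all(e[nzchar(e)] == o[seq_along(e)][nzchar(e)])
       }, logical(1L)))
  per_cat <- do.call(rbind, lapply(split(correct, truth$category),
                                   function(v) data.frame(n = length(v),
                                                          accuracy = mean(v))))
  per_cat <- data.frame(category = rownames(per_cat), per_cat,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_category = per_cat,
       overall_accuracy = mean(correct),
       confusion = table(truth = truth$expected_category,
                         observed = reads$category))
}
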