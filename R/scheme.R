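# Barcode scheme: ordered barcode sets plus the geometry parameters that
# constrain the positional search (barcode length, linker length, window).

#' Construct a barcode scheme
#'
#' A barcode scheme describes the combinatorial split-and-pool design: an
#' ordered list of barcode sets (outermost set first, i.e. the set ligated
#' last and therefore encountered first when reading from the 5' end) plus
#' the geometry used by the positional search.
#'
#' @param sets A named list of barcode sets. Each element is a
#'   `data.frame` with columns `well` (well label) and `sequence`
#'   (uppercase DNA); the element name is the set label (e.g. `"D"`).
#'   Sets must be given in read order: outermost (last-ligated) first.
#' @param barcodes_per_set Number of barcodes in every set (`-bn`).
#' @param barcode_length Length of every barcode in nucleotides (`-bs`).
#' @param linker_length Expected linker length between consecutive
#'   barcodes in nucleotides (`-ls`).
#' @param search_window Length of the region at each read end searched for
#'   barcodes (`-l`). Must be at least the nominal full-string length
#'   `n_sets * barcode_length + (n_sets - 1) * linker_length`.
#'
#' @return An object of class `barcode_scheme`.
#' @seealso [read_barcode_scheme()], [synthetic_scheme()],
#'   [combination_capacity()]
#' @export
barcode_scheme <- function(sets, barcodes_per_set, barcode_length,
                           linker_length, search_window) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("'sets' must be a non-empty list of barcode sets")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every barcode set must be named with its set label")
  if (anyDuplicated(labels))
    stop("duplicate set labels: ", paste(labels[duplicated(labels)], collapse = ", "))
  barcodes_per_set <- as.integer(barcodes_per_set)
  barcode_length <- as.integer(barcode_length)
  linker_length <- as.integer(linker_length)
  search_window <- as.integer(search_window)
  stopifnot(barcodes_per_set > 0L, barcode_length > 0L,
            linker_length >= 0L, search_window > 0L)

  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    lab <- labels[i]
    if (!is.data.frame(s) || !all(c("well", "sequence") %in% names(s)))
      stop("set ", lab, ": expected a data.frame with columns 'well' and 'sequence'")
    well <- as.character(s$well)
    sequence <- toupper(as.character(s$sequence))
    if (nrow(s) != barcodes_per_set)
      stop("set ", lab, ": has ", nrow(s), " barcodes, expected ",
           barcodes_per_set, " (-bn)")
    bad_len <- nchar(sequence) != barcode_length
    if (any(bad_len))
      stop("set ", lab, ": sequence length != ", barcode_length,
           " (-bs) for well(s) ", paste(well[bad_len], collapse = ", "))
    bad_chr <- grepl("[^ACGT]", sequence)
    if (any(bad_chr))
      stop("set ", lab, ": non-ACGT character in well(s) ",
           paste(well[bad_chr], collapse = ", "))
    if (anyDuplicated(sequence))
      stop("set ", lab, ": duplicate barcode sequence(s) ",
           paste(unique(sequence[duplicated(sequence)]), collapse = ", "))
    if (anyDuplicated(well))
      stop("set ", lab, ": duplicate well label(s) ",
           paste(unique(well[duplicated(well)]), collapse = ", "))
    list(set_label = lab, well = well, sequence = sequence)
  })
  names(sets) <- labels

  scheme <- structure(
    list(sets = sets,
         n_sets = length(sets),
         barcodes_per_set = barcodes_per_set,
         barcode_length = barcode_length,
         linker_length = linker_length,
         search_window = search_window),
    class = "barcode_scheme")
  nominal <- nominal_string_length(scheme)
  if (search_window < nominal)
    stop("search window (-l = ", search_window,
         ") is shorter than the nominal barcode string (", nominal, " nt)")
  scheme
}

#' Read a barcode scheme file
#'
#' Parses a tab-separated barcode scheme file into a [barcode_scheme()].
#' The dialect is: an optional header / comment lines starting with `#`,
#' then one row `set<TAB>well<TAB>sequence` per barcode. Sets must appear
#' in read order (outermost, i.e. last-ligated, first -- D, C, B, A for a
#' four-round plate). Lowercase sequences are uppercased; anything outside
#' A/C/G/T is rejected because matching is exact.
#'
#' @param path Path to the scheme file.
#' @param barcodes_per_set,barcode_length,linker_length,search_window
#'   Geometry parameters (the CLI's `-bn`, `-bs`, `-ls`, `-l`). They are
#'   validated against the file contents; a mismatch is an error, never
#'   silently reconciled.
#'
#' @return A `barcode_scheme`.
#' @export
read_barcode_scheme <- function(path, barcodes_per_set = 24L,
                                barcode_length = 8L, linker_length = 4L,
                                search_window = 88L) {
  if (!file.exists(path))
    stop("barcode scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("barcode scheme file has no data rows: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- idx[which(nf != 3L)[1L]]
    stop("malformed scheme line ", bad, " (expected 3 tab-separated fields): ",
         lines[bad])
  }
  df <- data.frame(set = vapply(parts, `[[`, "", 1L),
                   well = vapply(parts, `[[`, "", 2L),
                   sequence = vapply(parts, `[[`, "", 3L),
                   stringsAsFactors = FALSE)
  set_order <- unique(df$set)
  sets <- lapply(set_order, function(lab) {
    rows <- df[df$set == lab, , drop = FALSE]
    data.frame(well = rows$well, sequence = rows$sequence,
               stringsAsFactors = FALSE)
  })
  names(sets) <- set_order
  barcode_scheme(sets, barcodes_per_set = barcodes_per_set,
                 barcode_length = barcode_length,
                 linker_length = linker_length,
                 search_window = search_window)
}

#' Write a barcode scheme back to the file dialect
#'
#' Inverse of [read_barcode_scheme()]: the written file re-parses to an
#' identical scheme (given the same geometry parameters).
#'
#' @param scheme A `barcode_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  rows <- unlist(lapply(scheme$sets, function(s) {
    paste(s$set_label, s$well, s$sequence, sep = "\t")
  }), use.names = FALSE)
  writeLines(c("#set\twell\tsequence", rows), path)
  invisible(path)
}

#' Number of distinct barcode combinations a scheme can generate
#'
#' `barcodes_per_set ^ n_sets`: e.g. 24^4 = 331776 for a four-round,
#' 24-well-per-round plate.
#'
#' @param scheme A `barcode_scheme`.
#' @return A number (may exceed integer range, e.g. 96^4).
#' @export
combination_capacity <- function(scheme) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  as.numeric(scheme$barcodes_per_set)^scheme$n_sets
}

#' Nominal full barcode-string length
#'
#' Length in nucleotides of an error-free barcode string:
#' `n_sets * barcode_length + (n_sets - 1) * linker_length`
#' (44 nt for 4 x 8 nt barcodes with 4 nt linkers).
#'
#' @param scheme A `barcode_scheme`.
#' @return Integer length in nt.
#' @export
nominal_string_length <- function(scheme) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  scheme$n_sets * scheme$barcode_length +
    (scheme$n_sets - 1L) * scheme$linker_length
}

#' Generate a synthetic barcode scheme
#'
#' Draws random, unique (within and across sets) barcode sequences for a
#' given geometry. Useful for tests and simulations when a real plate's
#' barcode list is unavailable; sequences are deterministic for a given
#' `seed`.
#'
#' @param n_sets Number of ligation rounds (sets).
#' @param barcodes_per_set,barcode_length,linker_length,search_window
#'   Geometry, as in [barcode_scheme()].
#' @param seed Integer seed for the barcode draw (local RNG; the caller's
#'   RNG state is untouched).
#' @param set_labels Set labels, outermost first. Defaults to the last
#'   `n_sets` letters reversed (`D`, `C`, `B`, `A` for 4 sets).
#' @return A `barcode_scheme`.
#' @export
synthetic_scheme <- function(n_sets = 4L, barcodes_per_set = 24L,
                             barcode_length = 8L, linker_length = 4L,
                             search_window = 88L, seed = 20250801L,
                             set_labels = NULL) {
  n_sets <- as.integer(n_sets)
  if (is.null(set_labels))
    set_labels <- rev(LETTERS[seq_len(n_sets)])
  stopifnot(length(set_labels) == n_sets)
  n_total <- n_sets * barcodes_per_set
  if (4^barcode_length < 2L * n_total)
    stop("barcode length ", barcode_length,
         " too short to draw ", n_total, " distinct barcodes")
  seqs <- local_rng(seed, {
    pool <- character(0L)
    while (length(pool) < n_total) {
      draw <- vapply(seq_len(n_total), function(i)
        paste(sample(c("A", "C", "G", "T"), barcode_length, replace = TRUE),
              collapse = ""), "")
      pool <- unique(c(pool, draw))
    }
    pool[seq_len(n_total)]
  })
  sets <- lapply(seq_len(n_sets), function(i) {
    idx <- (i - 1L) * barcodes_per_set + seq_len(barcodes_per_set)
    data.frame(well = sprintf("%s%02d", set_labels[i], seq_len(barcodes_per_set)),
               sequence = seqs[idx], stringsAsFactors = FALSE)
  })
  names(sets) <- set_labels
  barcode_scheme(sets, barcodes_per_set, barcode_length,
                 linker_length, search_window)
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat("Barcode scheme: ", x$n_sets, " sets x ", x$barcodes_per_set,
      " barcodes x ", x$barcode_length, " nt\n", sep = "")
  cat("  set order (outermost first): ",
      paste(names(x$sets), collapse = " -> "), "\n", sep = "")
  cat("  linker ", x$linker_length, " nt; nominal string ",
      nominal_string_length(x), " nt; search window ", x$search_window,
      " nt\n", sep = "")
  cat("  combination capacity: ",
      format(combination_capacity(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
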