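---
title: "splitpool: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splitpool: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitpool)
```

## The problem

Split-and-pool combinatorial barcoding labels thousands of single-cell
compartments with a short number of ligation rounds: in each round the
pooled compartments are split across the wells of one plate section, a
round-specific well barcode is ligated, and everything is re-pooled. After
four rounds with 24 wells each, every compartment carries one of
$24^4 = 331{,}776$ possible ordered barcode strings. In the default
geometry each string is nominally 44 nt: four 8 nt barcodes separated by
three 4 nt linkers.

Demultiplexing such reads is harder than matching a single whitelist
barcode:

* the string sits at a variable offset from the read start, because
  long-read hairpin-adapter residues of varying length can precede it;
* small ligation errors shrink or stretch the linkers, shifting every
  downstream barcode;
* individual rounds can fail, producing strings with missing leading sets
  or skipped interior sets;
* the string can sit on either end of the read, in reverse-complement
  orientation on the 3′ end.

`splitpool` detects these strings by **exact** matching under positional
constraints, assigns every read to exactly one per-cell FASTQ file, and
reports the diagnostics (linker-length spectrum, per-well usage, category
fractions) a laboratory needs to tune its ligation protocol.

## The detection model

All coordinates below are 1-based and inclusive.

**Windowed chained search.** Only the first `-l` nucleotides of each read
end are searched (default 88). The window guards specificity: an 8 nt
barcode has a non-trivial chance of occurring in natural DNA, so matches
deep inside the read are not meaningful. The window deliberately exceeds
the nominal 44 nt string so that adapter residue and linker drift do not
push real strings out of reach.

The outermost set (ligated last, so first in the read) is searched over
the whole window. After a match of set $k$ ending at position $e$, set
$k+1$ is searched with lower bound $e + 1 - s$ where $s$ is the
`overlap_slack` (default 1 nt, so a 1 nt overlap is detectable and
reported as a linker of $-1$ nt), and with the same global window as the
upper bound. Within a set, among all exact occurrences the one with the
**smallest start** (closest to the preceding barcode) wins. When a set is
not found the search falls through to the next set *from the same lower
bound*. This single fall-through rule produces all the documented
behaviours at once: a missing leading set yields a restart with the inner
sets; a missing interior set yields a "skipped" chain; the gap between
any two consecutive found barcodes is recorded as the observed linker
length.

**Why exact matching.** Barcodes within a plate section are few and
short; allowing mismatches would trade a small sensitivity gain for
cross-well misassignment risk, and a barcode carrying an error is
operationally equivalent to a failed ligation, a case the category
taxonomy already covers. Consequently `N` bases never match, and no
error-correction is attempted.

**Both ends and the priority ladder.** Each read is scanned directly and
as its reverse complement. The merged assignment follows:
direct complete > reverse complete > direct partial (≥ 2 barcodes) >
reverse partial > bulk. Identical complete strings on both ends assign
the read once; complete-but-different ends are a flagged *conflict* and
the direct end names the file. Single-barcode evidence never names a
read: it joins the no-barcode reads in the bulk file, which remains
useful as conventional bulk data.

**Trimming.** A detected string of ≥ 2 barcodes is trimmed off its end,
by default together with everything before it (adapter residue is not
biological sequence; observed strings ending near position 54 rather
than 44 are exactly such residues). `keep_adapter_residue = TRUE`
excises only the string. A trim that would leave an empty sequence is
refused and the read is routed untrimmed to the bulk file with a
warning. Bulk reads are never modified.

## Output files

* `<L1>_<L2>_..._<Ln>.fastq` per detected combination, with missing sets
  shown as the placeholder (default `___`);
* `<stem>_3_2.fastq` — a combined copy of all partial/skipped reads;
* `<stem>_0_1.fastq` — bulk reads (one or no barcodes), untrimmed;
* `<stem>_summary.txt` — per read, the labels found on both ends;
* `<stem>_stats.txt` — per read, the storage file, last-barcode end
  position (1-based) and linker lengths;
* `<stem>_report.txt` / `.json` — aggregate category fractions, the
  linker-length × end-position histogram, per-well counts, both-end
  confirmation and conflict rates.

The placeholder default follows the operational description (`___`); the
alternative two-underscore form seen elsewhere is available through the
`placeholder` option. The bulk/combined filenames generalise the input
filename stem.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `-l` / `search_window` | nt | 88 | 2× the nominal string; tolerates ~30 nt residue plus linker drift without admitting deep chance matches |
| `-bn` / `barcodes_per_set` | — | 24 | 24-well plate sections |
| `-bs` / `barcode_length` | nt | 8 | plate chemistry |
| `-ls` / `linker_length` | nt | 4 | nominal linker; only used for reporting bins and geometry checks |
| `overlap_slack` | nt | 1 | permits the −1 nt linker a 1 nt over-chewed ligation can produce; configurable because the right bound is not observable from first principles |
| `placeholder` | — | `___` | missing-set label in filenames and tables |

Geometry flags are validated against the scheme file, never trusted: a
mismatch between `-bn`/`-bs` and the file contents is a hard error, since
silently proceeding would mis-demultiplex every read.

## The synthetic stated world

`sim_config()` + `simulate_reads()` generate reads as
`[residue][barcode string][insert][reverse-complement string]`, with:

* category mix (complete / partial₃ / partial₂ / skipped / single /
  none) defaulting to 11.20 / 13.62 / 3.82 / 0.63 / 20.0 / 50.73 % — the
  first three are reported run-level rates for a PacBio HiFi pilot of
  this chemistry; the published data do not split the 71.4 % one-or-no-
  barcode mass into single vs none, nor report skipped strings as a
  fraction of total reads (only of both-end-confirmed reads), so those
  three values are this package's modelling choice, fixed once. The
  implied bulk fraction is 70.73 %.
* linker lengths i.i.d. from {2:0.165 %, 3:0.65 %, 4:98.48 %, 5:0.54 %,
  6:0.165 %} (the reported spectrum, with the 0.33 % "other" mass split
  between 2 and 6 nt);
* adapter residue lengths Poisson(10)-shaped over 0–30 nt, so complete
  strings typically end near position 54;
* a 3′ reverse-complement string with probability 0.5 and, among
  both-end complete reads, a different combination (conflict) with
  probability 0.008 — together reproducing the reported 0.4 % conflict
  rate among complete-string reads;
* whole-read reverse-complement orientation with probability 0.5;
* partial runs preferring the leading sets for 3-barcode strings and the
  trailing sets for 2-barcode strings (leading 3-barcode failures
  dominate real data);
* inserts i.i.d. uniform ACGT, Uniform(150, 400) nt long — deliberately
  much shorter than real multi-kb amplified fragments, because only the
  end windows are ever scanned and shorter inserts keep 50k-read
  simulations inside test budgets.

**Collision control.** A random insert or residue can by chance contain
an exact barcode inside a scan window (~0.4 % of reads at the default
geometry), which would make the ground truth ambiguous and, worse, could
mis-anchor the chain in front of the true string. The generator
therefore resamples the random portions of *any* read whose scan windows
contain an unintended exact barcode occurrence — not only the
no-barcode reads. Chance hits beyond the windows are left in place, as
they are in real data. This is a property of the simulator, not of the
matcher: on real reads such chance anchors are a genuine, irreducible
error mode of exact matching.

**What a green test does not establish.** The generator draws linkers
independently, uses uniform well usage, constant quality, and no
substitution/indel errors inside barcodes (under exact matching a
corrupted barcode is identical to an absent one, which the category mix
already represents). Real libraries have correlated failures (a bad
ligation round depresses a whole set), non-uniform well loading and
residue distributions with heavier tails; recovery rates measured on the
simulator are therefore upper bounds on real-data behaviour, and the
category mix measured on real data is an *input* here, not a finding.

## Numerical and degenerate-case choices

* Coordinates are 1-based inclusive internally and in all outputs.
* Reads shorter than the window are scanned over their full length;
  reads shorter than one barcode are category `empty`.
* Ties cannot arise in nearest-match selection (two distinct barcodes
  cannot occupy the same start), and within a set the smallest start
  wins deterministically; the whole matcher is randomness-free.
* Percentages are reported to two decimals; fractions of an empty
  denominator are `NA`, not 0.
* The `n_found ≤ 1` bulk rule is applied after the degenerate-trim
  check, so a read whose string spans the entire sequence is preserved
  untrimmed rather than emptied.
* File appends are open-append-close per chunk and per file, bounding
  simultaneously open handles regardless of how many thousand
  combination files a run creates; processing is single-threaded by
  design because all reads share one set of output files.

## Known limitations

* Exact matching cannot rescue barcodes with sequencing errors; on
  error-rich platforms sensitivity drops with per-base error rate.
* One global barcode length per scheme (`-bs`); schemes mixing barcode
  lengths across sets are not supported.
* The downstream search is bounded only by the global window; a
  hypothetical tighter per-set bound could reject a few more chance
  matches but is not derivable from the published behaviour, so the
  simpler rule was chosen.
* No paired-end mode (consensus long reads are single sequences).
* The whole per-read digest is kept in memory for the statistics module
  (~a few hundred bytes/read), which is fine up to millions of reads but
  would need a spill-to-disk mode beyond that.
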