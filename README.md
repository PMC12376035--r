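# splitpool

Demultiplexing of sequencing reads barcoded by **split-and-pool
combinatorial ligation**.

In split-and-pool single-cell workflows, compartments are repeatedly
split across the wells of a barcoding plate, a round-specific barcode is
ligated, and everything is re-pooled. Four rounds over 24-well sections
yield strings of four 8 nt barcodes separated by 4 nt linkers — a
nominal 44 nt string identifying one of 24⁴ = 331,776 compartments.
`splitpool` is for anyone who needs to turn the resulting FASTQ file
back into per-cell files: it finds these strings by **exact matching
under positional constraints**, tolerating

* variable adapter residue before the string (long-read hairpin
  adapters are often incompletely trimmed),
* linkers that shrank or grew by a few nucleotides through ligation
  errors,
* strings with missing leading sets or skipped interior sets,
* reverse-complement strings on the 3′ end of the read.

Every read is routed to exactly one per-cell FASTQ file named by its
barcode combination (`D05_C12_B01_A20.fastq`; missing sets appear as
`___`), reads with two or three barcodes are additionally pooled in
`<stem>_3_2.fastq`, and reads with one or no barcodes go to the bulk
file `<stem>_0_1.fastq`. Per-read and aggregate diagnostics (linker
length spectrum by string position, per-well usage, category fractions)
support tuning of the laboratory protocol.

The core search: the outermost set is matched inside the first `-l`
nucleotides (default 88); after a match of set *k* ending at *e*, set
*k+1* is searched from *e* (1 nt overlap slack) to the window end, and
the nearest exact occurrence wins; a missed set falls through to the
next one from the same anchor, which covers both restarts (missing
leading sets) and skips (missing interior sets). Matching is exact —
no mismatches, no indels — so a corrupted barcode is treated as an
absent one. Both read ends are scanned; complete strings always have
priority, and when both ends are complete but disagree, the direct end
names the file and the conflict is flagged.

A synthetic read generator with ground truth
(`sim_config()` / `simulate_reads()` / `score_against_truth()`)
emulates the documented error structure (category mix, linker spectrum,
adapter residue, orientation, conflicting ends) so the whole pipeline is
testable without any sequencing data. See
`vignette("splitpool-methods")` for the model, assumptions and design
choices.

## Worked example

```r
library(splitpool)

scheme <- read_barcode_scheme(
  system.file("extdata", "barcodes_atrandi_synthetic.tsv",
              package = "splitpool"))   # synthetic stand-in plate, 4 x 24 x 8 nt
scheme
#> Barcode scheme: 4 sets x 24 barcodes x 8 nt
#>   set order (outermost first): D -> C -> B -> A
#>   linker 4 nt; nominal string 44 nt; search window 88 nt
#>   combination capacity: 331,776

# simulate a 5,000-read library with the default (documented) error mix
sim <- simulate_reads(sim_config(scheme, n_reads = 5000, seed = 7),
                      "reads.fastq")

res <- demultiplex("reads.fastq", scheme, "out/")
res
#> Demultiplexing of 5000 reads
#>   complete        525  (10.50%)
#>   partial_3       703  (14.06%)
#>   partial_2       197  (3.94%)
#>   skipped          36  (0.72%)
#>   bulk_0_1       3539  (70.78%)
#>   conflicting complete ends: 1
#>   distinct output files: 1424

aggregate_report(res)
#> Aggregate barcoding report (5000 reads)
#>   ...
#>   linkers observed: 4891
#>     <4 nt: 0.96%   4 nt: 98.32%   >4 nt: 0.72%
#>   strings confirmed on both ends: 748
#>   conflicting ends among complete reads: 0.19%

score_against_truth(res, sim$truth_table)$per_category
#>    category    n accuracy
#> 1  complete  525        1
#> 2      none 2557        1
#> 3 partial_2  197        1
#> 4 partial_3  703        1
#> 5    single  982        1
#> 6   skipped   36        1
```

Reading the numbers: 10.5% of reads carried a full D-C-B-A string and
became per-cell files; 18.7% carried partial or skipped strings (named
with `___` placeholders and also pooled in `reads_3_2.fastq`); 70.8%
had at most one barcode and went to the bulk file. 98.3% of observed
linkers had the nominal 4 nt length — the diagnostic a wet lab watches
when tuning ligation. Against the simulation's ground truth, every
category was recovered with accuracy 1.

## Command line

```sh
SPLITPOOL=$(Rscript -e 'cat(system.file("scripts", "splitpool", package = "splitpool"))')

$SPLITPOOL demux    --barcodes barcodes.tsv --out-dir out -l 88 -bn 24 -bs 8 -ls 4 reads.fastq
$SPLITPOOL report   --barcodes barcodes.tsv --out-dir rep reads.fastq   # no per-cell files
$SPLITPOOL simulate --barcodes barcodes.tsv --out-prefix sim --n-reads 10000 --seed 1
```

The short flags mirror the conventional vocabulary: `-l` search window,
`-bn` barcodes per set, `-bs` barcode length, `-ls` expected linker
length. `demux` writes, beside the per-cell files, `<stem>_summary.txt`
(labels found on both ends, per read), `<stem>_stats.txt` (storage file,
last barcode position, linker lengths, per read), `<stem>_report.txt`
(+ `.json`) and `<stem>_run_summary.json`.

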