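---
title: "Quality assessment and phred filtering of uniform-length reads"
author: "readqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment and phred filtering of uniform-length reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readqa)
```

## The problem

Short-read assemblers align reads by identity; a miscalled base breaks an
overlap and can seed a misassembly. The standard defense is to discard
low-quality reads before assembly, but the cutoff is a trade-off: too
stringent and coverage collapses, too lax and error-rich reads poison the
alignments. `readqa` supports that decision with three quantities computed
from the raw quality files alone: the mean quality at each base position
(where along the read do calls degrade?), the quality-value distribution at
a chosen position (how bad is the last base, exactly?), and the fold
coverage that survives any candidate cutoff.

## Model and conventions

Each base call carries an integer phred quality $Q = -10\log_{10}p_e$. We
accept the domain $[-1, 93]$; $-1$ is the SOLiD missed-call sentinel and
participates in read statistics as the value $-1$ — mapping it to 0 would
silently flatter reads with missed calls.

For a read with quality vector $q$ of length $L$:

* mean filter: keep iff $\bar q \ge t$;
* median filter: keep iff $\operatorname{med}(q) \ge t$, the middle sorted
  value for odd $L$ and the mean of the two middle values for even $L$
  (all datasets this tool was designed around use odd $L$ of 25 or 35, so
  the even-length convention is a free choice; averaging matches
  `stats::median` and keeps half-integer resolution).

The cutoff is **inclusive**: a read sitting exactly at $t$ is kept. The
statistics are exact and unrounded — a read with mean 19.995 fails $t=20$.
Both choices are deliberate resolutions of boundary cases the problem
statement leaves open; inclusivity makes "filter at QV20" keep a
constant-QV20 read, which is what practitioners expect.

Fold coverage is $C = \lfloor nL/S \rfloor$ with $n$ reads of length $L$
bases on an expected genome of $S$ bases, and retention percentages are
$\lfloor 10^4 \cdot \mathrm{kept}/\mathrm{raw}\rfloor / 100$. Truncation
rather than rounding is used in both places because it is the convention
under which published tables of this estimator reproduce exactly from their
own read counts (rounding is excluded by cells such as 199.97→199 and
74.994→74.99). One published retention cell (56.46%) is inconsistent with
its own printed counts (they compute to 56.43%); the package reproduces the
formula, not the typo.

## Input dialects and validation

Quality files are multifasta: a `>` header whose first
whitespace-delimited token is the record id, then one or more lines of
whitespace-separated integer QVs (values for one record may span lines —
the usual SOLiD `.qual` layout). Sequence files are nucleotide FASTA
(`ACGTN`, lowercase accepted and uppercased) or csfasta (primer base from
`ACGT` followed by exactly $L$ symbols from `0123.`).

Parsers make a single pass and never fail on content: every defective
record is eliminated and logged with one machine-readable reason.
Precedence when a record has several defects: for quality records
`NON_INTEGER_QV` > `QV_OUT_OF_RANGE` > `WRONG_LENGTH`; for sequence
records `INVALID_CHARACTER` > `WRONG_LENGTH`. Blank lines and pre-header
junk are logged (`BLANK_LINE`, `MALFORMED_HEADER`) but skip only
themselves; a blank line never terminates a record. This yields the
bookkeeping invariant the tests assert: retained records plus eliminating
log entries equal records seen, per file.

Pairing of the two files is positional with id verification rather than
id-keyed lookup: it preserves streaming and surfaces file corruption (a
desynchronized pair produces loud `UNPAIRED_RECORD` entries instead of a
silently reordered join). A mismatched positional pair drops both records.
Mate-pair tags (F3/R3) are filtered independently, each with its own
files, matching how such data is published; no cross-tag constraint is
applied.

## Aggregation

`accumulate_quality()` is a single pass with memory independent of the
number of reads: position tallies live in a fixed $95 \times L$ count
matrix (one row per QV in $[-1, 93]$), read-level sums in a vector indexed
by the exact integer sum, and read medians in a vector indexed by the
exact doubled median (always an integer). Per-base means, position
histograms, the read-statistic distributions and `coverage_table()` are
all pure projections of this aggregate; no operation re-reads the input.

The exported mean-frequency table keys means truncated to two decimals —
a display convention. Cutoff arithmetic never uses those keys:
`coverage_table()` thresholds the exact sum tally (comparing
$\mathrm{sum}/L \ge t$ with the very same division the filter performs), so
its counts agree with brute-force re-filtering bit for bit, with no
binning artifact at the cutoff.

## The synthetic generator: what a green test establishes

`generate_dataset()` writes paired `.qual`/sequence files from a
`quality_profile`: per-position QV sampling distributions, a corrupted
fraction, and a seed (R's Mersenne-Twister, so identical seeds give
byte-identical files anywhere). The manifest it returns is ground truth
computed directly from the sampled matrix — each read's exact mean and
median, and which records were deliberately corrupted and how.

`degraded_tail_profile()` is the canned 35-bp shape the tests lean on: a
two-position low-quality start (expected mean 18), a 17-position plateau
(expected mean 25), a decaying tail (19 falling to 14.8) and a bimodal
last base, QV 5 with probability 0.6 and QV 26 with 0.4, so the last
base's modal quality is 5 and its expected mean 13.4. Those numbers encode
the qualitative fingerprints of real SOLiD fragment data — exactly 17
positions at or above QV20, terminal degradation, a low last-base mode —
without claiming to be an error model of SOLiD chemistry. Sequence content
is uniform random; there is no base-composition structure, no correlation
between adjacent positions, and no realistic read-count scale. A green
test therefore establishes the arithmetic and the contracts (counts,
orders, logs, thresholds), not fidelity to any particular instrument run;
published full-scale tables are reproduced only where their own printed
counts are the input.

Corruption modes map one-to-one onto validation paths: `wrong_length`
(drop the last QV), `non_integer_qv` (first token becomes `x7`),
`invalid_char` (an `X` spliced into the sequence record) and `blank_line`
(inserted between header and values). The first three eliminate the record
in the respective parser; `blank_line` is logged only — the manifest's
`eliminated` column records the distinction.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `expected_length` / `L` | read length in bases (colors for csfasta), the validation yardstick | none, required | uniform-length platforms; anything else is a formatting error |
| `statistic` | `mean` or `median` | `mean` in the CLI | the stricter of the two on spiky reads |
| `threshold` / `--qv` | phred cutoff, inclusive | none required; `20,23,25` in `coverage-table` | QV20 ≈ 1% error is the conventional floor; 23/25 the stringent alternatives |
| `genome_size` / `S` | expected genome size in bases | optional | enables coverage; typically taken from a related reference genome |
| `fraction_malformed` | corrupted share in synthetic data | 0 | corruption is opt-in for validation tests |

## Numerical and degenerate-input choices

Counts and sums are integer-exact throughout (read sums are tallied as
integers; coverage uses integer floor division on doubles well inside the
exact range). Empty aggregates error on series construction rather than
emitting empty charts; an empty retained set still writes both `.new`
files (empty), keeping downstream tooling simple. Write failures remove
both partial outputs. The CLI exits nonzero only on fatal errors (missing
files, bad flags); validation problems are data, not errors, and land in
the log with exit 0. Rendering (`render_chart()`) is presentation-only;
every number on a chart comes from the series, and cairo SVG output is
byte-deterministic for a given series.

## Known limitations

* FASTQ and ASCII-offset-encoded qualities are out of scope — qualities
  here are plain integers in a `.qual` companion file.
* No trimming, masking, GC/duplication/adapter metrics; the unit of
  filtering is the whole read.
* Reads are held in memory as parsed lists (the aggregate itself is
  bounded); datasets in the hundreds of millions of reads would want a
  chunked front end.
* The generator's independence between positions understates the
  correlated quality decay of real runs; per-position marginals are
  faithful, joint structure is not.
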