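# readqa

Headless quality assessment and phred-quality filtering for uniform-length
second-generation sequencing reads — the QC step that sits between the
sequencer's raw output and genome assembly. `readqa` is aimed at anyone
preparing SOLiD or Illumina-era fixed-length read sets: it profiles where
along the read quality degrades, applies a mean- or median-based phred
cutoff to paired sequence/quality files, and tells you what coverage
survives the filter, so cutoffs can be chosen on evidence instead of habit.

## What it computes

Every base call carries a phred quality `Q = -10·log10(p_error)` (QV20 ≈ 1%
error). For a read of length `L` with quality vector `q`:

- the **mean filter** keeps the read iff `mean(q) ≥ t`;
- the **median filter** keeps the read iff `median(q) ≥ t`
  (middle value, or the mean of the two middle values for even `L`).

The two disagree in characteristic ways: a read with a handful of very bad
bases fails the mean but can pass the median; a read that is uniformly
mediocre can pass the mean but fail the median.

Expected fold genome coverage is estimated as

    C = (n × L) / S

where `n` is the read count, `L` the read length and `S` the expected
genome size, truncated to a whole number of folds. Retention percentages
are likewise truncated to two decimals — the conventions under which
published tables for this estimator reproduce exactly.

Input files are the SOLiD-style dialects: a multifasta `.qual` file (one
`>` header per read, then whitespace-separated integer QVs in `[-1, 93]`,
`-1` being the missed-call sentinel) and a matching sequence file in
nucleotide FASTA or color-space csfasta (primer base + `L` color calls from
`0123.`). Records with the wrong length, invalid characters, non-integer or
out-of-range QVs are eliminated and logged — never fatal — and blank lines
are logged without terminating a record.

## Worked example

```r
library(readqa)

# Synthetic 35-bp dataset shaped like SOLiD fragment data: a 17-position
# interior plateau at/above QV20 and a degraded tail whose last base is
# most often QV5.
d <- generate_dataset(degraded_tail_profile(), n = 200,
                      encoding = "colorspace", out_dir = tempdir())

pq  <- parse_quality_file(d$qual_path, expected_length = 35)
agg <- accumulate_quality(pq$reads, L = 35)
print(agg)
#> <per_base_aggregate> 200 reads of length 35
#>   per-base mean quality: 14.24 .. 25.85

sum(per_base_mean_series(agg) >= 20)   # positions at/above QV20
#> [1] 17

job <- run_filter_job(d$qual_path, d$seq_path, 35,
                      filter_config("mean", 20))
print(job$outcome)
#> Phred quality filter:
#>   raw reads:      200
#>   kept reads:     177 (88.50%)
#>   discarded:      23
#>   quality output: .../reads.qual.new
#>   sequence output: .../reads.csfasta.new

estimate_coverage(11349208, 35, 2.3e6)   # 11.3M 35-mers on a 2.3 Mb genome
#> [1] 172
```

The 177 kept reads are exactly the reads whose manifest (ground-truth) mean
is ≥ 20; the two `.new` files contain the same records in the same order as
the originals, minus the filtered ones.

Command line (same engine, script-friendly):

```sh
Rscript -e 'quit(status = readqa::qa_cli())' \
  filter --qual reads.qual --seq reads.csfasta --length 35 \
  --stat mean --qv 20 --genome-size 2300000 --out qc/
```

Subcommands: `stats` (per-base tables + PNG/SVG charts + validation log),
`filter` (`.new` outputs + text/JSON summary), `coverage-table`
(kept reads and coverage across cutoffs, e.g. `--qv 20,23,25`).

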