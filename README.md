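# estssr

Mining expressed sequence tags (ESTs) for simple sequence repeats (SSRs,
microsatellites) and turning them into candidate PCR markers — as a tested,
deterministic R pipeline.

SSRs are tandem arrays of short motifs, written `(m)_k` for a motif `m` of
period `p = |m|` repeated `k` times (e.g. `(CA)15`, a dinucleotide repeated
15 times). For non-model organisms, mining deposited EST collections is the
standard low-cost route to new co-dominant markers. `estssr` implements the
whole recipe:

1. **Trim** terminal poly-A/poly-T tails: no A/T homopolymer of length ≥ 10
   may intersect the first or last 10 bases after trimming
   (`trim_poly_tails()`).
2. **Detect** every maximal *perfect* repeat with primitive motif period
   2–6 and ≥ 5 complete copies (`find_ssrs()`); only complete units count,
   so a run of length `L` at period `p` is reported as `floor(L/p)` copies.
   Dinucleotides are reported in complement-paired classes (`AG/TC`,
   `CT/GA`, ...).
3. **Remove redundancy**: exact-identity/containment clustering keeps the
   longest representative (`dedupe_records()`); sequences that are pure
   repeat with no unique flank are discarded (`drop_flankless()`).
4. **Summarise** the catalogue (`summarize_catalogue()`): SSR frequency
   `100·n_SSR/n_EST`, density `bases/n_SSR` (one SSR every *x* kb),
   repeat-span fraction, per-period and per-motif distributions,
   repeat-count histogram, multi-SSR sequences. `tidy()`, `glance()` and
   `autoplot()` methods give the standard tabular and graphical views.
5. **Design primers** in the unique flanks under PRIMER3-style constraints
   (length 18–27 nt, Tm 55–60 °C, GC 30–70%, product 100–300 bp,
   self/pair-complementarity limits), with nearest-neighbor melting
   temperatures (`design_primers()`, `melt_tm()`). The default Tm model is
   the classic PRIMER3/oligotm formula (Breslauer table, CT/4,
   Schildkraut–Lifson salt correction), which reproduces published
   EST-SSR marker Tms to ±0.1 °C; SantaLucia-unified and Wallace-rule
   models are options.

A seeded generator (`simulate_est_set()`) produces EST-like datasets —
length and composition models, planted repeats with clean flanks,
duplicates, contained copies, flankless reads, poly-A/T tails — with
exhaustive ground truth, so every stage is testable without downloads.

## Worked example

```r
library(estssr)

sim <- simulate_est_set(sim_params(n_sequences = 500, seed = 7))
fa <- tempfile(fileext = ".fasta")
write_fasta(sim$records, fa)

res <- run_pipeline(fa, outdir = "demo_run")
#> input: 517 sequences
#> trimming: 517 kept, 0 emptied and dropped
#> detection: 24 loci in 24 sequences
#> flankless filter: 515 kept, 2 dropped
#> deduplication: 500 kept, 15 dropped
#> catalogue: 22 loci, frequency 4.4%
#> primer design: 20 loci designable, 2 skipped

res$summary
#> SSR catalogue: 22 loci in 500 sequences (238,473 bases)
#>   frequency: 4.4% of sequences
#>   density:   one SSR every 10.8 kb
#>   repeat spans: 0.209% of bases
#>   repeat counts: 5-16; sequences with >1 SSR: 0
#>   per period class: di 17 (77.3%), tri 5 (22.7%)

head(res$markers, 3)
#> # A tibble: 3 × 8
#>   name  seq_id ssr    product_size fw_primer            fw_tm rv_primer              rv_tm
#> 1 MK001 EST11  (GGA)7          113 GGGATTTCGCTTATCCAAC   57.1 GCTGATGTATGGTTTGGTGGT   57.1
#> 2 MK002 EST146 (AG)7           210 TTCGCATGGGTCGTACTA    56.1 GTTGTGCAGAGCAAGGGTAGT   56.1
#> 3 MK003 EST166 (GA)13          243 CGCCTACAGTATTTTCCCGT  59.1 CCGACTCATGCGTTTCATAG    59.1
```

Reading the output: 500 synthetic ESTs were generated, of which 17 extra
records (duplicates, contained copies, pure-repeat reads) were injected; the
pipeline removed them, catalogued 22 perfect SSRs (4.4 per 100 sequences,
one every 10.8 kb), and designed primer pairs for the 20 loci with
sufficient flanking sequence — the two skips are loci whose flank cannot
hold an 18-mer, the classic reason real survey loci go unmarked. The run
directory contains `loci.tsv`, `summary.json`, `markers.tsv`,
`redundancy.tsv` and the fully resolved `config.json`.

A thin command-line front end ships in `exec/`:

```sh
ssrmine simulate --n 2000 --seed 42 --outdir sim1
ssrmine mine --input sim1/simulated.fasta --outdir run1 --min-repeats 5
```

## Acceptance script

`scripts/acceptance.R` exercises the installed package end to end: it
simulates a seeded 2,000-read EST set, writes it to FASTA, runs the full
pipeline (trim → detect → filter → deduplicate → summarise → design
primers), reports the catalogue size and planted-locus recovery on standard
error, and writes the results JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Perfect repeats only (no mismatch-tolerant detection), exact redundancy
clustering (no alignment-based merging of diverged homologs), single-strand
scanning, and a primer designer that approximates PRIMER3 semantics rather
than wrapping the binary. See the methods vignette
(`vignettes/est-ssr-mining.Rmd`) for the model, parameter and tie-break
rationale and known limitations.
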