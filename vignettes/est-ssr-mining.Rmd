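---
title: "Mining EST collections for simple sequence repeats: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining EST collections for simple sequence repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(estssr)
library(dplyr)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem arrays of short
(1–6 bp) DNA motifs flanked by unique sequence. Because their repeat number
mutates rapidly, they are workhorse co-dominant genetic markers, and for
non-model organisms — insect disease vectors such as sand flies are a typical
case — the cheapest source of new markers is *in silico* mining of expressed
sequence tags (ESTs) already deposited in public databases. The recipe is
always the same: clean the reads, find perfect repeats, remove redundant
sequences so each candidate locus is counted once, summarise the repeat
landscape, and design PCR primers in the unique flanks. `estssr` implements
that recipe as a tested, deterministic pipeline that can be exercised
entirely on synthetic data with known ground truth.

## Pipeline stages

### Poly-A/T trimming

cDNA library construction leaves poly-A (or, on the reverse strand, poly-T)
tails on EST reads; left in place they masquerade as mononucleotide repeats
and corrupt composition statistics. `trim_poly_tails()` removes a terminal
segment whenever an A- or T-homopolymer of length ≥ `window` (default 10)
*starts* within the first `window` bases (mirrored at the 3′ end), and
iterates until no such run remains. Two consequences of this formulation are
deliberate:

* trimming always takes a whole prefix or suffix — up to `window − 1`
  legitimate bases 5′ of a triggering run are sacrificed with it, because an
  internal splice would fabricate sequence that never existed;
* a genuine internal homopolymer (one that starts deeper than `window`
  bases from either end) is never touched, and G/C homopolymers are never
  trimmed at all.

The postcondition — no A/T homopolymer of length ≥ `window` intersecting
either terminal window — is checked property-style in the test suite over
adversarial inputs (tails of length 9, 10 and 30, stacked and interleaved at
both ends). A record trimmed to nothing is kept as an empty sequence;
`run_pipeline()` drops and logs it.

### Perfect repeat detection

`find_ssrs()` reports every maximal perfect tandem repeat whose *primitive*
motif period lies in `[min_period, max_period]` (default 2–6) with at least
`min_repeats` (default 5) complete copies. Conventions that needed fixing,
and how they were fixed:

* **Complete units only.** A run of length `L` at period `p` is reported as
  `floor(L/p)` copies spanning exactly those copies from the run's first
  base; a trailing partial unit extends neither the count nor the span. This
  matches how marker tables write "(CA)15".
* **Primitivity.** `(AT)6` is never additionally reported as `(ATAT)3`:
  a run whose motif at the anchor is a repetition of a shorter unit is
  suppressed, because the same run is reported at the primitive period.
* **Anchoring and phase.** A maximal run is reported once, anchored at its
  leftmost base, and the motif is the rotation that appears there. This
  makes output deterministic under left-to-right scanning.
* **Ambiguity.** `N` matches nothing, so runs are split around ambiguous
  bases and each side is evaluated independently.
* **Strand.** Only the deposited strand is scanned. Dinucleotide *reporting*
  pairs each motif with its base-wise complement (`AG/TC`, `CT/GA`, …),
  but `AC/TG` and `CA/GT` remain distinct classes — rotations are not
  merged, mirroring how EST-SSR surveys tabulate them.
* **Mononucleotides** are detectable (`min_period = 1`) but excluded from
  the default catalogue: after poly-A/T trimming, the residual mono-runs
  are dominated by library artefacts rather than genomic repeats.

The implementation scans, for each period `p`, the boolean vector
`s[i] == s[i+p]` and reads maximal runs off its run-length encoding. The
test suite checks it against an independently written brute-force oracle
(greedy unit-by-unit extension from every start position) on a thousand
seeded random sequences and on hand-built corner cases.

### Redundancy removal

Published EST-SSR surveys typically removed redundancy with a BLAST
self-search followed by manual alignment; that procedure is neither
deterministic nor reproducible without external binaries. `dedupe_records()`
substitutes exact-identity and exact-containment clustering (transitive
closure, union–find): two sequences cluster when one is identical to or a
substring of the other, the longest member survives, ties go to input
order. Near-identical homologs with mismatches are *not* merged — a
documented narrowing of scope, not an oversight. `drop_flankless()`
implements the second classical criterion: a sequence whose detected repeat
spans (union, so compound repeats count) cover the whole read carries no
unique flank, cannot be identified or primed, and is discarded. Records with
no detected SSR are never dropped by this rule.

`run_pipeline()` applies flankless filtering and then deduplication *after*
detection (a sequence must be known to be SSR-bearing before the flankless
rule is meaningful); `dedup_first = TRUE` provides the opposite order for
sensitivity analysis. Both orders give identical catalogues on exact
duplicates; they can differ when a contained fragment carries a repeat its
container lost to trimming.

### Catalogue statistics

`summarize_catalogue()` counts exactly and rounds only for reporting:
SSR frequency (loci per 100 sequences), density (bases per SSR, also as kb
at one decimal), the fraction of bases inside repeat spans (overlaps counted
once per base), per-period and per-motif-class distributions, the
repeat-count histogram, and the number of multi-SSR sequences. Two knobs
exist because published tables are not internally consistent about them:

* **Rounding.** Default is half-up at one decimal; `"truncate"` is
  available because survey tables sometimes truncate (467/1,499 printed as
  31.1% is truncation, not rounding).
* **Density basis.** `density_basis = "analyzed"` (default) divides the
  post-trim, post-redundancy base total by the locus count;
  `"raw"` uses the post-trim total before redundancy filtering. Published
  density figures rarely state which total they used, so both are
  reproducible and the choice is recorded in the run's `config.json`.

### Primer design

`design_primers()` is a self-contained, deterministic approximation of a
PRIMER3-style search rather than a wrapper: forward primers are enumerated
over every allowed position and length (defaults 18–27 nt) in the 5′ flank,
reverse primers (reverse-complemented) in the 3′ flank, filtered by GC
(30–70%), calculated Tm (55–60 °C), self-complementarity (longest
complementary stretch ≤ 8, 3′-anchored ≤ 4), and paired under the product
size bounds (100–300 bp). Neither primer may overlap *any* detected SSR of
the template — priming out of a repeat is never acceptable for a
microsatellite marker. Pairs are scored
`|fw_tm − rv_tm| + (|fw_gc − 50| + |rv_gc − 50|)/100` and returned in
ascending order.

One scaling decision: single-primer filters are exhaustive, but pair
complementarity is evaluated lazily in penalty order, stopping after
`max_candidates` accepted pairs per locus. Evaluating full complementarity
on every one of the ~10^5 enumerable pairs per locus is not affordable in
pure R, and the check is monotone — tightening any constraint can only
shrink the accepted set, which the tests verify. Internally the threshold
checks use an exact equivalence: a complementary stretch longer than *t*
exists iff the two sequences share a (*t*+1)-mer after reverse
complementation.

### Melting temperature

`melt_tm()` offers three models. The default, `"breslauer"`, is the classic
PRIMER3/oligotm formula — Breslauer 1986 nearest-neighbor table, −10.8
cal/K helix-initiation entropy, total strand concentration divided by 4
(50 nM default) and the Schildkraut–Lifson `16.6·log10[Na+]` salt
correction (50 mM default). `"santalucia"` implements the unified
SantaLucia parameters with terminal initiation terms and the
`0.368·N·ln[Na+]` entropy correction; `"wallace"` is the 2(A+T)+4(G+C)
rule. The Breslauer default was chosen after cross-checking both models
against a published table of 40 EST-SSR markers whose Tms were computed
with PRIMER3 defaults of that era: the PRIMER3-classic formula reproduces
those printed values to ±0.1 °C, while the SantaLucia model at the same
salt/concentration settings sits ~9 °C lower. Both are exposed and the
model used is recorded on the result; duplex symmetry (a primer and its
reverse complement share a Tm) holds for all models and is tested.

Published marker tables also illustrate why the Tm *filter* and the printed
Tms need not agree: a stated design range of 55–60 °C can coexist with
printed primers up to 62 °C, because the printed values come from a
different stage of the tool. Here `[tm_min, tm_max]` filters the calculated
Tm, and the bounds are configurable.

## The synthetic world

`simulate_est_set()` generates datasets in which every repeat is known, so
pipeline recovery can be asserted exactly rather than approximately.

The stated world (defaults of `sim_params()`): read length normal with mean
469 bp and SD 150, truncated at 100 bp; base composition A/T 28% each, G/C
22% each (the slight A+T bias typical of insect ESTs); 3.5% of reads carry
one planted SSR; planted periods are drawn 67 / 31.1 / 1.5 / 0.4 % for
periods 2/3/4/5, the renormalised mix reported by EST-SSR surveys;
repeat counts uniform on 5–16. Rates without a published value were chosen
once as plausible for a normalized EST library and not revisited: 2% exact
duplicates, 1% contained prefix copies, 0.5% flankless pure-repeat reads,
15% terminal poly-A/T tails of 12–30 nt.

Design choices that make the truth exact:

* planted repeats get ≥ 25 bp flanks and their junction bases are rewritten
  so the run is maximal at its own period (`plant_ssr()` guarantees this);
* incidental repeats that arise by chance in the random background are not
  suppressed — the generator runs the detector on each finished base
  sequence, re-rolls only if an incidental run collides with the planted
  one, and records all remaining incidentals in the truth with
  `planted = FALSE`, so recovery checks are equalities, not inequalities;
* backgrounds are re-rolled until they are fixed points of the trimmer, and
  appended tails never share their first base with the adjacent core base,
  so trimming removes exactly the tail and planted coordinates survive as
  `start_core`;
* the same seed gives byte-identical FASTA output.

What the generator does **not** emulate: sequencing error, chimeric reads,
imperfect/interrupted repeats, genuine homologous families (only exact
copies), realistic motif usage within a period class (motifs are uniform
over primitive strings), or cDNA normalization depth effects. A green
recovery test therefore establishes correctness of the machinery on clean
perfect repeats — it says nothing about robustness to base-calling error,
which is out of scope throughout.

## Numerical conventions and degenerate inputs

* Coordinates in all user-facing tables are 1-based inclusive.
* Percentages are rounded half-up (configurable truncation); all underlying
  counts are exact integers and order-invariant.
* Density of an empty locus set is reported as absent, never zero; the
  composition of an empty record set is an error rather than NaNs.
* FASTA identifiers must be unique; ambiguity codes beyond N are normalised
  to N with a warning; N never seeds or extends a repeat, and primers may
  not contain N.
* Ties are broken deterministically everywhere: dedup representatives by
  length then input order, primer pairs by penalty, then leftmost forward
  start, then smallest product.

## Known limitations

* Containment clustering is exact; diverged duplicates survive redundancy
  filtering, so catalogue counts on real, error-containing EST data are
  upper bounds.
* The primer designer omits hairpin folding energies, mispriming libraries
  and positional end-stability, so its "designable" rate is more permissive
  than a full PRIMER3 run with strict internal spacing.
* Detection is single-strand by construction; loci are reported on the
  deposited strand only, with complement pairing applied at the reporting
  layer for dinucleotides.

## A worked run

```{r, eval = FALSE}
sim <- simulate_est_set(sim_params(n_sequences = 500, seed = 7))
fa <- tempfile(fileext = ".fasta")
write_fasta(sim$records, fa)
res <- run_pipeline(fa, outdir = "demo_run")
glance(res$summary)
tidy(res$summary)
autoplot(res$summary, type = "period")
```

The run writes `loci.tsv`, `summary.json`, `markers.tsv`, `redundancy.tsv`
and the fully resolved `config.json` beside each other, and the logged
per-stage counts always reconcile: input = kept + emptied + flankless +
duplicates.
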