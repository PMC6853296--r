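---
title: "cpseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpseq)
```

# The problem

2′,3′-cyclic phosphates (cP) are the 3′-terminal chemistry left by many
endoribonucleases (and by self-cleavage). Because a cP blocks standard
3′-adapter ligation, ordinary small-RNA-seq misses these molecules;
cP-RNA-seq enzymatically selects them, so the resulting libraries are an
enriched census of endonucleolytic cleavage products: tRNA halves cut in
the anticodon loop, and mRNA/rRNA fragments whose termini carry a
characteristic signature — cleavage between a cytidine (which becomes the
fragment's 3′ end, or the −1 flank of the downstream product) and an
adenosine (the fragment's 5′ end, or the +1 flank of the upstream
product). cpseq implements the downstream informatics for such libraries
and a ground-truthed simulator for validating them.

# The generative model behind the simulator

`simulate_library()` states the world the analysis assumes; its defaults
are the package's declared conditions, not tuning knobs.

* **Cleavage boundaries.** Each fragment boundary is drawn at a C|A
  dinucleotide junction with probability `p_ca_cleavage`, otherwise
  uniformly over the other junctions. The default 0.8 reflects the
  strength of the terminal base biases observed in real libraries (5′-A
  and 3′-C fractions around 0.7–0.9). Generic substrates (mRNA, rRNA,
  mitochondrial, genome) draw both boundaries independently from this
  model, rejecting pairs outside the 20–45 nt window (resampled up to a
  cap, then the read is dropped with a warning). Because boundaries are
  interior junctions, generic fragments never touch a reference edge —
  convenient for the flanking analyses, and realistic for fragments of
  long substrates.
* **tRNA fragments.** Toy tRNAs are canonical 76-nt bodies (np i at
  sequence index i−1) with CCA at np 74–76 and a fixed anticodon loop
  (np 32–38) containing exactly one C|A junction, between np 34 and 35.
  Intended fragment classes are drawn from `trna_class_weights`
  (default 60 % 5′-halves, 25 % 3′-halves, 5 % each tRF class, a
  halves-dominated mixture typical of these libraries). Half boundaries
  use the dinucleotide model restricted to loop junctions; 3′-half 3′
  ends take the C75|A76 cut (the 3′-CC-half) with probability
  `p_ca_cleavage` and otherwise one of the Di/C/CCA ends — at the default
  0.8 this reproduces the strong CC-half dominance seen in real data.
  The His-like record carries G at np −1; 5′-anchored His reads draw a
  variant from `his_variant_weights` (60 % G₋₁, 20 % U₋₁, 20 % G₁,
  matching the reported variant mixture); U₋₁ molecules substitute U for
  the reference G, so they map with one mismatch — exactly as in real
  data.
* **Spike-in.** A fixed 37-nt synthetic cP-RNA
  (`cp_spike_in_sequence()`) is emitted unfragmented for a
  `spike_in_fraction` (default 0.02) of reads.
* **Adapter and errors.** The 3′ adapter (a configurable 20-nt default,
  `cp_default_adapter()`) is appended to every molecule and per-base
  substitution errors are injected at `error_rate` (default 0.001,
  Illumina-like). Indels, quality-score realism, ligation chemistry and
  PCR duplication are deliberately out of scope.
* **Two-condition pairs.** `simulate_aging_pair()` scales the expected
  substrate yield of condition 2 by `1/reduction_factor` (default 4)
  while holding the expected spike-in yield fixed — the sequencing-pool
  composition that results when cP-RNA abundance genuinely drops against
  a constant spike-in dose. The accompanying mRNA table draws per-mRNA
  log-normal expression levels once and Poisson replicate counts per
  condition, so substrate mRNA levels are unchanged in expectation.

A consequence worth stating: a green parameter-recovery test establishes
that the pipeline inverts *this* model. Real libraries additionally
contain modified nucleotides that distort reverse transcription,
non-uniform ligation efficiencies, PCR duplicates and multi-locus
ambiguity at a scale the toy references cannot produce; none of those are
probed here.

## One engineered property of the toy references

All toy references exclude the four 5-mer blocks of the default adapter.
Any read suffix the trimmer could accept (≥5 nt overlap with the adapter
prefix, ≤10 % mismatches) necessarily contains one of those blocks
exactly, so on simulated data adapter detection is provably exact — no
substrate suffix can imitate an adapter. This is what lets error-free
round-trip tests assert equality rather than approximate recovery. Real
references offer no such guarantee, and real trimming loses a small
fraction of reads whose inserts end adapter-like; the trimmer's behavior
there is the standard, documented ≤10 %-mismatch rule.

# Read extraction

`trim_adapter()` removes the leftmost read suffix matching a prefix of
the adapter with ≥ `min_adapter_overlap` (default 5) bases and ≤10 %
mismatches of the overlap, no indels; `N` counts as a mismatch. Reads
with no detected adapter are discarded by default — a genuine cP read
must have ligated an adapter after cyclic-phosphate removal — with a
`keep_untrimmed` override. `length_select()` then keeps 20–45 nt
(inclusive), the gel-purified window. The exact parameters of the
original trimming step are not fixed by convention anywhere; these
defaults are explicit and oracle-tested against a brute-force overlap
enumeration.

# Sequential mapping

Each read is assigned to the first category in
`spike-in → cyto tRNA → rRNA → mito → mRNA → genome` with ≥1 placement at
Hamming distance ≤ `max_mismatch` (default 1). Priority precedes mismatch
count: a perfect mRNA hit loses to a 1-mismatch tRNA hit, mirroring the
sequential-filtering idiom of small-RNA annotation. Design choices where
the convention is genuinely open:

* **Multimappers** resolve by a deterministic tie-break (fewest
  mismatches, then lexicographic reference id, then smallest start, then
  + strand) and are counted once. Determinism beats fractional weighting
  for testability.
* **Antisense** placements are accepted only for mito/mRNA/genome;
  mature tRNAs, rRNAs and the spike-in are single-stranded entities, so
  only sense hits are meaningful there. This is configurable in spirit
  (the policy lives in one internal function) but fixed in the API.
* **No indels.** Pure Hamming distance matches the "one mismatch
  allowed" semantics and admits an exact brute-force oracle.

The engine seeds candidate placements by exact hashing of read halves
against the concatenated reference (pigeonhole: any ≤1-mismatch placement
has at least one exact half) and verifies candidates by direct
comparison. Equivalence with a literal scan over every offset and strand
is asserted in the acceptance suite; reads containing non-ACGT characters
take a slower exact-scan path.

# tRNA taxonomy

Classes are assigned by precedence — 5′-half > 3′-half > 5′-tRF >
3′-tRF > i-tRF — using np coordinates: a 5′-half starts at np 1 (np −1
for His) and ends inside the anticodon loop; a 3′-half starts inside the
loop (or at loop_end+1, so that both products of a cut after np 38 are
classified) and reaches np ≥ 73; tRFs are the 5′- or 3′-anchored
remainder; everything else is an i-tRF. The loop is np 32–38 by default
(the standard seven-base anticodon loop; configurable per record in the
annotation table). The "3′-Di-half" is read as ending at the
discriminator np 73 — the only reading consistent with the
CCA (np 76) / CC (75) / C (74) / Di ladder. His −1 variants are called
from the *read's* first base, not the reference's, so U₋₁ molecules
aligned to the G₋₁ reference with one mismatch are recovered as U₋₁.

# Cleavage-signature analyses

Composition matrices are computed per position with per-position
denominators (a read of length L contributes to end positions 1…L only);
columns are exact probability vectors wherever covered. Outputs use the
RNA alphabet (U, not T) to match convention, while all processing is
DNA-alphabet internally. Flanking context is strand-aware (antisense
fragments report reverse-complemented flanks in fragment orientation) and
edge fragments contribute only the flank positions that exist; the scalar
`ca_boundary_fraction()` excludes edge fragments from its denominators
because their boundary base is undefined. Cleavage sites are inferred by
voting: a 5′-half ending at index i votes for boundary (i, i+1), a
3′-half starting at j votes for (j−1, j); a boundary with votes from both
sides is *concordant* — the paired-arrowhead pattern of a single
endonucleolytic cut captured from both products.

# Quantification

`norm_rpkm = raw_count × 10⁹ / (substrate_length_nt × spike_count)`. The
exact constant convention behind "spike-normalized RPKM" is not fixed by
any standard; this form is declared and its two invariances are what the
tests pin down: scaling all substrate counts by k at fixed spike scales
norm_rpkm by k, and scaling the whole library (spike included) changes
nothing. Fold changes use per-condition arithmetic means across
replicates; substrates need a mean raw count ≥ `min_count` (default 10)
in both conditions, guarding against unstable ratios. The "aggregation
point" of the fold-change scatter is estimated as the mode of a fixed
0.25-wide 2-D histogram of (log₂ fc_mRNA, log₂ fc_cP) — an explicit,
testable estimator of what a scatter plot shows qualitatively; its
resolution is therefore ±one bin.

# Numerical and bookkeeping conventions

* Coordinates are 0-based half-open in every in-memory table and BED
  export, 1-based inclusive in user-facing TSV reports (converted at the
  writer).
* All randomness flows through a single seed per library; the generator
  saves and restores the caller's RNG state, and identical configurations
  produce byte-identical FASTQ and truth tables. Derived seeds (the two
  libraries of an aging pair) stay within 32-bit integer range.
* The pipeline writes a JSON manifest (config, seeds, input checksums,
  per-stage read counts) atomically at run end; a rerun from the same
  inputs and configuration is byte-identical, which the test suite
  asserts.
* Conservation identities are enforced, not assumed: input reads =
  preprocessing discards + unmapped + Σ category counts, and coverage
  sums equal fragment-length sums in alignment profiles.

# Known limitations

* The simulator's substrate category weights are illustrative defaults
  (tRNA-dominated, with rRNA/mRNA/genome shares in realistic ranges);
  real libraries vary by tissue and the package makes no claim to
  calibration beyond those ranges.
* Reads longer than the length window, splice-aware alignment,
  quality-aware scoring and indel tolerance are out of scope by design.
* Composition analyses are descriptive; no statistical test is attached
  to the biases, and none is defined for the fold-change aggregation
  beyond the histogram mode.
* The mitochondrial category is counted at category level only; mito
  tRNA taxonomy is not modeled.
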