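---
title: "Methods: mining, classifying and dating Tc1-mariner transposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, classifying and dating Tc1-mariner transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobilomr)
```

`mobilomr` annotates the DNA-transposon fraction of a genome assembly, with
the Tc1-mariner-IS630 superfamily as its centre of gravity: ~1300 bp
elements with short terminal inverted repeats (TIRs), a DDD-type transposase
and a strict TA target-site duplication (TSD). This vignette documents the
models and procedures, the tunable parameters, what the simulator does and
does not emulate, and the numerical choices a user may want to revisit.

## 1. Sequence primitives

All searches are internal seed-and-extend re-implementations, so results are
deterministic and self-contained:

* `search_nt()` — exact nucleotide word seeds (default 11), ungapped X-drop
  extension under +1/−2 scoring, both strands; minus-strand hits are stored
  on plus-strand subject coordinates with a strand flag. Default raw-score
  cutoff 20.
* `search_translated()` — exact amino-acid 4-mer seeds over all six reading
  frames, ungapped X-drop extension under BLOSUM62 that never crosses a stop
  codon. Default raw-score cutoff 60 (a 50-residue exact match scores well
  above this).
* `align_pair_vm()` — global alignment (match +1, mismatch −1, linear gap
  −2) scored with the *gap-as-fifth-nucleotide* distance
  `d_w = (mismatches + w · gap_columns) / columns`. At `w = 1` a gap column
  counts exactly like a mismatch; at `w = 0` gaps are free.
* Identity is *always* matches over all alignment columns, gap columns
  included in the denominator. The 0.80 clustering and 0.75
  horizontal-transfer thresholds are only meaningful once this is fixed;
  with gaps in the denominator, an internally deleted derivative does **not**
  reach 80 % identity with its full-length parent and correctly founds its
  own lineage.
* `build_consensus()` — per-column plurality with two deterministic ties:
  base beats gap (the consensus follows the longest elements) and ties among
  bases resolve in A<C<G<T order; plurality-gap columns are dropped.
* Ambiguity: `N` never matches anything, in searches or consensus votes.
  N-containing copies are excluded from clean counts downstream anyway.

Ungapped extension is a deliberate simplification: the simulator's mutation
process is substitutions-only, and structured losses (deletions,
rearrangements, N-runs) are handled *above* the hit level, by chaining and
block analysis — which is also how fragmented hits of old copies behave in
practice. Oracle tests hold the searches against exhaustive
dynamic-programming references on small fixtures.

All user-facing coordinates are 1-based inclusive, the R/Bioconductor
convention; the C++ kernels work 0-based half-open internally and are
converted at the boundary.

## 2. Library-based mining

`mine_transposons()` chains transposase hits on the same contig, strand and
query when the subject gap is under `chain_max_gap_bp` (1 kb) and the query
advances co-linearly; each chained candidate is then widened by the
unaligned query remainder (in nucleotides) so cores cover the homologous
region uniformly even where divergent ends fell below the extension
threshold. Candidates shorter than `min_copy_len_bp` (400) are dropped;
survivors are extracted with `flank_len_bp` (500) flanks,
reverse-complement-normalised, and clustered greedily: length-sorted,
first-fit against centroids at `cluster_identity` (0.80), testing both
orientations. Greedy centroid clustering is our reading of the classical
clusterer this step emulates; a single-linkage oracle bounds its behaviour
in the tests.

Clean-up mirrors the classical protocol: sequences with N anywhere in the
extraction (the element edges sit inside the flanks), assembly-truncated
copies, and copies whose both flanks match another member at
`flank_dup_identity` (0.90) — segmental duplications, which move copy *and*
flanks together — are excluded from the clean independent count. Only
clusters with at least `min_lineage_copies` (5) clean copies are
characterised.

### Element boundaries, TSD and TIR

The homology core is the ORF region, not the element: the real edges lie in
the flanks. Boundary refinement works on the star alignment of the extended
copies (members projected onto the longest copy, majority consensus with a
column map):

1. candidate boundaries come from the largest inverted-repeat pair of the
   consensus near the homology core;
2. boundaries are then shifted (±6 by default) to maximise *TSD votes*: the
   number of members whose flank k-mers just outside the boundary are
   duplicated (k = 2…8). Three guards make this robust: (i) a candidate
   whose immediate outer context is conserved across members is rejected —
   a real TSD is embedded in per-copy background, a conserved "duplication"
   is element structure (mariner TIRs begin with self-complementary CG/TA
   motifs that otherwise fake TA-like duplications); (ii) duplication
   lengths are compared across k and the largest k within 80 % of the best
   support wins — a shorter duplication can be manufactured by partially
   capturing a longer true TSD, a longer one by pairing a conserved TIR base
   with a shorter true TSD; (iii) a majority threshold
   (`max(3, half the members)`), below which the TSD is `"unclear"` and the
   boundaries stay at the TIR-pair estimate.

The TIR is then read from the trimmed consensus by walking inward scoring
+1/−2 for matching/mismatching prefix-versus-reverse-complement-suffix
columns and reporting the peak depth (minimum 10, mismatch fraction capped
at `tir_max_mismatch_frac`). The peak rule avoids the over-extension that a
pure tolerance rule produces by absorbing chance matches.

Activity: a lineage is potentially active when any clean copy carries an
uninterrupted ATG-initiated ORF longer than `active_orf_min_bp` (1 kb) in
any frame — a property of copies, not of the consensus. Status: a consensus
shorter than `deleted_len_frac` (0.80) of the longest same-subfamily
consensus is `"deleted"` (operationalising the 800–1000 bp deleted lineages
versus the 1280–1350 bp typical mariner); a TIR at or beyond
`rearranged_tir_min_bp` (50) marks `"rearranged"` — 5'-replaced-by-3' copies
carry TIRs of hundreds of bp.

## 3. De novo MITE discovery

`discover_mites()` finds maximal exact inverted matches (arms ≥
`tir_seed_min_bp` = 11, internal span ≤ `mite_max_span_bp` = 750) by hashed
self-comparison, reduces overlapping pairs to one candidate per locus,
extracts with `mite_flank_bp` (60) flanks, clusters as above, removes
flank-duplicates, and applies the funnel: at least `mite_min_copies` (10)
independent copies, mean pairwise identity ≥ `mite_homogeneity` (0.70 — the
published protocol requires "a certain level of homogeneity" without
quantifying it; 0.70 admits old families while excluding random
co-clusters), and a bona fide TIR (≥ 11 bp terminal inverted match with ≤ 2
mismatches) on the refined consensus. Every rejection is logged with its
reason, reproducing the raw-to-selected funnel structurally rather than by
count matching.

Sublineages — copies similar enough to witness amplification after
shortening — are connected components at ≥ 95 % identity and ≤ 5 % length
spread. The partner search takes the cluster TIR as query and keeps genomic
loci where it occurs in inverted orientation spanning more than
`partner_min_len_bp` (1 kb; bounded above by `partner_max_len_bp` to avoid
pairing TIR hits of unrelated copies), excluding the cluster members
themselves. Superfamily classification runs the translated search of the
protein library against the partner, then the consensus, with two
nested-insertion guards: consensus homology confined to a region most
members do not carry is ignored, and a "partner" whose homology block is
bracketed by an *internal* TIR pair flanked by its own direct duplication is
recognised as a transposon nested inside a longer copy, not as an
autonomous partner.

## 4. UPGM-VM classification

`upgm_vm()` is an ascending hierarchical classification with two departures
from UPGMA: no arithmetic mean — cluster distance is the *minimum* pairwise
`align_pair_vm()` distance, each pair aligned once — and a metric that
varies as the classification ascends: the gap weight follows
`w = 2^-p` with `p = floor(6 · merges_done / (n − 1))`, clamped to 0 from
`p ≥ 6`. Early rounds treat the gap as a fifth nucleotide and separate
sequences by full structure; late rounds make gaps free, letting full-length
elements gather their truncated and internally deleted derivatives (MITEs).
The published description fixes only "progressively and rapidly set to
zero"; the schedule is exposed (`weight_of`) and the default is recorded
here as this package's operational definition. Merge heights may
legitimately decrease between rounds (the metric changes); ties break
lexicographically on member ids so input order is irrelevant.

`assign_subfamily()` labels a consensus with the reference group of minimal
mean `w = 1` distance, or `novel` beyond `novelty_threshold` (0.45 —
between-subfamily mariner distances exceed this in any labelled panel we
simulate; the threshold is an argument). The full maximum-likelihood
transposase phylogeny of the original protocol is out of scope; distance
assignment against labelled references is the supported route.

## 5. Amplification dynamics

`build_copy_tree()` computes Jukes-Cantor-corrected p-distances
(`d = −¾ log(1 − 4p/3)`, p capped at 0.70) over a star projection of the
copies and clusters them with UPGMA — chosen over neighbour joining because
node *depths* are read as event ages (age = height/2), which requires
clock-like trees, and divergence-as-time is the axis of the whole analysis.
One duplicative transposition event is scored per internal node; the LTT
curve accumulates them oldest-first. Lineages larger than `max_copies`
(300) are subsampled under a fixed seed before the quadratic stage.

`classify_ltt_shape()` normalises event times to [0, 1] (time toward the
present) and compares the cumulative curve to the constant-rate diagonal:

* `L` — sup-norm deviation < `delta_L` (0.08);
* `E` — fewer than `f_lo` (0.35) of events in the ancient half (constant
  per-copy rate: density grows toward the present, median shifted recent);
* `C` — more than `f_hi` (0.65) in the ancient half (early burst);
* `S` — significant deviation with a centred median.

The generators in `sample_copy_ages()` are the operational definitions of
the four regimes: uniform ages (L), truncated exponential with dimensionless
intensity `burst = 4` (E, and mirrored for C), and a logistic event density
with scale `span/10` (S). Closed forms (`age_model_cdf()`,
`age_model_median()`) back the recovery tests. Known soft spot: with 200
events, the sampling fluctuation of the empirical sup-norm sits near
`delta_L`, so a uniform lineage is occasionally read as S; recovery stays
above 80 % per class in the validation runs. `recent_epsilon` (0.005
divergence units) defines "events at time 0" for the activity call.

## 6. Horizontal transfer, rearrangements, masking

`screen_ht()` merges co-linear hit blocks per locus (coverage is about the
query overall — old copies fragment) and requires identity >
`ht_min_identity` (0.75) over more than `ht_min_coverage` (0.90) of the
query. When the rule fails, identity is re-measured by a local alignment of
the whole query against the best locus before deciding *which* rule failed —
fragment-weighted identity is biased upward because only conserved
stretches seed. Candidates must additionally pass `check_synteny()`: both
flanking windows (default `synteny_window_bp` = 5 kb at desk scale; the
published screen used 50 kb on a 700 Mb assembly — the rule is structural,
not scale-dependent) must match the same reference contig in consistent
orientation at compatible positions; orphan short contigs — the
contamination signature — fail.

`detect_rearranged_copies()` keeps loci with exactly one plus- and one
minus-strand block of the full-length reference that tile the copy with at
most ±10 bp of junction jitter; blocks shorter than 50 bp are ignored (the
element's own TIR re-matching the reference tips is structure, not a
deletion), and uncovered reference *inside* a block's query span marks a
secondary internal deletion — such copies are flagged and leave the clean
set. Breakpoints are reported 1-based in reference coordinates.

`mask_genome()` lets higher-scoring hits claim overlapping bases first, so
masked intervals are disjoint, totals are library-order invariant, and
per-superfamily fractions sum to at most one.

## 7. The simulator, and what passing tests mean

`plant_genome()` writes each copy into an i.i.d. uniform-ACGT background at
a genuine TA site (or duplicates a site-specific k-mer for non-mariner
TSDs), on a random strand, with age-driven Jukes-Cantor substitutions under
one global clock shared by all families (ages are in divergence units;
`mutation_rate = 1` makes age equal expected distance). ORF intactness is
planted by rejecting stop-creating substitutions in designated copies, and
recorded in the ledger as measured on the realised copy — young unprotected
copies may stay intact by chance, exactly as in real genomes. Deletions and
5'-replaced-by-3' rearrangements are explicit structured events; N-runs
emulate assembly gaps; segmental duplications copy an insertion with 600 bp
of flanks onto a fresh contig and mark the twin non-independent; nested
insertions place one copy inside another with its own TSD; tandem-repeat
decoys provide MITE-filter hard negatives. The same seed reproduces genome
and ledger byte for byte.

What the simulator does *not* emulate: insertion-site preference beyond the
TSD, indel mutation processes (substitutions only), selection, GC
heterogeneity and low-complexity background, and chromosome-scale assembly
artefacts. Passing tests therefore demonstrate that the algorithms recover
planted truth under a clean, favourable null — they bound implementation
correctness, not annotation performance on real assemblies, where divergent
background repeats and compositional bias will erode precision first.

Problem sizes used in the validation suite — a 2-Mb genome with 8 families
(5–200 copies, 0–10 % divergence), a 400-kb MITE genome (150-copy family,
autonomous partner, 9-copy family, tandem decoys), a 25-sequence
5-subfamily panel, 50 replicates × 4 dynamics classes at 200 events, 112
rearranged copies, and a 600-kb genome carrying ~12 % repeats — were chosen
as the smallest scales at which every rule the pipeline implements is
actually exercised (segmental duplications need flanks, partner search
needs >1 kb loci, shape classes need enough events to be distinguishable).

## 8. Known limitations

* Ungapped hit extension under-reaches for indel-rich real copies; chaining
  compensates only partly.
* The TSD-vote boundary refinement assumes several independent copies with
  intact flanks; two- or three-copy families fall back to TIR-pair
  boundaries and an `"unclear"` TSD.
* UPGM-VM is quadratic in sequences with a full pairwise alignment pass —
  intended for hundreds of sequences, not tens of thousands.
* The dynamics shape classifier inherits the identifiability limits of its
  thresholds near the L/S boundary, and assumes a constant deletion rate
  across coexisting lineages.
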