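---
title: "Phasing blunt assembly graphs with proximity ligation or parental k-mers"
author: "hapchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing blunt assembly graphs with proximity ligation or parental k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapchain)
library(dplyr)
```

## The problem

Modern long-read assemblers produce diploid assembly graphs in which
heterozygous loci appear as *bubbles* — pairs of alternative segments —
separated by homozygous segments shared by both haplotypes. Local phasing
(which bubble side goes with which, within the span of a read) is often
available, but chromosome-scale phasing requires longer-range evidence.
Two such sources are supported here:

* **proximity ligation** (Hi-C read pairs, Pore-C concatemers): reads that
  link loci on the same chromosome copy, and
* **parental short reads** (a trio): k-mers unique to one parent identify
  the transmitted haplotype directly.

`hapchain` consumes a *blunt* GFA1 graph — adjacent segments do not
overlap, so concatenation along a path reproduces the assembled sequence
exactly — phases its bubbles, stitches them into bubble chains, and
"unzips" each chain into two haplotype paths and FASTA sequences.

## Contact phasing as a max-cut problem

Proximity-ligation reads are mapped to the graph segments; every pair of
mappings with the same read name is a *contact*, accumulated as a weighted
edge of a contact graph over segments (a Hi-C pair contributes one edge;
a Pore-C concatemer with $m$ mapped subreads contributes all
$\binom{m}{2}$ pairs). Mapping-quality filtering (default mapQ $> 0$)
removes the mappings that cannot distinguish haplotypes.

For two bubbles $a$ and $b$ there are four possible contacts between
their sides. Writing $w(x,y)$ for the contact weight between segments $x$
and $y$, and giving bubble $a$ an orientation $o_a \in \{0,1\}$ (side
$o_a$ is haplotype 0), the pair score is

$$s(a,b \mid o_a, o_b) \;=\; \big[w(a_{h0},b_{h0}) + w(a_{h1},b_{h1})\big]
  - \big[w(a_{h0},b_{h1}) + w(a_{h1},b_{h0})\big],$$

i.e. only contacts linking sides in matching phases score positively. The
total objective is the sum over bubble pairs sharing at least one contact.
Collapsing each pair to a single coupling
$s_{ab} = (w_{00}+w_{11})-(w_{01}+w_{10})$ and mapping orientations to
spins $\sigma \in \{-1,+1\}$ turns this into an Ising/max-cut objective
$\sum_{ab} s_{ab}\,\sigma_a \sigma_b$, which is what the optimizer works
on. Contacts between the two sides of one bubble are kept in the contact
graph (they are visible to QC) but contribute zero score: a read linking
the two alternatives of one locus is self-inconsistent evidence.

### The sampled greedy optimizer

Exact max-cut is intractable, and a single greedy run from a random state
is both noisy and irreproducible across thread counts. The optimizer
therefore:

1. runs `n_samples` independent greedy optimizations from uniformly random
   phase states (each sweep visits merged sets in random order and flips a
   set only when the objective strictly increases, until 1-flip-optimal);
2. tallies, for every coupled bubble pair, how often the two bubbles came
   out in the same vs opposite orientation across samples;
3. merges the most consistent pairs (ranked by $|n_\text{same} -
   n_\text{opp}|$, i.e. consistency weighted by tally depth; ties by depth
   then lexicographic bubble id) into rigid sets whose relative
   orientation is fixed to the majority, each set participating in at most
   one merge per round — so after round $r$ no set exceeds $2^r$ bubbles —
   and repeats for `n_rounds`.

The final state is the best-objective sample of the last round. Every
sample draws its own sub-seed derived from the configuration seed, so the
result is bit-identical for any `n_threads` and any bubble insertion
order. Zero-gain flips are never taken, which keeps ties deterministic.

Defaults (`sampler_config()`): 30 samples, 10 rounds, merge fraction 0.5.
These are deliberately modest: the sampling design favours many cheap
restarts over long anneals, and on the package's standard simulations the
optimum is typically reached within the first rounds while later rounds
consolidate merged sets.

### Identifiability

Flipping every orientation leaves the objective unchanged, so contact
phase is meaningful only up to a global flip — and since contacts only
ever link bubbles within a connected component of the contact graph, the
ambiguity is per component (in the simulations: per chromosome-like
chain). Accuracy is therefore always reported up to one flip per phase
block (`phase_error(groups = )`), the usual Hamming-error convention.
Trio phasing has no such ambiguity: haplotype 0 is the paternal
haplotype everywhere.

## Trio phasing

Parental k-mer counts (plain `KMER<TAB>COUNT` dumps, so any counter can
feed them) are canonicalized and subtracted: a k-mer is paternal-unique
if its paternal count reaches `hom_threshold` (default 2; with raw-read
counts a value near a quarter of the parent's coverage is sensible) and
it is absent from the mother, and symmetrically. K-mers are 31 bp by
convention — odd, so no k-mer equals its own reverse complement.

Each bubble is called by a net lean: with $p_i$, $m_i$ the
paternal/maternal unique-k-mer hits on side $i$,
$L = (p_0 - m_0) - (p_1 - m_1)$. $L \ge$ `min_votes` (default 3) calls
paternal-is-side0, $L \le -$`min_votes` the opposite, anything else —
including exact ties — stays unphased. The net-lean form is more robust
than independent per-side majorities when both sides share residual
k-mers. Swapping the parents provably swaps every call, and
canonicalization makes voting invariant to how a side happens to be
stored.

## Bubble detection

When the assembler's own annotation is available it is taken verbatim
(as a 3-column sidecar: segment, bubble id, side; bubbles with other than
two sides are dropped with a warning). Otherwise homologous pairs are
found by sequence similarity:

* **Sketching.** Each segment's canonical k-mers (k = 22) are hashed with
  a seeded 64-bit mix; the smallest `sketch_size` = 128 distinct values
  form a bottom-s MinHash sketch. The Jaccard similarity of two k-mer
  sets is estimated from the sketches' overlap within the bottom-s of
  their union; pairs at or above `similarity_threshold` = 0.05 become
  candidates. At 1% heterozygous divergence and k = 22 the true Jaccard
  is around 0.35, so the threshold is permissive by design and the
  alignment stage does the discriminating.
* **Refinement.** Candidates are globally aligned on both strands
  (match +1, mismatch −1, gap −2); a pair with identity at or above
  `identity_threshold` = 0.9 over at least half the shorter sequence
  becomes an edge, and a greedy descending-identity matching (ties broken
  lexicographically, for determinism) yields disjoint two-sided bubbles.
  Greedy rather than optimal matching: real bubbles are overwhelmingly
  isolated pairs, and the greedy rule is transparent and stable.

Segments shorter than k are silently excluded. Multi-allelic bubbles are
out of scope.

## Chains and unzipping

Chains follow a strict diploid topology: alternating homozygous segments
and phased heterozygous pairs. A bubble side is *diploid* when, in each
traversal direction, it has at most two direct neighbours and its
*sibling set* — the other segments entering its neighbours at the same
end, which is how this package reads "two-hop neighbours" in a bidirected
graph — contains nothing but its bubble partner, with the partner
satisfying the mirrored condition. A non-bubble segment is
*homozygous-in-chain* when each direction attaches either nothing (a
graph end) or exactly the two sides of one diploid bubble, and at least
one direction is non-empty; the last clause means a fully isolated
segment is left out of chains rather than being duplicated into both
haplotypes. Everything else — tangles, branch points — is excluded, and
interrupts chains, a strict reading that trades contiguity for fidelity
to the input graph.

Chains are maximal simple walks over these labelled nodes (isolated
bubbles count: a one-element chain still carries phase). Unzipping takes
side $h$ of every phased bubble and duplicates every homozygous segment
into both haplotypes; a chain containing an unphased bubble is split at
that bubble rather than being phased arbitrarily, and every emitted step
is verified against the input links. Total sequence is conserved by
construction: unzipped bases equal twice the homozygous bases plus both
het sides. Outputs are P lines in the GFA, per-haplotype FASTA (records
`<chain>.<hap>`), and a third FASTA of everything unphased, so the three
files partition the assembly.

## Contact-level QC

`contact_stats()` reports mappings-per-read and alignment-length
distributions of usable records. `signal_ratio()` scores every unordered
pair of mappings of a read against a diploid truth labelling: an edge is
consistent (cis) when both contigs carry the same haplotype label, and
edges are binned by the minimum mapping quality of the pair, bins 0–60
plus overflow and a total row. A read hitting both copies of the same
locus produces a genuine trans edge — pairs are deliberately not
deduplicated by homologous locus. Supplementary alignments are *kept*
here by default (Pore-C subreads often arrive as supplementary records)
although the phasing path drops them; both behaviours are flag-controlled
(`contact_config(include_supplementary=)`).

## The synthetic generator

`simulate_diploid_graph()` plants exactly the structure the method
assumes: chains of hom–het–hom alternation, het sides as mutated copies
at `het_divergence`, random storage orientations (a fifth of segments
stored reverse-complemented, so orientation handling is always
exercised), and optional tangle branches that split chains. Truth tables
(bubble map, per-segment haplotype, per-bubble orientation, chain
fragments) are emitted alongside, so every downstream test is
closed-loop. Defaults are the package's standard study conditions: 10
chains × 20 bubbles (200 bubbles), 1 kbp segments, 1% divergence, 20
contact reads per adjacent bubble pair, signal ratio 0.95, Pore-C
concatemers with Poisson(8) subreads, and a 90/10 mixture of mapQ 60 and
mapQ 0 records so the filter path is always active.

Contacts are generated per chain: each read carries a true haplotype, its
anchor endpoint sits on that haplotype, and every other endpoint stays
cis with probability `signal_ratio`. In Hi-C mode a pair at bubble
distance $d$ receives `contacts_per_pair`$/2^{d-1}$ reads — a minimal
geometric stand-in for contact distance decay — and the cis probability
of an edge is exactly the configured signal ratio. In Pore-C mode
concatemers are anchored at adjacent pairs and span consecutive bubbles;
edges between two non-anchor subreads are cis with probability
$s^2+(1-s)^2$, slightly below $s$, which only makes the phasing task
harder than nominal. Parental k-mer dumps are derived from each chain's
transmitted haplotypes with counts scaled by an idealized coverage of
30×.

What the generator does **not** emulate: sequencing error and chimeric
mappings, restriction-site geometry, inter-chromosomal background
contacts, repeat-induced mismapping, and assembler artefacts other than
simple tangles. Passing the closed-loop tests therefore demonstrates the
correctness and calibration of the algorithms under their stated model,
not performance on real libraries.

## Numerical and design choices

* Orientation convention: `+` is the stored sequence, `-` its reverse
  complement; links are stored once in a canonical direction and queried
  symmetrically; only blunt (`0M`/`*`) overlaps are accepted, rejected at
  parse time so nothing downstream ever sees an overlap.
* Sequences are uppercased on read; anything outside A/C/G/T/N is an
  error (deterministic k-mer and reverse-complement semantics).
* Sub-seeds are derived from the configuration seed with a fixed integer
  recurrence, never from execution order; all randomized loops shuffle
  with R's RNG under those sub-seeds.
* Reads mapping to more than 50 distinct segments are skipped outright (a
  quadratic-blow-up guard against chimeric concatemers); secondary
  alignments are always dropped; no PCR-duplicate collapsing is done
  (Pore-C is PCR-free, Hi-C dedup belongs upstream).
* Unsupported bubbles (no contact edge, or trio lean below `min_votes`)
  keep an orientation but are flagged, and chains split around them.
* Test and acceptance problem sizes — 200 bubbles for recovery runs, 100
  instances of ≤ 12 bubbles for the exhaustive-enumeration comparison, 30
  node graphs for the classification cross-check, ~10⁴ reads for
  estimator calibration — were chosen as the smallest sizes at which the
  statistics of interest are stable.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_chains = 2, bubbles_per_chain = 6, segment_bp = 400,
                  seed = 61)
d <- tempfile()
fx <- simulate_fixture(cfg, d)
res <- phase_contacts(fx$files[["gfa"]], fx$files[["sam"]],
                      file.path(d, "out"),
                      annotation = fx$files[["annotation"]],
                      sampler = sampler_config(seed = 12))
glance(res$fit)
phase_error(res$fit, fx$sim$bubble_phase,
            groups = fx$sim$chains |>
              dplyr::filter(kind == "het") |>
              dplyr::transmute(bubble, group = chain))
```

## Limitations

* Two haplotypes only; polyploid phasing and >2-sided bubbles are out of
  scope.
* Chains are not scaffolded across gaps: two chains on the same
  chromosome remain separate phase blocks unless contacts merge their
  bubbles, and no gap filling is attempted.
* The homology search compares all segment pairs; for graphs far beyond
  ~10³ sequenced segments an indexed prefilter would be the next step.
* The alignment refinement uses a simple global scorer; highly
  length-discordant homolog pairs are better served by the annotation
  channel.
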