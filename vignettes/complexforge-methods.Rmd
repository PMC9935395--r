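---
title: "Methods: scoring, validating and assembling predicted protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, validating and assembling predicted protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexforge)
```

complexforge analyzes *predicted* pairwise protein complex models — the kind
produced by AlphaFold-style pipelines, with per-residue plDDT confidence
stored in the B-factor field — after prediction: it scores them, validates
them against crosslinking restraints, maps variant and phosphosite tables
onto their interfaces, clusters co-regulated interface phosphosites, and
stitches pairwise models into higher-order assemblies. This vignette explains
each model and procedure, the parameters that matter, and the design choices
made where the design was genuinely open.

## The pDockQ confidence score

A modeled dimer is summarized by its interface: every residue with a heavy
atom within 10 Å (inclusive) of any heavy atom of the partner chain is an
interface residue. With $n$ the number of interface residues summed over both
chains and $\bar{p}$ the mean plDDT over those residues (equal residue
weight, both chains pooled), the score is the sigmoid

$$\mathrm{pDockQ} = \frac{0.707}{1 + e^{-0.03148\,(x - 388.06)}} + 0.03138,
\qquad x = \bar{p}\,\ln n .$$

Two conventions deserve comment because the published description of this
family of scores leaves them open:

* **Logarithm base.** The log is natural. With a base-10 log, $x \le 100
  \times \log_{10}(n) \approx 300$ for realistic interface sizes, so the
  midpoint 388.06 would be unreachable; with the natural log a confident
  model ($\bar p \approx 80$, 100–200 interface residues) sits near the
  midpoint, which is where a discriminative score should place it.
* **"Contacts" means interface residues**, not atom pairs: the residue-count
  reading follows directly from the definition of $x$ above, and is what
  makes the midpoint numerically sensible.

Degenerate input: with $n = 0$ the log is undefined and the pair is not
interacting, so the score is defined as exactly 0 rather than the sigmoid
baseline 0.03138 — a non-interacting pair should not start with a bonus.

`confidence_bin()` applies the conventional operating points: scores
strictly above 0.5 are *high* confidence, strictly above 0.23 *acceptable*,
the rest *low*. Both cuts are exclusive, matching the "score > cutoff"
reading under which they were derived.

A separate, coarser classification — `classify_direct()` — asks whether two
chains touch substantially at all: more than 20 Cα–Cα pairs closer than 8 Å
(both bounds strict). It distinguishes directly interacting pairs from pairs
that merely co-occur in a larger complex.

```{r pdockq-example}
cx <- make_complex(n_chains = 2, seed = 1)
glance(score_dimer(cx$complex, "A", "B"))
```

## Crosslink validation

Lysine-reactive crosslinkers report pairs of lysines that were close in
solution; a model is consistent with a link when the Euclidean distance
between the two NZ (ε-amino) atoms is at most 32 Å (inclusive — the span is
"within" the crosslinker's reach). Links whose residues are missing from the
model, are not lysine, or lack the NZ atom are *unevaluable*, not violations.
A Cα fallback exists (`ca_fallback = TRUE`) but is off by default because it
changes the measured quantity from side-chain to backbone distance.
`crosslink_support_by_bin()` reproduces the cohort-level view: per pDockQ
bin, the fraction of models with at least one satisfied link, excluding
models with no evaluable link from the denominator.

## Site mapping and enrichment

`map_sites()` intersects (protein, position) tables — pathogenic and benign
variants, cancer mutations, phosphosites — with the interface residues of
confident dimers. The enrichment of one class over another at interfaces
uses the 2×2 table of (class × at-interface) with fold enrichment
$(a/(a+b)) / (c/(c+d))$ and a Fisher's exact p-value. Choices made here:

* The comparison's denominator ("rest of the protein") is the *modeled*
  residue universe, not the full UniProt length — only modeled positions can
  be classified at all.
* No test is canonical for this contrast; Fisher's exact test (two-sided by
  default, one-sided available) is the natural exact choice for the 2×2
  table.
* A site occurring in several dimers counts once per protein position for
  enrichment; the per-interface listing keeps the duplicates.
* `recurrence_rank()` flags interfaces in the top 25% of mutation density
  (mutations per interface position), inclusive at the quantile boundary so
  tied interfaces are treated alike; with zero mutations everywhere nothing
  is flagged.

## Superposition and TM-score

The geometric primitives are a closed-form Kabsch superposition (proper
rotation only: the SVD sign correction forbids reflections, so mirror images
superpose imperfectly rather than spuriously well) and a TM-score

$$\mathrm{TM} = \max \frac{1}{L}\sum_i \frac{1}{1 + (d_i/d_0)^2},
\qquad d_0 = 1.24\,(L-15)^{1/3} - 1.8 \;(\text{floored at } 0.5),$$

normalized by the reference length $L$. The maximization seeds Kabsch fits
from contiguous fragments of length $L, L/2, \dots, 4$, iterates inclusion of
residues with $d_i < d_0$ to a fixed point, and finally polishes the best
transform with iteratively reweighted Kabsch using the TM kernel's
derivative weights. Correspondence between residues comes from residue
numbering (the intended use compares two models of the same protein) or an
explicit map; sequence-independent alignment is out of scope. Collinear
point sets are rejected (the rotation about the axis is undetermined), and
degenerate seed windows are skipped.

`assembly_rmsd()` evaluates a built assembly against a reference complex:
chains are matched by protein accession, the copy assignment for repeated
proteins is chosen by exhaustive search over per-protein permutations (up to
a combination cap, then greedy), and a *single global* superposition over
all matched Cα atoms yields both the RMSD and the TM-score (normalized by
the total reference length, so unmatched reference residues count against
the score).

## Greedy assembly from dimers

The assembly algorithm builds a complex from a ranked list of dimer models:

1. Rank all dimers by pDockQ (ties broken lexicographically by id, making
   the procedure deterministic).
2. Seed the assembly with the top-ranked dimer (or a user-chosen one).
3. Sweep the ranking. A dimer is usable only if *exactly one* of its
   proteins is already placed. Its shared chain is superposed onto each
   placed copy of that protein in placement order; the superposition must
   pass TM-score > 0.8 (strict), otherwise the dimer is rejected for this
   sweep (`rejected_tm`). The partner chain is then transformed into the
   assembly frame and rejected if strictly more than 25% of its residues
   fall within 5 Å (Cα–Cα, strict) of any placed chain (`rejected_clash`).
4. After any successful addition the sweep restarts from the top of the
   ranking. The procedure stops when a full sweep adds nothing.

Open points resolved here, as this package's own choices:

* **Added dimers are not retried.** Without this rule a homodimer would
  extend its own product indefinitely (each new copy licenses the next), so
  termination would not be guaranteed. Rejected dimers *are* retried on
  later sweeps, because a later addition can create a new copy of their
  shared protein.
* **Homodimers** with their protein already placed try both chains as the
  shared chain, in order.
* **"Identical chain" means same protein accession** as declared in the
  manifest; no sequence comparison is performed.
* A finite `max_copies` stoichiometry cap is available (default unlimited)
  and logs `skipped_max_copies`.

Every decision — seed, added, skipped (no shared chain / both present),
rejected (TM / clash) — is logged in order with its metrics; identical
inputs give identical logs.

```{r assembly-example}
cx <- make_complex(n_chains = 5, seed = 1)
asm <- assemble(cx$dimers)
tidy(asm)
assembly_rmsd(asm, cx$complex, reference_map = cx$chain_map)
```

## Phosphosite co-regulation

The pipeline mirrors a standard condition-panel analysis. Sites with more
than a twofold change (|log2FC| > 1, strict) in at least three conditions
are retained; all-by-all Pearson correlations are computed over
pairwise-complete conditions; each site is then represented by its row of
correlations, and Ward clustering (the `ward.D2` variant — Ward's
minimum-variance criterion applied to the Euclidean distances themselves;
implementations differ and this is stated explicitly) of the Euclidean
distances between those rows is cut at a height or into a target number of
clusters. A fixed cut height only makes sense for a fixed matrix, so the cut
is a parameter rather than a constant.

Numerical edge rules: correlations from fewer than `min_overlap = 5` shared
conditions, or involving a constant profile, are set to 0 — "no evidence of
co-regulation" — rather than propagating NA into the distance computation
(row-dropping is available instead).

Per-cluster condition regulation uses a Z test of the cluster mean against
the condition's overall fold-change distribution:
$z = (\bar{x}_{\mathrm{cluster}} - \bar{x}_{\mathrm{bg}}) /
(s_{\mathrm{bg}}/\sqrt{n_{\mathrm{cluster}}})$, with a one-sided p-value on
the side of the observed deviation and the sign of the reported
$-\log_{10} p$ set by whether the cluster *median* exceeds the background
median. The background includes the cluster's own members by default (the
comparison is against the overall distribution); excluding them is a flag.
Because the reported p is folded onto the observed side it lives in
(0, 0.5]; calibration checks therefore examine the directional tail
probability $\Phi(-z)$, which is uniform under the null exactly when $z$ is
calibrated. Term over-representation is a one-sided upper-tail
hypergeometric test with Benjamini–Hochberg adjustment across terms (the
correction choice is this package's; no particular correction is canonical
for this analysis).

## The synthetic-fixture generator

All quantitative guarantees are demonstrated on synthetic ground truth
generated by `make_complex()`, `make_crosslinks()` and `make_fc_matrix()`:

* **Complexes** are idealized poly-lysine α-helices (2.3 Å radius, 100°
  twist, 1.5 Å rise; CA, CB and NZ heavy atoms per residue) placed on a
  line, ring or grid with 10 Å axis spacing. That spacing makes adjacent
  chains span Cα distances of roughly 5.4–14.6 Å — genuine contacts, no
  clashes — while non-adjacent chains make none; the generator asserts this
  adjacency invariant post hoc and errors if it cannot hold (at the default
  spacing roughly 24+ residues per chain are needed). Each adjacent pair is
  exported as a dimer in its own randomly perturbed rigid frame, with the
  true transform recorded, emulating independently predicted dimer models
  whose mutual orientation the assembly algorithm must recover.
* **Crosslinks** are sampled lysine pairs with a controlled mix of NZ–NZ
  distances on either side of 32 Å, with expected statuses emitted.
* **Fold-change matrices** draw one latent signal per (cluster, condition)
  plus independent per-site noise. Defaults — 60 sites, 50 conditions, 3
  clusters, signal SD 2, noise SD 0.2 (signal-to-noise 10) — are a
  deliberately scaled-down, clearly structured analogue of a real panel of
  a few hundred sites over 200+ conditions; they are study conditions, not
  tuning knobs.

What passing tests on these fixtures shows — and does not show: the
geometry, scoring, restraint logic and clustering machinery are exact or
well-calibrated on inputs whose ground truth is known by construction. Real
predicted models add everything the generator deliberately omits: side-chain
packing, flexible loops, wrong-but-confident interfaces, partially modeled
chains, inconsistent dimer conformations of the same protein, and
phosphoproteomics matrices with structured missingness and correlated noise.
Performance on such data is bounded by the quality of the upstream
predictions, not by this machinery.

Randomness is confined to the generators, each of which takes an explicit
seed, uses R's Mersenne–Twister with inversion sampling, and restores the
caller's RNG state, so fixtures are bit-reproducible across machines.

## Problem sizes and determinism

The shipped tests and the acceptance script run on deliberately small
problems — chains of 15–40 residues, complexes of up to 8 chains, matrices
of up to 200 × 50 — chosen so the whole suite completes in well under a
minute while still exercising every code path; all quantitative claims
(superposition recovery to 1e-6 Å, sub-Å assembly round-trips, ARI ≥ 0.9
cluster recovery, uniform null p-values) hold at these sizes by computation,
not by construction. All pipelines are deterministic given their inputs and
seeds.

## Known limitations

* mmCIF support covers atom records (`_atom_site`), which is all the
  pipeline consumes; other categories are ignored on read and not written.
* TM-score requires a residue correspondence; it does not align sequences.
* The assembly algorithm emits one deterministic solution; alternative
  conformations can be explored via `start_dimer` but are not scored against
  each other.
* When a complex contains paralogous subunits the shared-chain logic cannot
  tell copies of *different but homologous* proteins apart any better than
  the input accessions do — misplacements among homologs are expected
  behavior inherited from the inputs, not detected here.
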