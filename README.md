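# complexforge

Post-prediction analysis of predicted protein complex models. Structure
prediction networks now produce pairwise complex models at interactome
scale, each carrying per-residue plDDT confidence (0–100) in the B-factor
field of its coordinate file. What those models are worth — which are
credible, which agree with orthogonal experiments, what biology sits on
their interfaces, and whether they can be combined into larger machines —
is a downstream analysis problem. complexforge implements that analysis for
structural bioinformaticians working with such model sets:

* **Interface detection and pDockQ scoring.** An interface residue has a
  heavy atom within 10 Å of the partner chain. With *n* interface residues
  (both chains) and mean interface plDDT p̄, the confidence score is

  pDockQ = 0.707 / (1 + exp(−0.03148 (x − 388.06))) + 0.03138,  x = p̄ · ln *n*,

  binned at the conventional 0.23 (acceptable) and 0.5 (high) operating
  points. A direct-contact classifier (more than 20 Cα–Cα pairs under 8 Å)
  separates truly touching chains from co-complex bystanders.
* **Crosslink validation.** Lysine–lysine crosslinking restraints are
  satisfied when the NZ–NZ distance is within 32 Å; cohort summaries report
  the fraction of models supported per confidence bin.
* **Interface site mapping.** Mutation and phosphosite tables are mapped
  onto confident interfaces, with Fisher-exact enrichment (e.g. pathogenic
  vs benign variants at interfaces) and recurrent-mutation-density ranking.
* **Phosphosite co-regulation.** Regulated interface phosphosites
  (|log2FC| > 1 in ≥ 3 conditions) are correlated across condition panels,
  Ward-clustered on their correlation profiles, and tested per cluster and
  condition (Z test) and per annotation term (hypergeometric).
* **Greedy assembly.** Dimer models are ranked by pDockQ and iteratively
  merged into higher-order assemblies: a dimer sharing exactly one protein
  with the growing complex is superposed on the shared chain (TM-score >
  0.8 gate), and its partner chain is placed unless it clashes with more
  than 25% of its residues (Cα–Cα < 5 Å). Kabsch superposition, TM-score
  and assembly-vs-reference RMSD are included.
* **Synthetic ground truth.** A fixture generator produces multi-chain
  complexes with known rigid transforms, planted crosslink mixes and
  planted co-regulation clusters, so the entire pipeline is testable
  offline with exact expectations.

Results are tibbles; fitted objects have `tidy()`/`glance()` methods and
ggplot2 helpers (`plot_pdockq_sigmoid()`, `plot_crosslink_support()`,
`plot_condition_regulation()`).

## Worked example

Build a 5-chain synthetic complex, decompose it into scored dimer models in
random frames, reassemble them, and compare with the ground truth:

```r
library(complexforge)

cx <- make_complex(n_chains = 5, seed = 1)
glance(score_dimer(cx$dimers$structure[[1]], "A", "B"))
#> # A tibble: 1 × 7
#>   chain_a chain_b n_contacts mean_if_plddt     x pdockq bin
#>   <chr>   <chr>        <int>         <dbl> <dbl>  <dbl> <chr>
#> 1 A       B               60            90  368.  0.279 acceptable
```

Sixty interface residues at uniform plDDT 90 give x = 90·ln(60) ≈ 368,
below the sigmoid midpoint of 388 — an "acceptable" but not high-confidence
model, exactly what a clean but small synthetic interface should score.

```r
asm <- assemble(cx$dimers)
tidy(asm)
#> # A tibble: 5 × 7
#>   sweep dimer_id action shared_protein copy_tried    tm clash_fraction
#>   <int> <chr>    <chr>  <chr>               <int> <dbl>          <dbl>
#> 1     0 D01_AB   seed   <NA>                   NA    NA             NA
#> 2     0 D01_AB   seed   <NA>                   NA    NA             NA
#> 3     1 D02_BC   added  P2                      1     1              0
#> 4     2 D03_CD   added  P3                      1     1              0
#> 5     3 D04_DE   added  P4                      1     1              0

assembly_rmsd(asm, cx$complex, reference_map = cx$chain_map)
#> # A tibble: 1 × 4
#>       rmsd tm_score n_matched n_chains_matched
#>      <dbl>    <dbl>     <int>            <dbl>
#> 1 1.15e-14        1       150                5
```

The log shows the greedy procedure: the top-ranked dimer seeds chains A and
B, and each remaining dimer is added through its shared protein at TM-score
1 with no clashes. All 150 Cα atoms land on the ground truth to machine
precision (RMSD ~1e-14 Å, TM-score 1), confirming that the recorded random
dimer frames were exactly inverted.

Crosslink restraints against the same complex:

```r
xl <- make_crosslinks(cx$complex, cx$chain_map, n_links = 10,
                      satisfied_fraction = 0.7, seed = 2)
glance(validate_crosslinks(xl$links, cx$complex, cx$chain_map))
#> # A tibble: 1 × 6
#>   n_links n_satisfied n_violated n_unevaluable fraction_satisfied any_satisfied
#>     <int>       <int>      <int>         <int>              <dbl> <lgl>
#> 1      10           7          3             0                0.7 TRUE
```

The planted 70/30 mix of satisfiable and violated links is recovered
exactly.

## Command line

A thin CLI over the same functions ships in `inst/cli/complexforge.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/complexforge.R", package="complexforge"))')
Rscript $CLI simulate complex --out-dir sim --seed 3
Rscript $CLI pdockq sim/D01_AB.pdb --chain-a A --chain-b B
Rscript $CLI assemble --dimers sim/manifest.tsv --out complex.pdb --log assembly.json
Rscript $CLI xl-validate model.pdb --links links.tsv --map chain_map.tsv
Rscript $CLI coreg --matrix fc_matrix.tsv --n-clusters 3 --out-prefix coreg
```

## Documentation

The methods vignette (`vignettes/complexforge-methods.Rmd`) describes the
models, the parameter conventions (log base, inclusive/strict boundaries,
Ward variant, background definitions), the synthetic generator's scope, and
known limitations.
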