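---
title: "Constraint-based signaling models and their metabolic crosstalk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based signaling models and their metabolic crosstalk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtalk)
library(tibble)
```

## The modeling idea

fluxtalk treats a cell-signaling pathway the way constraint-based (COBRA)
methods treat metabolism. The pathway is an m-by-r stoichiometric matrix $S$
over species (proteins, complexes, phosphorylated forms) and reactions
(binding, dimerization, phosphorylation events). A flux vector $v$ — reaction
rates in arbitrary units (AU) — is admissible when it satisfies steady state,
$S v = 0$, and box bounds $l \le v \le u$. All reactions are irreversible, so
$l \ge 0$; internal reactions default to $[0, 1000]$ AU. No kinetics are
assumed: everything the package computes is a property of the flux polytope
$\{v : Sv = 0,\ l \le v \le u\}$.

The pipeline has five stages, each usable on its own:

1. **Reconstruction** — turn a raw pathway (SBML, tabular workbook dialect,
   or JSON) into a feasible model: default bounds, modifier rewriting,
   GPR rules, and minimal-exchange dead-end closure.
2. **Contextualization** — tighten reaction bounds from differential gene
   expression between two cell states (here epithelial "E" vs mesenchymal
   "M"), yielding a paired model.
3. **Sampling** — characterize each context's flux space by hit-and-run
   sampling and compare per-reaction mean fluxes.
4. **Reversal** — find the smallest set of bound relaxations that lets the
   mesenchymal model reproduce the epithelial flux state (a MOMA-like
   distance minimization).
5. **Crosstalk** — translate a signaling pathway's flux difference into
   predicted regulation of downstream metabolic genes via a literature sign
   table, score it against observed expression, and propagate it into a
   metabolic model.

## Reconstruction

### Modifiers

A modifier is a phosphorylated protein that catalyzes a downstream
transition without being consumed by it; in raw pathway exports it is
annotated on the reaction but absent from the stoichiometry, which
disconnects it from its targets. `insert_modifiers()` rewrites each modified
reaction `A -> B` as

```
            -> mod        (production exchange)
A + mod     -> B + mod_p  (mod is spent into mod_p)
mod_p       ->            (consumption exchange)
```

The spent species `mod_p` gets the role `modifier-product`; the two
exchanges are shared when several reactions use the same modifier. The
rewrite adds exactly $-1$ (modifier) and $+1$ (spent form) to the reaction's
column, so the modifier is conserved.

### GPR rules

Gene-protein-reaction rules connect expression data to reactions.
Multiprotein complexes join their subunit genes with `AND`, isoform sets
with `OR`, and inhibitors are wrapped in `NOT` — an expressed inhibitor
suppresses its reaction. A reaction with both a modifier and an inhibitor
gets `modifier AND NOT inhibitor`. Modifier production/consumption
exchanges inherit the modifier's genes, so expression changes reach them
too. Reactions with no regulatory annotation carry no rule. The grammar
gives `NOT` precedence over `AND` over `OR`; `gpr_parse()` /
`gpr_deparse()` are exact inverses.

Evaluation is *ternary*: gene states live in $\{+1, 0, -1\}$ (up in E,
unchanged, up in M), with `AND` = min, `OR` = max, `NOT` = negation. The
Boolean intent of GPRs only fixes the $\pm 1$ corners; the ternary
extension is what lets "unchanged" propagate without forcing a call. Two
consequences worth knowing: a complex whose genes disagree (one up-E, one
up-M) resolves to the minimum, and a rule mixing a called with an unchanged
gene can absorb the call (e.g. `OR` over isoforms needs *every* isoform to
move before the inhibitor call flips a reaction). `evaluate_gpr(mode =
"boolean")` gives the strict two-valued semantics when that is preferred.

### Dead-end closure as a mixed-integer program

Raw pathways contain dead ends — species only produced or only consumed —
which block steady-state flux. `add_minimal_exchanges()` closes them while
keeping the boundary minimal, because opening an exchange for every species
would make the network topology irrelevant. Candidate exchanges with bounds
$[0,0]$ are added for every species, internal lower bounds are forced to 1
AU so every internal reaction must carry flux, and the program

$$\min \sum_{j \in R_r} y_j \quad \text{s.t.}\quad Sv = 0,\;
l_j - n_j \le v_j \le u_j + p_j \;(j \in R_r),\;
l_i \le v_i \le u_i \;(i \in R_n),\;
0 \le p_j, n_j \le M y_j,\; y_j \in \{0,1\}$$

selects the minimum number of candidates to relax ($M = 1000$). Only the
selected exchanges are kept, split by flux direction into an uptake
(`-> X`) or secretion (`X ->`) reaction with bounds $[0, 1000]$; internal
lower bounds are then restored. The result has no dead ends, supports
simultaneous flux $\ge 1$ through every internal reaction, and the
operation is a fixed point (re-running changes nothing).

No mixed-integer solver is available as an R package dependency here, so
the program is solved exactly in-package: branch-and-bound over the binary
indicators with a convex feasibility check (quadprog's dual active-set
method, which certifies infeasibility) at each node, an LP-relaxation lower
bound from a small two-phase simplex written for the purpose, and a greedy
irreducible incumbent. Among equal-cardinality optima the result minimizes
the total relaxation $\sum_j (p_j + n_j)$ (via an LP), with remaining ties
broken lexicographically by reaction id — so results are deterministic and
solver-independent. Tests verify the branch-and-bound against exhaustive
subset enumeration on every synthetic network with up to 14 candidates.
Numerical tolerances: feasibility $10^{-9}$ in the simplex, relaxation
amounts below $10^{-9}$ reported as zero.

## Contextualization

`classify_regulation()` calls a gene when $|\text{fold}| \ge$ cutoff and
$p \le \alpha_p$ (default 0.05); the sign convention is negative = higher
in the epithelial line. Cutoffs are data-set properties: the packaged
presets (`cell_line_cutoffs()`) are 2 for the D492 EMT pair and 0.5 /
0.5 / 0.3 for the MCF7 / MCF10A / HMLE panels, reflecting each platform's
housekeeping-gene variation. Fold changes are taken on the table's own
relative scale; a `log2_input` flag accommodates log-ratio tables. The
significance filter is exposed as an argument rather than hard-wired, since
one may reasonably apply it to signaling genes, metabolic genes, or both.

Since upper bounds are effectively infinite capacity, up-regulation in one
state is encoded by *down*-regulating the other model:
`build_context_pair()` multiplies both bounds of an up-E reaction by
`tighten_factor` (default 1/100; 1000 becomes 10) in the mesenchymal model
and vice versa; inhibition, entering through `NOT`, lands as
down-regulation in the same model. Tightened reactions are flagged so the
rule is idempotent. Exactly the called reactions differ between the pair.
Label swapping (negating all fold changes) mirrors the pair exactly when
rules are conflict-free; complexes mixing called with unchanged genes
break strict mirror symmetry, a direct consequence of the ternary min/max
semantics discussed above.

## Sampling

`sample_fluxes()` draws approximately uniform flux vectors with an
artificially-centered hit-and-run walk: warm-up points are the min/max
vertices of every reaction from flux variability analysis (so directions
span the polytope and lie exactly in the null space of $S$), directions
point from the running center to a random warm-up point, and each step is
uniform on the feasible chord. Defaults: 5000 samples, thinning 100, fixed
seed — runs are deterministic given the seed. The walker is re-projected
onto $\{Sv=0\}$ every 500 steps, keeping the steady-state residual below
$10^{-6}$ over arbitrarily long walks; every emitted sample is checked
against that tolerance and the bounds. Pointlike polytopes (all FVA spans
zero) yield constant samples rather than an error. The sampler is the one
place the package is stochastic; everything downstream records the seed.

`compare_fluxes()` reports, per reaction, the mean fluxes, the fold
$(\bar v_M + \epsilon)/(\bar v_E + \epsilon)$ with $\epsilon = 10^{-6}$ AU
guarding zero-flux reactions, its log2, and the linear difference (both a
ratio and a difference are emitted because either scale may be wanted for
display). The span statistic defaults to the mean flux; a max–min width
variant is available by flag, since "flux span" is used in both senses —
both are computed, and which one a given downstream table used cannot
always be recovered. `pathway_report()` aggregates folds over named
reaction sets by geometric mean (arithmetic by flag), excluding exchange
reactions by default, and exposes a heat-map-ready log2 matrix.
`density_estimate()` (Gaussian kernel, Silverman bandwidth) is for
reporting only — no decision in the pipeline depends on a density.

## Reversal

`minimize_distance()` replaces the cardinality objective with

$$\min\; \alpha\,\lVert v - v_E \rVert + (1-\alpha) \sum_{j \in R_r} y_j$$

subject to the same constraints, with bounds from the mesenchymal model and
$v_E$ the epithelial mean flux from a seeded sampling run. $\lVert\cdot\rVert$
is the Euclidean norm (not squared). The weight $\alpha$ is not fixed by
any external convention, so the package defaults to 0.5 and always reports
it; an optional `norm_scale = "relative"` divides the distance by
$\lVert v_E \rVert$, making the two terms commensurate when that is a
concern. $\alpha = 0$ degenerates to pure feasibility (ties to the
reconstruction MILP); as $\alpha \to 1$ the achieved distance is
non-increasing (tested over an $\alpha$ grid). The solver is the same
branch-and-bound with a convex QP per node; `method = "enumerate"`
exhaustively enumerates candidate subsets and must agree — both routes are
compared in the tests on networks with up to 14 candidates. The candidate
set defaults to all reactions, and $v_E$ entries for exchange reactions
participate in the norm (excluding them is a matter of passing a
restricted candidate set). `genes_for_reactions()` maps the relaxed set to
genes through the GPRs, flagging inhibitors (odd `NOT` parity) separately.

## Crosstalk

A literature sign table links a signaling pathway to metabolic genes:
$+1$ means the active pathway induces the gene, $-1$ that it suppresses it.
With the pathway's aggregate flux fold $f$ (mesenchymal over epithelial),
`predict_metabolic_expression()` returns `down_in_M` for induced genes when
$f < 1$, `down_in_E` for suppressed ones, the mirror image for $f > 1$,
and no call at exactly 1. The packaged `akt_regulation_signs()` table
covers 20 AKT-regulated genes of glycolysis, gluconeogenesis (the two
$-1$ entries, G6PC and PCK1), fatty-acid and purine/pyrimidine metabolism;
`akt_observed_d492()` carries their observed microarray direction in the
D492/D492M EMT cell pair, with `NA` where expression was undetectable.

`score_agreement()` counts exact matches over the evaluable (non-`NA`)
genes. On the packaged tables this gives 13 of 15 evaluable genes in
agreement, with GLUT1 and SREBF1 the two disagreements — printed as 86.6%
and 13.3%: percentages truncate toward zero at one decimal, the convention
under which 13/15 prints as 86.6, and the raw value is always carried
alongside. `constrain_metabolic_model()` then applies the identical
tightening mechanics to any GPR-bearing metabolic model (the package ships
none; point `read_model()` at a reconstruction of your choice), and
`compare_flux_span()` partitions reactions by the span ratio
$s_M(i)/s_E(i)$ with an $\epsilon$-guarded denominator and a log2
tolerance band (default 0.1) around "similar".

## The synthetic-data generator

`make_network()` / `make_expression()` / `make_sign_table()` generate every
input the pipeline consumes, with ground truth computed by independent
oracles at generation time: dead ends by a direct row-sign scan, minimal
exchange cardinality by exhaustive subset enumeration with a convex
feasibility check per subset (capped at 20 species so the oracle stays
under a second; larger networks carry no truth and serve as smoke tests).
Networks are one-to-one reactions along an acyclic topology (`chain`,
`branch`, `diamond`, `random-dag`), which makes them trivially mass
balanced and guarantees dead ends exist before closure. Planted
differential genes get fold magnitudes beyond the cutoff (default effect 3
against cutoff 2) with $p \le 0.01$; background genes stay below the
cutoff. The generator is deterministic per spec (identical spec, identical
output).

What the generator does *not* emulate: real microarray noise structure,
probe-level effects, correlated expression, reversible reactions, or
stoichiometry beyond one-to-one. Passing tests on synthetic data therefore
demonstrate algorithmic correctness (recovery of planted signal under the
stated conditions, agreement with enumeration oracles), not robustness to
real-data pathology.

## Problem sizes and reproducibility

The test suite and the acceptance script run on synthetic networks of 3–14
species with 5000-draw sampling runs (thinning 10–100); the enumeration
oracles cover every candidate set up to size 14. These sizes were chosen so
each oracle remains exhaustive and each sampling run converges well inside
a desk-scale compute budget. `scripts/acceptance.R --seed S --out F`
recomputes the headline quantities end-to-end from the given seed.

Two published reference checks require the authors' deposited
supplementary files, which are not redistributable with the package: the
deposited EGFR signaling network (182 reactions, 216 genes, 152 species,
83 internal / 99 exchange, 11 inhibitors) and the paired contextualized
models whose reversal analysis highlights 5 reactions mapping to 22 genes.
The acceptance tests look for these under
`inst/extdata/deposited/EGFR_SN/` (table dialect: `Reactions.tsv`,
`Species.tsv`, `GPRs.tsv`, `Modifiers.tsv`, `Activators.tsv`,
`Inhibitors.tsv`, `Proteins.tsv`) and `inst/extdata/deposited/EGFR_E.json`
/ `EGFR_M.json`, and fail visibly when the files are absent. A workbook
exported sheet-by-sheet to TSV drops in directly; whether a deposited
model encodes activators separately from modifiers does not matter to the
reader, which accepts both layouts. Whether a deposited model's 99
exchanges include the modifier production/consumption exchanges can be
checked from the species roles (`modifier-product`) after import — the
package keeps the two kinds distinguishable.

## Known limitations

- The branch-and-bound is exact but exponential in the worst case; it is
  intended for pathway-scale models (tens to low hundreds of reactions),
  not genome-scale reconstructions.
- Hit-and-run mixing is not diagnosed automatically; for fat polytopes
  increase thinning and compare runs across seeds.
- Ternary GPR semantics are a modeling choice, not an identity: strict
  Boolean evaluation is available, and conflicting complexes resolve to
  the minimum rather than erroring (use the comparison of both modes to
  audit).
- The crosstalk step is only as good as the sign table; the packaged AKT
  table is literature-curated and carries reference tags per row.
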