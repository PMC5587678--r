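---
title: "Genetic minimal cut sets: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic minimal cut sets: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmcsr)
```

## The problem

A constraint-based metabolic model describes a cell's metabolism as an
$m \times n$ stoichiometric matrix $S$ (metabolites by reactions, products
positive, educts negative), flux bounds per reaction, and a biomass
pseudo-reaction whose flux stands for proliferation. At steady state the
feasible fluxes satisfy $S r = 0$ with $lb \le r \le ub$.

A *reaction-level* minimal cut set (MCS) is an inclusion-minimal set of
reactions whose removal makes biomass flux impossible. Therapy, however,
acts on genes, and the mapping from genes to reactions is the boolean
gene–protein–reaction (GPR) rule of each reaction: `or` joins isozymes (any
one gene product suffices), `and` joins complex subunits (all are needed).
Because of isozymes, a reaction-minimal cut need not be achievable by a
minimal set of gene knockouts — deleting the reaction `gA or gB` requires
*two* genes. A *genetic* minimal cut set (gMCS) is therefore defined
directly at the gene level: an inclusion-minimal gene set whose joint
knockout blocks the task. The `isozyme_demo` fixture reproduces exactly
this divergence, and the acceptance tests assert it.

The package's purpose is synthetic-lethality prediction in a cancer
context: given a sample's *lowly expressed* gene set $L$ (transcriptionally
silent backup routes) and a candidate target gene, find gMCSs that contain
the target and otherwise draw only on $L$. If such a set exists, the
context has already lost every escape route and the target alone is
predicted essential in that sample.

## From GPR rules to the knockout matrix

All knockouts the search may use are compiled into a binary matrix $G$
($g \times n$): row $k$ corresponds to one inclusion-minimal subset of
knockable genes (from $L$ plus the target gene) whose joint deletion
disables at least one reaction, and marks *every* reaction column whose
GPR fails under that deletion. The gene count of each row is kept in the
vector $a$. With one-to-one GPRs, $G$ is the identity pattern and the
machinery reduces to reaction-level cut sets.

Per-reaction minimal deletion subsets are computed structurally on the
parsed rule tree restricted to the knockable genes (genes outside stay
"present"): a gene leaf contributes itself; an `and` node is disabled by
disabling any child (union of the children's families); an `or` node needs
every child disabled (cross-product union). Families are pruned to
antichains at each step. This is the prime-implicant expansion of the
rule's complement; a configurable term-count cap (default 10,000) guards
against pathological rules, and the test suite validates the routine
exhaustively against subset enumeration.

Two choices here were genuinely open:

* **Row pooling.** Rows are deduplicated by gene set and their blocked
  patterns recomputed globally, because the dual variable attached to a row
  must price *every* reaction that its knockout disables, not only the
  reaction that generated the row.
* **Double counting.** Rows may share genes, so the weighted objective
  $\sum a_k z_k$ can exceed the size of the union of the selected rows.
  Minimality is restored downstream by union-and-shrink verification (see
  below) rather than by complicating the objective.

## The dual-problem MILP

Blocking the task means making the primal system
$\{S r = 0,\ r \ge 0,\ G r \le 0,\ t^\top r \ge r^*\}$ infeasible, where
$t$ indicates the target reaction. By Farkas-type duality, infeasibility
certificates live in the cone $N^\top y \ge 0$ over the dual variables
$u$ (metabolites, free), $v \ge 0$ (one per $G$ row) and $w \ge 0$ (the
task), with $N = [S^\top\, G^\top\, -t]$. Support-minimal certificates
with $w$ active correspond to minimal cut sets. The MILP assembled by
`build_dual_milp()`:

* forces the task dual active, $r^* w \ge c$;
* forces the target gene into the solution: the summed $v$ over all rows
  containing the target is at least $b$. (With a single such row this is
  the textbook unit-vector constraint; summing over all rows is this
  package's generalisation, since a gene typically appears in several
  rows. Single-row instances reduce to the simpler form.)
* adds redundancy multipliers $x \ge 0$ with
  $S x = 0$, $G x - \varepsilon + \delta = d$, $-t^\top x + r^* x_{n+1} = 0$,
  which force the target-forcing constraint to be expressible as a
  non-negative combination of active rows — the guarantee that a feasible
  point contains a genuine cut rather than an arbitrary certificate;
* links binaries to continuous duals, $\alpha z \le v \le M z$ and
  $\varepsilon + \delta \le M(1 - z)$;
* minimises $\sum a_k z_k$.

Enumeration repeats solve → verify/shrink → exclusion cut. After each
solution the row-space integer cut
$\sum_{k \in \text{active}} z_k \le |\text{active}| - 1$ removes the exact
selection, and an additional gene-level cut (auxiliary covering
indicators, one per reported gene) bars any future selection whose
row-union covers the reported set — without it a different row combination
can re-derive the same genes. Since verified gMCS families are antichains,
this never excludes an unseen cut set.

### Verification and shrinking

Solver output is never trusted: the union of the selected rows' genes is
checked by an explicit LP (`check_cut()`: disable failing reactions,
maximise target flux) and then shrunk greedily — genes other than the
target are dropped, longest identifier first and ties lexicographic, so
output is reproducible — while the remainder still cuts. Minimality is
then certified by single-gene removals, which suffices because the cut
property is monotone under supersets; the acceptance tests additionally
re-check every proper subset exhaustively. A shrunk set can fail full
minimality in one legitimate way: the *target itself* may be redundant (a
subset without it already cuts), in which case no gMCS through the target
exists on that support; such candidates are excluded and enumeration
continues. Results from solves that hit the time limit are kept (flagged
`feasible_shrunk`) but verified identically; a timeout with no incumbent
yields an explicit `timeout_none` row and downstream verdicts become
`undetermined` rather than silently non-essential.

### Constants and numerics

The MILP constants are `r_star = 1`, `c = 1`, `b = 1`, `alpha = 1e-3`,
`big_m = 1e3`, all configurable in `gmcs_config()`. They are stated in the
framework only as "small and large positive constants"; the defaults
follow common minimal-cut-set MILP practice, and the test suite asserts
that doubling `big_m` while halving `alpha` leaves every returned family
unchanged. Free dual variables are capped at $\pm M$ for boundedness; a
too-small $M$ cannot corrupt results — it can only make the post-hoc LP
verification fail, which raises an explicit error advising a larger
constant. Blocked-reaction detection uses a `1e-9` tolerance on LP optima
(solver noise floor); cut verification uses `1e-6` on a task whose demand
is of order 1.

The linear programs are solved by the package's own dense two-phase
simplex with a Dantzig-to-Bland pivot switch (termination on degenerate
bases), and the MILP by deterministic depth-first branch and bound with
integral-objective rounding bounds. Both layers are validated in the test
suite against analytic optima and exhaustive search; during development
they were additionally cross-checked against an independent HiGHS-based
solver on hundreds of random programs. Keeping the solver inside the
package makes enumeration fully deterministic and dependency-free.

## Preprocessing

Reversible reactions are split into forward/reverse copies (both inherit
the parent GPR, so a knockout silences the pair), infinite bounds are
capped at 1000 flux units, and blocked columns are removed by
flux-variability analysis — one maximisation LP per column suffices after
splitting since minima are zero. The reduction preserves the maximal
target flux, is idempotent, and refuses to continue when the target task
itself is infeasible in the chosen medium. Thermodynamically infeasible
loops are deliberately *not* removed; they do not affect blocking
analysis. Growth media are applied as exchange-reaction bound overrides,
optionally closing the uptake of every unlisted exchange.

## Expression handling

Z-score tables are read at probe or gene level; probe-to-gene aggregation
takes the per-sample median over probes (midpoint convention for even
counts) and a consensus column is the per-gene median across samples. A
gene is called expressed at `z >= 5` (inclusive), the expression-barcode
convention; the threshold is a parameter. Genes present in the model but
missing from the table are treated as expressed — an unmeasured gene never
licenses a knockout, the conservative direction. A reaction is lowly
expressed exactly when its rule fails under deletion of the lowly
expressed genes; for flat rules this reproduces the three classical
conventions (single gene follows its gene; OR needs all genes low; AND
needs any), which the tests verify on an enumerated rule inventory.

## The statistics layer

* `logistic_or()` fits the single-binary-covariate logistic model of
  reference essentiality on predicted essentiality. For a saturated 2×2
  table the MLE is the cross-product ratio $\mathrm{OR} = e^{\beta_1} =
  ad/bc$, so the default method is the closed form (analytically exact);
  the iterative `glm` fit is retained for API symmetry and a
  likelihood-ratio p-value is available behind a flag (the default is the
  two-sided Wald test; the framework does not state which variant was
  used, and the odds ratio itself is identical under both). Zero cells
  error unless the Haldane 0.5 correction is requested explicitly.
* `binomial_frequency_test()` is the exact upper tail
  $P(X \ge s)$, $X \sim \mathrm{Bin}(n, p_0)$ with the conservative null
  $p_0 = 0.25$, the estimated false-positive probability of the
  prediction rule.
* `partner_summary()` defaults to the *maximum* partner expression: each
  partner is an escape route, and the most expressed one limits the
  knockout's effect; mean and sum are alternatives.
* `spearman_sensitivity()` and `mannwhitney_groups()` are one-tailed in
  the direction the synthetic-lethality hypothesis predicts (expressed
  escape routes ⇒ higher, less sensitive scores). Mann–Whitney uses the
  exact U distribution for tie-free groups with the smaller size ≤ 12
  and the tie-corrected normal approximation otherwise; fully degenerate
  input returns p = 0.5 by convention.
* `fdr_adjust()` is Benjamini–Hochberg, the FDR method of `p.adjust`.

## What the synthetic generator emulates — and what it does not

`generate_random_model()` draws connected networks with a guaranteed
uptake→chain→biomass backbone, random internal conversions (some
reversible), and random AND/OR rule trees of bounded depth, then verifies
task feasibility by LP before returning; all randomness is fixed by the
seed. Together with the four named fixtures it exercises isozyme escapes,
complex subunits, nested rules, parallel routes and dead ends at a scale
where exhaustive enumeration is possible, so MILP-vs-oracle equality is a
meaningful check (the suite runs it on the fixtures and twenty seeded
models of 9 reactions / 6 genes; enumeration is exact at this scale, so
agreement is a correctness statement, not a statistical one).

What the generator does *not* emulate: genome-scale dimensions (thousands
of reactions; accepted structurally and stored sparse, but the bundled
dense-simplex solver is not tuned for them), realistic stoichiometric
coefficients beyond ±1, compartments, currency-metabolite coupling, and
curated GPR complexity. Passing tests therefore demonstrate algorithmic
correctness of the enumeration and verification machinery, not predictive
performance on real transcriptomes.

## Worked example

```{r example}
fig <- make_fixture("figure1_like")
res <- enumerate_gmcs(fig, genes_L = c("g4", "g5", "g9"),
                      target_gene = "g2")
res
essentiality_verdict(res, genes_L = c("g4", "g5", "g9"),
                     target_gene = "g2")
logistic_or(contingency_table(167, 141, 111, 340))
```

## Known limitations

* The bundled simplex/branch-and-bound is exact but dense; genome-scale
  enumeration within minutes requires plugging a production MILP solver
  behind the same `build_dual_milp()` interface.
* `minimal_deletion_sets()` is exponential in pathological rules; the
  term cap fails loudly rather than silently truncating.
* Essentiality verdicts inherit every weakness of the expression calls:
  a mis-threshold or unmeasured gene moves sets in or out of $L$
  directly.
* The sensitivity analyses operate on user-supplied score tables; no
  screen data is bundled or downloaded.
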