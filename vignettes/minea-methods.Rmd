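---
title: "Minimal network enrichment analysis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal network enrichment analysis: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minea)
```

## The problem

Annotation-based pathway enrichment scores a fixed gene set per pathway map.
That framing misses two properties of metabolism: the same target metabolite
can usually be synthesized by several alternative routes spanning many
annotated subsystems, and any route that actually runs must balance every
intermediate, cofactor and byproduct at steady state.  Minimal network
enrichment analysis (MiNEA) replaces the pathway map with the model itself:
for a *metabolic task* — synthesize a named target metabolite at no less
than a fraction $c$ of its maximum achievable rate — it enumerates **all**
minimum-cardinality sets of reactions that can jointly carry a mass-balanced
flux fulfilling the task, and then asks, for each such *minimal network*
(MiN), whether the genes and reactions it contains are unusually often up-
or downregulated between two conditions.

## Minimal networks

Let $S$ be the stoichiometric matrix of a genome-scale model after every
reversible reaction has been split into two irreversible forward copies, so
all fluxes satisfy $0 \le v_i \le v_{\max,i}$.  A task adds a demand
reaction consuming one unit of the target; its maximum flux $V_{\max}$ is
the LP optimum of flux balance analysis.  A minimal network solves

$$
\min_{a, v} \sum_i a_i
\quad \text{s.t.} \quad
S v = 0,\qquad
0 \le v_i \le v_{\max,i}\, a_i,\qquad
v_{\mathrm{MT}} \ge c\, V_{\max},\qquad
a_i \in \{0, 1\},
$$

with $a_{\mathrm{fwd}} + a_{\mathrm{rev}} \le 1$ for each split pair, so a
network can never "use" both directions of one reaction at once.
Minimizing the number of active reactions is the unambiguous reading of the
objective (it is equivalent to maximizing the number of reactions barred
from carrying flux), and at the optimum every active reaction carries flux:
an idle indicator could be switched off for a strictly better objective.

Alternatives at the optimal size (`msize`) are enumerated by *integer
cuts*: after each solution with active (parent-level) set $A$, the
constraint $\sum_{i \in A} a_i \le |A| - 1$ is added and the MILP is
re-solved, until the optimum exceeds `msize` (or `msize + max_rank` when
near-minimal networks are requested).  Reactions present in every
alternative are the task's high-frequency reactions (HFRs); the
intersection across all alternatives of all tasks sharing a phenotype label
gives the phenotypic HFRs.

Sizes, cuts and HFRs are all computed over parent reaction ids — split
directions collapsed — and the demand reaction is excluded from counts.
Counting split copies separately would double-charge reversible reactions
for an artifact of normalization; the demand is scaffolding, not model
content.

### Solving the MILP

No linear or integer programming backend is available to this package, so
both layers are implemented here:

* an LP kernel (`lp_solve()`): a dense two-phase primal simplex with
  per-row scaling, a Dantzig pivot rule that falls back to Bland's rule
  (provably non-cycling) after 500 iterations, and ratio-test ties broken
  toward the smallest basis index.  Dense tableaus are entirely adequate at
  the problem sizes this package targets (tens to a few hundred reactions);
* an exact branch-and-bound (`milp_branch_and_bound()`): the LP relaxation
  ($a_i \in [0,1]$) is solved at each node and branching is on the most
  fractional indicator, exploring the "on" child first.  Before the search,
  flux variability analysis under the yield floor tightens every capacity
  $v_{\max,i}$ to the largest flux reaction $i$ can actually carry;
  blocked reactions drop out entirely.  This makes the relaxation bound
  $\lceil \sum_i a_i \rceil$ sharp (in a parallel-route model the
  relaxation sets $a_i = v_i / v_{\max,i} \approx c$ on one route rather
  than smearing flux), so trees stay small.

Every returned network is verified post hoc, independently of the MILP
solution values: an LP restricted to the active set must re-derive a flux
witness meeting the yield floor, and the reported active set is re-read
from that witness.  At rank 0, cardinality minimality implies subset
minimality — removing any single reaction makes the floor infeasible — and
the test suite checks this exhaustively on small models.

### Numerical choices

| quantity | value | role |
|---|---|---|
| `vmax` | 1000 | cap replacing infinite bounds; MILP big-M before FVA tightening |
| integrality tolerance | 1e-6 | an indicator counts as integral within this |
| activity threshold | 1e-6 | witness fluxes below this are treated as zero |
| yield-floor slack | 1e-6 | tolerance when verifying witnesses |
| LP pivot tolerance | 1e-8 | reduced-cost and ratio-test threshold |
| MILP gap | 0 | optimality is exact; enumeration order is lexicographic |

Enumerated networks are reported sorted lexicographically by their active
sets, so two runs produce identical output regardless of the search path.

## Regulation of reactions

Differential-expression calls (`up`/`down` per gene) are consumed as given;
calling them is upstream of this package.  A reaction's state is derived
from the calls on its associated genes, where association is plain set
membership in the gene–protein–reaction (GPR) rule — the boolean structure
is deliberately ignored, which yields a conservative upper bound on
regulation rather than a kinetic claim:

* all called genes up → reaction **up**;
* all called genes down → reaction **down**;
* mixed calls, no called gene, or no GPR → **unregulated**.

Note the consequence: one called gene suffices to regulate a reaction whose
other genes are silent.  Under background noise this makes per-reaction
regulation rates several-fold larger than per-gene call rates, which
matters when sizing simulations (below).  The model-wide census
$(R, R_{up}, R_{down}, R_{no})$ with $R = R_{up} + R_{down} + R_{no}$ is
asserted after every assignment.  Both split directions inherit the parent
state.

## Enrichment statistics

**Gene mode.**  With $N$ genes in the model, $n$ of them deregulated (up or
down jointly), and a MiN containing $K$ genes of which $k$ are deregulated,
the p-value is the upper hypergeometric tail
$P(X \ge k) = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
computed by log-space summation (no normal approximation).  The tail — not
the density — is the p-value; the density alone is not one.  The gene
universe $N$ is all model genes, not all measured genes: calls on genes
absent from the model are set aside (and reported) rather than diluting the
test.

**Reaction modes.**  A MiN with $T$ reactions, $T_{up}$ up and $T_{down}$
down, is scored against drawing $T$ reactions without replacement from the
censused model.  An outcome at least as "up" as the observed one has at
least $T_{up}$ upregulated **and** at most $T_{down}$ downregulated
members:

$$
p_{up} = \sum_{i=T_{up}}^{\min(R_{up},\,T)} \;\sum_{j=0}^{T_{down}}
\frac{\binom{R_{up}}{i}\binom{R_{down}}{j}\binom{R_{no}}{T-i-j}}
     {\binom{R}{T}}, \qquad i + j \le T,
$$

the joint tail of a multivariate hypergeometric law; $p_{down}$ exchanges
the up and down roles.  Both are validated in the tests against an
exhaustive subset-counting oracle (exact agreement for $R \le 15$) and
against Monte-Carlo draws without replacement for larger censuses.

**Summaries.**  DRP is the deregulated fraction of a MiN's genes, $k/K$
(undefined and reported missing when $K = 0$); UPR and DnRP are
$T_{up}/T$ and $T_{down}/T$.  AMiNF is the fraction of a task's
alternatives significant in a chosen mode: 1 when every alternative is
deregulated, 0 when none is.  Raw thresholds drive AMiNF — 0.05 in gene
mode, 0.005 in the reaction modes — following the method's convention;
Benjamini–Hochberg-adjusted columns are emitted alongside for the reader
but never feed AMiNF.  When both reaction modes clear the threshold the
network is labelled by the smaller p-value, with exact ties reported as
`both`.

## The synthetic generator, and what passing tests mean

`make_parallel_gem()` builds source → backbone → target models in which
each backbone stage offers several interchangeable parallel branches of
equal length and unit stoichiometry, so the family of minimal networks is
known by construction: one branch per stage, `msize` $= 1 + \sum_s L$
($+1$ with a cofactor stage), and the alternative count is the product of
per-stage branch counts.  Decoy reactions drain backbone intermediates —
the 20% slack under the default $c = 0.8$ keeps them flux-capable, but they
never lie on a minimal route.  Cofactor-coupled stages consume a shared
ATP/ADP-style pair whose recharge reaction every alternative must then
include, exercising exactly the byproduct balancing that annotation-based
enrichment cannot represent.  Each reaction receives a private synthetic
GPR over 2–3 genes.

The generator emulates route multiplicity, cofactor coupling and planted
regulation with controllable background noise.  It does **not** emulate
realistic stoichiometric coefficients, shared isoenzymes across reactions,
correlated expression, compartmental transport chains, or genome-scale
degeneracy; agreement on these fixtures certifies the algorithms and the
statistics, not biological conclusions on any particular organism's model.

Two oracles close the loop independently of the implementation under test:
exhaustive subset search with LP feasibility checks (refused above 14
candidate reactions; $2^{14}$ subsets is the practical ceiling) for the
enumeration, and exhaustive subset counting for the reaction-mode tails.

### Sizing the planted-recovery simulation

The recovery study plants one branch of a 3-branch fixture fully up at a
background per-gene call rate of 0.05 and asks that exactly the networks
using that branch test up-significant at $\alpha = 0.005$, across 50 noise
seeds.  Because a single noise-called gene regulates its whole reaction,
each background reaction turns "up" with probability ≈ 0.05–0.07 per seed,
and the planted tail must survive the resulting census drift: with a
planted branch of length $L$ the leading term scales like
$\binom{T}{L} (R_{up}/R)^L$, so the margin grows geometrically in $L$.
Branch length 8 with 12 decoys (37 parent reactions) keeps the planted
p-value at least twofold under $\alpha$ and non-planted p-values two
orders of magnitude above it across thousands of simulated noise draws;
that geometry is fixed in the tests and in the acceptance script.  The
permutation study of the gene-mode test uses 1000 label permutations on a
three-route fixture; discreteness makes the hypergeometric test
conservative, so the observed significant fraction sits below the nominal
level.

## Problem sizes and scope

All shipped analyses run at desk scale: fixtures of 3–50 reactions,
enumeration families up to a few dozen networks, and statistics validated
on censuses up to $R = 60$.  The dense simplex kernel is comfortable to a
few hundred reactions; genome-scale models (thousands of reactions) would
need an external MILP backend plugged in beneath `lp_solve()`, and exact
reproduction of published genome-scale numbers additionally depends on the
growth-medium bounds and thermodynamic directionality assignments used
there, which are consumed here only as an optional user-supplied
directionality table.  Within those limits, results are deterministic:
identical configurations reproduce identical TSV outputs byte for byte.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `c` | 0.8 | yield floor as a fraction of the task's maximum yield; lower values admit more, larger, alternatives |
| `max_rank` | 0 | also enumerate networks up to `msize + max_rank` |
| `cap` | 10000 | safety cap per task; a truncated family flags its HFRs as subset-only |
| `alpha_gene` | 0.05 | gene-mode significance threshold feeding AMiNF |
| `alpha_rxn` | 0.005 | reaction-mode threshold feeding AMiNF |
| `fdr_threshold` | 0.05 | filter applied when a DEG table carries an `fdr` column |
| `vmax` | 1000 | flux cap for unbounded reactions (model units) |

## Worked example

```{r example}
fx <- make_parallel_gem(branches_per_stage = c(2L, 3L), branch_length = 1L,
                        n_decoys = 2L, cofactor_stages = 1L, seed = 1)
prep <- prepare_task(split_reversible(fx$model), fx$task)
aset <- enumerate_alternatives(prep$model, prep$task)
aset
calls <- plant_regulation(fx$model,
                          grep("^S2B1", fx$model$reactions$id, value = TRUE),
                          "up", background_rate = 0, seed = 1)
reg <- assign_regulation(fx$model, calls, "planted_vs_ctrl")
report <- build_report(list(aset), fx$model, reg)
report$aminf[, c("task", "mode", "alpha", "aminf")]
```
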