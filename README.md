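# minea — minimal network enrichment analysis for metabolic models

Pathway enrichment scores a fixed gene set per annotated pathway map.  That
misses two facts about metabolism: a target metabolite can usually be made
by several alternative routes cutting across many annotated subsystems, and
any route that actually runs must balance every intermediate, cofactor and
byproduct at steady state.  `minea` works on the metabolic model itself.
For a **metabolic task** — synthesize a target metabolite at a rate of at
least a fraction *c* (default 0.8) of its maximum achievable rate — it
enumerates **all alternative minimal networks** (MiNs): minimum-cardinality
reaction sets that can jointly carry a mass-balanced flux fulfilling the
task.  It then scores each MiN for deregulation between two conditions.

The enumeration solves the mixed-integer linear program

```
min  Σᵢ aᵢ      s.t.  S·v = 0,   0 ≤ vᵢ ≤ vmaxᵢ·aᵢ,   v_MT ≥ c·V_MT,max,   aᵢ ∈ {0,1}
```

(reversible reactions split into forward pairs, with `a_fwd + a_rev ≤ 1`),
re-solving under integer cuts `Σ_{i∈A} aᵢ ≤ |A|−1` until all alternatives
at the minimum size are found.  Reactions shared by every alternative are
the task's **high-frequency reactions** (HFRs).  Scoring uses

* a gene-mode upper hypergeometric tail: `k` of a MiN's `K` genes
  deregulated, against `n` of the model's `N`;
* reaction-mode joint multivariate hypergeometric tails over the census
  `(R, R_up, R_down, R_no)`: the probability that `T` reactions drawn
  without replacement contain at least `T_up` upregulated and at most
  `T_down` downregulated ones (and the down-mode mirror);
* DRP/UPR/DnRP deregulated fractions and, per task, the **AMiNF** — the
  fraction of alternatives significant at the chosen threshold (0.05 gene
  mode, 0.005 reaction modes).

A reaction counts as up (down) when the called genes in its GPR rule are
all up (all down); mixed or absent calls leave it unregulated.

Both the LP kernel (dense two-phase simplex with Bland's-rule fallback) and
the exact branch-and-bound MILP are implemented in the package, with flux
variability analysis tightening the indicator capacities; every returned
network is re-verified by an independent restricted LP.  This is built for
desk-scale models (up to a few hundred reactions); genome-scale models
would need an external MILP backend beneath the same interfaces.

## Worked example

A six-reaction model (`inst/extdata/toy_model.json`): source `EX_A`, two
parallel conversions `R_AB1` (genes g1 and g2) / `R_AB2` (g3), a reversible
`R_BC` (g4 or g5), then `R_CD` (g6) to the target `D_c`.

```r
library(minea)
m    <- load_model(system.file("extdata", "toy_model.json", package = "minea"))
prep <- prepare_task(split_reversible(m), minea_task("D_SYN", "D_c"))
aset <- enumerate_alternatives(prep$model, prep$task)
aset
#> minea_altset task 'D_SYN': msize 4, 2 alternatives, 3 HFRs (75%)
```

Two minimal networks of size 4 — `{EX_A, R_AB1, R_BC, R_CD}` and
`{EX_A, R_AB2, R_BC, R_CD}` — differing only in the parallel step, so 3 of
4 reactions are HFRs.  Score them against a differential-expression table
(g1, g2, g6 up; g3 down):

```r
calls  <- load_deg_table(system.file("extdata", "toy_deg.tsv", package = "minea"))
reg    <- assign_regulation(m, calls, "disease_vs_ctrl")
reg
#> minea_regulation 'disease_vs_ctrl': 4 gene calls; reactions: 2 up, 1 down, 3 unregulated of 6
report <- build_report(list(aset), m, reg)
report$networks[, c("network", "size", "k", "K", "T_up", "T_down",
                    "p_gene", "p_up", "p_down", "drp")]
#>   network size k K T_up T_down p_gene  p_up p_down drp
#> 1       1    4 3 5    2      0      1 0.200  1.000 0.6
#> 2       2    4 2 4    1      1      1 0.933  0.467 0.5
```

The route through `R_AB1` carries both upregulated reactions and no
downregulated one; 2 upregulated among 4 drawn from a 6-reaction census
with 2 ups is still unremarkable (p_up = 0.2, the chance tail), and at this
toy scale nothing clears the significance thresholds — which is the point
of the worked example: the statistics only sharpen when the census is much
larger than the network.  `run_minea()` drives the same steps from a
`minea_config()` (or a TOML file) and writes `minea_summary.tsv`,
`minea_networks.tsv`, `minea_aminf.tsv`, `minea_hfr_regulation.tsv` plus
one JSON document of alternatives per task; outputs are byte-reproducible.

A thin command-line wrapper ships at `inst/cli/minea.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","minea.R",package="minea"))') run --model M --tasks T --deg label=D --out DIR`,
with `enumerate`, `enrich` and `synth` subcommands).

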