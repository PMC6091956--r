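# pppRank

Cost-efficiency prioritization of threatened-species management projects in
R: an implementation of the Project Prioritization Protocol (PPP) as used
to rank large state-wide portfolios of single-species conservation
projects under a budget.

Each project — a costed, scheduled set of management actions designed to
secure one species — is scored by

```
P = B × L / C
```

where `B = P_w − P_n` is the marginal gain in the species' probability of
a viable population in 100 years (with vs without management, anchored on
IUCN categories: Vulnerable 0.9, Endangered 0.3, Critically endangered
0.05), `L = Π Iᵢ Tᵢ Sᵢ` is the product over actions of input,
threat-outcome and species-outcome success probabilities, and `C` is the
50-year net-present-value cost (1% p.a. discount) of all actions, with
costs of co-located same-year actions shared between projects
proportionally to their proposals.

The package provides:

* the two-table (species × actions) data model with validation and a
  paired-CSV reader/writer (`ProjectPortfolio`, `readDataset`);
* scoring: `computeBenefit`, `computeLikelihood`, `discountCost`,
  `projectCosts`, `priorityScore`, `prioritize`;
* cost sharing: `findSharedGroups`, `apportion`, `dissolveMember`;
* budget-constrained iterative selection with dynamic dissolution of cost
  sharing (`selectUnderBudget`) and the cumulative-cost ROI curve
  (`roiCurve`);
* Monte Carlo propagation of elicitation uncertainty through triangular
  distributions into 95% rank likelihood intervals and five priority
  bands (`monteCarloRanks`, `assignBands`), per-parameter sensitivity
  (`sensitivityAnalysis`) and portfolio summaries (`summaryStatistics`);
* a calibrated synthetic portfolio generator emulating a 368-project
  state-wide program (`generatePortfolio`), plus a tiny hand-checked
  fixture (`workedFixture`).

See the vignette (`vignettes/ppp-methods.Rmd`) for the model, the
parameter choices and the design notes.

## Worked example

```r
library(pppRank)

pf <- workedFixture()        # 5 hand-built projects, one cost-sharing pair
prioritize(pf)
#>   project_id benefit likelihood        cost        score rank
#> 5         F5    0.90   0.125000    970.6862 1.158974e-04    1
#> 1         F1    0.90   0.729000  19598.0588 3.347781e-05    2
#> 2         F2    0.65   0.498636  38540.6678 8.409647e-06    3
#> 3         F3    0.05   1.000000  19598.0588 2.551273e-06    4
#> 4         F4    0.50   0.504000 391961.1753 6.429208e-07    5
```

F5 ranks first despite a coin-flip likelihood because it is two orders of
magnitude cheaper than anything else; F1 and F2 each pay half of their
shared 1000/yr weed-control action (F1's cost is `500 × 39.196`, the
50-year annuity factor at 1%); F4 ranks last: a large stale-site project
whose benefit per dollar is lowest.

```r
sim <- monteCarloRanks(pf, simulationConfig(nSims = 10500, seed = 1))
rankIntervals(sim)[, c("project_id", "rank", "rank_lo", "rank_hi", "band")]
```

gives each project's 95% rank likelihood interval (2.5/97.5 percentiles of
its simulated ranks) and its priority band (1 = highest priority).

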