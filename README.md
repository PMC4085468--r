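# lineagetracer

Cell lineage tracing from per-frame 3-D nuclear detections, for developmental
imaging of the kind produced by *in toto* fluorescence microscopy of
nuclear-labeled embryos (hundreds of cells, hundreds of frames, multiple
rounds of division).  The package consumes detection tables — one centroid,
radius and intensity per nuclear object per frame — and produces the binary
forest of cell identities over time, correcting detection errors along the
way.  It also ships a synthetic dividing-embryo simulator with ground truth
and a full evaluation module, so every stage is testable without microscopy
data.

## The method

Tracking is layered, spending effort only where the data are ambiguous:

1. **Conservative nearest-neighbor linking.**  A 1:1 link `c(t) → c(t+1)` is
   accepted only when the displacement is *safe*,

       dist(c, NN(c, t+1))  <  ½ · dist(c, NN(c, t)),

   the two detections are *mutual* nearest neighbors, and no third detection
   *conflicts* by claiming either endpoint as its NN.  During interphase this
   covers nearly all links with a negligible error rate.
2. **Tentative bifurcations.**  Every detection left without a backward link
   (orphan) is forced into a 1-to-2 match with a nearby parent.  The
   bifurcation plus a nearby terminating track (dangling end) and the
   minimal-displacement matching of their endpoints form a *semi-local
   neighborhood*.
3. **Naive Bayes classification** of each neighborhood into `division`,
   `two_cell` (movement / missed detection pair), `fp` (spurious detection)
   or `other`, via `P(class | M) ∝ P(class) ∏ P(mⱼ | class)` over 12
   morphological and kinematic features with per-class Gaussian densities.
4. **Class-specific repair**: accept the division; rewire to the 1:1 chains
   and fill detection gaps by linear interpolation; delete the spurious
   branch; or reattach the worse-matching child to its next-best parent,
   flagging it an unexplained appearance when candidates run out.

See `vignettes/methods.Rmd` for the model, parameter rationale, and design
notes.

## Worked example

```r
library(lineagetracer)

cfg   <- tracking_config()                      # all defaults documented
model <- train_model(n_per_class = 500, seed = 100)   # simulator-trained NB

# a 1 -> 64 cell embryo over 120 frames with 1% FN and 1% FP detection errors
sim <- simulate_dataset(sim_config(rng_seed = 7, fn_rate = 0.01, fp_rate = 0.01))
res <- trace_lineage(sim$observed$det, model, cfg)

instantaneous_accuracy(res$lineage, sim$truth)
division_scores(res$lineage, sim$truth)
table(res$log$class, res$log$action)
```

Output (what the tracker did with the injected errors):

```
instantaneous accuracy: 0.9964
division PPV 1.000 sensitivity 0.948 (55/55 predicted, 58 real)

           accept_division delete_fp reassign rematch rewire_interpolate unexplained
  division             110         0        0       0                  0           0
  fp                     0        15        0       0                  0           0
  none                   0         0        0       0                  0           3
  other                  0         0       14       0                  0           0
  two_cell               0         0        0      42                 11           0

deleted: 24  interpolated: 11  unexplained: 3
```

Reading this: 99.64% of cell-frames have a correct backward history step.
All 55 predicted divisions are real (PPV 1.0); 3 of 58 real divisions were
lost to compound errors (a daughter missing in its birth frame).  The 15
`fp` bifurcations led to 24 spurious detections deleted; the 11
`rewire_interpolate` actions each filled a detection gap with an
interpolated nucleus at the exact linear midpoint; 3 orphans exhausted
their candidates and were honestly flagged rather than force-linked.  On an
error-free embryo the same pipeline is exact (accuracy, PPV and sensitivity
all 1.0 — asserted by the test suite).

`export_newick(res$lineage, 1)` renders the tree for any phylogenetics tool:

```
((((((n1226:4,n1227:4)n633:18,(n1379:1,n1380:1)n634:21)n299: ...
```

## Command line

```
Rscript -e 'lineagetracer::lt_cli()' simulate --out simdir --seed 33
Rscript -e 'lineagetracer::lt_cli()' train    --neighborhoods nbh.csv --out model.json
Rscript -e 'lineagetracer::lt_cli()' trace    --detections det.csv --config cfg.json \
                                              --model model.json --out outdir
Rscript -e 'lineagetracer::lt_cli()' evaluate --pred outdir/lineage.csv \
                                              --truth simdir/truth_lineage.csv --out report.json
```

(the same entry points are installed as `exec/lineagetracer`).

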