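# paintrial

Endpoint and statistical analysis machinery for randomized acute-pain
trials scored with time-weighted composite endpoints — the design used in
phase 3 studies of postoperative analgesics delivered by
patient-controlled analgesia (PCA), where four arms (placebo, two doses of
an investigational drug, an active comparator such as morphine) are
compared on cumulative pain reduction over 24 hours.

The package is aimed at trial statisticians and methods researchers who
need the full pipeline — scoring, imputation, gatekept testing, rescue
outcomes, design calculations — as tested, reusable code, together with a
synthetic-trial simulator so that every stage can be exercised and
validated without patient data.

## The endpoints and analysis

Pain intensity (PI) is assessed on the 0–10 numerical rating scale and
pain relief (PR) on a 0–4 Likert scale, on a fixed post-dose grid
(baseline, end of the loading infusion at 10 min, then 20 min … 24 h). The
primary endpoint is the **summed pain intensity difference**,

SPID_t = Σ PID_t · (TIME_t − TIME_{t−1}),  PID_t = PI_t − PI_0,

with the sum over grid points in (0, t]; total pain relief is
TOTPAR_t = Σ PR_t · (TIME_t − TIME_{t−1}). On the protocol grid the
weights sum to exactly 24 h, so SPID_24 ranges over [−240, 240] and
TOTPAR_24 over [0, 96]. All interval weights are carried as exact integer
minutes, so these identities — and the decomposition
SPID_24 = SPID_12 + SPID_{12–24} — hold exactly, not just to rounding.

Missing scores are imputed by the standard clinical rules, in precedence
order: scores missing inside a post-rescue window (6 h after parecoxib,
2 h after sufentanil) carry back the last pre-rescue observation; missing
night-sleep PI is set to NRS 3 (missing night PR takes the previous PR);
everything else is last observation carried forward. A sensitivity mode
disables the rescue rule entirely.

The primary comparisons use a **fixed-sequence gatekeeping** procedure:
the high dose is tested against placebo by a pooled-variance group t test
at two-sided α = 0.05, and the low dose is tested confirmatorily only if
the first test rejects — this controls the familywise type-I error at α
without adjusting the p values. Rescue-medication outcomes come with
exact Clopper–Pearson intervals, Fisher's exact tests, Kaplan–Meier time
to first rescue with log-rank tests, and zero-filled consumption
summaries. Design functions reproduce the z-approximation sample-size
formula n = ⌈(z_{1−α/2} + z_{1−β})²(σ₁² + σ₀²)/δ²⌉ with dropout inflation.

## Worked example

```r
library(paintrial)

ds  <- simulate_trial(simulation_config(n_per_arm = 132), seed = 7)
fit <- analyze_trial(ds)
fit
```

```
Acute-pain trial analysis (FAS population, imputation mode primary)

Primary endpoint, fixed-sequence gatekeeping at alpha 0.05:
spid_24, tegileridine_1_0 vs placebo [confirmatory]
  difference -18.76 (SE 3.02), 95% CI (-24.70 to -12.82), p <0.001
spid_24, tegileridine_0_75 vs placebo [confirmatory]
  difference -11.06 (SE 2.83), 95% CI (-16.62 to -5.49), p <0.001

No-rescue proportions:
  placebo             50/132 =  37.9% (95% CI, 29.6-46.7)
  tegileridine_0_75   75/132 =  56.8% (95% CI, 47.9-65.4)  p = 0.003
  tegileridine_1_0    80/132 =  60.6% (95% CI, 51.7-69.0)  p <0.001
  morphine            76/132 =  57.6% (95% CI, 48.7-66.1)  p = 0.002
```

The first block is the gatekept primary analysis: the high dose rejects
at α = 0.05, which opens the gate, so the low-dose comparison is also
confirmatory; the differences are mean SPID_24 contrasts in NRS-hours
(negative = greater cumulative pain reduction than placebo) with pooled
standard errors and t-based intervals. The second block gives each arm's
proportion of participants needing no rescue medication over (0, 24], its
exact binomial interval, and Fisher's exact p against placebo.

`summary(fit)` renders the publication-style endpoint table (arm mean
(SD), difference with placebo (SE), CI and p for all SPID/TOTPAR
horizons), `plot(fit)` draws the Kaplan–Meier rescue-free curves, and
`compute_endpoint_panel(ds)` exposes the per-participant endpoint panel.
The design numbers print via:

```r
design_summary()
```

```
Two-group design (z approximation)
  assumed means 88.0 vs 70.0, SDs 45.0 / 40.0
  two-sided alpha 0.050, target power 0.90
  evaluable n per group: 118 (achieved power 0.901)
  planned n per group after 10% dropout: 132
  planned total over 4 arms: 528
```

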