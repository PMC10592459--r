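# boutkin

Swim bout segmentation and balance kinematics for vertical locomotion
assays.

Larval zebrafish keep their balance actively: they are front-heavy, tip
in the pitch (nose-up/nose-down) axis, and correct themselves with
discrete swim bouts. High-throughput videographic rigs record a freely
swimming animal at 166 Hz and reduce each frame to a body centroid, a
head centroid, and a pitch angle. `boutkin` turns those per-frame streams
into the four quantitative signatures of balance and vertical
navigation, and tells you how much data you need to resolve a change in
any of them. It is written for labs running (or building) such rigs:
screen analysts comparing genotypes or treatments, and methods people who
want every threshold of the pipeline explicit and testable.

## What it computes

From a raw per-frame stream, the package segments **epochs** (contiguous
single-animal detection), **swim bouts** (speed > 5 mm/s, aligned in a
134-frame window around peak speed), and **inter-bout intervals** (the
sub-threshold gaps, shortened by a 100 ms buffer at each end). Per-bout
features feed four models:

| model | relation | headline parameter |
|---|---|---|
| bout timing | bout frequency vs IBI pitch: `y = a(x-b)^2 + c` | sensitivity `a` (Hz/deg^2) |
| steering | pitch at peak speed vs trajectory (linear) | steering gain (slope) |
| fin-body | attack angle vs body rotation: `y = a + h/(1+e^{-k(x+b)})` | fin-body ratio `kh/4` |
| righting | righting rotation vs initial pitch (linear) | righting gain (abs slope), set point (x-intercept) |

Here *trajectory* is the direction of travel at peak speed (climbing
positive), *attack angle* = trajectory − pitch (the fin-generated lift of
a climb), and the rotation decomposition satisfies steering = body +
residual exactly. A resampling module maps confidence-interval width
against sample size and simulates Cohen's *d* for imposed fractional
offsets on any of the four parameters — the power analysis behind "how
many bouts do I need to see a 5 % change?". A detection module
re-implements the real-time single-animal detector (background
subtraction, blob analysis, body/head split, orientation), and a
synthetic-data generator produces `.dlm` streams with fully known ground
truth so the whole chain is testable offline. Details and rationale live
in `vignettes/boutkin-methods.Rmd`.

## Worked example

Simulate a small two-repeat experiment, run the pipeline, and fit the
models:

```r
library(boutkin)

cfg <- analysis_config()                 # every threshold, documented
gp  <- generator_params()                # ground truth: gain 0.7, ratio 0.8,
                                         # righting 0.18 @ 12 deg, a = 0.003
ds  <- generate_dataset(gp, n_repeats = 2, bouts_per_repeat = 800, seed = 42)
an  <- analyze_dataset(ds$traces, ds$meta, cfg)
an
#> <analysis> 1629 bouts, 1583 IBIs over 2 repeat(s); t_maxAngVel -42.2 ms
fit_models(an, cfg)
#> <timing fit> sensitivity a = 0.0030153 Hz/deg^2 (SE 2.1e-05), baseline posture b = 10.1 deg, base rate c = 1.01 Hz, R^2 = 0.938, n = 1583 IBIs
#> <steering fit> gain = 0.697 (SE 0.0015), intercept = -10.9 deg, r = 0.996, R^2 = 0.992, n = 1629 bouts
#> <fin-body fit> ratio kh/4 = 0.902 (SE 1.3), k = 0.188 /deg, h = 19.2 deg, R^2 = 0.230, n = 1543 bouts
#> <righting fit> gain = 0.180 (slope -0.180, SE 0.0032), set point = 11.4 deg, R^2 = 0.666, n = 1629 bouts
```

Every fitted parameter lands on its generator value: the timing
sensitivity within 1 % of 0.003, the steering gain within half a percent
of 0.7, the righting gain and set point on 0.18 and 12°, and the
fin-body ratio — the hardest parameter, a 4-coefficient sigmoid — within
13 % of 0.8 at this deliberately small sample (it tightens to a few
percent at 10,000 bouts). How fast precision grows with data:

```r
steer <- resolution_dataset(an$features, NULL, "steering", cfg)
ci_width_curve(steer, "steering", Ns = c(400, 1600), config = cfg, seed = 1)
#> <CI width curve> steering, level 0.95
#>     N mean_width     sd_width
#>   400 0.01221696 0.0007888296
#>  1600 0.00588392 0.0002234516
```

Quadrupling the bout count halves the CI width, the expected 1/sqrt(N)
shrinkage.

For real recordings, replace the simulated traces with
`analyze_dlm(c("repeat1.dlm", ...), "metadata.txt", cfg)`; the same
functions apply. A thin command-line wrapper is installed at
`exec/boutkin` (`boutkin analyze`, `boutkin simulate`, `boutkin power`)
for shell pipelines.

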