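# taskfmriqc

Quality control for task-based fMRI, for researchers screening runs before
analysis. Task fMRI has two failure surfaces that routine pipelines rarely
report together: the imaging side (head motion, failed acquisition or
preprocessing) and the task side (trials not presented, participants not
performing the task). `taskfmriqc` implements a four-criterion screen over
both, from standard BIDS artifacts, and assembles the evidence into concise
reports plus a machine-readable decision record.

## The four criteria

For each run, exclude it if:

| | Criterion | Type | Rule |
|---|---|---|---|
| A | Excessive motion | quantitative | 20% or more of the frames have framewise displacement (FD) > 0.9 mm |
| B | Improper task presentation | quantitative | fewer than half of the expected trials have usable data |
| C | Invalid task performance | quantitative + qualitative | no response for 5 or more trials in a row, or more than 40% of all trials; single-button or repetitive responding is flagged for review |
| D | Failed acquisition / preprocessing | qualitative | temporal mean, sd and tSNR maps look wrong; decided by a human, recorded as an override |

FD is the Power-style summary of frame-to-frame head movement:

    FD_t = Σᵢ |Δdᵢ,t| + r · Σᵢ |Δθᵢ,t|

the sum of absolute backward differences of the three translations (mm)
plus the three rotations converted to arc length on a sphere of radius
r = 50 mm. Frames with FD > 0.9 mm are censored (strict: exactly 0.9 is
kept); a run with a censored fraction ≥ 0.20 fails criterion A. tSNR is
the per-voxel temporal mean divided by the temporal standard deviation
(sample, n−1 denominator), computed over the entire run without censoring.

Criterion D is deliberately not automated: the package computes the
summary volumes, slice montages, and an acquisition-metadata consistency
check (e.g. a run whose `PhaseEncodingDirection` deviates from the dataset
majority), then requires a recorded human override with a note before a
run can fail on it.

## Worked example

Everything is testable without real data: the synthetic module generates
events tables, motion traces and 4D ellipsoid phantoms with planted ground
truth.

```r
library(taskfmriqc)

# a 64-trial run with a planted 5-trial no-response block
spec <- synth_spec(seed = 42,
                   missing_pattern = list(kind = "block", k = 5, start_index = 30))
ev <- synth_events(spec, run_id = "sub-001")
evaluate_behavior(ev, expected_by_type = c(CONTROL = 32, TASK = 32))
#> <behavior_result> run 'sub-001': 64 trials, 59 responses (LEFT=21, RIGHT=38)
#>   no-response: 5 (7.8%), longest streak 5; accuracy 0.95
#>   flags: criterion_c_exclude

# motion with one planted 1.3 mm spike at frame 120
mot <- synth_motion(synth_spec(seed = 42, n_frames = 280,
                               spikes = list(list(frame = 120, magnitude_mm = 1.3))),
                    run_id = "sub-001")
censor_frames(mot)
#> <censor_result> run 'sub-001': 1/280 frames censored (0.4%, FD > 0.9 mm) -> keep run

# a phantom built for tSNR 50 recovers it
img <- synth_bold(synth_spec(seed = 42, n_frames = 200), run_id = "sub-001")
s <- temporal_summaries(img)
s
#> <volume_summaries> run 'sub-001': 16x16x10 voxels over 200 frames; 1960 zero-sd voxel(s)
median(s$tsnr_vol[attr(img, "brain_mask")])
#> [1] 50.0
```

The first run fails criterion C: the 5-trial no-response streak meets the
"five or more in a row" rule even though only 7.8% of trials lack a
response. The second keeps its run — one censored frame out of 280 is far
below the 20% exclusion fraction. The phantom's recovered median in-brain
tSNR (50.0) matches its construction target; the 1960 zero-sd voxels are
the empty background outside the ellipsoid, reported rather than hidden.

`run_qc()` orchestrates the whole screen over a list of runs and writes two
HTML reports (motion/images and behavior) plus `qc_decisions.json`. A thin
command-line wrapper lives at `inst/cli/taskfmri-qc.R`:

```sh
Rscript inst/cli/taskfmri-qc.R synth --out demo_bids --n-runs 3
Rscript inst/cli/taskfmri-qc.R run --bids-dir demo_bids --out qc_out \
    --expected-counts '{"CONTROL":32,"TASK":32}'
```

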