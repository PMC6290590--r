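# wristshapes

Feature derivation from raw wrist accelerometer data for physical-activity
(PA) assessment: identifying what someone is doing (sedentary vs.
non-sedentary, locomotion vs. stationary, and the specific activity type)
and estimating the energy cost of doing it, in metabolic equivalents
(MET), from a wrist-worn triaxial accelerometer sampled at 30–100 Hz.

Machine-learning models for these tasks consume feature vectors computed
over 15-s epochs of the vector magnitude
`VM = sqrt(x^2 + y^2 + z^2)`. The package implements three feature
families over one signal core:

1. **Standard statistical wrist features** — the seven classic variables
   per epoch: mean and SD of VM (`MVM`, `SDVM`), mean and SD of the arm
   angle `(180/π)·asin(x/VM)` (`MANGLE`, `SDANGLE`), the dominant
   frequency `DF` of the epoch's FFT, its fraction of power `FPDF`, and
   the fraction of power in the 0.6–2.5 Hz human-movement band (`P625`).
2. **Bag-of-words shape features (unsupervised)** — k-second sliding
   subsequences of the low-pass-filtered VM are clustered (k-means) into
   a codebook of `d` representative patterns ("atoms"); each subsequence
   of a document is replaced by its nearest atom under banded dynamic
   time warping (DTW), and the resulting word counts `h` are weighted by
   augmented term frequency `tf(i) = 0.5 + 0.5·h(i)/max_j h(j)` times
   inverse document frequency `idf(i) = log(n / Σ_h h(i))` fitted on
   training documents.
3. **Supervised shape features (motif mining)** — per participant and
   activity, each subsequence gets a *distance score*: its minimum DTW
   distance to any non-overlapping later subsequence. Low scores mark
   recurring motifs; the lowest-scoring, mutually non-overlapping
   subsequences (a fraction `beta` of the pool) form initial codebooks,
   which are merged by average-linkage hierarchical clustering on the
   DTW matrix into a final codebook of *medoids*. Epoch features are
   mean DTW distances to each final atom over 50%-overlapping windows.

Downstream, random forests classify epochs (with per-activity majority
voting) and regress MET on per-activity mean feature vectors, optionally
augmented with the predicted category flags and one-hot predicted
activity types. A seeded synthetic cohort generator emulates a
laboratory study (sedentary / locomotion / household activity templates
with per-participant pace and strength variation, plus MET ground truth)
so the whole pipeline is testable without any data download. The DTW
kernel (Sakoe-Chiba band, absolute local cost, exact LB_Keogh/early-
abandoning fast paths) is implemented in C++.

See `vignettes/shape-features.Rmd` for the full model description,
parameter meanings, and numerical choices.

## Worked example

```r
library(wristshapes)

# a small synthetic cohort: 6 participants x 9 activities, 2 min each
co <- generate_cohort(cohort_config(n_participants = 6, duration_s = 120,
                                    sampling_rate = 30, seed = 42))
co$recordings[["P001/rapid_walk"]]
#> <triaxial_recording> P001 / rapid_walk: 3600 samples @ 30 Hz (120.0 s), MET 4.81618

head(standard_features(co$recordings[["P001/rapid_walk"]]), 3)
#>   participant_id activity_id epoch_start   MVM  SDVM  MANGLE SDANGLE  P625  DF  FPDF
#> 1           P001  rapid_walk           0 1.004 0.254 -40.980   1.234 0.929 2.4 0.590
#> 2           P001  rapid_walk          15 0.999 0.254 -40.936   1.269 0.926 2.4 0.592
#> 3           P001  rapid_walk          30 0.999 0.254 -40.998   1.192 0.939 2.4 0.605
```

Each row is one 15-s epoch: this participant walks with a cadence around
2.4 Hz (`DF`), with ~93% of spectral power inside the movement band
(`P625`) and the wrist held at about −41° (`MANGLE`) — exactly the
signature the rapid-walk template plants.

The bag-of-words weighting on the worked four-word example: a document
whose four subsequences are nearest atoms 1, 2, 3, 3 has `h = (1,1,2,0)`,
and the augmented term frequency is

```r
term_frequency(c(1, 1, 2, 0))
#> [1] 0.75 0.75 1.00 0.50
```

The full pipeline — features, classifiers, voting, metrics, and MET
regression at three augmentation levels — in one call:

```r
r <- evaluate_pipeline(co, "standard", run_config(n_test = 2), seed = 1)
r
#> <pa_report> method = standard, seed = 1
#>   train 4 / test 2 participants
#>   sedentary:  <metrics> accuracy 1.000 | sensitivity 1.000 | precision 1.000 | F1 1.000 (positive: sedentary)
#>   locomotion: <metrics> accuracy 1.000 | sensitivity 1.000 | precision 1.000 | F1 1.000 (positive: locomotion)
#>   EE [none]: <ee_report> rMSE 0.5023 MET | adjusted R2 0.8657 (n = 18, p = 7)
#>   EE [sedloc]: <ee_report> rMSE 0.4843 MET | adjusted R2 0.8439 (n = 18, p = 9)
#>   EE [sedloc_type]: <ee_report> rMSE 0.4369 MET | adjusted R2 0.4920 (n = 18, p = 15)
```

On this toy cohort the held-out sedentary and locomotion identification
is perfect and the MET error sits near the generator's 0.3-MET noise
floor (the gap is finite-sample slack: only 4 training participants
here); `method = "bow"` and `method = "ssf"` run the two shape-feature
routes on the same interface.

A thin command-line interface wraps the same functions:

```sh
exec/wristshapes synth --out cohort/ --n-participants 6 --duration 120 --rate 30 --seed 42
exec/wristshapes features --method standard --input cohort/P001_rapid_walk.csv --rate 30 --out feats.csv
exec/wristshapes codebook learn-bow --input cohort/metadata.csv --d 32 --k 3 --seed 1 --out cb.json
exec/wristshapes assess --metadata cohort/metadata.csv --method bow --seed 1 --out report.json
```

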