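# mackin — kinetics of MAC pore assembly from time-lapse AFM movies

The membrane attack complex (MAC) is the pore the complement system
drills into target membranes: a C5b-8 complex recruits 18 copies of C9
that oligomerize into an ~11 nm transmembrane pore. In time-lapse atomic
force microscopy (AFM) movies of a supported bilayer, pores appear as
growing annular features, and two very different timescales are visible:
pores *appear* slowly over an hour, but each individual pore *completes*
within seconds to minutes.

`mackin` is an analysis pipeline for such movies. It measures both
timescales and converts them into the rate constants of a two-step
kinetic model, treating initiation and propagation as separate reactions
under constant C9 excess:

* appearance curve: the per-frame pore count is fitted with
  N(t) = A (1 − exp(−t/τ_init)), and k_init ≈ 1/(τ_init [C9]);
* oligomerization: each pore's average-height trace is fitted with the
  sigmoid f(t) = A tanh((t − t0)/τ) + B, whose width 3τ (≈ 90% of the
  transition) is the oligomerization time τ_olig; the time per C9
  addition is τ_+ = τ_olig/17 and k_+ ≈ 1/(τ_+ [C9]);
* occupancy model: the probability p_n(t) that a growing pore holds n of
  18 subunits follows a linear birth chain with absorbing completed
  state, solved numerically and cross-checked against its Poisson closed
  form and stochastic simulation.

Because no instrument data are deposited, the package includes a
synthetic AFM movie generator with known ground truth (exponential
initiation, sequential C9 additions, annular arc rendering, membrane
noise), and the whole pipeline is validated by parameter recovery on
those movies. Pipeline stages: plane levelling / line flattening /
Gaussian smoothing → normalized cross-correlation detection (threshold
0.6) → greedy track linking with gap closing → per-track crops, height
traces and sigmoid fits → kinetic parameter estimation.

## Worked example

The `analysis/` scripts run the full study on a synthetic movie generated
at the study conditions (50 C5b-8 complexes in a 512 × 512 nm field,
[C9] = 1.4e-3 mM, k_init = 0.78 and k_+ = 108 s⁻¹ mM⁻¹, 6.5 s/frame for
3250 s, 0.3 nm noise):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_track.R
Rscript analysis/03_fit_traces.R
Rscript analysis/04_kinetics.R
```

which prints (seed 1):

```
Simulated 50 complexes; 49 initiate within the 501-frame movie.
18600 detections over 501 frames -> 55 tracks (49 curated).
40 / 49 tracks pass QC; tau_olig = 118 +/- 10 s (mean +/- sem, sd 64 s).
MAC assembly kinetics ([C9] = 0.0014 mM)
  tau_init = 869 s   -> k_init = 0.82 s^-1 mM^-1
  tau_olig = 118 s over 17 additions -> tau_+ = 6.9 s
  k_+ = 103 s^-1 mM^-1   (tau_init / tau_+ = 125)
Recovery vs generating rates: k_init 0.82 (gen 0.78, +5%), k_+ 103 (gen 108, -5%).
```

Reading the output: the appearance fit recovers the initiation time
(869 s estimated vs 916 s generating), the mean sigmoid transition width
recovers the oligomerization time (118 s vs the 112 s implied by the
generating k_+), and both rate constants come back within ~5% of the
values used to generate the movie. The two-orders-of-magnitude ratio
τ_init/τ_+ ≈ 125 is the signature that the *first* C9 insertion is the
rate-limiting step of MAC assembly.

The same chain is available in one call:

```r
library(mackin)
report <- run_pipeline(config = pipeline_config())
report$kinetics
```

See `vignettes/mac-assembly-kinetics.Rmd` for the model, the numerical
choices, and what validation on synthetic movies does and does not show.

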