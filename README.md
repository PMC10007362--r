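# edanet

Synthetic electrodermal activity (EDA) and fully convolutional stress
classification, in R.

Skin conductance is one of the few physiological signals a comfortable
wearable can record continuously, and its phasic peaks — skin conductance
responses (SCRs) — track sympathetic arousal.  The practical task `edanet`
addresses is labeling two-minute conductance windows as **neutral**
(relaxed) or **active** (stressed/aroused), for settings such as assisting
caregivers of non-verbal autistic people, where an imminent stress episode
should be flagged early.  Real labeled EDA corpora are tiny, so the package
takes a simulation-first approach: it generates unlimited, perfectly
annotated synthetic conductance, trains a deep classifier purely on the
simulation, and applies it to windowed real recordings.

## The model

A conductance window sampled at rate $f_s$ is simulated as

$$ y(n) = (h * x)(n) + b(n) + v(n) $$

* $x(n)$ — sparse spike train; the peak count per minute is
  discrete-uniform on {1..5} for neutral windows, {6..20} for active ones;
* $h(n)$ — Bateman SCR kernel $g\,(e^{-t/\tau_1} - e^{-t/\tau_2})$, with
  $\tau_1 \sim U(1, 40)$ s and $\tau_2 \sim U(0.2, 1)$ s redrawn for
  every peak, normalized to unit maximum so each spike's amplitude
  ($U(0.1, 1)$ μS) is its SCR peak height;
* $b(n)$ — slowly varying tonic baseline (level 2–10 μS plus bounded
  drift);
* $v(n)$ — white Gaussian noise (σ = 0.05 μS).

The classifier is a 1D fully convolutional network: three blocks of
same-padded width-3 convolution (64 filters) + batch normalization + ReLU,
global average pooling over time, and a dense softmax — 25,858 parameters,
trained with Adam on sparse categorical cross-entropy.  An autoencoder
baseline module demonstrates why reconstruction-error anomaly detection
fails for this signal (the neutral and active MAE distributions overlap),
which is what motivates training a discriminative network on simulated
data for both classes.

## Worked example

```r
library(edanet)

cfg <- eda_sim_config()                       # 5 Hz, 600 samples, defaults
ds   <- generate_eda_dataset(2000, cfg, seed = 11)
fit  <- fcn_train(ds, epochs = 8, seed = 1)   # 80/20 split, Adam, z-scored
test <- generate_eda_dataset(500, cfg, seed = 99)
evaluate_classifier(test$labels, predict(fit, test))
```

```
Binary EDA evaluation on 500 sequences
         predicted
true      neutral active
  neutral     229     21
  active       11    239
accuracy  0.9360
precision 0.9192 (positive = active)
recall    0.9560
```

At this small scale the network already recovers the peak-rate signal:
93.6% of independently simulated windows are labeled correctly, precision
and recall are computed with *active* as the positive class, and most
errors are neutral windows misread as active.  Training on 10,000 windows
(the desk-scale study condition) brings independent-test accuracy to about
97%;
the ground-truth peak-rate oracle (`spike_counts` thresholded at 5.5/min)
is 100% by construction and bounds what any classifier can learn.

Long recordings are windowed before inference:

```r
rec <- load_recording_csv("subject01.csv", sampling_rate_hz = 5, label = 1)
windows <- segment_recordings(list(rec), 600, 300)  # 50% overlap
predict(fit, windows)
```

A command-line front end wraps the same pipeline
(`Rscript $(Rscript -e 'cat(system.file("cli/edanet.R", package="edanet"))') simulate --n 100 --seed 7 --out ds`),
with subcommands `simulate`, `segment`, `train`, `evaluate` and `ae-demo`.

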