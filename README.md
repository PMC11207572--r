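# vepdecode

Multiclass decoding of visually evoked EEG with a reduced electrode
montage: mutual-information-based discriminant channel selection, an
evoked-response enhancement chain, and two compact deep classifiers,
evaluated under k-fold and leave-one-subject-out protocols.

## The problem

Decoding which of 40 stimulus categories a subject viewed from
single 440 ms EEG segments is a demanding multiclass problem, and
embedded brain-computer interfaces cannot afford to stream all 128
channels of a research montage. The pipeline implemented here tackles
both constraints at once:

1. **Channel selection.** For channels $i, j$ with discretized
   amplitude distributions, mutual information is evaluated as the
   Kullback-Leibler divergence between the joint distribution and the
   product of marginals,
   $I(M_i; M_j) = \mathrm{KLD}\big(P(M_i, M_j)\,\|\,P(M_i)P(M_j)\big)$,
   with $I = 0$ for independent channels and $I = H(M_i)$ for fully
   dependent ones. A greedy procedure seeds the subset with the
   maximal pair and grows it one most-informative channel at a time,
   typically down to a 54-channel discriminant montage.
2. **Enhancement.** Bad-channel repair, robust (median/MAD) artifact
   span rejection, per-channel standardization
   ($\mu_n = \frac{1}{N}\sum_i x_i$,
   $\sigma_n^2 = \frac{1}{N-1}\sum_i (x_i - \mu_n)^2$, fitted on
   training folds only), epoching into nine canonical post-stimulus
   windows, and evoked averaging.
3. **Classification.** A compact temporal/depthwise/separable
   convolutional network (54,632 parameters) and a hybrid
   1-D CNN + LSTM (107,278 parameters), trained with categorical
   cross-entropy, the Nadam optimizer and a triangular cyclical
   learning rate ($10^{-7}$ to $10^{-3}$, half-period 8 epochs of
   iterations, batch 440). The training engine is built into the
   package (BLAS matrix products plus a few compiled kernels) and its
   gradients are finite-difference-verified in the test suite.

The real 6-subject, 11,964-segment corpus is an external resource;
the package ships a synthetic generator that emulates its structure
(per-subject counts, 40 balanced classes, 128 named channels,
class-dependent evoked templates in an informative channel subset,
1/f background, 50 Hz line residue, artifacts, bad channels) with
full ground truth, so every stage is testable offline.

## Worked example

```r
library(vepdecode)

cfg <- synth_config(n_subjects = 2, per_subject_counts = c(60, 60),
                    subject_order = 1:2, n_classes = 5, n_channels = 8,
                    n_samples = 440, channel_names = paste0("CH", 1:8),
                    informative_channels = paste0("CH", 1:3), seed = 42)
gen <- generate_dataset(cfg)
gen$dataset
#> <segment_set> 120 segments x 8 channels x 440 samples @ 1000 Hz
#>   classes: 5; subjects: 1 2

m <- pairwise_mutin_matrix(gen$dataset, n_bins = 32)
round(m[1:4, 1:4], 3)
#>       CH1   CH2   CH3   CH4
#> CH1 2.807 0.233 0.227 0.012
#> CH2 0.233 2.858 0.206 0.011
#> CH3 0.227 0.206 2.812 0.011
#> CH4 0.012 0.011 0.011 2.827

select_channels(m, 3)
#> <selection_result> 3 channels (sum aggregation)
#>   CH1 CH2 CH3
```

The matrix diagonal holds each channel's self-entropy (~2.8 nats
here); the three informative channels share ~0.2 nats pairwise while
background channels share ~0.01 nats, and greedy selection recovers
exactly the planted subset. Training the compact convolutional model
on the late 360-440 ms window of the same toy corpus:

```r
rep <- evaluate_protocol(gen$dataset, "eegnet", window = "360:440",
                         scheme = "kfold",
                         cfg = train_config(epochs = 15, batch_size = 60,
                                            seed = 1), k = 2)
rep
#> <eval_report> eegnet, kfold, window 360:440
#>   per-split accuracy [%]: 50.0 45.0
#>   mean accuracy: 47.5%
```

47.5% on 5 classes (chance 20%) after 15 epochs on 60 training
segments per fold; larger corpora and budgets push this far higher.
The architecture audit is exact:

```r
count_parameters(build_eegnet())$total
#> [1] 54632
count_parameters(build_cnn_lstm())$total
#> [1] 107278
```

See `vignettes/vepdecode-methods.Rmd` for the full model description,
numerical choices and limitations.

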