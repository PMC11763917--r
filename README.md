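# timeArrow

Self-supervised **arrow-of-time pretraining** and saliency analysis for
multivariate neural time courses, in R.

## The problem

Deep models for resting-state fMRI dynamics (subject = a T x N matrix of
ICA component time courses) need more labeled data than small clinical
cohorts can provide, and their predictions are hard to trust without
explanations. `timeArrow` implements both halves of a remedy:

1. **Time-reversal (TR) pretraining.** For a sequence
   X in R^(T x N), the reversal operator is
   R(X)[t, n] = X[T - t - 1, n]. A recurrent attention classifier
   f_theta is trained on the balanced set
   {(X, y = 0), (R(X), y = 1)} to predict whether an input runs
   forward or backward, minimizing binary cross-entropy
   L(theta) = -mean[ y log f_theta(X) + (1 - y) log(1 - f_theta(X)) ].
   Telling the two apart requires encoding the data's temporal
   dependency structure, so the learned weights transfer to downstream
   binary classification (patient vs control) on small labeled cohorts.
2. **Explainability.** Integrated-gradients saliency maps (midpoint-rule
   path integral of the output gradient), forward/reverse *flip
   alignment* (Pearson correlation between the forward map and the
   time-flipped reverse map of the same subject), an **EMD spikiness**
   statistic (1-Wasserstein distance between the top-5% saliency time
   marginal and the uniform distribution: scattered = 0, a single
   endpoint spike = (T-1)/2), and submodular pick of representative
   subjects.

The model is an LSTM (or GRU) encoder, concatenation attention
(score_t = w2' tanh(W1 [h_t; h_T] + b1) + b2, softmax, weighted context),
and a linear-dropout-linear-sigmoid decoder, trained with Adam (lr 7e-4,
batch 32), a reduce-on-plateau scheduler and early stopping, evaluated by
stratified 10-fold cross-validation (AUC, accuracy, balanced accuracy).
Order-contrastive (OCP) and permutation-contrastive (PCL) pretraining
baselines are included. All recurrent forward/backward passes are
hand-derived RcppArmadillo code, finite-difference-verified in the tests.

Real pretraining and clinical datasets are access-restricted, so the
package ships seeded generators for (a) concatenated up-chirp cohorts
(the classic synthetic arrow-of-time design) and (b) two-class
"episodic disease" cohorts (AR(1) controls; patients with transient
boxcar events at random onsets).

## Worked example

```r
library(timeArrow)

# a small chirp cohort: 8 components, 200 time points, 4 chirp segments
cohort <- generateChirpCohort(60, ChirpParams(nComponents = 8,
                                              nTimepoints = 200, seed = 0))
cohort
#> Cohort 'chirp': 60 subjects, 200 time points x 8 components

# self-supervised pretraining on forward-vs-reversed classification
fit <- pretrain("tr", cohort, ModelConfig(inputSize = 8),
                TrainConfig(seed = 1))
round(fit$testAccuracy, 3)
#> [1] 1

# what does the model look at?
s  <- subjects(cohort)[[1]]
Sf <- integratedGradients(fit$model, tsValues(s), steps = 64,
                          subjectId = subjectId(s))
round(emdSpikiness(Sf), 2)   # temporal concentration of top-5% salience
#> [1] 91.47
```

`fit$testAccuracy` is the held-out forward/reverse accuracy (1 = the
pretext task is fully learned; chance is 0.5). The spikiness value 91.47
is close to the maximum (200 - 1)/2 = 99.5 and far from the scattered
extreme 0: the top-5% salient mass sits in a narrow time interval — the
model keys on a short, specific stretch of the signal, here the
slow-oscillation onset of a chirp segment. `runPipeline()` chains simulation, pretraining, fine-tuning
with and without transfer, saliency, and reporting into one seeded,
reproducible experiment.

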