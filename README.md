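# charmark

Character-level Markov-chain fingerprints for speech transcripts, with a
statistical screening pipeline for group differences between dementia and
control speakers.

## The problem and who this is for

Speech changes early in cognitive decline — more and longer pauses, more
repetition, less flexible phrasing — and transcripts of standardized
picture-description tasks capture a usable trace of it. Most computational
approaches work at the semantic or acoustic level; charmark instead works
at the most granular level available in a transcript: transitions between
individual characters. It is aimed at researchers in digital biomarkers and
speech-language science who want compact, interpretable, language-agnostic
features plus a defensible statistical screen, and who need every stage to
be testable without access-restricted clinical corpora.

## The model

Each transcript is normalized to a 27-symbol vocabulary (a–z plus space;
the space preserves pausing) and modelled as a first-order Markov chain.
Transition probabilities use Laplace smoothing,

    P_ij = (n_ij + α) / Σ_u (n_iu + α),   k = 27, α = 0.01,

and the transcript's *fingerprint* is the stationary distribution π of that
chain, the unique solution (for strictly positive P) of

    π = πP,   Σ_i π_i = 1,

i.e. the long-run usage frequency of each character. Fingerprints stack
into an n × 27 feature matrix (a `CharFingerprints` object, built on
`SummarizedExperiment`) which feeds:

* a per-character two-sample Kolmogorov–Smirnov screen with Bonferroni
  correction across the 27 characters,
* k-means clustering with silhouette-based selection of k, and a 2-D PCA
  projection for visualization,
* L1-penalized (lasso) logistic regression with stratified cross-validated
  ROC-AUC and sparse feature selection,
* per-transcript transition-network rigidity summaries (self-loop mass,
  outgoing-entropy),
* a calibrated synthetic-corpus generator: two-group corpora from
  ground-truth 27-state chains with a controllable shift in the stationary
  space probability, plus Monte-Carlo power analysis of the screen.

## Worked example

```r
library(charmark)

corpus <- generateCorpus(list(
  groupSpec("dementia", 60, targetSpaceMass = 0.19, lengthRange = c(400, 700)),
  groupSpec("control",  60, targetSpaceMass = 0.17, lengthRange = c(400, 700))
), seed = 42, returnGroundTruth = FALSE)

built <- buildFingerprints(corpus$manifest)
built$fingerprints
#> CharFingerprints: 120 transcripts x 27 character features
#>   groups: control=60, dementia=60
#>   space stationary mass: mean 0.1763  range [ 0.1394 , 0.2175 ]

screen <- screenCharacters(built$fingerprints)
head(screen[, 1:5], 4)
#>   character ks_statistic  p_value p_adjusted significant
#> 1     space        0.550 2.62e-08   7.08e-07        TRUE
#> 2         d        0.250 4.70e-02   1.00e+00       FALSE
#> 3         g        0.233 7.63e-02   1.00e+00       FALSE
#> 4         i        0.233 7.63e-02   1.00e+00       FALSE

fit <- lassoClassifier(built$fingerprints, seed = 42)
sprintf("cross-validated AUC: %.3f", fit$cvAucMean)
#> "cross-validated AUC: 0.831"
fit$selectedFeatures
#>   character coefficient
#> 1     space        11.5

clusterFingerprints(built$fingerprints, seed = 42)$kSelected
#> [1] 2
```

Reading the output: the groups were generated with stationary space masses
0.19 vs 0.17, and the screen flags exactly the space character (KS D =
0.55, Bonferroni-adjusted p = 7.1e-7) while the other 26 characters stay
below the family-wise threshold. The lasso selects the space probability as
the single informative feature with a cross-validated AUC of 0.83 —
consistent with the information limit of a 0.02 shift at these transcript
lengths — and silhouette-based selection finds k = 2 clusters.

Real corpora come in as plain-text files plus a manifest CSV
(`transcript_id,path,group`): `built <- buildFingerprints(readManifest("manifest.csv"))`,
or end to end with `runPipeline("manifest.csv", validateConfig(list(seed = 1)), outdir = "results")`.
A thin command-line front end with `features`, `stats`, `cluster`,
`classify`, `network`, `simulate`, `power` and `run` subcommands lives at
`inst/cli/charmark.R`.

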