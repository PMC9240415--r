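---
title: "Measuring discourse coherence and mapping its lesion correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring discourse coherence and mapping its lesion correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cohmap implements a three-stage analysis of discourse production in
post-stroke aphasia: a computational measure of *global coherence* — how
well a speaker's discourse stays on the expected topic — followed by
behavioural statistics relating coherence to language/cognitive component
scores, and voxel-wise lesion-symptom mapping of coherence deficits. This
vignette explains the models, the tunable parameters, the synthetic-data
generator used to validate every stage, and the numerical choices made
where the design was genuinely open.

## The coherence model

Word meanings are represented by latent semantic analysis (LSA): a
term-document count matrix is weighted (log-entropy by default), factored
by truncated SVD, and each term's k-dimensional row (scaled by the
singular values) is L2-normalized. Two conventions make builds exactly
reproducible: the vocabulary is sorted, and each singular vector's sign is
fixed by making its largest-magnitude entry positive, so the space is
invariant to document order.

A discourse response is reduced to its content tokens (everything except a
packaged function-word stoplist: articles, prepositions, pronouns,
auxiliaries, conjunctions, fillers) and represented by the unweighted mean
of its in-vocabulary token vectors — one vector for the entire response,
because short aphasic responses often cannot be windowed. For each task, a
*prototype* of typical semantic content is the element-wise mean of control
participants' response vectors; a control's own response is excluded from
the prototype it is scored against (leave-one-out), which keeps the score
independent of the response and is why a control never scores exactly 1
unless all controls coincide. Global coherence is the cosine between a
response vector and the prototype; a composite score averages a
participant's available task scores. A *deficit* is a score strictly more
than 1.5 sample SDs below the control mean for that task.

Two readings of the per-response averaging were possible: counting token
instances (a repeated word contributes twice) or token types. Instance
averaging is the default (`mode = "instance"`), the simplest reading of
"averaging" and arguably the right one for disordered speech where
perseverative repetition genuinely shifts content; type averaging is
exposed as an option. Interjection fillers ("um", "uh") are stoplisted.
Out-of-vocabulary tokens are skipped but counted per response.

## Behavioural statistics

The group comparison is a classical 2 (group) x 3 (task) mixed ANOVA on
complete cases only — repeated-measures ANOVA needs all cells, and
participants missing a task are excluded with a logged count (the study's
own exclusion rule removes only participants with no response in *any*
task, so composite scores still average whatever tasks are present).
Within-subject effects are reported both uncorrected and
Greenhouse-Geisser corrected, with epsilon computed from the pooled
within-group covariance of the task scores; with three tasks the
correction is typically negligible but it is reported because sphericity
is never guaranteed. Effect sizes are partial eta squared,
F·df1/(F·df1 + df2).

The component analysis regresses patients' composite coherence on seven
orthogonal language/cognitive component scores (consumed as given, not
re-derived) in four nested OLS models: core language components
(phonological production, phonological recognition, semantic processing);
plus connected-speech components (verbal fluency, verbal quality, motor
speech); plus executive functions; plus interactions between executive
functions and every predictor significant at p < 0.001 in the earlier
models. Interaction terms are built from mean-centred factors — the
conventional choice that keeps main effects interpretable; raw-product
terms would change only the intercept and main-effect estimates, not the
interaction tests. A fifth, single-predictor model uses executive
functions alone. Rank-deficient designs error naming the collinear
columns rather than silently dropping them.

## Lesion-symptom mapping

**VBCM (univariate).** Continuous abnormality images (values in [0, 1],
smoothed with an 8 mm FWHM Gaussian; sigma = FWHM / (2*sqrt(2 ln 2))) are
analysed voxel-wise: behaviour is regressed on the voxel value plus
covariates (age, months post-onset; optionally lesion volume), and the t
statistic of the voxel coefficient is kept. Negative t means more
abnormality goes with lower coherence — the deficit direction, which is
what cluster reporting uses by default. Suprathreshold voxels (two-tailed
p < 0.001) form clusters under 26-connectivity (configurable 6/18/26), and
cluster-level familywise error is controlled by permutation: behaviour is
permuted under the Freedman-Lane scheme (residuals of behaviour on the
covariates are permuted and re-residualized), the maximum cluster size is
recorded per permutation, and a cluster's corrected p is the tail
probability of its size. This permutation route replaces random-field
theory deliberately: it is distribution-free, exact at any sample size,
and honest on a desk-scale grid; permutation p-values can never be
smaller than 1/(nPerm + 1). Inference is two-tailed with signed
reporting, since nothing in the design rules out positive associations.

**SVR-LSM (multivariate).** Binary lesion masks (continuous images
thresholded at u = 0.5, strict ">") are the features of an epsilon-SVR
with a linear kernel; behaviour is first residualized on the covariates.
Voxels lesioned in fewer than 4 patients are excluded (the lesion
threshold). With volume control on, lesion volume is regressed out of
every retained voxel column *and* out of behaviour. The statistic per
voxel is the back-projected weight w = X'alpha. Hyper-parameters are
chosen once by a seeded random search over log-uniform C in [1e-2, 1e3]
and epsilon in [1e-3, 1] with 5-fold cross-validated MSE, then held fixed
across permutations (re-tuning per permutation would multiply cost by the
candidate count while leaving the null distribution exchangeable either
way). Voxel-wise p-values pool the observed and permuted weight maps and
rank |beta| per voxel, so observed and null maps are treated
exchangeably; clusters are formed from deficit-direction (negative)
suprathreshold voxels at p < 0.005 and FWE-corrected by the same
max-cluster-size route. One computational identity is worth noting: the
linear-kernel SVR dual depends on the feature matrix only through the
Gram matrix XX', so the model is fit on an n x n factor of it — exactly
the same solution, at a cost independent of the voxel count.

## The synthetic-data generator

No clinical data ship with the package; every stage is validated on
generated cohorts with known ground truth, at the published study's
conditions: 20 controls, 46 patients, three discourse tasks.

*Transcripts.* Each pool of task vocabulary (20 words per task, plus an
off-topic pool, all disjoint from the stoplist) forms a topic block in a
generated corpus; documents sample a sparse Dirichlet word preference
(concentration 0.15) so words within a topic get differentiated vectors
rather than collapsing onto one direction. A response samples content
tokens from the on-topic pool under a participant-by-task word preference
(Dirichlet concentration `focus`) and from the off-topic pool with
probability equal to the participant's *drift rate*, Beta-distributed
around the group-by-task mean. Function-word fillers are interleaved and
removed again by scoring. Drift and focus defaults were calibrated once so
that scored group means land near the reported task means — controls about
0.86/0.84/0.91 and patients 0.65/0.61/0.74 for storytelling, picture
description and procedural discourse — with procedural discourse the most
tightly constrained topic (highest focus, lowest drift) in both groups. A
subtlety found during calibration: drift shared by the whole control group
cancels, because the prototype drifts with it; group separation therefore
comes from the drift *gap*, and control-mean level mainly from word-choice
idiosyncrasy. About 4% of patient responses are generated empty to
exercise the missing-task path.

*Component scores.* Seven exactly orthogonalized standard-normal columns
(centred, QR-orthogonalized, rescaled), with composite coherence
regenerated as intercept + XB + noise in forward mode (planted
B = 0.132, 0.101, 0.08 for phonological production, semantic processing
and verbal fluency) or independent of the components in null mode. The
residual SD defaults to 0.05, a power choice: the smallest planted gap
(0.021) must be at least twice the coefficient standard error at n = 46
for the planted ordering to be recoverable in >= 90% of replicates, which
bounds the SD at about 0.05. A noise level matched instead to the
published variance-explained (about 0.09) makes that ordering only ~1.1
SE wide and recovery tops out near 80% — the two desiderata cannot both
hold, and the generator privileges recoverability since its purpose is
ground-truth testing.

*Lesions.* Per patient, a contiguous blob is grown by seeded random
6-connected wave growth from a seed voxel in a configurable zone, with
volume drawn from a truncated lognormal inside the published 175-41379
voxel range (upper tail capped to what the default 32^3 grid at 2 mm can
hold; shape realism is explicitly out of scope — contiguity is what
cluster inference needs). Continuous images are the smoothed masks. The
brain-behaviour link has two modes. In `"overlap"` mode (default)
behaviour is baseline - effect x (fraction of a planted critical region
lesioned) + noise: realistic, but neighbouring voxels inherit *genuine*
signal through lesion contiguity, so recovered clusters are correctly
larger than the nominal region. In `"direct"` mode a graded abnormality
severity is added to the critical region of the continuous images and
behaviour follows that severity, confining the true signal exactly to the
planted voxels — the clean target for spatial-recovery tests (Dice of the
top cluster against the planted region is 1.0 across trial seeds), used
wherever a test needs a sharp ground-truth boundary. Covariates (age,
months post-onset) are drawn from the published ranges, independent of
behaviour.

## Problem sizes used by the tests

The validation suite runs at desk scale, chosen as the smallest problems
that still measure what they claim: oracle comparisons on 4-6 unit
fixtures; regression recovery over 200 seeded replicates at n = 46; VBCM
null calibration over 200 replicates of 1000 permutations on a 12^3 grid;
SVR-LSM null calibration over 200 replicates of 200 permutations on an
8^3 grid (200 is the smallest permutation count whose granularity,
1/201, still admits voxels below the 0.005 threshold); end-to-end checks
over 5 seeds at the full 20 + 46 cohort. The two calibration experiments
check that the familywise false-positive count over 200 null replicates
falls inside the central 95% binomial band of the nominal 0.05 level.

## What passing tests do and do not show

The generator produces topic blocks with no syntax, no morphology, no
word frequency skew, and lesions without vascular-territory shape; the
semantic space is tiny (80 words) next to any real LSA space. Passing
tests therefore certify the *computational machinery* — scoring,
exclusion rules, model fits, permutation inference, calibration — under
known ground truth, not the linguistic validity of LSA coherence on real
speech (established in the prior literature) nor anatomical conclusions,
which require real cohorts. Known limitations: coherence scores depend on
the semantic space used, so cross-study comparisons need a shared space;
the mixed ANOVA uses complete cases (no mixed-effects imputation); VBCM
assumes a linear voxel-behaviour relation; SVR weight maps are
interpreted voxel-wise although the model is multivariate — and at
desk-scale cohorts the SVR's voxel-level permutation test has limited
power for spatially diffuse signals (the weight map still localizes the
planted region sharply, which is what the recovery checks assert), so the
cluster endpoint is most meaningful at realistic grid sizes; and cluster
peak coordinates are reported 0-based in voxel space, with any affine
carried through for mm conversion downstream.
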