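# cohmap

Discourse coherence scoring and lesion-symptom mapping for post-stroke
aphasia.

People with aphasia often struggle to keep connected speech on topic.
`cohmap` quantifies that ability and asks two questions of a patient
cohort: *which cognitive components* explain coherence deficits, and
*which lesion sites* are associated with them. It is written for
researchers in aphasiology and clinical neuroimaging who have discourse
transcripts, neuropsychological component scores and co-registered lesion
images — and, because such data rarely travel, it ships a synthetic
cohort generator with known ground truth so the full pipeline can be run,
tested and audited end to end without any clinical data.

## The measures

**Global coherence.** Word meanings come from latent semantic analysis: a
weighted (log-entropy) term–document matrix is factored by truncated SVD
and each term keeps a unit-length k-dimensional vector. A discourse
response is the mean vector of its content words (function words removed
by a packaged stoplist). For each task, control participants' response
vectors are averaged into a composite *prototype* of typical semantic
content — leave-one-out when scoring a control. Global coherence of a
response is the cosine

    gc(r) = cos(v_r, c_task),    composite = mean over tasks,

and a *deficit* is a score below the control mean − 1.5 SD for that task.

**Behavioural models.** A 2 (group) × 3 (task) mixed ANOVA on coherence
(partial η² = F·df1/(F·df1+df2), Greenhouse–Geisser reported for
within-subject effects), then staged OLS regressions of patients'
composite coherence on seven orthogonal language/cognitive components:
M1 core language, M2 + connected speech, M3 + executive functions, M4 +
executive × (significant predictors) interactions on mean-centred terms,
plus an executive-only model.

**Lesion mapping.** Univariate VBCM: per voxel, behaviour ~ continuous
abnormality + covariates (age, months post-onset, optionally lesion
volume); the voxel t map is thresholded at p < 0.001 two-tailed and
clusters are FWE-corrected at p < 0.05 by the permutation distribution of
the maximum cluster size (Freedman–Lane permutation of behaviour
residuals). Multivariate SVR-LSM: binary lesions (U = 0.5) at voxels
lesioned in ≥ 4 patients feed a linear-kernel ε-SVR; back-projected voxel
weights are tested by permutation at p < 0.005 voxel-wise, clusters
FWE-corrected as above, with optional lesion-volume control on both
features and behaviour.

## Worked example

```r
library(cohmap)

cfg <- cohortConfig(seed = 2)          # 20 controls, 46 patients
cs  <- makeCorpusAndSpace(cfg)         # corpus + LSA space
tr  <- makeTranscripts(cfg)            # synthetic discourse responses
sc  <- scoreCohort(recordsFromTable(tr$data, cs$space))
sc
#> CoherenceTable: 66 participants, 198 participant x task rows
#>   control mean coherence: picture_description=0.881, procedural=0.919, storytelling=0.902
#>   patient mean coherence: picture_description=0.576, procedural=0.712, storytelling=0.622

mixedAnova(sc)[, c("effect", "F", "df1", "df2", "p")]
#>       effect          F df1 df2            p
#> 1      group 43.1683382   1  61 1.262228e-08
#> 2       task  4.5646198   2 122 1.225399e-02
#> 3 group:task  0.9046068   2 122 4.073979e-01

cp  <- makeComponentScores(cfg, mode = "forward")   # planted B = .132/.101/.08
reg <- stagedRegressions(cp$composite, cp$components)
reg$models[, c("label", "R2", "delta_R2")]
#>   label        R2     delta_R2
#> 1    M1 0.7672014           NA
#> 2    M2 0.9482091 0.1810077242
#> 3    M3 0.9487668 0.0005577171
#> 4    M4 0.9500627 0.0012958279
```

Patients score well below controls on every task, procedural discourse is
the most coherent task for both groups, and the staged regressions
recover the planted coefficients (here at the generator's power-designed
noise level). For the lesion stage:

```r
lc <- makeLesionCohort(cfg)                     # blobs + planted critical region
vb <- vbcm(lc$continuous, nPerm = 1000, seed = 1)
clusterTable(vb$clusters)[1, ]
#>   cluster_id size peak_stat peak_x peak_y peak_z       p_fwe
#> 1          1 2500 -11.57701      9     23     15 0.000999001
```

The top deficit-direction cluster is FWE-significant and peaks inside the
planted critical region (the cluster is wider than the region because
contiguous lesions spread genuine signal to neighbouring voxels; see the
vignette for the sharp-recovery generator mode). `svrLsm(lc$binary, ...)`
runs the multivariate counterpart; `runPipeline(cfg, "out/")` writes
scores, ANOVA/regression tables, NIfTI maps and cluster CSVs in one call,
and `inst/scripts/cohmap` wraps these steps for shell use.

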