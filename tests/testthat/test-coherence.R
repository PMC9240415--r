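test_that("preprocessing lowercases, strips punctuation and removes function words", {
  expect_equal(preprocess("The boy is stealing the cookies."),
               c("boy", "stealing", "cookies"))
  expect_equal(preprocess(""), character(0))
  expect_equal(preprocess("um, the the tea"), "tea")
  # numerals dropped, intra-word apostrophes kept
  expect_equal(preprocess("he's got 3 cups, doesn't he?"),
               c("got", "cups"))
})

test_that("response vectors are instance means over in-vocabulary tokens", {
  sp <- handSpace(tea = c(1, 0, 0), kettle = c(0, 1, 0))
  expect_equal(composeResponseVector(sp, "tea"), c(1, 0, 0),
               ignore_attr = TRUE)
  expect_equal(composeResponseVector(sp, c("tea", "kettle")),
               c(0.5, 0.5, 0), ignore_attr = TRUE)
  # instances count twice; type mode counts once
  inst <- composeResponseVector(sp, c("tea", "tea", "kettle"))
  expect_equal(inst, c(2 / 3, 1 / 3, 0), ignore_attr = TRUE)
  expect_equal(composeResponseVector(sp, c("tea", "tea", "kettle"),
                                     mode = "type"),
               c(0.5, 0.5, 0), ignore_attr = TRUE)
  expect_null(composeResponseVector(sp, c("zzz", "qqq")))
  expect_equal(attr(composeResponseVector(sp, c("tea", "zzz")), "n_oov"), 1L)
})

test_that("composite prototypes average contributors and honour exclusion", {
  sp <- handSpace(a = c(1, 0, 0), b = c(0, 1, 0), d = c(0, 0, 1))
  recs <- handRecords(sp, list(
    list(id = "c1", group = "control", task = "procedural", tokens = "a"),
    list(id = "c2", group = "control", task = "procedural", tokens = "b"),
    list(id = "c3", group = "control", task = "procedural", tokens = "d")))
  p <- compositePrototype(recs, "procedural", excludeId = "c2")
  expect_equal(p@vector, c(0.5, 0, 0.5))
  expect_equal(p@nContributors, 2L)
  pAll <- compositePrototype(recs, "procedural")
  expect_equal(pAll@vector, rep(1 / 3, 3))
  expect_error(compositePrototype(recs[1], "procedural", excludeId = "c1"),
               "no prototype contributors")
})

test_that("global coherence is the cosine, with exact identity and orthogonality", {
  expect_equal(globalCoherence(c(0.2, 0.4, 0.1), c(0.2, 0.4, 0.1)), 1)
  expect_equal(globalCoherence(c(1, 0), c(0, 1)), 0)
  expect_equal(globalCoherence(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(globalCoherence(c(0, 0), c(1, 0)), "degenerate")
  expect_error(globalCoherence(c(1, 0, 0), c(1, 0)), "dimensions differ")
})

test_that("coherence is invariant to positive rescaling of either vector", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    s <- globalCoherence(a, b)
    expect_equal(globalCoherence(a * runif(1, 0.01, 100), b), s,
                 tolerance = 1e-12)
    expect_equal(globalCoherence(a, b * runif(1, 0.01, 100)), s,
                 tolerance = 1e-12)
  }
})

test_that("cohort scoring uses leave-one-out for controls and composites over present tasks", {
  sp <- handSpace(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0), d = c(0, 0, 1, 0),
                  e = c(0, 0, 0, 1))
  recs <- handRecords(sp, list(
    list(id = "c1", group = "control", task = "procedural", tokens = c("a", "b")),
    list(id = "c2", group = "control", task = "procedural", tokens = c("a", "b")),
    list(id = "c3", group = "control", task = "procedural", tokens = c("a", "d")),
    list(id = "p1", group = "patient", task = "procedural", tokens = "a")))
  tab <- scoreCohort(recs)
  sc <- coherenceScores(tab)
  # c1 duplicates c2's tokens but is scored against a prototype excluding
  # itself, so its score is below 1
  expect_lt(sc$global_coherence[sc$participant_id == "c1"], 1)
  # patient scored against the all-controls prototype
  proto <- compositePrototype(recs, "procedural")
  expect_equal(sc$global_coherence[sc$participant_id == "p1"],
               globalCoherence(c(1, 0, 0, 0), proto))

  # composite over present tasks only
  sp2 <- handSpace(a = c(1, 0), b = c(0, 1))
  mk <- function(id, group, task, tokens)
    list(id = id, group = group, task = task, tokens = tokens)
  recs2 <- handRecords(sp2, list(
    mk("c1", "control", "procedural", c("a")),
    mk("c2", "control", "procedural", c("b")),
    mk("c1", "control", "storytelling", c("a")),
    mk("c2", "control", "storytelling", c("b")),
    mk("p1", "patient", "procedural", c("a", "b")),
    mk("p1", "patient", "storytelling", character(0))))
  tab2 <- scoreCohort(recs2)
  comp <- compositeScores(tab2)
  s <- coherenceScores(tab2)
  p1 <- s[s$participant_id == "p1", ]
  expect_true(is.na(p1$global_coherence[p1$task == "storytelling"]))
  expect_equal(comp$composite_coherence[comp$participant_id == "p1"],
               p1$global_coherence[p1$task == "procedural"])
})

test_that("participants with no scorable response are dropped with a warning", {
  sp <- handSpace(a = c(1, 0), b = c(0, 1))
  recs <- handRecords(sp, list(
    list(id = "c1", group = "control", task = "procedural", tokens = c("a")),
    list(id = "c2", group = "control", task = "procedural", tokens = c("b")),
    list(id = "p1", group = "patient", task = "procedural", tokens = "a"),
    list(id = "p2", group = "patient", task = "procedural", tokens = character(0))))
  expect_warning(tab <- scoreCohort(recs), "p2")
  expect_false("p2" %in% compositeScores(tab)$participant_id)
})

test_that("a task with fewer than two scorable control responses errors", {
  sp <- handSpace(a = c(1, 0), b = c(0, 1))
  recs <- handRecords(sp, list(
    list(id = "c1", group = "control", task = "procedural", tokens = "a"),
    list(id = "p1", group = "patient", task = "procedural", tokens = "b")))
  expect_error(scoreCohort(recs), "at least 2")
})

test_that("deficit rule flags scores strictly below mean - 1.5 SD of controls", {
  # control scores with mean 0.86 and SD 0.07 give cutoff 0.755
  ctl <- c(0.79, 0.86, 0.93)
  expect_equal(mean(ctl), 0.86)
  expect_equal(sd(ctl), 0.07)
  expect_equal(deficitCutoff(ctl), 0.86 - 1.5 * 0.07)
  expect_true(flagDeficit(0.65, ctl))
  expect_false(flagDeficit(0.755, ctl))   # exactly at the cutoff
  expect_false(flagDeficit(0.95, ctl))
  expect_error(flagDeficit(0.5, 0.8), "SD undefined")
})

test_that("including a control's own response never lowers its score", {
  set.seed(42)
  for (rep in 1:20) {
    k <- 5; nc <- sample(3:6, 1)
    vecs <- matrix(abs(rnorm(nc * k)), nc, k)
    proto_loo <- colMeans(vecs[-1, , drop = FALSE])
    proto_all <- colMeans(vecs)
    s_loo <- globalCoherence(vecs[1, ], proto_loo)
    s_all <- globalCoherence(vecs[1, ], proto_all)
    expect_gte(s_all, s_loo - 1e-12)
  }
})

test_that("expected coherence is non-increasing in topic drift", {
  set.seed(9)
  onPool <- letters[1:8]; offPool <- letters[9:16]
  docs <- c(replicate(6, sample(onPool, 10, replace = TRUE), simplify = FALSE),
            replicate(6, sample(offPool, 10, replace = TRUE), simplify = FALSE))
  sp <- buildSpace(docs, k = 6, weighting = "raw", minCount = 1)
  proto <- composeResponseVector(sp, onPool)
  meanScore <- function(d, nrep = 60) {
    mean(replicate(nrep, {
      off <- runif(30) < d
      toks <- ifelse(off, sample(offPool, 30, replace = TRUE),
                     sample(onPool, 30, replace = TRUE))
      globalCoherence(composeResponseVector(sp, toks), proto)
    }))
  }
  ms <- sapply(c(0, 0.25, 0.5, 0.75, 1), meanScore)
  expect_true(all(diff(ms) < 0.02))  # non-increasing up to Monte Carlo noise
  expect_gt(ms[1] - ms[5], 0.3)
})
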