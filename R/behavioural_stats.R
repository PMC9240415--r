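.COMPONENTS <- c("phonological_production", "semantic_processing",
                 "phonological_recognition", "verbal_fluency",
                 "verbal_quality", "motor_speech", "executive_functions")

#' Partial eta squared from an F statistic
#'
#' \code{F * df1 / (F * df1 + df2)}, the effect-size identity used for all
#' reported ANOVA effects.
#'
#' @param f,df1,df2 F statistic and its degrees of freedom
#' @return numeric in [0, 1]
#' @export
partialEtaSq <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Two-by-three mixed ANOVA on global coherence
#'
#' Group (control vs patient) is the between-subject factor and discourse
#' task the within-subject factor. Only participants with scores on all
#' three tasks enter (classical repeated-measures ANOVA requires complete
#' cells); incomplete participants are excluded with a message. The
#' within-subject effects are also reported with Greenhouse-Geisser
#' corrected p-values (epsilon from the pooled within-group covariance of
#' the task scores). Post-hoc paired task contrasts are Bonferroni
#' corrected.
#'
#' @param x a \linkS4class{CoherenceTable} or a long data.frame with
#'   columns participant_id, group, task, global_coherence
#' @return data.frame with one row per effect (group, task, group:task):
#'   F, df1, df2, p, partial_eta_sq, gg_epsilon, p_gg (NA for the
#'   between-subject effect). Attribute \code{"posthoc"} holds the paired
#'   task contrasts; attribute \code{"n_excluded"} the number of
#'   incomplete participants removed.
#' @export
mixedAnova <- function(x) {
  d <- if (is(x, "CoherenceTable")) coherenceScores(x) else x
  d <- d[!is.na(d$global_coherence), c("participant_id", "group", "task",
                                       "global_coherence")]
  tasks <- sort(unique(d$task))
  q <- length(tasks)
  if (q < 2L) stop("need at least 2 tasks")
  wide <- stats::reshape(d, idvar = c("participant_id", "group"),
                         timevar = "task", direction = "wide")
  scorecols <- paste0("global_coherence.", tasks)
  complete <- stats::complete.cases(wide[, scorecols])
  n_excl <- sum(!complete)
  if (n_excl > 0L)
    message(n_excl, " participant(s) without all ", q,
            " task scores excluded from the ANOVA")
  wide <- wide[complete, , drop = FALSE]
  if (any(table(wide$group) < 2L))
    stop("each group needs at least 2 complete-case participants")

  long <- data.frame(
    participant_id = factor(rep(wide$participant_id, times = q)),
    group = factor(rep(wide$group, times = q)),
    task = factor(rep(tasks, each = nrow(wide))),
    global_coherence = unlist(wide[, scorecols], use.names = FALSE))
  fit <- stats::aov(global_coherence ~ group * task +
                      Error(participant_id / task), data = long)
  sm <- summary(fit)
  between <- sm[["Error: participant_id"]][[1]]
  within <- sm[["Error: participant_id:task"]][[1]]
  pick <- function(tab, eff) {
    i <- match(eff, trimws(rownames(tab)))
    c(ss = tab[i, "Sum Sq"], df = tab[i, "Df"])
  }
  g <- pick(between, "group"); ge <- pick(between, "Residuals")
  t1 <- pick(within, "task"); gt <- pick(within, "group:task")
  we <- pick(within, "Residuals")

  eff <- function(name, e, err) {
    f <- (e["ss"] / e["df"]) / (err["ss"] / err["df"])
    data.frame(effect = name, F = unname(f), df1 = unname(e["df"]),
               df2 = unname(err["df"]),
               p = unname(stats::pf(f, e["df"], err["df"], lower.tail = FALSE)),
               partial_eta_sq = unname(e["ss"] / (e["ss"] + err["ss"])),
               stringsAsFactors = FALSE)
  }
  out <- rbind(eff("group", g, ge), eff("task", t1, we),
               eff("group:task", gt, we))

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  y <- as.matrix(wide[, scorecols])
  centred <- do.call(rbind, lapply(split(as.data.frame(y), wide$group),
                                   function(m) scale(as.matrix(m),
                                                     scale = FALSE)))
  S <- crossprod(centred) / (nrow(y) - length(unique(wide$group)))
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  epsilon <- sum(diag(Sdc))^2 / ((q - 1) * sum(Sdc^2))
  epsilon <- min(1, max(1 / (q - 1), epsilon))
  out$gg_epsilon <- c(NA, epsilon, epsilon)
  out$p_gg <- ifelse(is.na(out$gg_epsilon), NA,
                     stats::pf(out$F, out$df1 * out$gg_epsilon,
                               out$df2 * out$gg_epsilon, lower.tail = FALSE))

  pairs <- utils::combn(tasks, 2, simplify = FALSE)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    a <- y[, paste0("global_coherence.", pr[1])]
    b <- y[, paste0("global_coherence.", pr[2])]
    tt <- tryCatch(stats::t.test(a, b, paired = TRUE),
                   error = function(e) NULL)  # constant differences
    data.frame(task_a = pr[1], task_b = pr[2],
               mean_diff = mean(a - b),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_bonferroni = if (is.null(tt)) NA_real_ else
                 min(1, tt$p.value * length(pairs)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "posthoc") <- posthoc
  attr(out, "n_excluded") <- n_excl
  rownames(out) <- NULL
  out
}

.checkFullRank <- function(X, label) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    bad <- setdiff(bad, "(Intercept)")
    stop("rank-deficient design in ", label, ": collinear column(s) ",
         paste(bad, collapse = ", "))
  }
}

.fitModel <- function(label, y, X) {
  .checkFullRank(cbind(`(Intercept)` = 1, X), label)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  n <- length(y); p <- ncol(X)
  res <- fit$residuals
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  df2 <- n - p - 1L
  fstat <- ((tss - rss) / p) / (rss / df2)
  sigma2 <- rss / df2
  XtXinv <- chol2inv(qr.R(qr(cbind(1, X))))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df2)
  list(models = data.frame(label = label, R2 = r2, F = fstat, df1 = p,
                           df2 = df2,
                           p = stats::pf(fstat, p, df2, lower.tail = FALSE),
                           stringsAsFactors = FALSE),
       coefficients = data.frame(label = label,
                                 term = names(fit$coefficients),
                                 B = unname(fit$coefficients),
                                 p = unname(pval), stringsAsFactors = FALSE))
}

.mergeScores <- function(composite, components) {
  comp <- if (is(composite, "CoherenceTable")) {
    cs <- compositeScores(composite)
    cs[cs$group == "patient", c("participant_id", "composite_coherence")]
  } else composite
  stopifnot(all(c("participant_id", "composite_coherence") %in% names(comp)))
  miss <- setdiff(.COMPONENTS, names(components))
  if (length(miss))
    stop("components table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(components[, .COMPONENTS]))))
    stop("component scores must be finite")
  d <- merge(comp, components, by = "participant_id")
  d[!is.na(d$composite_coherence), , drop = FALSE]
}

#' Staged regression models of composite coherence on cognitive components
#'
#' Ordinary-least-squares fits of four nested models with composite global
#' coherence as the dependent variable: Model 1, the main language
#' components (phonological production, phonological recognition, semantic
#' processing); Model 2 adds the connected speech components (verbal
#' fluency, verbal quality, motor speech); Model 3 adds executive
#' functions; Model 4 adds interaction terms between executive functions
#' and every predictor significant in Models 1-3 at \code{alpha}
#' (interactions built from mean-centred factors).
#'
#' @param composite a \linkS4class{CoherenceTable} (patients' composite
#'   scores are used) or a data.frame with participant_id and
#'   composite_coherence
#' @param components data.frame with participant_id and the seven component
#'   columns
#' @param alpha significance threshold selecting "significant variables"
#'   for Model 4's interactions (default 0.001)
#' @return list with \code{models} (label, R2, delta_R2, F, df1, df2, p)
#'   and \code{coefficients} (label, term, B, p) data.frames
#' @export
stagedRegressions <- function(composite, components, alpha = 0.001) {
  d <- .mergeScores(composite, components)
  y <- d$composite_coherence
  specs <- list(
    M1 = .COMPONENTS[1:3],
    M2 = .COMPONENTS[1:6],
    M3 = .COMPONENTS[1:7])
  if (length(y) <= length(specs$M3) + 4L)
    stop("need more patients than predictors: n = ", length(y))
  fits <- lapply(names(specs), function(lb)
    .fitModel(lb, y, as.matrix(d[, specs[[lb]], drop = FALSE])))
  names(fits) <- names(specs)

  co <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  sig <- unique(co$term[co$term %in% setdiff(.COMPONENTS, "executive_functions") &
                          co$p < alpha])
  X4 <- as.matrix(d[, specs$M3, drop = FALSE])
  ef <- d$executive_functions - mean(d$executive_functions)
  for (v in sig) {
    inter <- (d[[v]] - mean(d[[v]])) * ef
    X4 <- cbind(X4, inter)
    colnames(X4)[ncol(X4)] <- paste0("executive_functions:", v)
  }
  fits$M4 <- .fitModel("M4", y, X4)

  models <- do.call(rbind, lapply(fits, `[[`, "models"))
  models$delta_R2 <- c(NA, diff(models$R2))
  coefficients <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  rownames(models) <- rownames(coefficients) <- NULL
  list(models = models[, c("label", "R2", "delta_R2", "F", "df1", "df2", "p")],
       coefficients = coefficients)
}

#' Regression of composite coherence on executive functions alone
#'
#' @inheritParams stagedRegressions
#' @return as one element of [stagedRegressions()]: list with
#'   \code{models} and \code{coefficients} for the single-predictor fit
#' @export
executiveOnlyRegression <- function(composite, components) {
  d <- .mergeScores(composite, components)
  if (stats::sd(d$executive_functions) == 0)
    stop("zero-variance predictor: executive_functions is constant")
  fit <- .fitModel("executive_only", d$composite_coherence,
                   as.matrix(d[, "executive_functions", drop = FALSE]))
  fit$models$delta_R2 <- NA
  fit$models <- fit$models[, c("label", "R2", "delta_R2", "F", "df1", "df2", "p")]
  fit
}
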