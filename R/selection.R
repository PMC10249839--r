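#' Candidate model enumeration
#'
#' All non-empty subsets of the optical variable pool (each optical entering
#' with its seasonal interaction pair) crossed with inclusion/exclusion of
#' turbidity and flow. Optical-free models are excluded by default: the
#' surrogate relation is anchored on the fluorescence signals.
#'
#' @param marker response marker.
#' @param pool optical variable pool (canonical order
#'   \code{c("S1-CF", "S1-A", "S2-F")}).
#' @param regime regime label for all candidates.
#' @param turbidity,flow candidate inclusion values for the two scalar
#'   covariates (default both in and out).
#' @return list of \code{\link{model_spec}} in canonical order.
#' @export
enumerate_candidates <- function(marker, pool = optical_pool(),
                                 regime = "combined",
                                 turbidity = c(FALSE, TRUE),
                                 flow = c(FALSE, TRUE)) {
  pool <- intersect(optical_pool(), pool)
  if (length(pool) == 0) stop("empty optical pool")
  subsets <- list()
  for (k in seq_along(pool)) {
    cmb <- utils::combn(pool, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  out <- list()
  for (s in subsets) for (tu in turbidity) for (fl in flow) {
    out[[length(out) + 1]] <- model_spec(marker, opticals = s, turbidity = tu,
                                         flow = fl, regime = regime)
  }
  out
}

#' Root mean squared error of prediction in log10 space
#'
#' RMSE over scorable points, in log10 units of the response. A left-censored
#' observation is scored max(0, prediction - limit): predicting at or below
#' the detection limit is consistent with a nondetect and incurs no penalty.
#' Normalization is configurable; the default \code{"none"} reports the raw
#' log10 RMSE.
#'
#' @param observed_log10 observed log10 values (censored rows hold the log10
#'   limit).
#' @param predicted_log10 predicted log10 values.
#' @param censored logical flags.
#' @param normalization \code{"none"}, \code{"range"} or \code{"mean"} (of
#'   uncensored observed values).
#' @return scalar error.
#' @export
nrmsep <- function(observed_log10, predicted_log10, censored = NULL,
                   normalization = c("none", "range", "mean")) {
  normalization <- match.arg(normalization)
  if (length(observed_log10) != length(predicted_log10))
    stop("observed/predicted lengths differ")
  if (is.null(censored)) censored <- rep(FALSE, length(observed_log10))
  ok <- is.finite(observed_log10) & is.finite(predicted_log10)
  if (!any(ok)) stop("no scorable points")
  err <- ifelse(censored, pmax(0, predicted_log10 - observed_log10),
                predicted_log10 - observed_log10)[ok]
  rmse <- sqrt(mean(err^2))
  obs_u <- observed_log10[ok & !censored]
  switch(normalization,
         none = rmse,
         range = rmse / diff(range(obs_u)),
         mean = rmse / mean(obs_u))
}

#' Repeated k-fold cross-validation of one candidate model
#'
#' For each repetition the samples are partitioned into k folds by a seeded
#' shuffle (stratified by regime label for combined-data models so no
#' training fold is CSO-free); each fold is predicted by a model fit on the
#' remainder, one error is computed on the pooled out-of-fold predictions,
#' and the median over repetitions is reported.
#'
#' @param samples discrete-sample data.frame.
#' @param covariates named list of covariate \code{wq_ts}.
#' @param spec a \code{\link{model_spec}}.
#' @param k number of folds.
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @param normalization passed to \code{\link{nrmsep}}.
#' @return list of class \code{cv_result}: spec, nrmsep_values (length reps),
#'   median_nrmsep, n_terms.
#' @export
cross_validate <- function(samples, covariates, spec, k = 5, reps = 50,
                           seed = 1, normalization = "none") {
  d <- build_design(samples, covariates, spec)
  n <- length(d$y)
  strata <- if (spec$regime == "combined") {
    s <- samples[samples$marker == spec$marker, , drop = FALSE]
    s$regime
  } else rep("all", n)
  # canonical time order so CV is invariant to input row order
  ord <- order(as.numeric(d$timestamps))
  d$X <- d$X[ord, , drop = FALSE]
  d$y <- d$y[ord]
  d$censored <- d$censored[ord]
  d$detection_limit <- d$detection_limit[ord]
  strata <- strata[ord]
  vals <- rep(NA_real_, reps)
  skipped <- 0L
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, reps))
  for (r in seq_len(reps)) {
    fold <- with_seed(seeds[r], stratified_folds(strata, k))
    pred <- rep(NA_real_, n)
    bad <- FALSE
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- tryCatch(
        tobit_fit(d$X[tr, , drop = FALSE], d$y[tr], d$censored[tr],
                  limit = d$detection_limit[tr]),
        error = function(e) NULL)
      if (is.null(fit)) { bad <- TRUE; break }
      pred[!tr] <- drop(d$X[!tr, , drop = FALSE] %*% fit$beta)
    }
    if (bad) { skipped <- skipped + 1L; next }
    vals[r] <- nrmsep(d$y, pred, d$censored, normalization)
  }
  if (skipped > 0) {
    warning(skipped, " repetition(s) skipped: fold too small to fit")
    if (skipped > 0.2 * reps) stop("more than 20% of CV repetitions unusable")
  }
  structure(list(spec = spec, nrmsep_values = vals,
                 median_nrmsep = stats::median(vals, na.rm = TRUE),
                 n_terms = n_terms(spec)),
            class = "cv_result")
}

stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (g in unique(strata)) {
    idx <- which(strata == g)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))  # balanced within stratum
  }
  fold
}

#' Two-step model selection rule
#'
#' Step 1: find the lowest median cross-validated error m*. Step 2: among
#' candidates whose median is within three percent of m* (median <= 1.03 m*,
#' relative because error scale varies by marker), choose the one with the
#' fewest explanatory-variable terms (design columns excluding the
#' intercept). Ties on terms break by lower median, then by candidate order.
#'
#' @param cv_results list of \code{cv_result}.
#' @param tolerance parsimony window as a fraction of the minimum median
#'   (default 0.03).
#' @return the selected \code{cv_result}.
#' @export
select_model <- function(cv_results, tolerance = 0.03) {
  if (length(cv_results) == 0) stop("no cross-validation results")
  med <- vapply(cv_results, function(r) r$median_nrmsep, numeric(1))
  trm <- vapply(cv_results, function(r) r$n_terms, numeric(1))
  m_star <- min(med)
  win <- which(med <= (1 + tolerance) * m_star)
  win <- win[order(trm[win], med[win], win)]
  cv_results[[win[1]]]
}

#' Fit and select models for every marker and regime
#'
#' For each marker and each of the three regimes (CSO-only, non-CSO,
#' combined): enumerate candidates, cross-validate each, select by the
#' two-step rule and refit the winner on the full regime data. Eight markers
#' by three regimes gives the 24 model scenarios of the full analysis.
#'
#' @param samples discrete-sample data.frame.
#' @param covariates named list of covariate \code{wq_ts}.
#' @param markers markers to model (default: those present in samples).
#' @param regimes regime labels to fit.
#' @param pool optical variable pool for enumeration.
#' @param k,reps,seed,tolerance,normalization cross-validation and selection
#'   settings.
#' @return list of class \code{selection_report}: \code{report} (one row per
#'   scenario with x-marks per variable and median error), \code{models}
#'   (named list of fitted \code{fib_model}, keys "marker|regime"),
#'   \code{cv} (all cv_result lists).
#' @export
fit_all_regimes <- function(samples, covariates,
                            markers = unique(samples$marker),
                            regimes = c("CSO", "nonCSO", "combined"),
                            pool = optical_pool(), k = 5, reps = 50,
                            seed = 1, tolerance = 0.03,
                            normalization = "none") {
  rows <- list(); models <- list(); cvs <- list()
  seeds <- with_seed(seed, sample.int(2147483000L,
                                      length(markers) * length(regimes)))
  i <- 0L
  for (mk in markers) for (rg in regimes) {
    i <- i + 1L
    key <- paste(mk, rg, sep = "|")
    cands <- enumerate_candidates(mk, pool = pool, regime = rg)
    scenario <- tryCatch({
      cv <- lapply(seq_along(cands), function(j)
        cross_validate(samples, covariates, cands[[j]], k = k, reps = reps,
                       seed = (seeds[i] + j) %% 2147483000L,
                       normalization = normalization))
      best <- select_model(cv, tolerance = tolerance)
      model <- fit_surrogate(samples, covariates, best$spec)
      list(cv = cv, best = best, model = model)
    }, error = function(e) e)
    if (inherits(scenario, "error")) {
      warning("scenario ", key, " unfit: ", conditionMessage(scenario))
      rows[[i]] <- data.frame(marker = mk, regime = rg,
                              `S1-CF` = "", `S1-A` = "", `S2-F` = "",
                              turbidity = "", flow = "",
                              median_nrmsep = NA_real_, fitted = FALSE,
                              check.names = FALSE)
      next
    }
    sp <- scenario$best$spec
    rows[[i]] <- data.frame(
      marker = mk, regime = rg,
      `S1-CF` = if ("S1-CF" %in% sp$opticals) "x" else "",
      `S1-A` = if ("S1-A" %in% sp$opticals) "x" else "",
      `S2-F` = if ("S2-F" %in% sp$opticals) "x" else "",
      turbidity = if (sp$turbidity) "x" else "",
      flow = if (sp$flow) "x" else "",
      median_nrmsep = scenario$best$median_nrmsep, fitted = TRUE,
      check.names = FALSE)
    models[[key]] <- scenario$model
    cvs[[key]] <- scenario$cv
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, models = models, cv = cvs),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d scenarios (%d fitted)\n",
              nrow(x$report), sum(x$report$fitted)))
  print(x$report, row.names = FALSE)
  invisible(x)
}
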