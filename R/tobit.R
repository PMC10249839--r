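#' Left-censored Gaussian (Tobit) regression by maximum likelihood
#'
#' Fits y = X beta + e, e ~ Normal(0, sigma^2), where some responses are known
#' only to lie at or below a detection limit. Uncensored points contribute the
#' Normal density to the likelihood; left-censored points contribute the
#' Normal CDF at the (log10) detection limit. Optimization is quasi-Newton
#' (BFGS) on (beta, log sigma) with analytic gradients, initialized at
#' ordinary least squares on the uncensored points; when nothing is censored
#' the OLS solution is the exact MLE and is returned directly (sigma without
#' degrees-of-freedom correction, for likelihood consistency).
#'
#' @param X design matrix (n x p), first column typically an intercept.
#' @param y numeric response (log10 concentrations).
#' @param censored logical vector; TRUE where the response is left-censored.
#' @param limit numeric detection limits on the response scale for censored
#'   rows; defaults to \code{y} itself (the convention that censored values
#'   are stored at their limit).
#' @param reltol relative log-likelihood convergence tolerance.
#' @return object of class \code{fib_tobit} with elements beta, sigma,
#'   logLik, residuals (uncensored rows only, NA elsewhere), fitted, n_obs,
#'   n_censored, converged.
#' @export
tobit_fit <- function(X, y, censored = rep(FALSE, length(y)), limit = y,
                      reltol = 1e-8) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n || length(censored) != n) stop("X, y, censored lengths differ")
  if (all(censored)) stop("all observations censored: model unidentifiable")
  if (sum(!censored) < p + 2)
    stop("need at least ", p + 2, " uncensored observations for ", p, " columns")
  u <- !censored
  ols <- stats::lm.fit(X[u, , drop = FALSE], y[u])
  if (ols$rank < p) stop("singular design matrix")
  beta0 <- ols$coefficients
  rss <- sum(ols$residuals^2)
  sigma0 <- sqrt(rss / sum(u))
  if (sigma0 <= 0) sigma0 <- 1e-6

  make_fit <- function(beta, sigma, ll, converged) {
    fitted <- drop(X %*% beta)
    res <- rep(NA_real_, n)
    res[u] <- y[u] - fitted[u]
    structure(list(beta = stats::setNames(beta, colnames(X)),
                   sigma = unname(sigma),
                   logLik = ll, residuals = res, fitted = fitted,
                   censored = censored, n_obs = n, n_censored = sum(censored),
                   converged = converged),
              class = "fib_tobit")
  }

  if (!any(censored)) {
    ll <- sum(stats::dnorm(y - drop(X %*% beta0), 0, sigma0, log = TRUE))
    return(make_fit(beta0, sigma0, ll, TRUE))
  }

  L <- limit
  nll <- function(par) {
    beta <- par[1:p]; sigma <- exp(par[p + 1])
    mu <- drop(X %*% beta)
    z <- (y[u] - mu[u]) / sigma
    a <- (L[!u] - mu[!u]) / sigma
    -(sum(stats::dnorm(z, log = TRUE) - log(sigma)) +
        sum(stats::pnorm(a, log.p = TRUE)))
  }
  gnll <- function(par) {
    beta <- par[1:p]; sigma <- exp(par[p + 1])
    mu <- drop(X %*% beta)
    z <- (y[u] - mu[u]) / sigma
    a <- (L[!u] - mu[!u]) / sigma
    lambda <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
    gb <- -drop(crossprod(X[u, , drop = FALSE], z)) / sigma +
      drop(crossprod(X[!u, , drop = FALSE], lambda)) / sigma
    gs <- sum(1 - z^2) + sum(lambda * a)
    c(gb, gs)
  }
  par0 <- c(beta0, log(sigma0))
  opt <- stats::optim(par0, nll, gnll, method = "BFGS",
                      control = list(maxit = 500, reltol = reltol))
  ll0 <- -nll(par0)
  ll <- -opt$value
  if (opt$convergence != 0 && !is.finite(ll))
    stop("censored-Gaussian fit did not converge (optim code ",
         opt$convergence, ")")
  if (ll < ll0 - 1e-8) {  # never accept a fit worse than the OLS start
    opt$par <- par0; ll <- ll0
  }
  make_fit(opt$par[1:p], exp(opt$par[p + 1]), ll, opt$convergence == 0)
}

#' @export
print.fib_tobit <- function(x, ...) {
  cat(sprintf("<fib_tobit> n=%d (%d censored), sigma=%.4g, logLik=%.4g\n",
              x$n_obs, x$n_censored, x$sigma, x$logLik))
  print(signif(x$beta, 5))
  invisible(x)
}

#' @export
coef.fib_tobit <- function(object, ...) object$beta

#' @export
logLik.fib_tobit <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) + 1, class = "logLik")
}

#' @export
residuals.fib_tobit <- function(object, ...) object$residuals

#' @export
summary.fib_tobit <- function(object, ...) {
  cat(sprintf("Censored Gaussian regression: %d obs, %d left-censored\n",
              object$n_obs, object$n_censored))
  cat(sprintf("Residual scale sigma = %.4g (log10 units), logLik = %.4g\n",
              object$sigma, object$logLik))
  print(signif(object$beta, 5))
  invisible(object)
}

#' @export
predict.fib_tobit <- function(object, newX, type = c("link", "response"),
                              smearing = NULL, ...) {
  type <- match.arg(type)
  newX <- as.matrix(newX)
  if (ncol(newX) != length(object$beta))
    stop("design has ", ncol(newX), " columns; model expects ",
         length(object$beta))
  eta <- drop(newX %*% object$beta)
  if (type == "link") return(eta)
  D <- if (is.null(smearing)) smearing_factor(stats::na.omit(object$residuals))
       else smearing
  D * 10^eta
}

#' Duan smearing factor for log10 models
#'
#' Nonparametric retransformation bias correction: the mean of 10^e over the
#' model's uncensored residuals e. Always at least 10^mean(e) by Jensen's
#' inequality.
#'
#' @param residuals numeric vector of uncensored log10-scale residuals.
#' @return the smearing factor D (unitless, >= 1 when residuals center at 0).
#' @export
smearing_factor <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) == 0) stop("no uncensored residuals for smearing factor")
  mean(10^residuals)
}

#' Fit a surrogate model for one marker and regime
#'
#' Builds the canonical design from the discrete samples, fits the
#' left-censored Gaussian regression, and attaches the prediction-stage
#' quantities: the smearing factor and the calibration maximum (largest
#' uncensored observed concentration, linear units), beyond which
#' estimation-stage predictions are capped.
#'
#' @param samples discrete-sample data.frame.
#' @param covariates named list of covariate \code{wq_ts}.
#' @param spec a \code{\link{model_spec}}.
#' @return object of class \code{fib_model}: the \code{fib_tobit} elements
#'   plus spec, D, calibration_max.
#' @export
fit_surrogate <- function(samples, covariates, spec) {
  d <- build_design(samples, covariates, spec)
  fit <- tobit_fit(d$X, d$y, d$censored, limit = d$detection_limit)
  fit$spec <- spec
  fit$D <- smearing_factor(stats::na.omit(fit$residuals))
  fit$calibration_max <- max(10^d$y[!d$censored])
  class(fit) <- c("fib_model", class(fit))
  fit
}

#' @export
print.fib_model <- function(x, ...) {
  cat(sprintf("<fib_model> %s [%s]\n", x$spec$marker, x$spec$regime))
  NextMethod()
  cat(sprintf("  smearing D=%.4f, calibration max=%.4g\n",
              x$D, x$calibration_max))
  invisible(x)
}

#' Predict concentrations from a fitted surrogate model
#'
#' Smeared back-transform D * 10^(x beta) at arbitrary timestamps, using the
#' model's own spec to assemble design rows from covariate series. No
#' calibration-range capping is applied here; capping is estimation-stage
#' policy (see \code{\link{estimate_continuous}}).
#'
#' @param object a \code{fib_model}.
#' @param covariates named list of covariate \code{wq_ts}.
#' @param times POSIXct timestamps (default: the full grid of the first
#'   covariate).
#' @param ... unused.
#' @return numeric vector of concentrations in linear units.
#' @export
predict.fib_model <- function(object, covariates, times = NULL, ...) {
  if (is.null(times)) times <- ts_times(covariates[[1]])
  X <- design_matrix(covariates, times, object$spec)
  object$D * 10^drop(X %*% object$beta)
}

#' Serialize a fitted surrogate model to JSON
#' @param model a \code{fib_model}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(spec = unclass(model$spec),
              beta = as.list(model$beta), sigma = model$sigma,
              smearing = model$D, calibration_max = model$calibration_max,
              n_obs = model$n_obs, n_censored = model$n_censored)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
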