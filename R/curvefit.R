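#' @include AllClasses.R
NULL

curveModels <- list(
  # survival-style Weibull tail: a * exp(-(m/lambda)^k)
  weibull = list(
    fn = function(par, x) par[["a"]] * exp(-(x / par[["lambda"]])^par[["k"]]),
    start = function(x, y, meanMatch) {
      c(a = max(y[1], 1e-3), lambda = meanMatch + 0.5, k = 1)
    },
    lower = c(a = 1e-8, lambda = 1e-8, k = 1e-8),
    upper = c(a = 1, lambda = Inf, k = Inf)
  ),
  # logistic decay: a / (1 + exp((m - x0)/s))
  sigmoid = list(
    fn = function(par, x) par[["a"]] / (1 + exp((x - par[["x0"]]) / par[["s"]])),
    start = function(x, y, meanMatch) {
      c(a = max(y[1], 1e-3), x0 = stats::median(x), s = 1)
    },
    lower = c(a = 1e-8, x0 = -Inf, s = 1e-8),
    upper = c(a = 2, x0 = Inf, s = Inf)
  )
)

#' Fit a Weibull or sigmoid curve to a null reverse cumulative
#'
#' Nonlinear least squares (Levenberg-Marquardt with box bounds, via
#' \pkg{minpack.lm}) of a three-parameter tail model to the reverse
#' cumulative of the expected frequencies over m = 0..M. Models:
#' Weibull `a * exp(-(m/lambda)^k)` and sigmoid `a / (1 + exp((m-x0)/s))`.
#' Starting values are fixed and documented: `a = R(0)`,
#' `lambda = mean match count + 0.5`, `k = 1` (Weibull); `a = R(0)`,
#' `x0 = median support`, `s = 1` (sigmoid); the fit is deterministic
#' given the data.
#'
#' A null whose reverse cumulative has fewer than three points strictly
#' between 0 and 1 (e.g. all mass at m = 0) cannot constrain three
#' parameters; the fit is returned with `wellConstrained = FALSE`.
#'
#' @param null A [NullDistribution] (or a bare numeric vector of reverse
#'   cumulative values over m = 0..M).
#' @param family `"weibull"` or `"sigmoid"`.
#' @param start Optional named vector overriding the documented starting
#'   values (e.g. to warm-start from a previous fit).
#' @return A [CurveFit].
#' @export
fitCurve <- function(null, family = c("weibull", "sigmoid"),
                     start = NULL) {
  family <- match.arg(family)
  if (is(null, "NullDistribution")) {
    y <- as.numeric(reverseCumulative(null))
    meanMatch <- sum((0:null@M) * null@EF)
  } else {
    y <- as.numeric(null)
    pmf <- c(-diff(y), y[length(y)])
    meanMatch <- sum((seq_along(y) - 1L) * pmf)
  }
  x <- seq_along(y) - 1
  if (length(y) < 3L)
    stop("need at least 3 support points to fit a 3-parameter curve",
         call. = FALSE)
  model <- curveModels[[family]]
  if (is.null(start)) start <- model$start(x, y, meanMatch)
  else start <- start[names(model$lower)]
  resid <- function(par) {
    names(par) <- names(start)
    y - model$fn(par, x)
  }
  fit <- minpack.lm::nls.lm(par = start, lower = model$lower,
                            upper = model$upper, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 5000))
  converged <- fit$info %in% 1:4
  par <- stats::setNames(as.numeric(fit$par), names(start))
  fitted <- model$fn(par, x)
  sse <- sum((y - fitted)^2)
  if (!converged)
    warning(family, " fit did not converge (info = ", fit$info,
            "); best-found parameters returned", call. = FALSE)
  interior <- sum(y > 1e-12 & y < 1 - 1e-12)
  new("CurveFit", family = family, params = par, sse = sse,
      fitted = fitted, data = y, converged = converged,
      wellConstrained = interior >= 3L)
}

#' Rank curve fits by goodness of fit
#'
#' Orders fits of the same data by increasing sum of squared residuals;
#' exact ties are broken alphabetically by family name (stable).
#'
#' @param fits List of [CurveFit] objects fitted to identical data.
#' @return A data.frame with columns `family`, `sse`, `converged` and
#'   `rank`, best fit first.
#' @export
compareFits <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, is, logical(1), "CurveFit")))
  if (length(fits) > 1L) {
    ref <- fits[[1]]@data
    same <- vapply(fits, function(f) isTRUE(all.equal(f@data, ref)),
                   logical(1))
    if (!all(same))
      stop("fits must be computed on identical data", call. = FALSE)
  }
  fam <- vapply(fits, function(f) f@family, character(1))
  sse <- vapply(fits, function(f) f@sse, numeric(1))
  conv <- vapply(fits, function(f) f@converged, logical(1))
  ord <- order(sse, fam)
  data.frame(family = fam[ord], sse = sse[ord], converged = conv[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Write curve-fit summaries and plot-ready fitted curves
#'
#' @param fits List of [CurveFit] objects.
#' @param summaryPath TSV of family, parameters, sse, convergence.
#' @param curvePath Optional TSV of (m, data, fitted) per family for
#'   plotting.
#' @return Invisibly, the summary data.frame.
#' @export
writeFitSummary <- function(fits, summaryPath, curvePath = NULL) {
  df <- data.frame(
    family = vapply(fits, function(f) f@family, character(1)),
    params = vapply(fits, function(f)
      paste(sprintf("%s=%.6g", names(f@params), f@params),
            collapse = ";"), character(1)),
    sse = vapply(fits, function(f) f@sse, numeric(1)),
    converged = vapply(fits, function(f) f@converged, logical(1)),
    well_constrained = vapply(fits, function(f) f@wellConstrained,
                              logical(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, summaryPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(curvePath)) {
    curves <- do.call(rbind, lapply(fits, function(f) {
      data.frame(family = f@family, m = seq_along(f@data) - 1L,
                 data = f@data, fitted = f@fitted)
    }))
    utils::write.table(curves, curvePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(df)
}
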