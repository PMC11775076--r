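# Binomial logistic psychometric fitting.
#
# The model is logit P(alcohol) = beta * (x - alpha): location-slope
# parameterisation, so the PSE (alpha) is a parameter rather than the ratio
# -intercept/slope of a reparameterised GLM. Internally we fit intercept and
# slope on the standardized predictor by Newton scoring (IRLS), vectorised
# over many count vectors at once so that parametric-bootstrap refits of
# thousands of replicates cost one pass of matrix arithmetic. A weak ridge
# penalty on the standardized slope handles separated data (all-or-none
# proportions), which individual subjects routinely produce.

# Vectorised Newton/IRLS for R binomial regressions sharing one design.
#  K: R x m matrix of success counts; n: length-m trials per design point;
#  x: length-m distinct predictor values; ridge: penalty on the standardized
#  slope. Returns location/slope on the original scale per row.
irls_many <- function(K, n, x, ridge = 0, max_iter = 60, tol = 1e-9) {
  K <- as.matrix(K)
  m <- length(x)
  stopifnot(ncol(K) == m, length(n) == m)
  mx <- mean(x)
  sx <- sd(x)
  if (!is.finite(sx) || sx == 0)
    stop_ccaf("predictor has fewer than 2 distinct values; slope unidentifiable")
  xs <- (x - mx) / sx
  N <- matrix(n, nrow(K), m, byrow = TRUE)

  el <- log((K + 0.5) / (N - K + 0.5))
  c1 <- drop(el %*% xs) / sum(xs^2)
  c0 <- rowMeans(el)
  conv <- rep(FALSE, nrow(K))

  for (it in seq_len(max_iter)) {
    eta <- outer(c0, rep(1, m)) + outer(c1, xs)
    mu <- plogis(eta)
    res <- K - N * mu
    w <- pmax(N * mu * (1 - mu), 1e-12)
    g0 <- rowSums(res)
    g1 <- drop(res %*% xs) - 2 * ridge * c1
    h00 <- rowSums(w)
    h01 <- drop(w %*% xs)
    h11 <- drop(w %*% (xs^2)) + 2 * ridge
    det <- pmax(h00 * h11 - h01^2, 1e-300)
    d0 <- (h11 * g0 - h01 * g1) / det
    d1 <- (h00 * g1 - h01 * g0) / det
    # cap the Newton step: protects against overshoot on near-separated data
    bad <- !is.finite(d0) | !is.finite(d1)
    d0[bad] <- 0; d1[bad] <- 0
    step <- pmax(abs(d0), abs(d1))
    damp <- ifelse(step > 4, 4 / step, 1)
    c0 <- c0 + damp * d0
    c1 <- c1 + damp * d1
    conv <- conv | (step < tol & !bad)
    if (all(conv)) break
  }
  eta <- outer(c0, rep(1, m)) + outer(c1, xs)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  ll <- rowSums(K * log(mu) + (N - K) * log1p(-mu))
  # |c1| > 15 on the standardized scale flags (near-)separation for the
  # unpenalised fit; with a ridge active the penalty itself bounds the
  # slope, so only true non-convergence counts as divergence
  list(c0 = c0, c1 = c1,
       alpha = mx - c0 * sx / c1, beta = c1 / sx,
       converged = conv,
       diverged = !conv | (ridge == 0 & abs(c1) > 15),
       loglik = ll, mx = mx, sx = sx)
}

# pooled counts per distinct predictor value
pool_counts <- function(k, n, x) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; x <- x[keep]
  ux <- sort(unique(x))
  list(k = as.vector(rowsum(k, factor(x, levels = ux))),
       n = as.vector(rowsum(n, factor(x, levels = ux))),
       x = ux)
}

#' Fit a logistic psychometric function to choice counts
#'
#' Maximises the binomial log-likelihood
#' \deqn{\sum_j k_j \log p_j + (n_j - k_j)\log(1 - p_j), \quad
#'       p_j = \mathrm{logit}^{-1}(\beta (x_j - \alpha))}
#' over the location `alpha` (the point of subjective equality) and slope
#' `beta`. Counts sharing a predictor value are pooled (binomial weights).
#' When the data are separated (e.g. every observed proportion is 0 or 1, so
#' the unpenalised slope diverges) the fit is repeated with a weak ridge
#' penalty `ridge` on the standardized slope and flagged via
#' `separation_flag`; the flagged estimates are finite but should be treated
#' as bounded summaries, not maximum-likelihood estimates.
#'
#' @param data data frame with columns `k` (alcohol choices), `n` (responded
#'   trials) and the predictor named by `predictor`; typically a
#'   [aggregate_choices()] summary, possibly subset to one group, one subject
#'   or one level. Rows with `n = 0` are dropped.
#' @param predictor name of the predictor column: the relative point level
#'   for choice curves (default), or `"audit"` for severity curves.
#' @param ridge ridge penalty applied on separation (default `1e-4` on the
#'   standardized slope).
#' @param scope optional label (`"group"`, `"subject"`, `"covariate"`)
#'   recorded in the fit.
#' @return An object of class `"psychfit"`: a list with elements
#'   `coefficients` (`alpha`, `beta`), `intercept_slope` (the equivalent
#'   intercept-slope parameterisation), `loglik`, `converged`,
#'   `separation_flag`, `ridge_used`, `data`, `predictor`, `scope`. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `predict`, `fitted`, `residuals`
#'   (deviance), `plot`, `simulate`, `confint` (parametric bootstrap).
#' @examples
#' d <- data.frame(relative_point_level = c(-2, 0, 2),
#'                 k = c(4, 16, 28), n = 32)
#' fit <- fit_psychometric(d)
#' coef(fit)
#' predict(fit, newdata = c(-2, 0, 2))
#' @seealso [interpolate_pse()], [parametric_bootstrap()],
#'   [fit_vs_covariate()]
#' @export
fit_psychometric <- function(data, predictor = "relative_point_level",
                             ridge = 1e-4, scope = NULL) {
  need <- c("k", "n", predictor)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_ccaf("data lacks column(s): ", paste(miss, collapse = ", "))
  pc <- pool_counts(data$k, data$n, data[[predictor]])
  if (length(pc$x) < 2)
    stop_ccaf("need >= 2 distinct predictor values to identify a slope")

  props <- pc$k / pc$n
  if (all(props == 1) || all(props == 0)) {
    # constant all-or-none choice: the direction of preference is
    # unambiguous but no finite location exists and the slope is
    # unidentified; return an explicit boundary fit
    return(structure(list(
      coefficients = c(alpha = if (all(props == 1)) -Inf else Inf,
                       beta = 0),
      intercept_slope = c(intercept = if (all(props == 1)) Inf else -Inf,
                          slope = 0),
      loglik = sum(lchoose(pc$n, pc$k)),
      converged = FALSE, separation_flag = TRUE, ridge_used = 0,
      data = data.frame(x = pc$x, k = pc$k, n = pc$n),
      predictor = predictor, scope = scope %||% "group",
      call = match.call()
    ), class = "psychfit"))
  }
  degenerate <- all(props %in% c(0, 1))
  res <- irls_many(matrix(pc$k, 1), pc$n, pc$x, ridge = 0)
  separated <- degenerate || res$diverged[1]
  ridge_used <- 0
  if (separated) {
    res <- irls_many(matrix(pc$k, 1), pc$n, pc$x, ridge = ridge)
    ridge_used <- ridge
  }
  structure(list(
    coefficients = c(alpha = res$alpha[1], beta = res$beta[1]),
    intercept_slope = c(intercept = -res$alpha[1] * res$beta[1],
                        slope = res$beta[1]),
    loglik = res$loglik[1] + sum(lchoose(pc$n, pc$k)),
    converged = res$converged[1],
    separation_flag = separated,
    ridge_used = ridge_used,
    data = data.frame(x = pc$x, k = pc$k, n = pc$n),
    predictor = predictor,
    scope = scope %||% "group",
    call = match.call()
  ), class = "psychfit")
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = sum(object$data$n),
            class = "logLik")
}

#' @export
print.psychfit <- function(x, digits = 4, ...) {
  cat("Logistic psychometric fit (", x$scope, " scope, predictor: ",
      x$predictor, ")\n", sep = "")
  cat("  PSE (alpha): ", signif(x$coefficients["alpha"], digits),
      "   slope (beta): ", signif(x$coefficients["beta"], digits), "\n",
      sep = "")
  cat("  log-likelihood:", signif(x$loglik, digits + 2), "\n")
  if (x$separation_flag)
    cat("  NOTE: separated data; ridge-penalised estimates (lambda =",
        x$ridge_used, ")\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  print(object)
  cat("\nPooled counts:\n")
  d <- object$data
  d$prop <- round(d$k / d$n, 4)
  print.data.frame(d, row.names = FALSE)
  invisible(object)
}

#' @rdname fit_psychometric
#' @param object,x a `psychfit` object.
#' @param newdata numeric vector of predictor values (or a data frame with
#'   the predictor column); defaults to the design points of the fit.
#' @param type `"response"` for probabilities, `"link"` for logits.
#' @param ... unused.
#' @export
predict.psychfit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  xx <- if (is.null(newdata)) object$data$x
        else if (is.data.frame(newdata)) newdata[[object$predictor]]
        else newdata
  alpha <- object$coefficients["alpha"]
  if (!is.finite(alpha)) {
    # boundary fit from constant all-or-none data
    eta <- rep(if (alpha < 0) Inf else -Inf, length(xx))
  } else {
    eta <- object$coefficients["beta"] * (xx - alpha)
  }
  if (type == "link") unname(eta) else unname(plogis(eta))
}

#' @export
fitted.psychfit <- function(object, ...) predict(object)

#' @export
residuals.psychfit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  d <- object$data
  p <- predict(object)
  if (type == "pearson")
    return((d$k - d$n * p) / sqrt(d$n * p * (1 - p)))
  mu <- pmin(1 - 1e-12, pmax(1e-12, p))
  obs <- pmin(1 - 1e-12, pmax(1e-12, d$k / d$n))
  dev <- 2 * (d$k * log(obs / mu) +
                (d$n - d$k) * log((1 - obs) / (1 - mu)))
  sign(d$k / d$n - p) * sqrt(pmax(dev, 0))
}

#' @rdname fit_psychometric
#' @param nsim number of parametric datasets to draw.
#' @param seed optional integer seed.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$data
  p <- predict(object)
  with_seed(seed, {
    out <- as.data.frame(matrix(
      rbinom(nsim * nrow(d), size = rep(d$n, each = nsim),
             prob = rep(p, each = nsim)),
      nrow = nrow(d), byrow = TRUE))
    names(out) <- paste0("sim_", seq_len(nsim))
    cbind(d[c("x", "n")], out)
  })
}

#' @export
plot.psychfit <- function(x, xlab = x$predictor,
                          ylab = "% alcohol choice", ...) {
  d <- x$data
  xr <- range(d$x) + c(-0.5, 0.5) * diff(range(d$x)) / 4
  xx <- seq(xr[1], xr[2], length.out = 200)
  graphics::plot(xx, 100 * predict(x, xx), type = "l",
                 ylim = c(0, 100), xlab = xlab, ylab = ylab, ...)
  graphics::points(d$x, 100 * d$k / d$n, pch = 19)
  graphics::abline(h = 50, lty = 3)
  graphics::abline(v = x$coefficients["alpha"], lty = 3)
  invisible(x)
}

#' Interpolate the point of subjective equality from a fit
#'
#' In the location-slope parameterisation the relative point level at which
#' alcohol and snack are equally likely to be chosen is the location
#' parameter itself, so interpolation is the identity; for an
#' intercept-slope fit it equals `-intercept/slope`. Errors when the fit did
#' not converge or a separated fit produced an unbounded estimate.
#'
#' @param fit a [fit_psychometric()] object.
#' @return The PSE, a single number on the predictor scale.
#' @export
interpolate_pse <- function(fit) {
  stopifnot(inherits(fit, "psychfit"))
  alpha <- unname(fit$coefficients["alpha"])
  if (!fit$converged || !is.finite(alpha))
    stop_ccaf("cannot interpolate the PSE: fit ",
              if (!fit$converged) "did not converge" else
                "is separated with an unbounded location estimate",
              " (alpha = ", alpha, ", separation_flag = ",
              fit$separation_flag, ")")
  alpha
}

#' Fit pooled psychometric curves per group or per subject
#'
#' Convenience wrappers around [fit_psychometric()]: `fit_group_curves()`
#' pools choice counts over all subjects within each drinking group (binomial
#' weights) and fits one curve per group; `fit_subject_curves()` fits each
#' subject's own 3-point count table, with no pooling across subjects.
#'
#' @param summary a [aggregate_choices()] data frame (needs a `group` column
#'   for the group version).
#' @param ... passed to [fit_psychometric()].
#' @return A named list of `psychfit` objects.
#' @export
fit_group_curves <- function(summary, ...) {
  if (!"group" %in% names(summary))
    stop_ccaf("summary data lacks a 'group' column")
  parts <- split(as.data.frame(summary), summary$group)
  lapply(parts, fit_psychometric, scope = "group", ...)
}

#' @rdname fit_group_curves
#' @export
fit_subject_curves <- function(summary, ...) {
  parts <- split(as.data.frame(summary), summary$subject_id)
  lapply(parts, fit_psychometric, scope = "subject", ...)
}

# Reference-route fit through stats::glm in the intercept-slope
# parameterisation, converted algebraically to location-slope. Used as an
# internal cross-check of the Newton engine.
fit_binom_glm <- function(k, n, x) {
  fit <- glm(cbind(k, n - k) ~ x, family = binomial())
  b <- coef(fit)
  c(alpha = unname(-b[1] / b[2]), beta = unname(b[2]))
}
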