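## The logistic meta-model.  The probability that a hexapeptide is a hot
## spot is modelled as plogis(b0 + sum_j b_j S_j) where the S_j are
## component scorer outputs.  Coefficients are maximum-likelihood estimates
## obtained by iteratively reweighted least squares with step-halving, so
## the log-likelihood is non-decreasing across iterations.

#' Fitting control parameters
#'
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum number of IRLS iterations.
#' @return A list of control parameters.
#' @export
meta_control <- function(tol = 1e-8, maxit = 100L) {
  stopifnot(tol > 0, maxit >= 1L)
  list(tol = tol, maxit = as.integer(maxit))
}

## stable Bernoulli log-likelihood at linear predictor eta
bernoulli_loglik <- function(eta, y) {
  sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
}

## IRLS core.  X includes the intercept column.  Step-halving guarantees a
## monotone log-likelihood path (recorded in `trace`).
irls_logistic <- function(X, y, tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("collinear columns in design matrix: ",
         paste(dep, collapse = ", "))
  }
  beta <- numeric(p)
  ## start the intercept at the empirical log-odds
  pos <- mean(y)
  beta[1] <- log(pos / (1 - pos))
  ll <- bernoulli_loglik(drop(X %*% beta), y)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * sw), z * sw)
    ll_new <- bernoulli_loglik(drop(X %*% beta_new), y)
    ## step-halve back towards the current estimate if the full Newton
    ## step decreases the likelihood
    half <- 0L
    while (ll_new < ll && half < 30L) {
      beta_new <- (beta + beta_new) / 2
      ll_new <- bernoulli_loglik(drop(X %*% beta_new), y)
      half <- half + 1L
    }
    delta <- abs(ll_new - ll) / (abs(ll) + 0.1)
    beta <- beta_new
    ll <- ll_new
    trace <- c(trace, ll)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  ## complete/quasi-complete separation: fitted values collapse onto the
  ## labels and the likelihood approaches 0
  separation <- ll > -1e-6 || (max(abs(beta)) > 25 && min(w) < 1e-9)
  info <- crossprod(X * sqrt(pmax(w, 1e-12)))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p, dimnames = dimnames(info))
  })
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       loglik = ll, loglik_trace = trace,
       converged = converged && !separation,
       separation = separation, iter = iter,
       vcov = vc, fitted.values = mu)
}

## Resolve a plain-column formula against a data frame: the response name
## and the predictor column names (`.` expands to all other columns).
parse_meta_formula <- function(formula, data) {
  tt <- stats::terms(formula, data = data)
  if (attr(tt, "response") != 1L) stop("formula needs a response (the label)")
  response <- as.character(attr(tt, "variables"))[2L]
  predictors <- attr(tt, "term.labels")
  missing <- setdiff(c(response, predictors), names(data))
  if (length(missing)) {
    stop("columns not found in data: ", paste(missing, collapse = ", "))
  }
  list(response = response, predictors = predictors)
}

coerce_label <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  as.numeric(y)
}

#' Fit a logistic meta-model of amyloidogenicity
#'
#' Fits the stacked logistic regression
#' \deqn{P(Y = 1 \mid S) = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j S_j)}
#' where the \eqn{S_j} are component predictor scores (one column per
#' scorer) and \eqn{Y} is the binary amyloid label.  Coefficients are
#' maximum-likelihood estimates (IRLS with step-halving).  With
#' `select = "stepwise"` the component set is chosen by bidirectional
#' stepwise search minimizing BIC, starting from the intercept-only model
#' (see [stepwise_bic()]).
#'
#' The formula must use plain column names (e.g. `label ~ .` or
#' `label ~ hydropathy + core_pssm`); predictions of a fitted (or
#' deserialized) model look columns up by name in `newdata`.
#'
#' @param formula model formula; the response is the binary label column.
#' @param data data frame of component scores plus the label column
#'   (e.g. from [compute_features()] cbound to a label).
#' @param select `"none"` (fit all formula predictors) or `"stepwise"`
#'   (bidirectional BIC search over the formula predictors).
#' @param standardize logical; standardize score columns to mean 0 / sd 1
#'   before fitting.  The transform is recorded in the model and replayed on
#'   `newdata` at prediction time.
#' @param control see [meta_control()].
#' @return An object of class `"amylometa"` with components
#'   `coefficients`, `vcov`, `loglik`, `loglik_trace`, `converged`,
#'   `separation`, `n`, `n_pos`, `n_neg`, `standardize` (transform record or
#'   `NULL`), `selection` (stepwise trace or `NULL`), `fitted.values`, `y`.
#'   Supports `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `simulate`, `plot`, `logLik` (hence `AIC`/`BIC`).
#' @examples
#' d <- gen_features_from_logistic(400, beta0 = -1,
#'                                 beta = c(s1 = 0.8, s2 = -0.5), seed = 1)
#' fit <- amylometa(label ~ ., d)
#' coef(fit)
#' head(predict(fit, d))
#' @export
amylometa <- function(formula, data, select = c("none", "stepwise"),
                      standardize = FALSE, control = meta_control()) {
  select <- match.arg(select)
  pf <- parse_meta_formula(formula, data)
  y <- coerce_label(data[[pf$response]])
  if (sum(y == 1) < 1L || sum(y == 0) < 1L) {
    stop("training data must contain both classes")
  }
  predictors <- pf$predictors
  X <- as.matrix(data[predictors])
  if (length(predictors) && !is.numeric(X)) {
    stop("all predictor columns must be numeric component scores")
  }
  std_record <- NULL
  if (standardize && length(predictors)) {
    std <- standardize_features(X)
    X <- std$x
    std_record <- list(center = std$center, scale = std$scale)
  }
  selection <- NULL
  if (select == "stepwise" && length(predictors)) {
    sel <- stepwise_bic(cbind(as.data.frame(X),
                              stats::setNames(list(y), pf$response)),
                        response = pf$response, candidates = predictors,
                        control = control)
    selection <- sel$trace
    predictors <- sel$selected
    X <- X[, predictors, drop = FALSE]
  }
  design <- cbind(`(Intercept)` = 1, X)
  fit <- irls_logistic(design, y, tol = control$tol, maxit = control$maxit)
  structure(
    c(fit,
      list(n = length(y), n_pos = sum(y == 1), n_neg = sum(y == 0),
           response = pf$response, scorers = predictors,
           standardize = std_record, selection = selection,
           y = y, call = match.call())),
    class = "amylometa")
}

#' Predicted hot-spot probability
#'
#' Evaluates \eqn{\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j S_j)} on new
#' component scores.  Columns are matched to coefficients by name; a
#' standardization recorded at fit time is replayed.
#'
#' @param object a fitted [amylometa()] model.
#' @param newdata data frame (or matrix) containing one column per model
#'   scorer.  If omitted, fitted values are returned.
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... unused.
#' @return Numeric vector of probabilities (or linear predictors).
#' @export
predict.amylometa <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted.values)
    return(stats::qlogis(object$fitted.values))
  }
  newdata <- as.data.frame(newdata)
  need <- object$scorers
  missing <- setdiff(need, names(newdata))
  if (length(missing)) {
    stop("newdata is missing scorer column(s): ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[need])
  if (length(need) && !is.null(object$standardize)) {
    X <- standardize_features(X, record = object$standardize)$x
  }
  eta <- drop(cbind(1, X) %*%
                object$coefficients[c("(Intercept)", need)])
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
coef.amylometa <- function(object, ...) object$coefficients

#' @export
vcov.amylometa <- function(object, ...) object$vcov

#' @export
logLik.amylometa <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.amylometa <- function(object, ...) object$n

#' @export
print.amylometa <- function(x, digits = 4, ...) {
  cat("Logistic meta-model of amyloidogenicity\n")
  cat("  n =", x$n, "hexapeptides (", x$n_pos, "amyloid /", x$n_neg,
      "non-amyloid )\n")
  if (!is.null(x$selection)) {
    cat("  components selected by stepwise BIC:",
        if (length(x$scorers)) paste(x$scorers, collapse = ", ")
        else "(none)", "\n")
  }
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nlog-likelihood:", format(x$loglik, digits = digits),
      "  BIC:", format(stats::BIC(x), digits = digits), "\n")
  if (x$separation) {
    cat("Warning: (quasi-)complete separation detected;",
        "estimates are unreliable.\n")
  } else if (!x$converged) {
    cat("Warning: IRLS did not converge in", x$iter, "iterations.\n")
  }
  invisible(x)
}

#' @export
summary.amylometa <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 bic = stats::BIC(object), n = object$n,
                 n_pos = object$n_pos, n_neg = object$n_neg,
                 converged = object$converged,
                 separation = object$separation,
                 selection = object$selection,
                 standardized = !is.null(object$standardize)),
            class = "summary.amylometa")
}

#' @export
print.summary.amylometa <- function(x, ...) {
  cat("Logistic meta-model of amyloidogenicity\n")
  cat("  n =", x$n, "(", x$n_pos, "amyloid /", x$n_neg, "non-amyloid )",
      if (x$standardized) " [standardized scores]", "\n\n", sep = " ")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nlog-likelihood:", format(x$loglik), "  BIC:", format(x$bic), "\n")
  if (!is.null(x$selection)) {
    cat("\nStepwise BIC selection trace:\n")
    print(x$selection, row.names = FALSE)
  }
  if (x$separation) cat("\nWarning: (quasi-)complete separation detected.\n")
  invisible(x)
}

#' @export
residuals.amylometa <- function(object,
                                type = c("deviance", "pearson", "response"),
                                ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted.values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu))))
}

#' Simulate labels from a fitted meta-model
#'
#' Draws Bernoulli labels at the model's fitted probabilities.
#'
#' @param object a fitted [amylometa()] model.
#' @param nsim number of simulated label vectors.
#' @param seed RNG seed (optional).
#' @param ... unused.
#' @return A data frame with `nsim` columns of 0/1 labels.
#' @export
simulate.amylometa <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted.values
  out <- with_seed(seed, {
    replicate(nsim, stats::rbinom(length(mu), 1L, mu))
  })
  out <- as.data.frame(matrix(out, ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the training ROC curve of a fitted meta-model
#'
#' @param x a fitted [amylometa()] model.
#' @param ... passed to [plot.roc_curve()].
#' @return The [roc_curve()] of the fitted probabilities, invisibly.
#' @export
plot.amylometa <- function(x, ...) {
  rc <- roc_curve(x$fitted.values, x$y)
  plot(rc, ...)
  invisible(rc)
}
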