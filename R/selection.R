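## Stepwise BIC component selection and cross-validated scores.

fit_subset_bic <- function(X, y, subset, control) {
  design <- cbind(`(Intercept)` = 1,
                  X[, subset, drop = FALSE])
  fit <- irls_logistic(design, y, tol = control$tol, maxit = control$maxit)
  -2 * fit$loglik + length(fit$coefficients) * log(length(y))
}

#' Bidirectional stepwise component selection by BIC
#'
#' Starting from the intercept-only model, every single component addition
#' and single deletion is evaluated at each step; the move with the lowest
#' BIC is accepted if it strictly improves the current BIC, and the search
#' stops when no move improves.  Ties are broken in favour of the move
#' keeping fewer parameters (deletions before additions), then by
#' lexicographic scorer name, making the search deterministic.
#'
#' @param data data frame holding the candidate score columns and the label.
#' @param response name of the binary label column (default `"label"`).
#' @param candidates candidate scorer column names (default: every column
#'   except the response).
#' @param control see [meta_control()].
#' @return A list with `selected` (character vector of kept scorers, in
#'   entry order) and `trace` (data frame of accepted moves with columns
#'   `step`, `action`, `scorer`, `bic_before`, `bic_after`; the BIC column
#'   is strictly decreasing).
#' @examples
#' d <- gen_features_from_logistic(500, beta0 = -1, beta = c(s1 = 1.5),
#'                                 n_noise = 2, seed = 7)
#' stepwise_bic(d)$selected
#' @export
stepwise_bic <- function(data, response = "label", candidates = NULL,
                         control = meta_control()) {
  if (is.null(candidates)) candidates <- setdiff(names(data), response)
  if (!length(candidates)) stop("need at least one candidate scorer")
  y <- coerce_label(data[[response]])
  X <- as.matrix(data[candidates])
  current <- character(0)
  bic_cur <- fit_subset_bic(X, y, current, control)
  trace <- data.frame(step = integer(0), action = character(0),
                      scorer = character(0), bic_before = numeric(0),
                      bic_after = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    ## deletions first, then additions, lexicographic within each: the
    ## first strict improvement of the minimal BIC wins ties
    drops <- sort(current)
    adds <- sort(setdiff(candidates, current))
    moves <- rbind(
      if (length(drops)) data.frame(action = "drop", scorer = drops,
                                    stringsAsFactors = FALSE),
      if (length(adds)) data.frame(action = "add", scorer = adds,
                                   stringsAsFactors = FALSE))
    if (is.null(moves) || !nrow(moves)) break
    moves$bic <- vapply(seq_len(nrow(moves)), function(i) {
      subset <- if (moves$action[i] == "drop") {
        setdiff(current, moves$scorer[i])
      } else {
        c(current, moves$scorer[i])
      }
      fit_subset_bic(X, y, subset, control)
    }, numeric(1))
    best <- which.min(moves$bic)  # ties: first in drop-then-add order
    if (moves$bic[best] >= bic_cur - 1e-10) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, action = moves$action[best], scorer = moves$scorer[best],
      bic_before = bic_cur, bic_after = moves$bic[best],
      stringsAsFactors = FALSE))
    current <- if (moves$action[best] == "drop") {
      setdiff(current, moves$scorer[best])
    } else {
      c(current, moves$scorer[best])
    }
    bic_cur <- moves$bic[best]
  }
  list(selected = current, trace = trace)
}

#' Cross-validated meta-model scores
#'
#' Returns, for every row, the hot-spot probability predicted by a model
#' fitted without that row's fold: leave-one-out by default (`k = NULL` or
#' `k = n`), or seeded k-fold otherwise.  Used to de-bias thresholds and
#' reported performance, since in-sample scores are optimistically biased.
#'
#' @param formula model formula (plain column terms), as in [amylometa()].
#' @param data data frame of component scores plus the label column.
#' @param k number of folds; `NULL` (default) or `n` means leave-one-out.
#' @param seed RNG seed for the fold assignment (ignored for leave-one-out,
#'   which is deterministic).
#' @param standardize as in [amylometa()]; the standardization is
#'   re-estimated inside each training fold.
#' @param control see [meta_control()].
#' @return Numeric vector of held-out probabilities, one per row of `data`.
#' @export
cv_scores <- function(formula, data, k = NULL, seed = 1L,
                      standardize = FALSE, control = meta_control()) {
  pf <- parse_meta_formula(formula, data)
  n <- nrow(data)
  y <- coerce_label(data[[pf$response]])
  if (is.null(k) || k == n) {
    folds <- seq_len(n)
    k <- n
  } else {
    if (k < 2L || k > n) stop("k must be between 2 and n")
    folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  }
  out <- numeric(n)
  for (f in unique(folds)) {
    test <- folds == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L) {
      stop("training fold ", f, " contains a single class; ",
           "use fewer folds")
    }
    fit <- amylometa(formula, data[!test, , drop = FALSE],
                     standardize = standardize, control = control)
    out[test] <- predict(fit, data[test, , drop = FALSE])
  }
  out
}
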