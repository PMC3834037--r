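## JSON serialization of fitted meta-models.  The serialized form carries
## everything prediction needs (coefficient names and values plus the
## standardization record), so a read-back model predicts identically.

#' Serialize a fitted meta-model to JSON
#'
#' @param model a fitted [amylometa()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "amylometa"))
  obj <- list(
    package = "amylometa",
    coefficients = as.list(model$coefficients),
    scorers = model$scorers,
    standardize = if (!is.null(model$standardize)) {
      list(center = as.list(model$standardize$center),
           scale = as.list(model$standardize$scale))
    },
    training = list(n = model$n, n_pos = model$n_pos, n_neg = model$n_neg,
                    loglik = model$loglik, converged = model$converged))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized meta-model
#'
#' @param path path to a JSON file written by [write_model()].
#' @return An `"amylometa"` object supporting [predict.amylometa()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$coefficients)) stop("not a serialized meta-model: ", path)
  coefs <- unlist(obj$coefficients)
  std <- NULL
  if (!is.null(obj$standardize)) {
    std <- list(center = unlist(obj$standardize$center),
                scale = unlist(obj$standardize$scale))
  }
  structure(list(coefficients = coefs,
                 scorers = as.character(obj$scorers %||% setdiff(
                   names(coefs), "(Intercept)")),
                 standardize = std,
                 n = obj$training$n, n_pos = obj$training$n_pos,
                 n_neg = obj$training$n_neg,
                 loglik = obj$training$loglik,
                 converged = isTRUE(obj$training$converged),
                 separation = FALSE,
                 deserialized = TRUE),
            class = "amylometa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
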