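## Component window scorers.  Two generic families cover the usual
## sliding-window amyloid predictors: per-residue scales aggregated over the
## window (FoldAmyloid/AGGRESCAN style) and 6x20 position-specific matrices
## (Waltz style).  Predictors whose algorithms are not expressible in either
## family (e.g. an externally trained SVM) enter as precomputed score tables.

#' Residue-scale window scorer
#'
#' A scorer that assigns each amino acid a real value and aggregates the six
#' residue values of a window by their mean (default) or sum.
#'
#' @param name scorer name (used as the coefficient/column name downstream).
#' @param values named numeric vector of length 20, one value per amino acid.
#' @param aggregation `"mean"` (default; length-independent and comparable
#'   across scales) or `"sum"`.
#' @return An object of class `c("scale_scorer", "scorer")`.
#' @examples
#' sc <- scale_scorer("hydropathy", kd_hydropathy())
#' score_hex(sc, "VLIVLI")
#' @export
scale_scorer <- function(name, values, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  values <- values[AA_ALPHABET]
  if (length(values) != 20L || anyNA(values) || !all(is.finite(values))) {
    stop("scale '", name, "' must provide a finite value for each of the ",
         "20 amino acids")
  }
  names(values) <- AA_ALPHABET
  structure(list(name = name, kind = "scale", aggregation = aggregation,
                 values = values),
            class = c("scale_scorer", "scorer"))
}

#' Position-specific matrix window scorer
#'
#' A scorer defined by a 6 x 20 matrix M; the score of hexapeptide
#' `x` is \eqn{\sum_{p=1}^{6} M[p, x_p]}.
#'
#' @param name scorer name.
#' @param values 6 x 20 numeric matrix with amino-acid column names.
#' @return An object of class `c("pssm_scorer", "scorer")`.
#' @export
pssm_scorer <- function(name, values) {
  values <- as.matrix(values)
  if (nrow(values) != 6L) stop("position matrix must have exactly 6 rows")
  if (is.null(colnames(values)) || !setequal(colnames(values), AA_ALPHABET)) {
    stop("position matrix must have the 20 amino acids as column names")
  }
  values <- values[, AA_ALPHABET, drop = FALSE]
  if (anyNA(values) || !all(is.finite(values))) {
    stop("position matrix '", name, "' contains non-finite values")
  }
  rownames(values) <- as.character(1:6)
  structure(list(name = name, kind = "pssm", values = values),
            class = c("pssm_scorer", "scorer"))
}

#' Precomputed-table window scorer
#'
#' A scorer backed by a lookup table of hexapeptide scores, for predictors
#' whose algorithm cannot be expressed as a scale or position matrix.  The
#' table must cover every queried 6-mer.
#'
#' @param name scorer name.
#' @param scores named numeric vector, names are 6-mers.
#' @return An object of class `c("table_scorer", "scorer")`.
#' @export
table_scorer <- function(name, scores) {
  if (is.null(names(scores)) || any(nchar(names(scores)) != 6L)) {
    stop("'scores' must be a numeric vector named by 6-mers")
  }
  structure(list(name = name, kind = "external",
                 values = scores),
            class = c("table_scorer", "scorer"))
}

#' @export
print.scorer <- function(x, ...) {
  cat("<", x$kind, " scorer '", x$name, "'", sep = "")
  if (x$kind == "scale") cat(", aggregation =", x$aggregation)
  if (x$kind == "external") cat(",", length(x$values), "precomputed 6-mers")
  cat(">\n")
  invisible(x)
}

#' Score hexapeptides with a component scorer
#'
#' Vectorized over `hex`.  Windows containing a residue the scorer cannot
#' score (e.g. `X` under the skip-window policy) yield `NA`.
#'
#' @param scorer a scorer object ([scale_scorer()], [pssm_scorer()],
#'   [table_scorer()]).
#' @param hex character vector of 6-mers.
#' @return Numeric vector of scores, one per element of `hex`.
#' @export
score_hex <- function(scorer, hex) UseMethod("score_hex")

check_hex <- function(hex) {
  if (any(nchar(hex) != 6L)) {
    stop("all peptides must have length 6; offending: '",
         hex[which(nchar(hex) != 6L)[1]], "'")
  }
}

#' @export
score_hex.scale_scorer <- function(scorer, hex) {
  check_hex(hex)
  ch <- matrix(unlist(strsplit(hex, "", fixed = TRUE), use.names = FALSE),
               nrow = 6L)
  v <- matrix(scorer$values[ch], nrow = 6L)
  out <- if (scorer$aggregation == "mean") colMeans(v) else colSums(v)
  names(out) <- NULL
  out
}

#' @export
score_hex.pssm_scorer <- function(scorer, hex) {
  check_hex(hex)
  ch <- matrix(unlist(strsplit(hex, "", fixed = TRUE), use.names = FALSE),
               nrow = 6L)
  col <- match(ch, AA_ALPHABET)           # NA for nonstandard residues
  idx <- cbind(rep(1:6, ncol(ch)), as.vector(col))
  v <- matrix(scorer$values[idx], nrow = 6L)
  out <- colSums(v)
  names(out) <- NULL
  out
}

#' @export
score_hex.table_scorer <- function(scorer, hex) {
  check_hex(hex)
  out <- unname(scorer$values[hex])
  miss <- is.na(out) & !hex %in% names(scorer$values)
  if (any(miss)) {
    stop("external scorer '", scorer$name, "' has no score for '",
         hex[which(miss)[1]], "'")
  }
  out
}

#' Score every sliding hexapeptide window of a sequence
#'
#' Window `w` covers residues `w .. w+5` (1-based); a sequence of length `L`
#' has exactly `L - 5` windows.
#'
#' @param scorer a scorer object.
#' @param seq a `protein_sequence` or raw amino-acid string.
#' @return Numeric vector of `L - 5` window scores; windows covering an
#'   unscoreable residue are `NA`.
#' @export
score_windows <- function(scorer, seq) {
  seq <- as_protein_sequence(seq)
  L <- nchar(seq$residues)
  if (L < 6L) stop("sequence '", seq$id, "' is shorter than 6 residues")
  starts <- 1:(L - 5L)
  hex <- substring(seq$residues, starts, starts + 5L)
  out <- rep(NA_real_, length(starts))
  ok <- rep(TRUE, length(starts))
  if (length(seq$unscoreable)) {
    for (p in seq$unscoreable) {
      ok[starts >= p - 5L & starts <= p] <- FALSE
    }
  }
  if (any(ok)) out[ok] <- score_hex(scorer, hex[ok])
  out
}

#' Component score matrix for a set of peptides
#'
#' @param peptides character vector of 6-mers (or a `hex_dataset`, whose
#'   `peptide` column is used).
#' @param scorers a list of scorer objects (default [builtin_scorers()]).
#' @return Numeric matrix, one row per peptide, one named column per scorer.
#' @export
compute_features <- function(peptides, scorers = builtin_scorers()) {
  if (inherits(peptides, "hex_dataset") || is.data.frame(peptides)) {
    peptides <- peptides$peptide
  }
  nm <- vapply(scorers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("scorer names must be unique")
  out <- vapply(scorers, score_hex, numeric(length(peptides)),
                hex = peptides)
  out <- matrix(out, nrow = length(peptides),
                dimnames = list(NULL, nm))
  out
}

#' Number of distinct k-mers over an alphabet
#'
#' For the 20 amino acids and 6-residue windows this is
#' \eqn{20^6 = 64{,}000{,}000}, the size of the full hexapeptide score store.
#'
#' @param alphabet character vector of letters (default the 20 amino acids).
#' @param k window length.
#' @return `length(alphabet)^k` as a double.
#' @examples
#' hexapeptide_space_size()  # 64e6
#' @export
hexapeptide_space_size <- function(alphabet = AA_ALPHABET, k = 6L) {
  if (length(alphabet) < 1L) stop("alphabet must be non-empty")
  if (k < 1L) stop("k must be >= 1")
  length(unique(alphabet))^as.numeric(k)
}

#' Precompute a scorer over a peptide set
#'
#' Memoizes a scorer into a [table_scorer()] lookup keyed by 6-mer, the
#' in-memory analogue of a precomputed hexapeptide score store.
#'
#' @param scorer a scorer object.
#' @param peptides 6-mers to precompute.
#' @return A [table_scorer()] returning bit-identical scores for `peptides`.
#' @export
precompute_scorer <- function(scorer, peptides) {
  peptides <- unique(peptides)
  sc <- score_hex(scorer, peptides)
  names(sc) <- peptides
  table_scorer(scorer$name, sc)
}

#' Standardize a component score matrix
#'
#' Centres and scales each scorer column to sample mean 0 and sample
#' standard deviation 1, recording the transform so it can be replayed on
#' new data (e.g. at prediction time).
#'
#' @param x numeric matrix of component scores (columns = scorers).
#' @param record an existing record (list with `center`, `scale`) to apply
#'   instead of estimating a new one.
#' @return A list with `x` (standardized matrix), `center` and `scale`
#'   (named per-scorer vectors).
#' @export
standardize_features <- function(x, record = NULL) {
  x <- as.matrix(x)
  if (is.null(record)) {
    if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    zero <- which(scale < .Machine$double.eps^0.5)
    if (length(zero)) {
      stop("zero-variance scorer column: ",
           paste(colnames(x)[zero], collapse = ", "))
    }
  } else {
    center <- record$center[colnames(x)]
    scale <- record$scale[colnames(x)]
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  list(x = z, center = center, scale = scale)
}

## ---- parameter-file readers -------------------------------------------

#' Read a residue scale from TSV
#'
#' Expects header columns `residue` and `value`, one row per amino acid.
#'
#' @param path path to the TSV file.
#' @param name scorer name (default: file name without extension).
#' @inheritParams scale_scorer
#' @return A [scale_scorer()].
#' @export
read_scale <- function(path, name = NULL, aggregation = "mean") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(d))) {
    stop("scale TSV must have columns 'residue' and 'value'")
  }
  v <- stats::setNames(as.numeric(d$value), toupper(d$residue))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  scale_scorer(name, v, aggregation = aggregation)
}

#' Read a position-specific matrix from TSV
#'
#' Expects a header with `position` followed by the 20 amino-acid one-letter
#' codes, and six data rows (positions 1-6).
#'
#' @inheritParams read_scale
#' @return A [pssm_scorer()].
#' @export
read_pssm <- function(path, name = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"position" %in% names(d)) {
    stop("position-matrix TSV must have a 'position' column")
  }
  d <- d[order(as.integer(d$position)), ]
  m <- as.matrix(d[, setdiff(names(d), "position"), drop = FALSE])
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pssm_scorer(name, m)
}

#' Read a precomputed hexapeptide score table from TSV
#'
#' Expects header columns `peptide` and `score`.
#'
#' @inheritParams read_scale
#' @return A [table_scorer()].
#' @export
read_score_table <- function(path, name = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "score") %in% names(d))) {
    stop("score-table TSV must have columns 'peptide' and 'score'")
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  table_scorer(name, stats::setNames(as.numeric(d$score),
                                     toupper(d$peptide)))
}

## ---- built-in scorer configurations -----------------------------------

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
kd_hydropathy <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Chou-Fasman beta-sheet propensity scale
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
cf_beta_propensity <- function() {
  c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75, H = 0.87,
    I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89, P = 0.55, Q = 1.10,
    R = 0.93, S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)
}

## standardized mean of hydropathy and beta propensity; the generic
## "aggregation propensity" axis used by the synthetic generators and the
## built-in position matrix.
aggregation_propensity <- function() {
  z1 <- scale(kd_hydropathy()[AA_ALPHABET])[, 1]
  z2 <- scale(cf_beta_propensity()[AA_ALPHABET])[, 1]
  z <- (z1 + z2) / 2
  stats::setNames(z / stats::sd(z), AA_ALPHABET)
}

#' Built-in component scorer registry
#'
#' Four generic scorer configurations spanning the two scorer families:
#' `hydropathy` (Kyte-Doolittle scale), `beta_propensity` (Chou-Fasman
#' beta-sheet scale), `charge` (unit charges at physiological pH), and
#' `core_pssm`, a synthetic 6 x 20 position matrix that weights a combined
#' hydropathy/beta-propensity axis more strongly in the window core
#' (positions 3-4).  These are generic stand-ins for published window
#' predictors, not re-derivations of them; users supply their own parameter
#' files (see [read_scale()], [read_pssm()], [read_score_table()]) to plug
#' in specific published scorers.
#'
#' @return Named list of scorer objects.
#' @export
builtin_scorers <- function() {
  z <- aggregation_propensity()
  pos_weight <- c(0.8, 1, 1.2, 1.2, 1, 0.8)
  pssm <- outer(pos_weight, z)
  colnames(pssm) <- AA_ALPHABET
  charge <- stats::setNames(numeric(20), AA_ALPHABET)
  charge[c("K", "R")] <- 1
  charge["H"] <- 0.5
  charge[c("D", "E")] <- -1
  list(
    hydropathy = scale_scorer("hydropathy", kd_hydropathy()),
    beta_propensity = scale_scorer("beta_propensity", cf_beta_propensity()),
    charge = scale_scorer("charge", charge),
    core_pssm = pssm_scorer("core_pssm", pssm)
  )
}
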