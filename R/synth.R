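## Seeded synthetic-data generators.  These emulate the structure of the
## data the meta-predictor consumes — a labelled hexapeptide training set
## with tunable class separation, feature matrices drawn from a known
## logistic model, and proteins with planted hot spots — without any
## external download.  Every generator is bit-reproducible from its seed.

#' Generate a labelled hexapeptide dataset
#'
#' Negative peptides draw residues from a background distribution (uniform
#' over the 20 amino acids by default); positives draw from the background
#' tilted towards high aggregation-propensity residues with weight
#' \eqn{\exp(\mathrm{separation} \cdot z / 2)}, where `z` is the
#' standardized combined hydropathy/beta-propensity axis of the built-in
#' scorers.  `separation = 0` makes the classes indistinguishable; the
#' default 2 yields strongly informative component scores.  Exact class
#' counts are honoured and duplicate (peptide, label) pairs are regenerated.
#'
#' @param n_pos,n_neg class sizes (defaults 116 amyloid / 162 non-amyloid,
#'   the composition of the classic experimentally labelled hexapeptide
#'   compendium this generator stands in for).
#' @param separation non-negative effect size of the positive-class
#'   enrichment.
#' @param seed RNG seed.
#' @param background residue sampling weights for the negative class
#'   (recycled over [AA_ALPHABET] order; default uniform).
#' @return A [hex_dataset()] with `n_pos + n_neg` rows.
#' @examples
#' d <- gen_labelled_hexapeptides(seed = 1)
#' table(d$label)
#' @export
gen_labelled_hexapeptides <- function(n_pos = 116L, n_neg = 162L,
                                      separation = 2, seed = 1L,
                                      background = rep(1, 20)) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, separation >= 0)
  z <- aggregation_propensity()
  bg <- background / sum(background)
  wpos <- bg * exp(separation * z / 2)
  wpos <- wpos / sum(wpos)
  with_seed(seed, {
    draw <- function(n, w) {
      vapply(seq_len(n), function(i) {
        paste(sample(AA_ALPHABET, 6L, replace = TRUE, prob = w),
              collapse = "")
      }, "")
    }
    pos <- draw(n_pos, wpos)
    neg <- draw(n_neg, bg)
    ## regenerate any duplicate (peptide, label) pair to honour exact counts
    for (iter in 1:100) {
      key <- paste(c(pos, neg), rep(1:0, c(n_pos, n_neg)))
      dup <- duplicated(key)
      if (!any(dup)) break
      idx <- which(dup)
      for (i in idx) {
        if (i <= n_pos) pos[i] <- draw(1L, wpos) else {
          neg[i - n_pos] <- draw(1L, bg)
        }
      }
    }
    hex_dataset(c(pos, neg), rep(1:0, c(n_pos, n_neg)),
                provenance = sprintf(
                  "synthetic (seed=%d, separation=%g)", seed, separation))
  })
}

#' Generate a feature matrix from a known logistic model
#'
#' Draws standard-normal component score columns, optionally with
#' correlated redundant copies, and labels each row Bernoulli with
#' probability \eqn{\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j)}.
#' Supports the two simulation designs used to validate the meta-model:
#' parameter recovery (independent causal columns) and selection
#' consistency (causal columns plus `n_redundant` noisy copies of them,
#' each correlated `redundant_r` with its parent and carrying no
#' independent signal).
#'
#' @param n number of rows (peptides).
#' @param beta0 intercept.
#' @param beta named vector of causal coefficients (one per causal column;
#'   unnamed vectors get names `s1, s2, ...`).
#' @param n_noise number of additional independent pure-noise columns
#'   (coefficient 0), named `noise1, ...`.
#' @param n_redundant number of redundant copies of causal columns
#'   (assigned round-robin to parents), named `copy1, ...`.
#' @param redundant_r correlation between a redundant copy and its parent.
#' @param seed RNG seed.
#' @return A data frame with the feature columns and a binary `label`
#'   column; the causal column names are stored in the `"signal"`
#'   attribute.
#' @examples
#' d <- gen_features_from_logistic(1000, beta0 = -1,
#'                                 beta = c(0.8, -0.5, 0.6, 0.9), seed = 1)
#' mean(d$label)
#' @export
gen_features_from_logistic <- function(n, beta0, beta, n_noise = 0L,
                                       n_redundant = 0L, redundant_r = 0.8,
                                       seed = 1L) {
  p <- length(beta)
  if (is.null(names(beta))) names(beta) <- paste0("s", seq_len(p))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, names(beta)))
    cols <- as.data.frame(X)
    if (n_noise > 0L) {
      for (i in seq_len(n_noise)) {
        cols[[paste0("noise", i)]] <- stats::rnorm(n)
      }
    }
    if (n_redundant > 0L) {
      parent <- rep_len(seq_len(p), n_redundant)
      for (i in seq_len(n_redundant)) {
        cols[[paste0("copy", i)]] <-
          redundant_r * X[, parent[i]] +
          sqrt(1 - redundant_r^2) * stats::rnorm(n)
      }
    }
    eta <- beta0 + drop(X %*% beta)
    cols$label <- stats::rbinom(n, 1L, stats::plogis(eta))
    structure(cols, signal = names(beta))
  })
}

#' Generate a protein with planted amyloid hot spots
#'
#' Builds a background sequence of residues drawn uniformly over the
#' alphabet and plants `n_hotspots` non-overlapping segments (lengths drawn
#' from `hotspot_len`) whose residues are tilted towards high aggregation
#' propensity with effect size `separation` (same tilt as
#' [gen_labelled_hexapeptides()], default 3 so the planted segments score
#' clearly above background).  Segment coordinates are recorded as
#' annotations; segments are separated by at least 6 background residues so
#' planted regions cannot merge into one called hot spot.
#'
#' @param length total protein length.
#' @param n_hotspots number of planted segments (0 for pure background).
#' @param seed RNG seed.
#' @param separation tilt effect size for hot-spot residues.
#' @param hotspot_len candidate segment lengths.
#' @param id sequence identifier.
#' @return A list with `seq` (a `protein_sequence`) and `regions` (data
#'   frame `sequence_id`, `start`, `end`, `status = "amyloid"`; zero rows
#'   when `n_hotspots = 0`).
#' @export
gen_annotated_protein <- function(length, n_hotspots = 1L, seed = 1L,
                                  separation = 3, hotspot_len = 6:12,
                                  id = "synthetic_protein") {
  z <- aggregation_propensity()
  whot <- exp(separation * z / 2)
  whot <- whot / sum(whot)
  with_seed(seed, {
    lens <- if (n_hotspots > 0L) {
      sample(rep(hotspot_len, 2L), n_hotspots, replace = TRUE)
    } else {
      integer(0)
    }
    gap <- 6L
    need <- sum(lens) + gap * (n_hotspots + 1L)
    if (length < need) {
      stop("cannot place ", n_hotspots, " hot spots with 6-residue gaps ",
           "in a sequence of length ", length, " (need >= ", need, ")")
    }
    ## distribute the slack uniformly over the n_hotspots + 1 gaps
    slack <- length - need
    extra <- if (n_hotspots > 0L) {
      stats::rmultinom(1L, slack, rep(1, n_hotspots + 1L))[, 1L]
    } else {
      slack
    }
    chars <- character(0)
    regions <- data.frame(sequence_id = character(0), start = integer(0),
                          end = integer(0), status = character(0),
                          stringsAsFactors = FALSE)
    bg_draw <- function(n) sample(AA_ALPHABET, n, replace = TRUE)
    for (i in seq_len(n_hotspots)) {
      chars <- c(chars, bg_draw(gap + extra[i]))
      start <- length(chars) + 1L
      chars <- c(chars, sample(AA_ALPHABET, lens[i], replace = TRUE,
                               prob = whot))
      regions <- rbind(regions, data.frame(
        sequence_id = id, start = start, end = start + lens[i] - 1L,
        status = "amyloid", stringsAsFactors = FALSE))
    }
    chars <- c(chars, bg_draw(gap + extra[n_hotspots + 1L]))
    seq <- validate_sequence(paste(chars, collapse = ""), id = id)
    list(seq = seq, regions = regions)
  })
}

#' Uniformly scramble a protein sequence
#'
#' Returns a random permutation (anagram) of the input residues, emulating
#' scrambled-peptide experimental designs.
#'
#' @param seq a `protein_sequence` or string.
#' @param seed RNG seed.
#' @param id identifier for the scrambled sequence.
#' @return A `protein_sequence` with the same residue multiset.
#' @export
scramble_sequence <- function(seq, seed = 1L, id = NULL) {
  seq <- as_protein_sequence(seq)
  if (is.null(id)) id <- paste0(seq$id, "_scrambled")
  with_seed(seed, {
    ch <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
    validate_sequence(paste(sample(ch), collapse = ""), id = id)
  })
}
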