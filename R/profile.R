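## Per-residue amyloidogenicity profiles, hot-spot calling, TA/NHSA and
## mutation-effect deltas.  Window w covers residues w..w+5 and its score
## is assigned to the window's third residue (w+2), so residues 1-2 and
## L-2..L carry no score.

#' Per-residue amyloidogenicity profile of a protein
#'
#' Slides a 6-residue window along the sequence, computes the component
#' scores of each hexapeptide, and evaluates the fitted meta-model on them;
#' each window probability is assigned to the window's third residue.
#'
#' @param seq a `protein_sequence` (see [validate_sequence()]) or raw
#'   amino-acid string of length >= 6.
#' @param model a fitted [amylometa()] model.
#' @param scorers named list of scorer objects covering the model's
#'   coefficients (default [builtin_scorers()]).
#' @return An object of class `"score_profile"`: a list with
#'   `sequence_id`, `length`, `window_start` (1-based window starts),
#'   `score` (window probabilities; `NA` for unscoreable windows) and
#'   `residue_score` (length-`L` vector, window score at the window's third
#'   residue, `NA` at the 2+3 terminal residues).
#' @export
compute_profile <- function(seq, model, scorers = builtin_scorers()) {
  seq <- as_protein_sequence(seq)
  L <- nchar(seq$residues)
  if (L < 6L) stop("sequence '", seq$id, "' is shorter than 6 residues")
  need <- model$scorers
  have <- vapply(scorers, `[[`, "", "name")
  if (!all(need %in% have)) {
    stop("scorers do not cover model coefficient(s): ",
         paste(setdiff(need, have), collapse = ", "))
  }
  scorers <- scorers[match(need, have)]
  win <- vapply(scorers, score_windows, numeric(L - 5L), seq = seq)
  win <- matrix(win, nrow = L - 5L, dimnames = list(NULL, need))
  score <- rep(NA_real_, L - 5L)
  ok <- stats::complete.cases(win)
  if (any(ok)) {
    score[ok] <- predict(model, as.data.frame(win[ok, , drop = FALSE]))
  }
  residue_score <- rep(NA_real_, L)
  residue_score[seq_len(L - 5L) + 2L] <- score
  structure(list(sequence_id = seq$id, length = L,
                 window_start = seq_len(L - 5L), score = score,
                 residue_score = residue_score,
                 residues = seq$residues),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat("Amyloidogenicity profile of '", x$sequence_id, "' (",
      x$length, " aa, ", length(x$score), " windows)\n", sep = "")
  cat("  window score range: ",
      paste(format(range(x$score, na.rm = TRUE), digits = 3),
            collapse = " - "),
      "; TA = ", format(total_area(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn compute_profile per-residue table (`position`, `residue`,
#'   `score`) of a profile; terminal residues have `NA` scores.
#' @param x a `"score_profile"`.
#' @param row.names,optional,... as in [as.data.frame()].
#' @export
as.data.frame.score_profile <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(sequence_id = x$sequence_id,
             position = seq_len(x$length),
             residue = strsplit(x$residues, "", fixed = TRUE)[[1]],
             score = x$residue_score,
             stringsAsFactors = FALSE)
}

#' @export
plot.score_profile <- function(x, threshold = NULL, ...) {
  graphics::plot(seq_len(x$length), x$residue_score, type = "h",
                 xlab = "Residue position", ylab = "Meta-model score",
                 ylim = c(0, 1), ...)
  if (!is.null(threshold)) {
    graphics::abline(h = threshold, lty = 2, col = "red3")
  }
  invisible(x)
}

#' Call hot spots from a profile
#'
#' A hot spot is a maximal run of consecutive windows whose scores are at
#' or above the threshold; its residue span is the union of the run's
#' windows, i.e. residues `first_window .. last_window + 5`.  `NA`
#' (unscoreable) windows interrupt runs.
#'
#' @param profile a [compute_profile()] result.
#' @param threshold decision threshold on the window probability.
#' @return A data frame of class `"hotspots"` with columns `first_window`,
#'   `last_window`, `residue_start`, `residue_end`, `peak_score`, `nhsa`,
#'   plus `threshold` and `sequence_id` attributes.  Zero rows when no
#'   window reaches the threshold.
#' @export
call_hotspots <- function(profile, threshold) {
  stopifnot(inherits(profile, "score_profile"))
  above <- !is.na(profile$score) & profile$score >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(first_window = starts[keep],
                    last_window = ends[keep])
  out$residue_start <- out$first_window
  out$residue_end <- out$last_window + 5L
  out$peak_score <- vapply(seq_len(nrow(out)), function(i) {
    max(profile$score[out$first_window[i]:out$last_window[i]])
  }, numeric(1))
  out$nhsa <- vapply(seq_len(nrow(out)), function(i) {
    nhsa(profile, out[i, ], threshold)
  }, numeric(1))
  structure(out, threshold = threshold,
            sequence_id = profile$sequence_id,
            class = c("hotspots", "data.frame"))
}

#' Total Area of a profile
#'
#' TA is the sum of the window scores along the entire sequence; it is
#' independent of any hot-spot threshold.  Unscoreable (`NA`) windows are
#' dropped with a warning.
#'
#' @param profile a [compute_profile()] result.
#' @return The sum of window scores.
#' @export
total_area <- function(profile) {
  stopifnot(inherits(profile, "score_profile"))
  if (anyNA(profile$score)) {
    warning("profile contains unscoreable windows; TA omits them")
  }
  sum(profile$score, na.rm = TRUE)
}

#' Normalized Hot Spot Area
#'
#' The area between the profile and the threshold over a hot spot's
#' windows, divided by the hot spot's residue length:
#' \deqn{\mathrm{NHSA} = \frac{\sum_{w} (s_w - t)}{\mathrm{residue\_end} -
#'   \mathrm{residue\_start} + 1}.}
#' A single-window hot spot spans 6 residues, two consecutive windows span
#' 7, and so on.
#'
#' @param profile a [compute_profile()] result.
#' @param hotspot one row of a [call_hotspots()] data frame (or any list
#'   with `first_window` and `last_window`).
#' @param threshold the threshold the hot spot was called at.
#' @return The NHSA (non-negative for any called hot spot).
#' @export
nhsa <- function(profile, hotspot, threshold) {
  fw <- hotspot$first_window
  lw <- hotspot$last_window
  if (fw < 1L || lw > length(profile$score) || fw > lw) {
    stop("hotspot does not match the profile")
  }
  s <- profile$score[fw:lw]
  if (anyNA(s)) stop("hotspot covers unscoreable windows")
  n_res <- (lw + 5L) - fw + 1L
  sum(s - threshold) / n_res
}

## region-restricted TA: windows attributed to the region by start residue
region_ta <- function(profile, start, end) {
  w <- profile$window_start
  keep <- w >= start & w <= end
  sum(profile$score[keep], na.rm = TRUE)
}

## region-restricted NHSA: per hot spot, the (score - threshold) mass of its
## windows starting inside the region, normalized by that hot spot's full
## residue length; summed over hot spots
region_nhsa <- function(profile, hotspots, start, end, threshold) {
  if (!nrow(hotspots)) return(0)
  total <- 0
  for (i in seq_len(nrow(hotspots))) {
    w <- hotspots$first_window[i]:hotspots$last_window[i]
    inreg <- w >= start & w <= end
    if (!any(inreg)) next
    n_res <- hotspots$residue_end[i] - hotspots$residue_start[i] + 1L
    total <- total + sum(profile$score[w[inreg]] - threshold) / n_res
  }
  total
}

#' Aggregation-propensity change of a sequence variant
#'
#' Scores a mutant sequence against its wild type over a fixed analysis
#' region: computes both profiles, calls hot spots at `threshold`, and
#' reports the mutant-minus-wild-type differences of the region-restricted
#' NHSA (summed over hot spots) and of the region-restricted TA (windows
#' attributed to the region by their start residue).  The variant kind is
#' inferred: equal lengths with one substitution is a missense variant,
#' equal lengths with several substitutions is reported (with a warning) as
#' multi-substitution, and differing lengths are treated as a frameshift
#' (the region is clipped to each sequence's length).
#'
#' @param wt,mut wild-type and mutant sequences (`protein_sequence` or
#'   string), each of length >= 6.
#' @param region integer pair `c(start, end)` (1-based inclusive) of the
#'   analysis region.
#' @param model a fitted [amylometa()] model.
#' @param scorers scorer list covering the model (default
#'   [builtin_scorers()]).
#' @param threshold hot-spot threshold.
#' @return An object of class `"mutation_effect"`: list with `wt_id`,
#'   `mut_id`, `region`, `mutation_kind`, `delta_nhsa`, `delta_ta`, and the
#'   per-sequence `nhsa_wt`, `nhsa_mut`, `ta_wt`, `ta_mut`.
#' @export
mutation_effect <- function(wt, mut, region, model,
                            scorers = builtin_scorers(), threshold) {
  wt <- as_protein_sequence(wt, id = "wt")
  mut <- as_protein_sequence(mut, id = "mut")
  if (length(region) != 2L || region[1] < 1L || region[2] < region[1]) {
    stop("region must be c(start, end) with 1 <= start <= end")
  }
  Lw <- nchar(wt$residues)
  Lm <- nchar(mut$residues)
  kind <- if (Lw == Lm) {
    nsub <- sum(strsplit(wt$residues, "")[[1]] !=
                  strsplit(mut$residues, "")[[1]])
    if (nsub == 0L) {
      "identity"
    } else if (nsub == 1L) {
      "missense"
    } else {
      warning("sequences differ at ", nsub,
              " positions; reporting as multi-substitution")
      "multi-substitution"
    }
  } else {
    "frameshift"
  }
  one_side <- function(seq, L) {
    prof <- compute_profile(seq, model, scorers)
    hs <- call_hotspots(prof, threshold)
    s <- min(region[1], L)
    e <- min(region[2], L)
    list(nhsa = region_nhsa(prof, hs, s, e, threshold),
         ta = region_ta(prof, s, e))
  }
  w <- one_side(wt, Lw)
  m <- one_side(mut, Lm)
  structure(list(wt_id = wt$id, mut_id = mut$id,
                 region = c(start = region[1], end = region[2]),
                 mutation_kind = kind,
                 delta_nhsa = m$nhsa - w$nhsa,
                 delta_ta = m$ta - w$ta,
                 nhsa_wt = w$nhsa, nhsa_mut = m$nhsa,
                 ta_wt = w$ta, ta_mut = m$ta),
            class = "mutation_effect")
}

#' @export
print.mutation_effect <- function(x, digits = 4, ...) {
  cat("Variant effect (", x$mutation_kind, "): ", x$wt_id, " -> ",
      x$mut_id, ", region ", x$region["start"], "-", x$region["end"],
      "\n", sep = "")
  cat("  delta NHSA:", format(x$delta_nhsa, digits = digits),
      "  delta TA:", format(x$delta_ta, digits = digits), "\n")
  invisible(x)
}

#' Write a per-residue profile to TSV
#'
#' @param profile a [compute_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called hot spots to TSV
#'
#' @param hotspots a [call_hotspots()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspots <- function(hotspots, path) {
  d <- as.data.frame(hotspots)
  d <- cbind(sequence_id = attr(hotspots, "sequence_id"), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
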