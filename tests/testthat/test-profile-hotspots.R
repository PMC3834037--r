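# Profiles and hot spots are exercised with a small model fitted on
# synthetic hexapeptides (helper fit_small_model) plus hand-built scorers
# where exact window arithmetic matters.

test_that("profile geometry: L-5 windows, third-residue assignment", {
  model <- fit_small_model(seed = 1)
  prof <- compute_profile("MKVLAAC", model)   # L = 7 -> 2 windows
  expect_length(prof$score, 2)
  expect_equal(prof$residue_score[3:4], prof$score)
  expect_true(all(is.na(prof$residue_score[c(1, 2, 5, 6, 7)])))
  expect_true(all(prof$score > 0 & prof$score < 1))

  one <- compute_profile("MKVLAA", model)
  expect_length(one$score, 1)
  expect_equal(which(!is.na(one$residue_score)), 3L)
  expect_error(compute_profile("MKVLA", model), "shorter than 6")
})

test_that("profile equals window-by-window closed-form evaluation", {
  model <- fit_small_model(seed = 2)
  seq <- validate_sequence(paste(random_hex(6, seed = 3), collapse = ""),
                           id = "rnd")
  prof <- compute_profile(seq, model)
  b <- coef(model)
  for (w in seq_along(prof$score)) {
    hex <- substr(seq$residues, w, w + 5)
    s <- vapply(builtin_scorers()[model$scorers], score_hex, numeric(1),
                hex = hex)
    eta <- b["(Intercept)"] + sum(b[model$scorers] * s[model$scorers])
    expect_equal(prof$score[w], unname(plogis(eta)), tolerance = 1e-12)
  }
})

test_that("intercept-only model gives a flat profile at its base rate", {
  d <- data.frame(label = rep(c(1, 0), each = 20))
  flat <- amylometa(label ~ 1, d)
  prof <- compute_profile("MKVLAAWWFFYY", flat, scorers = list())
  expect_true(all(abs(prof$score - 0.5) < 1e-9))
})

test_that("hot spot calling finds maximal runs with correct residue spans", {
  # hand-made profile via a table scorer covering each window
  model <- fit_small_model(seed = 4)
  seq <- paste(random_hex(3, seed = 5), collapse = "")  # L=18, 13 windows
  prof <- compute_profile(seq, model)

  # synthetic profile object with known scores
  prof$score <- c(0.2, 0.8, 0.9, 0.3, rep(0.1, 9))
  hs <- call_hotspots(prof, 0.5)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$first_window, 2)
  expect_equal(hs$last_window, 3)
  expect_equal(hs$residue_start, 2)
  # union of windows 2..3 is residues 2..8: length (3 - 2) + 6 = 7
  expect_equal(hs$residue_end, 8)
  expect_equal(hs$peak_score, 0.9)

  # all below -> empty; threshold 0 -> everything; threshold 1.01 -> none
  expect_equal(nrow(call_hotspots(prof, 0.95)), 0)
  all_in <- call_hotspots(prof, 0)
  expect_equal(nrow(all_in), 1)
  expect_equal(all_in$residue_end - all_in$residue_start + 1,
               nchar(seq))
  expect_equal(nrow(call_hotspots(prof, 1.01)), 0)
})

test_that("raising the threshold never grows hot-spot residue coverage, and
          spans stay disjoint and ordered", {
  model <- fit_small_model(seed = 6)
  gen <- gen_annotated_protein(150, n_hotspots = 3, seed = 7)
  prof <- compute_profile(gen$seq, model)
  coverage <- function(hs) {
    if (!nrow(hs)) return(0)
    sum(amylometa:::region_mask(
      data.frame(start = hs$residue_start, end = hs$residue_end), 150))
  }
  prev <- Inf
  for (t in seq(0.1, 0.9, by = 0.1)) {
    hs <- call_hotspots(prof, t)
    cov <- coverage(hs)
    expect_lte(cov, prev)
    prev <- cov
    if (nrow(hs) > 1) {
      # hot spots are ordered and their window ranges are disjoint
      expect_true(all(diff(hs$residue_start) > 0))
      expect_true(all(utils::head(hs$last_window, -1) <
                        utils::tail(hs$first_window, -1)))
    }
    # every constituent window is at or above threshold; maximality
    for (i in seq_len(nrow(hs))) {
      expect_true(all(prof$score[hs$first_window[i]:hs$last_window[i]] >= t))
      if (hs$first_window[i] > 1) {
        expect_lt(prof$score[hs$first_window[i] - 1], t)
      }
      if (hs$last_window[i] < length(prof$score)) {
        expect_lt(prof$score[hs$last_window[i] + 1], t)
      }
    }
  }
})

test_that("TA is the plain window-score sum and threshold-independent", {
  model <- fit_small_model(seed = 8)
  prof <- compute_profile(paste(random_hex(4, seed = 9), collapse = ""),
                          model)
  expect_equal(total_area(prof), sum(prof$score))
  flat <- prof
  flat$score <- rep(0.5, 5)
  expect_equal(total_area(flat), 2.5)
})

test_that("NHSA matches its area-over-length definition", {
  model <- fit_small_model(seed = 10)
  prof <- compute_profile(paste(random_hex(3, seed = 11), collapse = ""),
                          model)
  t <- 0.5
  # one window exactly at threshold -> 0
  prof$score <- c(0.5, rep(0.1, 12))
  hs <- call_hotspots(prof, t)
  expect_equal(hs$nhsa, 0)

  # single window at t + 0.3 spans 6 residues -> 0.05
  prof$score <- c(0.8, rep(0.1, 12))
  hs <- call_hotspots(prof, t)
  expect_equal(hs$nhsa, 0.3 / 6)

  # two consecutive windows 0.7, 0.9 span 7 residues
  prof$score <- c(0.7, 0.9, rep(0.1, 11))
  hs <- call_hotspots(prof, t)
  expect_equal(hs$nhsa, (0.2 + 0.4) / 7)
  expect_true(all(hs$nhsa >= 0))
})

test_that("identity 'mutation' has zero deltas; substitutions touch at most
          six windows", {
  model <- fit_small_model(seed = 12)
  seq <- paste(random_hex(5, seed = 13), collapse = "")  # L = 30
  eff <- mutation_effect(seq, seq, c(1, 30), model, threshold = 0.5)
  expect_equal(eff$mutation_kind, "identity")
  expect_equal(eff$delta_nhsa, 0)
  expect_equal(eff$delta_ta, 0)

  prof_wt <- compute_profile(seq, model)
  ch <- strsplit(seq, "")[[1]]
  for (p in seq_len(nchar(seq))) {
    mutch <- ch
    mutch[p] <- if (ch[p] == "W") "A" else "W"
    mut <- paste(mutch, collapse = "")
    prof_mut <- compute_profile(mut, model)
    changed <- which(abs(prof_mut$score - prof_wt$score) > 1e-12)
    expect_lte(length(changed), 6)
    # changed windows all contain position p
    expect_true(all(changed >= p - 5 & changed <= p))
  }
})

test_that("mutation kinds are inferred and frameshift regions clipped", {
  model <- fit_small_model(seed = 14)
  wt <- paste(random_hex(4, seed = 15), collapse = "")        # L = 24
  mut1 <- sub("^(.{5}).", "\\1W", wt)                         # 1 substitution
  eff <- mutation_effect(wt, mut1, c(1, 24), model, threshold = 0.5)
  expect_equal(eff$mutation_kind, "missense")

  ch <- strsplit(wt, "")[[1]]
  ch[c(2, 10)] <- ifelse(ch[c(2, 10)] == "W", "A", "W")
  mut2 <- paste(ch, collapse = "")
  expect_warning(
    eff2 <- mutation_effect(wt, mut2, c(1, 24), model, threshold = 0.5),
    "multi-substitution")
  expect_equal(eff2$mutation_kind, "multi-substitution")

  trunc <- substr(wt, 1, 15)
  eff3 <- mutation_effect(wt, trunc, c(1, 24), model, threshold = 0.5)
  expect_equal(eff3$mutation_kind, "frameshift")
})

test_that("a substitution creating a strong segment raises delta NHSA", {
  # scorer where W alone is amyloidogenic: mutating A->W in a poly-A
  # context pushes the six covering windows above threshold
  w_scale <- scale_scorer("w", stats::setNames(
    ifelse(amylometa:::AA_ALPHABET == "W", 5, -5),
    amylometa:::AA_ALPHABET))
  d <- data.frame(
    w = c(rnorm(40, 2), rnorm(40, -2)),
    label = rep(c(1, 0), each = 40))
  model <- amylometa(label ~ w, d)
  wt <- strrep("A", 20)
  mut <- paste0(strrep("A", 8), strrep("W", 6), strrep("A", 6))
  eff <- suppressWarnings(
    mutation_effect(wt, mut, c(1, 20), model,
                    scorers = list(w_scale), threshold = 0.5))
  expect_gt(eff$delta_nhsa, 0)
  expect_gt(eff$delta_ta, 0)
})

test_that("profiles and hot spots export to TSV", {
  model <- fit_small_model(seed = 16)
  prof <- compute_profile(paste(random_hex(4, seed = 17), collapse = ""),
                          model)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, f)
  d <- utils::read.delim(f)
  expect_equal(nrow(d), prof$length)
  expect_equal(d$score[3], prof$score[1])

  hs <- call_hotspots(prof, min(prof$score))  # everything above threshold
  fh <- withr::local_tempfile(fileext = ".tsv")
  write_hotspots(hs, fh)
  dh <- utils::read.delim(fh)
  expect_equal(nrow(dh), nrow(hs))
})
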