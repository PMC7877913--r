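fake_metric_rows <- function(fS, fM, fN, ids = NULL, mode = "SO") {
  tibble::tibble(
    transcript_id = ids %||% paste0("t", seq_along(fS)),
    mode = mode, fS = fS, fM = fM, fN = fN
  )
}

test_that("cluster statistics are plain per-axis mean/SD with NA exclusion", {
  same <- fake_metric_rows(rep(0.25, 5), rep(0.70, 5), rep(0.05, 5))
  st <- central_cluster_stats(same, c("fS", "fM", "fN"))
  expect_equal(st$sd, rep(0, 3))
  expect_equal(attr(st, "n"), 5)

  withna <- fake_metric_rows(c(0.2, 0.3, NA), c(0.7, 0.6, 0.5), c(0.1, 0.1, 0.5))
  st2 <- central_cluster_stats(withna, c("fS", "fM", "fN"))
  expect_equal(attr(st2, "n"), 2)
  expect_equal(st2$mean[1], 0.25)
  expect_error(central_cluster_stats(same[1, ], c("fS", "fM")), "at least 2")
  expect_equal(names(tidy(st)), c("axis", "mean", "sd"))
  expect_equal(glance(st)$n, 5)
})

test_that("neutral-cohort cluster means sit near the generating expectation", {
  coh <- simulate_cohort(simulation_config(
    n_transcripts = 1000, seed = 13,
    regimes = default_regimes()[1, ] |> dplyr::mutate(fraction = 1),
    count_range = c(150, 150), profile = uniform_profile()
  ))
  rec <- suppressMessages(apply_filters(parse_somatic_records(coh$somatic)))
  mt <- observed_fractions(tally_by_transcript(rec), "SO")
  st <- central_cluster_stats(mt, c("fS", "fM", "fN"))
  ev <- uniform_code_expectation()
  for (i in 1:3) {
    se <- st$sd[i] / sqrt(attr(st, "n"))
    expect_lt(abs(st$mean[i] - unlist(ev)[i]), 3 * se)
  }
})

test_that("SD-set assignment uses ALL-axes for PG, ANY-axis for CG, ties inward", {
  mt <- fake_metric_rows(
    fS = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25),
    fM = c(0.70, 0.70, 0.70, 0.70, 0.70, 0.70),
    fN = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05)
  )
  # dyadic values keep the k*SD ties exact in floating point
  s <- 0.015625
  st <- tibble::tibble(axis = c("fS", "fM", "fN"),
                       mean = c(0.25, 0.70, 0.05), sd = c(s, s, s))
  class(st) <- c("cluster_stats", class(st))
  probe <- fake_metric_rows(
    fS = c(0.25, 0.25 + 3 * s, 0.25 + 1.5 * s, 0.25 + s, 0.25 + 2 * s, NA),
    fM = c(0.70, 0.70, 0.70, 0.70, 0.70, 0.70),
    fN = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    ids = c("at_mean", "far", "between", "tie1sd", "tie2sd", "undef")
  )
  sets <- assign_sd_sets(probe, st)
  got <- stats::setNames(sets$set, sets$transcript_id)
  expect_equal(unname(got["at_mean"]), "PG")
  expect_equal(unname(got["far"]), "CG")
  expect_equal(unname(got["between"]), "intermediate")
  expect_equal(unname(got["tie1sd"]), "PG")            # exactly 1 SD stays PG
  expect_equal(unname(got["tie2sd"]), "intermediate")  # exactly 2 SD is not CG
  expect_equal(unname(got["undef"]), "undefined")
})

test_that("shrinking the outer cutoff never shrinks the candidate set", {
  set.seed(5)
  mt <- fake_metric_rows(stats::rbeta(400, 25, 75), stats::rbeta(400, 70, 30),
                         stats::rbeta(400, 5, 95))
  st <- central_cluster_stats(mt, c("fS", "fM", "fN"))
  sizes <- vapply(c(3, 2.5, 2, 1.5), function(k) {
    sum(assign_sd_sets(mt, st, k_outer = k)$set == "CG")
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  sets <- assign_sd_sets(mt, st)
  expect_equal(sum(sets$set == "PG") + sum(sets$set == "CG") <= nrow(mt), TRUE)
  expect_equal(length(intersect(
    sets$transcript_id[sets$set == "PG"], sets$transcript_id[sets$set == "CG"]
  )), 0)
})

test_that("candidate union preserves set algebra with provenance", {
  sets <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d", "e", "f", "g", "c", "d", "x"),
    set = c(rep("CG", 7), "CG", "CG", "PG"),
    space = c(rep("f_SO", 7), "r3_SO", "r3_SO", "f_SO")
  )
  u <- union_candidates(sets)
  expect_equal(nrow(u), 7)
  expect_equal(u$n_spaces[u$transcript_id == "c"], 2)
  expect_false("x" %in% u$transcript_id)
  # identical sets union to the same size; disjoint sets add
  s1 <- tibble::tibble(transcript_id = c("a", "b", "c"), set = "CG", space = "s1")
  expect_equal(nrow(union_candidates(dplyr::bind_rows(s1, dplyr::mutate(s1, space = "s2")))), 3)
  s2 <- tibble::tibble(transcript_id = c("d", "e", "f", "g"), set = "CG", space = "s2")
  expect_equal(nrow(union_candidates(dplyr::bind_rows(s1, s2))), 7)
})

test_that("class thresholds label candidates as the metrics dictate", {
  cand <- tibble::tibble(transcript_id = c("tsg", "teg", "none"),
                         spaces = "f_SO", n_spaces = 1L)
  so <- tibble::tibble(
    transcript_id = c("tsg", "teg", "none"), mode = "SO",
    rMSN = c(1.0, 1.1, 1.2), rSMN = c(0.2, 0.66, 0.3), rNSM = c(0.4, 0.02, 0.05)
  )
  ssi <- tibble::tibble(
    transcript_id = c("tsg", "teg", "none"), mode = "SSI",
    rMSN = c(0.9, 1.0, 1.1), rSMN = c(0.15, 0.6, 0.28), rNSM = c(0.30, 0.05, 0.05)
  )
  cls <- classify_candidates(cand, dplyr::bind_rows(so, ssi))
  expect_equal(cls$label[cls$transcript_id == "tsg"], "TSG-like")
  expect_equal(cls$label[cls$transcript_id == "teg"], "TEG-like")
  expect_equal(cls$label[cls$transcript_id == "none"], "unclassified-candidate")
  expect_equal(cls$indel_rNSM, ssi$rNSM)
  # multi-label candidates keep all labels and warn
  so2 <- dplyr::mutate(so, rMSN = c(1, 5, 1.2))
  ssi2 <- dplyr::mutate(ssi, rNSM = c(0.3, 0.2, 0.05))
  expect_warning(
    cls2 <- classify_candidates(cand, dplyr::bind_rows(so2, ssi2)),
    "multiple"
  )
  expect_equal(cls2$label[cls2$transcript_id == "teg"], "TSG-like;OG-like;TEG-like")
})

test_that("starred-mode classification uses the starred thresholds", {
  cand <- tibble::tibble(transcript_id = "t", spaces = "f_SO", n_spaces = 1L)
  so <- tibble::tibble(transcript_id = "t", mode = "SO",
                       rMSN_star = 1.6, rSMN_star = 0.5, rNSM_star = 0.5,
                       rMSN = 10, rSMN = 10, rNSM = 10)
  cls <- classify_candidates(cand, so, thresholds = class_thresholds(starred = TRUE))
  expect_true(cls$is_OG_like)
  expect_false(cls$is_TSG_like)
  expect_false(cls$is_TEG_like)
})

test_that("silent hotspots are flagged and demote TEG-like calls", {
  # 60 of 100 silent hits at one position: both defaults exceeded
  sc <- tibble::tibble(
    transcript_id = "hot",
    position = c(1, 2:41),
    n_hits = c(60, rep(1, 40))
  )
  expect_true(flag_silent_hotspots(sc)$hotspot)
  # uniform silent hits over 300 positions: not flagged
  sc2 <- tibble::tibble(transcript_id = "cold", position = 1:300, n_hits = 1)
  expect_false(flag_silent_hotspots(sc2)$hotspot)
  # recurrent synonymous hits at three adjacent codons inflating fS:
  # flagged and the TEG-like call demoted, flag retained
  sc3 <- tibble::tibble(
    transcript_id = "adj",
    position = c(498, 501, 504, seq(3, 120, by = 3)),
    n_hits = c(20, 15, 12, rep(1, 40))
  )
  expect_true(flag_silent_hotspots(sc3)$hotspot)
  cand <- tibble::tibble(transcript_id = "adj", spaces = "f_SO", n_spaces = 1L)
  mt <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "adj", mode = "SO",
                   rMSN = 1, rSMN = 0.8, rNSM = 0.02),
    tibble::tibble(transcript_id = "adj", mode = "SSI",
                   rMSN = 1, rSMN = 0.7, rNSM = 0.04)
  )
  cls <- suppressMessages(classify_candidates(
    cand, mt, hotspot_flags = flag_silent_hotspots(sc3)
  ))
  expect_false(cls$is_TEG_like)
  expect_true(cls$hotspot)
  expect_equal(cls$label, "unclassified-candidate")
})

test_that("planted regimes are recovered on a small synthetic cohort", {
  coh <- small_cohort(n = 400, seed = 3)
  res <- suppressMessages(run_selection_pipeline(coh$somatic, coh$cds))
  scores <- classification_scores(res$classes, coh$truth)
  # precision is near-perfect at these planted effect sizes; recall is
  # bounded below conservatively here (the acceptance suite exercises the
  # full-scale reference operating point)
  expect_true(all(scores$precision > 0.9, na.rm = TRUE))
  expect_gt(scores$recall[scores$class == "TSG"], 0.6)
  expect_gt(scores$recall[scores$class == "TEG"], 0.4)
  expect_gt(scores$recall[scores$class == "OG"], 0.3)
})
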