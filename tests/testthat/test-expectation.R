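test_that("uniform-code expectation equals the census ratios exactly", {
  ev <- uniform_code_expectation()
  expect_equal(ev$fS_exp, 134 / 549, tolerance = 1e-15)
  expect_equal(ev$fM_exp, 392 / 549, tolerance = 1e-15)
  expect_equal(ev$fN_exp, 23 / 549, tolerance = 1e-15)
  expect_equal(ev$fS_exp + ev$fM_exp + ev$fN_exp, 1)
  expect_equal(round(unlist(ev), 5),
               c(fS_exp = 0.24408, fM_exp = 0.71403, fN_exp = 0.04189))
})

test_that("expected fractions match hand-enumerated single-codon compositions", {
  tgg <- expected_fractions(c(TGG = 1), uniform_profile())
  expect_equal(tgg$fS_exp, 0)
  expect_equal(tgg$fM_exp, 7 / 9)
  expect_equal(tgg$fN_exp, 2 / 9)
  atg <- expected_fractions(c(ATG = 5), tumor_average_profile())
  expect_equal(atg$fM_exp, 1)
  expect_error(expected_fractions(tibble::tibble(), uniform_profile()), "Empty")
  bad <- c("C>A" = 0.5, "C>G" = 0.4, "C>T" = 0.2, "T>A" = 0, "T>C" = 0, "T>G" = 0)
  expect_error(expected_fractions(c(ATG = 1), bad), "sum to 1")
})

test_that("expectation model agrees with brute-force weighted enumeration", {
  set.seed(101)
  for (i in 1:100) {
    codons <- sample(sense_codons(), sample(3:12, 1))
    counts <- stats::setNames(sample(1:20, length(codons), replace = TRUE), codons)
    p <- stats::runif(6)
    p <- stats::setNames(p / sum(p), substitution_classes())
    got <- expected_fractions(counts, signature_profile(p))
    want <- oracle_expected_fractions(as.list(counts), as.list(p))
    expect_equal(got$fS_exp, want[["silent"]], tolerance = 1e-12)
    expect_equal(got$fM_exp, want[["missense"]], tolerance = 1e-12)
    expect_equal(got$fN_exp, want[["nonsense"]], tolerance = 1e-12)
  }
})

test_that("class-mass shifts move expectations the way the code structure dictates", {
  comp <- stats::setNames(rep(1, 61), sense_codons())
  base <- expected_fractions(comp, uniform_profile())
  shift_to <- function(cls, eps = 0.3) {
    p <- rep((1 - eps) / 6, 6)
    names(p) <- substitution_classes()
    p[cls] <- p[cls] + eps
    expected_fractions(comp, signature_profile(p))
  }
  # transition-heavy spectra (C>T, T>C) favor silent changes;
  # C>G dominance favors missense
  expect_gt(shift_to("C>T")$fS_exp, base$fS_exp)
  expect_gt(shift_to("T>C")$fS_exp, base$fS_exp)
  expect_gt(shift_to("C>G")$fM_exp, base$fM_exp)
})

test_that("96-channel collapse sums context channels per class", {
  ch <- names(synthetic_sbs1())
  uni <- stats::setNames(rep(1 / 96, 96), ch)
  expect_equal(as.numeric(collapse_96_to_6(uni)), rep(1 / 6, 6), tolerance = 1e-12)

  delta <- stats::setNames(rep(0, 96), ch)
  delta["A[C>T]G"] <- 1
  expect_equal(as.numeric(collapse_96_to_6(delta)),
               c(0, 0, 1, 0, 0, 0))

  two <- stats::setNames(rep(0, 96), ch)
  two["A[C>A]A"] <- 0.5
  two["T[T>G]T"] <- 0.5
  expect_equal(as.numeric(collapse_96_to_6(two)), c(0.5, 0, 0, 0, 0, 0.5))

  expect_error(collapse_96_to_6(uni[-1]), "Malformed")
})

test_that("profile mixing is a convex combination", {
  d1 <- signature_profile(
    c("C>A" = 0, "C>G" = 0, "C>T" = 1, "T>A" = 0, "T>C" = 0, "T>G" = 0))
  d2 <- signature_profile(
    c("C>A" = 0, "C>G" = 0, "C>T" = 0, "T>A" = 1, "T>C" = 0, "T>G" = 0))
  expect_equal(as.numeric(mix_profiles(list(d1), 1)), as.numeric(d1))
  expect_equal(as.numeric(mix_profiles(list(d1, d2), c(0.5, 0.5))),
               c(0, 0, 0.5, 0.5, 0, 0))
  expect_equal(as.numeric(mix_profiles(list(d1, d2), c(0.1, 0.9))),
               c(0, 0, 0.1, 0.9, 0, 0))
  expect_error(mix_profiles(list(d1, d2), c(0.5, 0.4)), "sum to 1")
  expect_error(mix_profiles(list(d1), c(0.5, 0.5)), "equal length")
})

test_that("cohort-average profile weights signatures by attributed mutations", {
  ch <- names(synthetic_sbs1())
  dA <- stats::setNames(rep(0, 96), ch); dA["A[C>T]G"] <- 1
  dB <- stats::setNames(rep(0, 96), ch); dB["A[T>A]G"] <- 1
  sigs <- list(SA = dA, SB = dB)
  att1 <- tibble::tibble(sample = "s1", SA = 10, SB = 0)
  expect_equal(as.numeric(cohort_average_profile(att1, sigs)),
               as.numeric(collapse_96_to_6(dA)))
  att2 <- tibble::tibble(sample = c("s1", "s2"), SA = c(10, 0), SB = c(0, 10))
  expect_equal(as.numeric(cohort_average_profile(att2, sigs)),
               c(0, 0, 0.5, 0.5, 0, 0))
  # activity- vs sample-weighting differ when burdens differ
  att3 <- tibble::tibble(sample = c("s1", "s2"), SA = c(30, 0), SB = c(0, 10))
  expect_equal(as.numeric(cohort_average_profile(att3, sigs))[3], 0.75)
  expect_equal(as.numeric(cohort_average_profile(att3, sigs, weighting = "sample"))[3], 0.5)
  expect_error(cohort_average_profile(att2, sigs["SA"]), "missing")
  att0 <- tibble::tibble(sample = "s1", SA = 0, SB = 0)
  expect_error(cohort_average_profile(att0, sigs), "activity")
})

test_that("germline default profile is the 0.1/0.9 SBS1/SBS5 mixture", {
  g <- germline_default_profile()
  expect_equal(sum(g), 1, tolerance = 1e-12)
  byhand <- 0.1 * collapse_96_to_6(synthetic_sbs1()) +
    0.9 * collapse_96_to_6(synthetic_sbs5())
  expect_equal(as.numeric(g), as.numeric(byhand), tolerance = 1e-12)
})

test_that("codon composition handles frames, stops and ambiguity codes", {
  comp <- codon_composition(c(t1 = "ATGAAATAA"))  # terminal stop dropped
  expect_equal(sum(comp$count), 2)
  expect_error(codon_composition(c(t1 = "ATGA")), "frame")
  expect_error(codon_composition(c(t1 = "ATGTAAAAA")), "Stop codon")
  expect_error(codon_composition(c(t1 = "ATGANA")), "Malformed")
})

test_that("signature matrix TSVs round-trip through the reader", {
  ch <- names(synthetic_sbs1())
  df <- tibble::tibble(Type = ch, SBSX = as.numeric(synthetic_sbs1()),
                       SBSY = as.numeric(synthetic_sbs5()))
  path <- write_fixture_tsv(df)
  sigs <- read_signature_matrix(path)
  expect_named(sigs, c("SBSX", "SBSY"))
  expect_equal(as.numeric(collapse_96_to_6(sigs$SBSX)),
               as.numeric(collapse_96_to_6(synthetic_sbs1())), tolerance = 1e-12)
})
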