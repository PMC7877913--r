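test_that("CDS simulation is deterministic, stop-free and ATG-initiated", {
  set.seed(7)
  a <- simulate_cds(10, c(300, 300))
  set.seed(7)
  b <- simulate_cds(10, c(300, 300))
  expect_identical(a, b)
  expect_true(all(nchar(a) == 900))
  expect_true(all(startsWith(a, "ATG")))
  comp <- codon_composition(a)  # errors if any stop codon present
  expect_equal(sum(comp$count), 10 * 300)
  set.seed(1)
  expect_true(all(nchar(simulate_cds(50, 100)) == 300))
})

test_that("uniform codon usage is statistically uniform", {
  set.seed(99)
  cds <- simulate_cds(40, c(200, 200))
  comp <- codon_composition(cds) |>
    dplyr::group_by(codon) |>
    dplyr::summarise(count = sum(count))
  # drop the forced initiator ATGs before testing uniformity
  comp$count[comp$codon == "ATG"] <- comp$count[comp$codon == "ATG"] - 40
  expect_gt(stats::chisq.test(comp$count)$p.value, 0.001)
})

test_that("whole-cohort generation is seed-deterministic", {
  cfg <- simulation_config(n_transcripts = 60, seed = 123)
  a <- simulate_cohort(cfg, germline = TRUE)
  b <- simulate_cohort(cfg, germline = TRUE)
  expect_identical(a$cds, b$cds)
  expect_identical(a$somatic, b$somatic)
  expect_identical(a$germline, b$germline)
  expect_identical(a$truth, b$truth)
  expect_identical(a$essentiality, b$essentiality)
})

test_that("generated tables pass reading and filtering with no unexplained rejects", {
  coh <- small_cohort(n = 80, seed = 19)
  rec <- parse_somatic_records(coh$somatic)
  expect_equal(nrow(attr(rec, "rejected")), 0)
  kept <- suppressMessages(apply_filters(rec))
  drops <- attr(kept, "drop_counts")
  # every dropped record is a planted contaminant or a sampling duplicate
  n_contam <- sum(coh$somatic$SNP == "y") +
    sum(coh$somatic$`Sample Type` == "cell-line")
  expect_equal(sum(drops[c("sample_type", "snp_flag")]), n_contam)
  expect_equal(unname(drops["category"]), 0L)
  expect_equal(unname(drops["somatic_status"]), 0L)
  # contaminant fractions track the configured binomial rates
  cfg <- coh$config
  n_real <- nrow(coh$somatic) - n_contam
  rate_hat <- n_contam / n_real
  rate_cfg <- cfg$cell_line_rate + cfg$snp_rate
  expect_lt(abs(rate_hat - rate_cfg), 0.02)
})

test_that("neutral generation reproduces the closed-form expectation at scale", {
  cfg <- simulation_config(
    n_transcripts = 60, seed = 41,
    regimes = default_regimes()[1, ] |> dplyr::mutate(fraction = 1),
    count_range = c(1500, 1500), profile = uniform_profile(),
    cell_line_rate = 0, snp_rate = 0, inframe_rate = 0, frameshift_rate = 0
  )
  coh <- simulate_cohort(cfg)
  rec <- suppressMessages(apply_filters(parse_somatic_records(coh$somatic)))
  n <- nrow(rec)
  f <- c(mean(rec$category == "silent"), mean(rec$category == "missense"),
         mean(rec$category == "nonsense"))
  ev <- unlist(uniform_code_expectation())
  se <- sqrt(ev * (1 - ev) / n)
  expect_true(all(abs(f - ev) < 4 * se))
})

test_that("TSG and TEG regimes push the metrics past their class thresholds", {
  base <- default_regimes()
  mk <- function(lab) {
    cfg <- simulation_config(
      n_transcripts = 60, seed = 53,
      regimes = base[base$label == lab, ] |> dplyr::mutate(fraction = 1),
      count_range = c(150, 150)
    )
    coh <- simulate_cohort(cfg)
    rec <- suppressMessages(apply_filters(parse_somatic_records(coh$somatic)))
    tal <- tally_by_transcript(rec)
    list(
      so = add_ratios(observed_fractions(tal, "SO")),
      ssi = add_ratios(observed_fractions(tal, "SSI"))
    )
  }
  tsg <- mk("TSG")
  expect_gt(mean(tsg$ssi$rNSM > 0.125), 0.8)  # indel_rNSM beyond the TSG cut
  teg <- mk("TEG")
  expect_gt(mean(teg$so$rSMN > 0.5), 0.8)
  # the OG effect size (missense boost on 30% of codons, nonsense
  # suppression) puts most but not all planted genes past the rMSN cut at
  # 150 mutations
  og <- mk("OG")
  expect_gt(mean(og$so$rMSN > 3), 0.7)
})

test_that("germline generator emits multi-allelic rsIDs at the configured rate", {
  cfg <- simulation_config(n_transcripts = 40, seed = 71, multiallelic_rate = 0.1)
  coh <- simulate_cohort(cfg, germline = TRUE)
  g <- coh$germline
  frac2 <- mean(stringr::str_detect(g$Alleles, ","))
  n <- nrow(g)
  expect_lt(abs(frac2 - 0.1), 4 * sqrt(0.1 * 0.9 / n))
  rec <- read_germline_table(write_fixture_tsv(g))
  expect_equal(nrow(attr(rec, "rejected")), 0)
  expect_equal(nrow(rec), sum(stringr::str_count(g$Alleles, ",") + 1))
})

test_that("identical multipliers and profile make germline match somatic fractions", {
  cfg <- simulation_config(
    n_transcripts = 50, seed = 83,
    regimes = default_regimes()[1, ] |> dplyr::mutate(fraction = 1),
    count_range = c(400, 400),
    profile = uniform_profile(),
    germline_profile = uniform_profile(),
    germline_multipliers = c(S = 1, M = 1, N = 1),
    cell_line_rate = 0, snp_rate = 0, inframe_rate = 0, frameshift_rate = 0,
    multiallelic_rate = 0
  )
  coh <- simulate_cohort(cfg, germline = TRUE)
  rec_s <- suppressMessages(apply_filters(parse_somatic_records(coh$somatic)))
  rec_g <- read_germline_table(write_fixture_tsv(coh$germline))
  fS_s <- mean(rec_s$category == "silent")
  fS_g <- mean(rec_g$category == "silent")
  n <- nrow(rec_s)
  expect_lt(abs(fS_s - fS_g), 4 * sqrt(2 * 0.25 / n))
})

test_that("cohort files round-trip through disk with identical content", {
  coh <- small_cohort(n = 25, seed = 29)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cds.fasta", "somatic.tsv", "truth.tsv", "essentiality.tsv", "config.json")
  ))))
  cds2 <- read_cds_fasta(file.path(dir, "cds.fasta"))
  expect_identical(cds2, coh$cds)
  som2 <- readr::read_tsv(file.path(dir, "somatic.tsv"), show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  expect_equal(as.data.frame(som2), as.data.frame(coh$somatic))
  cfg2 <- jsonlite::fromJSON(file.path(dir, "config.json"))
  expect_equal(cfg2$seed, coh$config$seed)
  expect_equal(cfg2$n_transcripts, coh$config$n_transcripts)
  expect_equal(unlist(cfg2$profile), unclass(coh$config$profile)[names(cfg2$profile)])
})
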