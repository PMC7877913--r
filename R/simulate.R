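#' Planted selection regimes
#'
#' Selection is implemented as event-level weighted sampling: each possible
#' mutation's probability (profile weight of its substitution class) is
#' multiplied by the regime's acceptance multiplier for its effect
#' category. `w = (w_S, w_M, w_N)` of (1, 1, 1) is the neutral passenger
#' regime. Defaults:
#' * `PG` -- neutral.
#' * `TSG` -- positive selection for truncating events: `w_N = 8`,
#'   frameshift-indel rate x 4.
#' * `OG` -- positive selection for activating missense at driver sites
#'   (30% of codons get missense weight x 2.5) with purifying selection
#'   against truncation (`w_N = 0.2`, frameshift x 0.2).
#' * `TEG` -- purifying selection against amino-acid-changing events:
#'   `w = (1, 0.5, 0.3)`, frameshift x 0.3, inframe x 0.5.
#'
#' @return Tibble with one row per regime and columns `label`, `fraction`,
#'   `w_S`, `w_M`, `w_N`, `driver_fraction`, `driver_boost`, `fs_mult`,
#'   `inframe_mult`, `hotspot_sites`, `hotspot_boost`.
#' @export
default_regimes <- function() {
  tibble(
    label          = c("PG", "TSG", "OG", "TEG"),
    fraction       = c(0.70, 0.10, 0.10, 0.10),
    w_S            = c(1, 1, 1, 1),
    w_M            = c(1, 1, 1, 0.5),
    w_N            = c(1, 8, 0.2, 0.3),
    driver_fraction = c(0, 0, 0.3, 0),
    driver_boost   = c(1, 1, 2.5, 1),
    fs_mult        = c(1, 4, 0.2, 0.3),
    inframe_mult   = c(1, 1, 1, 0.5),
    hotspot_sites  = c(0L, 0L, 0L, 0L),
    hotspot_boost  = c(1, 1, 1, 1)
  )
}

#' @rdname default_regimes
#' @param fraction Cohort fraction assigned to the hotspot regime.
#' @param sites Number of adjacent codons forming the silent hotspot.
#' @param boost Multiplier applied to silent changes at hotspot codons. The
#'   default makes the hotspot carry well over half of a gene's silent hits
#'   across the default CDS-length range (the defining property of a silent
#'   hotspot), mimicking recurrent synonymous mutation that falsely
#'   suggests purifying selection.
#' @export
hotspot_regime <- function(fraction = 0.1, sites = 3L, boost = 300) {
  tibble(
    label = "HOTSPOT_PG", fraction = fraction,
    w_S = 1, w_M = 1, w_N = 1,
    driver_fraction = 0, driver_boost = 1,
    fs_mult = 1, inframe_mult = 1,
    hotspot_sites = as.integer(sites), hotspot_boost = boost
  )
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is tested under:
#' 3000 transcripts of 100-300 codons with uniform codon usage, 100-300
#' somatic mutations per transcript, the pan-tumor average substitution
#' profile, subtle-indel rates of 1% (inframe) and 4% (frameshift) relative
#' to substitutions, and small contaminant fractions (cell-line rows,
#' SNP-flagged rows) to exercise the filters. Germline variants are
#' generated under the 0.1xSBS1 + 0.9xSBS5 profile with uniform
#' organism-level purifying multipliers.
#'
#' @param n_transcripts Number of transcripts.
#' @param regimes Regime table, see [default_regimes()].
#' @param cds_length Codon-count range (uniform integer draw), or a single
#'   number for constant length.
#' @param count_dist `"uniform"` (over `count_range`) or `"nbinom"`
#'   (mean `count_mean`, size `count_dispersion`; heavy-tailed per-gene
#'   burden).
#' @param count_range,count_mean,count_dispersion Mutation-count
#'   distribution parameters.
#' @param profile Somatic substitution profile.
#' @param germline_profile Germline substitution profile.
#' @param germline_multipliers Organism-level acceptance multipliers
#'   `c(S=, M=, N=)` applied uniformly in germline generation.
#' @param inframe_rate,frameshift_rate Indel event mass relative to a
#'   substitution mass of 1 (before regime multipliers).
#' @param cell_line_rate,snp_rate Expected contaminant rows per somatic
#'   record (binomial).
#' @param multiallelic_rate Probability that a germline rsID carries a
#'   second alternate allele.
#' @param n_samples Tumor sample pool size.
#' @param seed Integer seed; fully determines all outputs.
#' @return List with class `"simulation_config"`.
#' @export
simulation_config <- function(n_transcripts = 3000,
                              regimes = default_regimes(),
                              cds_length = c(100, 300),
                              count_dist = c("uniform", "nbinom"),
                              count_range = c(100, 300),
                              count_mean = 200,
                              count_dispersion = 10,
                              profile = tumor_average_profile(),
                              germline_profile = germline_default_profile(),
                              germline_multipliers = c(S = 1, M = 0.6, N = 0.3),
                              inframe_rate = 0.01,
                              frameshift_rate = 0.04,
                              cell_line_rate = 0.05,
                              snp_rate = 0.03,
                              multiallelic_rate = 0.05,
                              n_samples = 1000,
                              seed = 1L) {
  count_dist <- match.arg(count_dist)
  stopifnot(
    n_transcripts >= 1,
    abs(sum(regimes$fraction) - 1) < 1e-9,
    all(c("S", "M", "N") %in% names(germline_multipliers))
  )
  structure(
    list(
      n_transcripts = as.integer(n_transcripts), regimes = regimes,
      cds_length = cds_length, count_dist = count_dist,
      count_range = count_range, count_mean = count_mean,
      count_dispersion = count_dispersion,
      profile = .check_profile(profile),
      germline_profile = .check_profile(germline_profile),
      germline_multipliers = germline_multipliers,
      inframe_rate = inframe_rate, frameshift_rate = frameshift_rate,
      cell_line_rate = cell_line_rate, snp_rate = snp_rate,
      multiallelic_rate = multiallelic_rate,
      n_samples = as.integer(n_samples), seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# cached per-codon change lookups: 61 x 9 matrices over (codon, change slot)
.sim_lookup <- function() {
  if (!is.null(.pkg_cache$sim_lookup)) return(.pkg_cache$sim_lookup)
  tab <- substitution_table()  # ordered by codon, position, alt
  codons <- sense_codons()
  tab <- tab[order(match(tab$codon, codons)), ]
  mk <- function(x) matrix(x, nrow = length(codons), ncol = 9, byrow = TRUE,
                           dimnames = list(codons, NULL))
  lk <- list(
    pos = mk(tab$position),
    ref = mk(tab$ref),
    alt = mk(tab$alt),
    eff = mk(match(tab$effect, c("silent", "missense", "nonsense"))),
    cls = mk(match(tab$class, substitution_classes()))
  )
  .pkg_cache$sim_lookup <- lk
  lk
}

#' Simulate stop-free coding sequences
#'
#' Random sense-codon sequences beginning with ATG, codons drawn uniformly
#' from the 61 sense codons (no terminal stop codon is appended; the
#' expectation model censuses sense codons only).
#'
#' @param n Number of transcripts.
#' @param length_codons Codon-count range `c(min, max)` (uniform integer),
#'   or one constant value. Lengths include the initiator ATG.
#' @param prefix Transcript identifier prefix.
#' @return Named character vector of CDS sequences.
#' @export
simulate_cds <- function(n, length_codons = c(100, 300), prefix = "TX") {
  if (length(length_codons) == 1) length_codons <- rep(length_codons, 2)
  lens <- .sample_range(length_codons, n)
  codons <- sense_codons()
  seqs <- vapply(lens, function(L) {
    paste0("ATG", paste(sample(codons, L - 1, replace = TRUE), collapse = ""))
  }, character(1))
  names(seqs) <- sprintf("%s%05d", prefix, seq_len(n))
  seqs
}

.sample_range <- function(rng, n) {
  vals <- seq(rng[1], rng[length(rng)])
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}

.draw_counts <- function(n, config) {
  if (config$count_dist == "uniform") {
    .sample_range(config$count_range, n)
  } else {
    pmax(1L, stats::rnbinom(n, mu = config$count_mean, size = config$count_dispersion))
  }
}

# core event sampler for one transcript; returns substitution events plus
# indel counts. regime is a one-row regime list.
.sample_events <- function(codon_idx, n_mut, profile6, regime, lookup) {
  L <- length(codon_idx)
  W <- matrix(profile6[lookup$cls[codon_idx, , drop = FALSE]], nrow = L) *
    matrix(c(regime$w_S, regime$w_M, regime$w_N)[lookup$eff[codon_idx, , drop = FALSE]],
           nrow = L)
  if (regime$driver_fraction > 0 && regime$driver_boost != 1) {
    drivers <- sample.int(L, max(1L, round(regime$driver_fraction * L)))
    boost <- matrix(1, nrow = L, ncol = 9)
    is_m <- lookup$eff[codon_idx[drivers], , drop = FALSE] == 2L
    boost[drivers, ][is_m] <- regime$driver_boost
    W <- W * boost
  }
  if (regime$hotspot_sites > 0 && regime$hotspot_boost != 1) {
    # a synonymous hotspot needs silent-capable codons (ATG/TGG have none)
    can_silent <- which(rowSums(lookup$eff[codon_idx, , drop = FALSE] == 1L) > 0)
    hs <- sample(can_silent, min(regime$hotspot_sites, length(can_silent)))
    boost <- matrix(1, nrow = L, ncol = 9)
    is_s <- lookup$eff[codon_idx[hs], , drop = FALSE] == 1L
    boost[hs, ][is_s] <- regime$hotspot_boost
    W <- W * boost
  }
  w <- as.vector(W)
  p_inf <- regime$inframe_mult * regime$inframe_rate
  p_fs <- regime$fs_mult * regime$frameshift_rate
  n_type <- as.vector(stats::rmultinom(1, n_mut, c(1, p_inf, p_fs)))
  idx <- sample.int(L * 9L, n_type[1], replace = TRUE, prob = w)
  r <- ((idx - 1L) %% L) + 1L
  s <- ((idx - 1L) %/% L) + 1L
  ci <- codon_idx[r]
  flat <- cbind(ci, s)
  list(
    position = (r - 1L) * 3L + lookup$pos[flat],
    ref = lookup$ref[flat],
    alt = lookup$alt[flat],
    eff = lookup$eff[flat],
    cls = lookup$cls[flat],
    n_inframe = n_type[2],
    n_frameshift = n_type[3],
    cds_len_nt = L * 3L
  )
}

.CATEGORY_DESCRIPTION <- c(
  silent = "Substitution - coding silent",
  missense = "Substitution - Missense",
  nonsense = "Substitution - Nonsense",
  inframe = "Deletion - In frame",
  frameshift = "Deletion - Frameshift"
)

.SITES <- c("lung", "breast", "large_intestine", "skin", "liver", "prostate")

#' Simulate a COSMIC-like somatic mutation table
#'
#' For every mutation event a (site, alternative base) is drawn with weight
#' equal to the profile probability of its substitution class times the
#' regime's acceptance multiplier for its effect (weighted sampling is
#' distribution-equivalent to rejection sampling against selection and
#' exactly seedable). Frameshift and inframe indels are emitted at the
#' configured rates times the regime multiplier, with position and frame
#' class only (tallies consume nothing else). Records carry
#' dialect-correct flags (Confirmed somatic, SNP "n", tissue sample type);
#' contaminant rows (cell-line sample type, SNP-flagged) are added at the
#' configured binomial rates to exercise the filters.
#'
#' @param cds Named character vector of CDS sequences.
#' @param truth Tibble with `transcript_id`, `label` assigning a regime to
#'   every transcript.
#' @param config See [simulation_config()].
#' @return Tibble in the [cosmic_dialect()] column layout.
#' @export
simulate_somatic <- function(cds, truth, config = simulation_config()) {
  lookup <- .sim_lookup()
  codons61 <- sense_codons()
  regimes <- split(config$regimes, config$regimes$label)
  missing <- setdiff(truth$label, names(regimes))
  if (length(missing) > 0) {
    abort(sprintf("Regime(s) not in config: %s.", paste(missing, collapse = ", ")))
  }
  stopifnot(all(truth$transcript_id %in% names(cds)))
  n_mut <- .draw_counts(nrow(truth), config)
  profile6 <- as.numeric(config$profile)
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tx <- truth$transcript_id[i]
    seq_i <- cds[[tx]]
    codon_idx <- match(
      substring(seq_i, seq(1, nchar(seq_i), 3), seq(3, nchar(seq_i), 3)),
      codons61
    )
    reg <- as.list(regimes[[truth$label[i]]][1, ])
    reg$inframe_rate <- config$inframe_rate
    reg$frameshift_rate <- config$frameshift_rate
    ev <- .sample_events(codon_idx, n_mut[i], profile6, reg, lookup)
    n_sub <- length(ev$position)
    n_cell <- stats::rbinom(1, n_mut[i], config$cell_line_rate)
    n_snp <- stats::rbinom(1, n_mut[i], config$snp_rate)
    # contaminants re-draw substitution events with contaminating flags
    contam <- .sample_events(codon_idx, n_cell + n_snp, profile6, reg, lookup)
    n_con <- length(contam$position)
    cat_main <- c(
      c("silent", "missense", "nonsense")[ev$eff],
      rep("inframe", ev$n_inframe), rep("frameshift", ev$n_frameshift)
    )
    indel_pos <- if (ev$n_inframe + ev$n_frameshift > 0) {
      sample.int(ev$cds_len_nt, ev$n_inframe + ev$n_frameshift, replace = TRUE)
    } else integer(0)
    cds_change <- c(
      if (n_sub > 0) paste0("c.", ev$position, ev$ref, ">", ev$alt) else character(0),
      if (ev$n_inframe > 0) paste0("c.", indel_pos[seq_len(ev$n_inframe)], "_",
                                   indel_pos[seq_len(ev$n_inframe)] + 2, "del") else character(0),
      if (ev$n_frameshift > 0) paste0("c.", indel_pos[seq_len(ev$n_frameshift) + ev$n_inframe], "del") else character(0)
    )
    cat_con <- c("silent", "missense", "nonsense")[contam$eff]
    n_all <- length(cat_main) + n_con
    is_cell <- c(rep(FALSE, length(cat_main)),
                 rep(c(TRUE, FALSE), c(n_cell, n_snp))[seq_len(n_con)])
    is_snp <- c(rep(FALSE, length(cat_main)), !is_cell[length(cat_main) + seq_len(n_con)])
    out[[i]] <- tibble(
      gene = sub("^TX", "G", tx),
      transcript = tx,
      description = unname(.CATEGORY_DESCRIPTION[c(cat_main, cat_con)]),
      cds_change = c(cds_change,
                     if (n_con > 0) paste0("c.", contam$position, contam$ref, ">", contam$alt) else character(0)),
      somatic_status = "Confirmed somatic variant",
      sample_type = ifelse(is_cell, "cell-line", "Tumour Sample"),
      snp = ifelse(is_snp, "y", "n"),
      sample_id = paste0("S", sample.int(config$n_samples, n_all, replace = TRUE)),
      site = sample(.SITES, n_all, replace = TRUE)
    )
  }
  df <- dplyr::bind_rows(out)
  d <- cosmic_dialect()
  names(df) <- unname(unlist(d[c("gene", "transcript", "description", "cds_change",
                                 "somatic_status", "sample_type", "snp",
                                 "sample_id", "site")]))
  df$`Mutation AA` <- "p.?"
  df[, unlist(d)]
}

#' Simulate a dbSNP-like germline variant table
#'
#' Same event mechanism as [simulate_somatic()] under the germline profile,
#' with organism-level purifying multipliers applied uniformly to all
#' transcripts (no per-gene regimes) and no indels. A configured fraction
#' of rsIDs carries a second alternate allele at the same site; each
#' allele is an independent polymorphism for tallying.
#'
#' @param cds Named character vector of CDS sequences.
#' @param config See [simulation_config()].
#' @param multipliers Named acceptance multipliers `c(S=, M=, N=)`;
#'   defaults to `config$germline_multipliers`.
#' @return Tibble in the [dbsnp_dialect()] column layout (multi-allelic
#'   rows carry comma-separated alleles and consequences).
#' @export
simulate_germline <- function(cds, config = simulation_config(),
                              multipliers = config$germline_multipliers) {
  lookup <- .sim_lookup()
  codons61 <- sense_codons()
  profile6 <- as.numeric(config$germline_profile)
  csq <- c("synonymous_variant", "missense_variant", "stop_gained")
  n_var <- .draw_counts(length(cds), config)
  reg <- list(
    w_S = multipliers[["S"]], w_M = multipliers[["M"]], w_N = multipliers[["N"]],
    driver_fraction = 0, driver_boost = 1, hotspot_sites = 0, hotspot_boost = 1,
    inframe_mult = 0, fs_mult = 0, inframe_rate = 0, frameshift_rate = 0
  )
  out <- vector("list", length(cds))
  rs_offset <- 0L
  for (i in seq_along(cds)) {
    seq_i <- cds[[i]]
    codon_idx <- match(
      substring(seq_i, seq(1, nchar(seq_i), 3), seq(3, nchar(seq_i), 3)),
      codons61
    )
    ev <- .sample_events(codon_idx, n_var[i], profile6, reg, lookup)
    n <- length(ev$position)
    alleles <- ev$alt
    consequences <- csq[ev$eff]
    second <- stats::runif(n) < config$multiallelic_rate
    if (any(second)) {
      w <- which(second)
      pos <- ev$position[w]
      codon_i <- (pos - 1L) %/% 3L
      within <- pos - codon_i * 3L
      codon <- substr(rep(seq_i, length(w)), codon_i * 3L + 1L, codon_i * 3L + 3L)
      alt2 <- vapply(seq_along(w), function(j) {
        sample(setdiff(.BASES, c(ev$ref[w[j]], ev$alt[w[j]])), 1)
      }, character(1))
      eff2 <- effect_of_substitution(codon, within, alt2)
      alleles[w] <- paste(alleles[w], alt2, sep = ",")
      consequences[w] <- paste(
        consequences[w],
        csq[match(eff2, c("silent", "missense", "nonsense"))],
        sep = ","
      )
    }
    out[[i]] <- tibble(
      rsid = paste0("rs", rs_offset + seq_len(n)),
      transcript = names(cds)[i],
      alleles = alleles,
      consequence = consequences
    )
    rs_offset <- rs_offset + n
  }
  df <- dplyr::bind_rows(out)
  names(df) <- unname(unlist(dbsnp_dialect()))
  df
}

#' Simulate cell-essentiality scores
#'
#' Scores are drawn from label-conditional normal distributions; by default
#' every label shares the same distribution, encoding the null that
#' tumor-essential genes are not more cell-essential than passengers
#' (knockout-screen convention: more negative = more essential).
#'
#' @param truth Tibble with `transcript_id`, `label`.
#' @param mean,sd Baseline score distribution.
#' @param shift_by_label Optional named numeric of per-label mean shifts,
#'   e.g. `c(TEG = -0.2)`.
#' @return Tibble with `gene_id` (= transcript id), `label`, `score`.
#' @export
simulate_essentiality <- function(truth, mean = -0.1, sd = 0.2,
                                  shift_by_label = NULL) {
  mu <- rep(mean, nrow(truth))
  if (!is.null(shift_by_label)) {
    sh <- shift_by_label[truth$label]
    mu <- mu + ifelse(is.na(sh), 0, sh)
  }
  tibble(
    gene_id = truth$transcript_id,
    label = truth$label,
    score = stats::rnorm(nrow(truth), mu, sd)
  )
}

#' Assign regimes to transcripts in fixed proportions
#'
#' @param n Number of transcripts.
#' @param regimes Regime table with `label` and `fraction`.
#' @return Character vector of labels (shuffled).
#' @export
assign_regimes <- function(n, regimes = default_regimes()) {
  counts <- floor(regimes$fraction * n)
  counts[1] <- counts[1] + (n - sum(counts))
  sample(rep(regimes$label, counts))
}

#' Simulate a full synthetic cohort
#'
#' Generates CDS, somatic and germline tables, truth labels and
#' essentiality scores under one seed; the seed fully determines all
#' outputs.
#'
#' @param config See [simulation_config()].
#' @param germline Also generate the germline table (slower; off for
#'   somatic-only studies).
#' @return List with class `"sel_cohort"`: `cds`, `somatic`, `germline`
#'   (or NULL), `truth`, `essentiality`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), germline = FALSE) {
  set.seed(config$seed)
  cds <- simulate_cds(config$n_transcripts, config$cds_length)
  truth <- tibble(
    transcript_id = names(cds),
    label = assign_regimes(config$n_transcripts, config$regimes)
  )
  somatic <- simulate_somatic(cds, truth, config)
  germ <- if (germline) simulate_germline(cds, config) else NULL
  ess <- simulate_essentiality(truth)
  structure(
    list(cds = cds, somatic = somatic, germline = germ, truth = truth,
         essentiality = ess, config = config),
    class = "sel_cohort"
  )
}

#' Write a simulated cohort to disk
#'
#' CDS as FASTA, tables as TSV, configuration snapshot as JSON.
#'
#' @param cohort From [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(cohort$cds),
    file.path(dir, "cds.fasta")
  )
  readr::write_tsv(cohort$somatic, file.path(dir, "somatic.tsv"))
  if (!is.null(cohort$germline)) {
    readr::write_tsv(cohort$germline, file.path(dir, "germline.tsv"))
  }
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(cohort$essentiality, file.path(dir, "essentiality.tsv"))
  cfg <- cohort$config
  cfg$profile <- as.list(unclass(cfg$profile))
  cfg$germline_profile <- as.list(unclass(cfg$germline_profile))
  writeLines(
    jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(dir, "config.json")
  )
  invisible(dir)
}
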