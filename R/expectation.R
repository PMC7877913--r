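#' Codon composition of coding sequences
#'
#' Splits each CDS into codons and counts them. Sequences must be in frame
#' (length divisible by 3), contain only A/C/G/T (ambiguity codes are an
#' error, not silently skipped, since skipping would bias the
#' composition-dependent expectations), and contain no internal stop
#' codon. A terminal stop codon, if present, is dropped:
#' expectations are computed over sense codons only, including the
#' initiator ATG.
#'
#' @param cds Named character vector of CDS sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return Tibble with columns `transcript_id`, `codon`, `count`.
#' @export
codon_composition <- function(cds) {
  if (methods::is(cds, "DNAStringSet")) {
    cds <- stats::setNames(as.character(cds), names(cds))
  }
  if (!is.character(cds) || is.null(names(cds)) || any(names(cds) == "")) {
    abort("`cds` must be a named character vector or DNAStringSet.")
  }
  bad_len <- nchar(cds) %% 3 != 0 | nchar(cds) < 3
  if (any(bad_len)) {
    abort(sprintf(
      "CDS not in frame (length not a positive multiple of 3): %s.",
      paste(names(cds)[bad_len], collapse = ", ")
    ))
  }
  rows <- purrr::imap(cds, function(seq, id) {
    codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
    n <- length(codons)
    if (codons[n] %in% .STOP_CODONS) codons <- codons[-n]
    .check_sense_codon(codons, arg = id)
    tab <- table(codons)
    tibble(transcript_id = id, codon = names(tab), count = as.integer(tab))
  })
  dplyr::bind_rows(rows)
}

# per-codon expected effect mass under a profile: 61 x 3 matrix
# (rows = sense codons, cols = silent/missense/nonsense), entry = sum over
# the codon's nine possible changes of the profile probability of the
# change's class, split by effect. Each directed change inherits the full
# class probability (no intra-class split); normalization downstream makes
# this well defined.
.codon_effect_mass <- function(profile) {
  profile <- .check_profile(profile)
  tab <- substitution_table()
  effs <- c("silent", "missense", "nonsense")
  w <- unname(profile[tab$class])
  m <- vapply(effs, function(e) {
    tapply(w * (tab$effect == e), tab$codon, sum)
  }, numeric(length(sense_codons())))
  m[sense_codons(), , drop = FALSE]
}

#' Expected silent/missense/nonsense fractions for codon compositions
#'
#' Every possible single-base change of every codon instance is weighted by
#' the profile probability of its substitution class; the expected fraction
#' of a category is its weighted mass divided by the total weighted mass.
#' This is the neutral (selection-free) expectation against which observed
#' fractions are compared.
#'
#' @param composition Tibble as from [codon_composition()]
#'   (`transcript_id`, `codon`, `count`), or a named numeric vector of
#'   codon counts for a single anonymous transcript.
#' @param profile Six-class substitution profile (see
#'   [signature_profile()]).
#' @return Tibble with columns `transcript_id`, `fS_exp`, `fM_exp`,
#'   `fN_exp` (summing to 1 per transcript).
#' @examples
#' expected_fractions(c(TGG = 1), uniform_profile())  # fS 0, fM 7/9, fN 2/9
#' @export
expected_fractions <- function(composition, profile) {
  if (is.numeric(composition)) {
    composition <- tibble(
      transcript_id = ".", codon = names(composition),
      count = as.numeric(composition)
    )
  }
  stopifnot(is.data.frame(composition))
  if (nrow(composition) == 0) abort("Empty codon composition.")
  if (any(composition$count < 0)) abort("Codon counts must be non-negative.")
  .check_sense_codon(composition$codon)
  mass <- .codon_effect_mass(profile)
  ids <- unique(composition$transcript_id)
  cmat <- matrix(0, nrow = length(ids), ncol = nrow(mass),
                 dimnames = list(ids, rownames(mass)))
  cmat[cbind(
    match(composition$transcript_id, ids),
    match(composition$codon, rownames(mass))
  )] <- composition$count
  if (any(rowSums(cmat) <= 0)) abort("Each transcript needs total codon count >= 1.")
  em <- cmat %*% mass
  em <- em / rowSums(em)
  tibble(
    transcript_id = ids,
    fS_exp = em[, "silent"],
    fM_exp = em[, "missense"],
    fN_exp = em[, "nonsense"]
  )
}

#' Neutral expectation under equal codon frequency and a uniform profile
#'
#' The closed-form baseline of the genetic code: with the 61 sense codons
#' equally frequent, all substitution classes equally probable and no
#' selection, the expected fractions are the census ratios 134/549 silent,
#' 392/549 missense and 23/549 nonsense (0.24408, 0.71403, 0.04189).
#'
#' @return One-row tibble with `fS_exp`, `fM_exp`, `fN_exp`.
#' @export
uniform_code_expectation <- function() {
  comp <- stats::setNames(rep(1, 61), sense_codons())
  out <- expected_fractions(comp, uniform_profile())
  out[, c("fS_exp", "fM_exp", "fN_exp")]
}

#' Expected fractions directly from CDS sequences
#'
#' Convenience wrapper: [codon_composition()] then [expected_fractions()].
#'
#' @inheritParams codon_composition
#' @inheritParams expected_fractions
#' @return Tibble with `transcript_id`, `fS_exp`, `fM_exp`, `fN_exp`.
#' @export
expectation_for_cds <- function(cds, profile = tumor_average_profile()) {
  expected_fractions(codon_composition(cds), profile)
}

#' Read CDS sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences. Names are truncated at the
#'   first whitespace of the FASTA header.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}
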