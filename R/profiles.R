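#' Construct a six-class substitution probability profile
#'
#' A profile assigns a probability to each of the six pyrimidine-centric
#' substitution classes (see [substitution_classes()]). Profiles drive both
#' the expectation model and the synthetic mutation generator.
#'
#' @param probabilities Named numeric vector over the six classes (any
#'   order; all six must be present). Must be non-negative and sum to 1
#'   within `1e-9`.
#' @param name Optional free-text profile name, stored as an attribute.
#' @return Named numeric vector in canonical class order, with a `name`
#'   attribute.
#' @export
signature_profile <- function(probabilities, name = NULL) {
  cls <- substitution_classes()
  if (is.null(names(probabilities)) || !setequal(names(probabilities), cls)) {
    abort("`probabilities` must be named by the six substitution classes.")
  }
  p <- as.numeric(probabilities[cls])
  names(p) <- cls
  if (any(p < 0) || anyNA(p)) abort("Profile probabilities must be non-negative.")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("Profile probabilities must sum to 1 (got %.12f).", sum(p)))
  }
  attr(p, "name") <- name %||% "profile"
  p
}

.check_profile <- function(profile) {
  cls <- substitution_classes()
  if (is.null(names(profile)) || !setequal(names(profile), cls)) {
    abort("Profile must be a numeric vector named by the six substitution classes; see `signature_profile()`.")
  }
  signature_profile(profile, name = attr(profile, "name"))
}

#' Uniform substitution profile (each class 1/6)
#' @return A profile; see [signature_profile()].
#' @export
uniform_profile <- function() {
  p <- rep(1 / 6, 6)
  names(p) <- substitution_classes()
  signature_profile(p, name = "uniform")
}

#' Pan-tumor average substitution profile
#'
#' Average contribution of the six substitution classes to single-base
#' substitutions across tumors: C>T dominates (0.3726), followed by
#' T>C (0.1842), C>A (0.1583), C>G (0.1162), T>G (0.0891) and T>A
#' (0.0796). Bundled so the somatic expectation model runs without any
#' signature download; supply your own profile (e.g. via
#' [cohort_average_profile()]) for tumor-type-specific work.
#'
#' @return A profile; see [signature_profile()].
#' @export
tumor_average_profile <- function() {
  signature_profile(
    c("C>A" = 0.1583, "C>G" = 0.1162, "C>T" = 0.3726,
      "T>A" = 0.0796, "T>C" = 0.1842, "T>G" = 0.0891),
    name = "tumor-average"
  )
}

.context_channels <- function() {
  cls <- substitution_classes()
  ctx <- expand.grid(
    five = .BASES, class = cls, three = .BASES,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  paste0(ctx$five, "[", ctx$class, "]", ctx$three)
}

#' Collapse a 96-channel context signature to six substitution classes
#'
#' Trinucleotide-context signatures (SBS style) distribute each class over
#' 16 flanking contexts, keyed `"A[C>T]G"`. Per-class probability is the
#' sum of its 16 context channels; the result is renormalized. Flanking
#' context is discarded afterwards: the expectation model is context-free.
#'
#' @param sig Named numeric vector of 96 non-negative channel values keyed
#'   by context strings, or a two-column data frame (context, value).
#' @param name Optional profile name.
#' @return A profile; see [signature_profile()].
#' @export
collapse_96_to_6 <- function(sig, name = NULL) {
  if (is.data.frame(sig)) {
    if (ncol(sig) < 2) abort("Data-frame signature needs context and value columns.")
    v <- sig[[2]]
    names(v) <- sig[[1]]
    sig <- v
  }
  keys <- names(sig)
  m <- stringr::str_match(keys, "^([ACGT])\\[([ACGT]>[ACGT])\\]([ACGT])$")
  if (is.null(keys) || anyNA(m[, 1]) || length(sig) != 96 || anyDuplicated(keys)) {
    abort("Malformed context signature: expected 96 distinct channels keyed like \"A[C>T]G\".")
  }
  if (any(sig < 0) || anyNA(sig)) abort("Signature channels must be non-negative.")
  tot <- sum(sig)
  if (tot <= 0) abort("Signature has zero total mass.")
  p <- tapply(as.numeric(sig), m[, 3], sum)[substitution_classes()]
  signature_profile(p / tot, name = name %||% attr(sig, "name"))
}

#' Convex combination of substitution profiles
#'
#' @param profiles List of profiles (see [signature_profile()]).
#' @param weights Non-negative weights of the same length, summing to 1
#'   within `1e-9`. The germline expectation profile of the package is
#'   `mix_profiles(list(SBS1, SBS5), c(0.1, 0.9))`.
#' @param name Optional profile name.
#' @return A profile.
#' @export
mix_profiles <- function(profiles, weights, name = NULL) {
  if (length(profiles) != length(weights)) {
    abort("`profiles` and `weights` must have equal length.")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be non-negative and sum to 1.")
  }
  profiles <- lapply(profiles, .check_profile)
  p <- Reduce(`+`, Map(function(pr, w) pr * w, profiles, weights))
  signature_profile(p, name = name %||% "mixture")
}

#' Cohort-average substitution profile from per-sample signature activities
#'
#' Collapses each signature to six classes and averages over samples
#' weighted by attributed mutation counts (activity-weighted; the number of
#' mutations each signature explains in each sample). With
#' `weighting = "sample"` every sample contributes equally instead (its
#' activities are normalized to 1 first).
#'
#' @param attributions Data frame: first column sample identifier, remaining
#'   columns one per signature, entries = attributed mutation counts
#'   (non-negative).
#' @param signatures Named list mapping signature name to a 96-channel
#'   context signature (or an already-collapsed profile).
#' @param weighting `"activity"` (default) or `"sample"`.
#' @param name Optional profile name.
#' @return A profile.
#' @export
cohort_average_profile <- function(attributions, signatures,
                                   weighting = c("activity", "sample"),
                                   name = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(attributions), ncol(attributions) >= 2)
  sig_names <- setdiff(names(attributions), names(attributions)[1])
  missing <- setdiff(sig_names, names(signatures))
  if (length(missing) > 0) {
    abort(sprintf(
      "Signature(s) named in attributions but missing from `signatures`: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  acts <- as.matrix(attributions[, sig_names, drop = FALSE])
  if (any(acts < 0) || anyNA(acts)) abort("Activities must be non-negative.")
  if (weighting == "sample") {
    rs <- rowSums(acts)
    if (any(rs <= 0)) abort("Some samples have zero total activity.")
    acts <- acts / rs
  }
  w <- colSums(acts)
  if (sum(w) <= 0) abort("Zero total activity across the cohort.")
  collapsed <- lapply(signatures[sig_names], function(s) {
    if (length(s) == 96 || is.data.frame(s)) collapse_96_to_6(s) else .check_profile(s)
  })
  mix_profiles(collapsed, w / sum(w), name = name %||% "cohort-average")
}

#' Synthetic stand-ins for the SBS1 and SBS5 signatures
#'
#' Constructed 96-channel signatures that reproduce the salient class
#' structure of SBS1 (C>T concentrated at NpCpG contexts, the CpG
#' deamination clock) and SBS5 (a flat, C>T/T>C-tilted background). They
#' are synthetic: suitable for building the default germline expectation
#' profile and for tests, not for analysing real signature attributions --
#' load the real matrices with [read_signature_matrix()] for that.
#'
#' @return Named numeric vector of 96 channel probabilities.
#' @name synthetic-signatures
NULL

#' @rdname synthetic-signatures
#' @export
synthetic_sbs1 <- function() {
  ch <- .context_channels()
  v <- rep(0.05 / 92, 96)
  names(v) <- ch
  cpg <- grepl("\\[C>T\\]G$", ch)
  v[cpg] <- 0.95 / sum(cpg)
  attr(v, "name") <- "synthetic-SBS1"
  v
}

#' @rdname synthetic-signatures
#' @export
synthetic_sbs5 <- function() {
  ch <- .context_channels()
  class_mass <- c("C>A" = 0.07, "C>G" = 0.05, "C>T" = 0.30,
                  "T>A" = 0.09, "T>C" = 0.38, "T>G" = 0.11)
  cls <- stringr::str_match(ch, "\\[([ACGT]>[ACGT])\\]")[, 2]
  v <- unname(class_mass[cls]) / 16
  names(v) <- ch
  attr(v, "name") <- "synthetic-SBS5"
  v
}

#' Default germline substitution profile
#'
#' The human germline spectrum is well approximated by a 0.1 x SBS1 +
#' 0.9 x SBS5 signature mixture; this default builds that mixture from the
#' bundled synthetic SBS1/SBS5 stand-ins. Pass real signatures through
#' [collapse_96_to_6()] and [mix_profiles()] to use downloaded matrices.
#'
#' @return A profile; see [signature_profile()].
#' @export
germline_default_profile <- function() {
  mix_profiles(
    list(collapse_96_to_6(synthetic_sbs1()), collapse_96_to_6(synthetic_sbs5())),
    c(0.1, 0.9),
    name = "germline-default (0.1xSBS1 + 0.9xSBS5, synthetic)"
  )
}

#' Read a 96-channel signature matrix from TSV
#'
#' Expects a header row; the first column holds context strings of the form
#' `"A[C>T]G"`, each further column one signature.
#'
#' @param path TSV path.
#' @return Named list of 96-channel signatures (named numeric vectors).
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ctx <- df[[1]]
  sigs <- lapply(df[-1], function(col) {
    v <- as.numeric(col)
    names(v) <- ctx
    v
  })
  sigs
}

#' Read a per-sample signature attribution table from TSV
#'
#' First column: sample identifier; remaining columns: per-signature
#' attributed mutation counts.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_attribution_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
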