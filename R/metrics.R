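# division with explicit undefined marker: zero (or undefined) denominator
# yields NA_real_, never a sentinel number
.safe_div <- function(num, den) {
  ifelse(!is.na(den) & den > 0, num / den, NA_real_)
}

#' Observed silent/missense/nonsense fractions per transcript
#'
#' In `"SO"` mode (substitutions only) the counts (nS, nM, nN) are divided
#' by the substitution total. In `"SSI"` mode (substitutions and subtle
#' indels) inframe indels join the amino-acid-changing numerator and
#' frameshift indels the truncating numerator, with all five counts in the
#' denominator. A transcript with zero total in the chosen mode gets NA
#' fractions (explicit undefined marker).
#'
#' @param tallies Tibble from [tally_by_transcript()].
#' @param mode `"SO"` or `"SSI"`.
#' @return The input with added columns `mode`, `n_total`, `fS`, `fM`,
#'   `fN`.
#' @export
observed_fractions <- function(tallies, mode = c("SO", "SSI")) {
  mode <- match.arg(mode)
  out <- tallies
  if (mode == "SO") {
    out$n_total <- out$total_sub
    out$fS <- .safe_div(out$nS, out$n_total)
    out$fM <- .safe_div(out$nM, out$n_total)
    out$fN <- .safe_div(out$nN, out$n_total)
  } else {
    out$n_total <- out$total_ssi
    out$fS <- .safe_div(out$nS, out$n_total)
    out$fM <- .safe_div(out$nM + out$n_inframe, out$n_total)
    out$fN <- .safe_div(out$nN + out$n_frameshift, out$n_total)
  }
  out$mode <- mode
  dplyr::relocate(out, "mode", .after = "transcript_id")
}

#' Ratio statistics from fraction columns
#'
#' Adds the pairwise ratios rSM = fS/fM, rNM = fN/fM, rNS = fN/fS and the
#' one-vs-rest ratios rSMN = fS/(fM+fN), rMSN = fM/(fS+fN),
#' rNSM = fN/(fS+fM). High rNSM marks positive selection for truncating
#' mutations (TSG-like), high rMSN positive selection for missense
#' (OG-like), high rSMN purifying selection (TEG-like). Zero denominators
#' yield NA for that entry only.
#'
#' @param df Data frame with columns `fS`, `fM`, `fN` (e.g. from
#'   [observed_fractions()]).
#' @param suffix Optional suffix for input/output columns (e.g. `"_exp"`
#'   computes expected ratios from `fS_exp` etc.).
#' @return `df` with the six ratio columns added.
#' @export
add_ratios <- function(df, suffix = "") {
  fS <- df[[paste0("fS", suffix)]]
  fM <- df[[paste0("fM", suffix)]]
  fN <- df[[paste0("fN", suffix)]]
  if (is.null(fS) || is.null(fM) || is.null(fN)) {
    abort(sprintf("Columns fS%s/fM%s/fN%s are required.", suffix, suffix, suffix))
  }
  df[[paste0("rSM", suffix)]] <- .safe_div(fS, fM)
  df[[paste0("rNM", suffix)]] <- .safe_div(fN, fM)
  df[[paste0("rNS", suffix)]] <- .safe_div(fN, fS)
  df[[paste0("rSMN", suffix)]] <- .safe_div(fS, fM + fN)
  df[[paste0("rMSN", suffix)]] <- .safe_div(fM, fS + fN)
  df[[paste0("rNSM", suffix)]] <- .safe_div(fN, fS + fM)
  df
}

#' Observed/expected ("starred") metrics
#'
#' Divides each observed quantity by its expectation under the
#' transcript's codon composition and the chosen substitution profile:
#' fraction-level rS*, rM*, rN* and ratio-level rSM*, rNM*, rNS*, rSMN*,
#' rMSN*, rNSM* (expected ratios are built from the expectation vector by
#' the same formulas as the observed ratios). Undefined observed entries
#' propagate as NA. Under neutrality all starred metrics are 1 in
#' expectation.
#'
#' @param df Data frame carrying observed columns (`fS` ... `rNSM`) and
#'   expectation columns (`fS_exp`, `fM_exp`, `fN_exp`), e.g. a join of
#'   [add_ratios()] output with [expected_fractions()] output.
#' @return `df` with columns `rS_star` ... `rNSM_star` added.
#' @export
add_starred <- function(df) {
  need <- c("fS", "fM", "fN", "fS_exp", "fM_exp", "fN_exp")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(stats::na.omit(c(df$fS_exp, df$fM_exp, df$fN_exp)) <= 0)) {
    abort("Expectation components must be strictly positive to form starred metrics.")
  }
  if (!"rSM" %in% names(df)) df <- add_ratios(df)
  df <- add_ratios(df, suffix = "_exp")
  df$rS_star <- .safe_div(df$fS, df$fS_exp)
  df$rM_star <- .safe_div(df$fM, df$fM_exp)
  df$rN_star <- .safe_div(df$fN, df$fN_exp)
  for (r in c("rSM", "rNM", "rNS", "rSMN", "rMSN", "rNSM")) {
    df[[paste0(r, "_star")]] <- .safe_div(df[[r]], df[[paste0(r, "_exp")]])
  }
  df
}

#' Build the per-transcript metric table
#'
#' One row per transcript per requested mode, carrying counts, observed
#' fractions, ratio statistics, composition-specific expectations and
#' starred metrics. Transcripts without a matching expectation (e.g. no
#' CDS available) are reported and skipped.
#'
#' @param tallies Tibble from [tally_by_transcript()].
#' @param expectations Tibble from [expected_fractions()] /
#'   [expectation_for_cds()] (`transcript_id`, `fS_exp`, `fM_exp`,
#'   `fN_exp`).
#' @param modes Character subset of `c("SO", "SSI")`.
#' @return Tibble of metric rows; skipped transcripts in the `"skipped"`
#'   attribute.
#' @export
build_metric_table <- function(tallies, expectations, modes = c("SO", "SSI")) {
  modes <- match.arg(modes, several.ok = TRUE)
  skipped <- setdiff(tallies$transcript_id, expectations$transcript_id)
  if (length(skipped) > 0) {
    message(sprintf("build_metric_table: %d transcript(s) without expectation skipped.",
                    length(skipped)))
    tallies <- tallies[!tallies$transcript_id %in% skipped, , drop = FALSE]
  }
  rows <- lapply(modes, function(m) {
    tallies |>
      observed_fractions(mode = m) |>
      add_ratios() |>
      dplyr::inner_join(expectations, by = "transcript_id") |>
      add_starred()
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Export 3D scatter coordinates for a chosen axis set
#'
#' Writes CSV triples (plus transcript id) for external 3D plotting.
#'
#' @param metric_table Tibble from [build_metric_table()].
#' @param axes Character vector of three metric column names.
#' @param path Output CSV path.
#' @param mode Which mode's rows to export.
#' @return `path`, invisibly.
#' @export
export_coordinates <- function(metric_table, axes, path, mode = "SO") {
  stopifnot(length(axes) == 3, all(axes %in% names(metric_table)))
  df <- metric_table[metric_table$mode == mode, c("transcript_id", axes)]
  readr::write_csv(df, path)
  invisible(path)
}
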