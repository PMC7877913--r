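#' Tally mutation records per transcript
#'
#' Counts substitutions by effect category and substitution class, plus
#' inframe and frameshift indels, for each transcript.
#'
#' @param records Tibble of filtered records with at least `transcript_id`
#'   and `category`; `class` and `position` are used when present.
#' @return Tibble with one row per transcript: `nS`, `nM`, `nN`,
#'   `n_inframe`, `n_frameshift`, per-class substitution counts
#'   (`n_CA` ... `n_TG`), `total_sub` (= nS + nM + nN) and `total_ssi`
#'   (substitutions plus subtle indels).
#' @export
tally_by_transcript <- function(records) {
  stopifnot(all(c("transcript_id", "category") %in% names(records)))
  cls <- substitution_classes()
  cls_cols <- paste0("n_", gsub(">", "", cls))
  out <- records |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      nS = sum(.data$category == "silent"),
      nM = sum(.data$category == "missense"),
      nN = sum(.data$category == "nonsense"),
      n_inframe = sum(.data$category == "inframe"),
      n_frameshift = sum(.data$category == "frameshift"),
      .groups = "drop"
    )
  if ("class" %in% names(records)) {
    class_counts <- records |>
      dplyr::filter(!is.na(.data$class)) |>
      dplyr::count(.data$transcript_id, .data$class) |>
      tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
    for (k in seq_along(cls)) {
      if (!cls[k] %in% names(class_counts)) class_counts[[cls[k]]] <- 0L
    }
    names(class_counts)[match(cls, names(class_counts))] <- cls_cols
    out <- dplyr::left_join(out, class_counts[, c("transcript_id", cls_cols)],
                            by = "transcript_id")
    out[cls_cols] <- lapply(out[cls_cols], function(x) tidyr::replace_na(x, 0L))
  } else {
    for (cc in cls_cols) out[[cc]] <- 0L
  }
  out$total_sub <- out$nS + out$nM + out$nN
  out$total_ssi <- out$total_sub + out$n_inframe + out$n_frameshift
  out
}

#' Per-position recurrence of silent substitutions
#'
#' Recurrent synonymous hits at a few CDS positions can inflate fS and
#' mimic purifying selection; this map feeds [flag_silent_hotspots()].
#'
#' @param records Tibble of filtered records with `transcript_id`,
#'   `category` and `position`.
#' @return Tibble with `transcript_id`, `position`, `n_hits`, sorted by
#'   descending recurrence within transcript.
#' @export
silent_site_counts <- function(records) {
  records |>
    dplyr::filter(.data$category == "silent", !is.na(.data$position)) |>
    dplyr::count(.data$transcript_id, .data$position, name = "n_hits") |>
    dplyr::arrange(.data$transcript_id, dplyr::desc(.data$n_hits))
}

#' Retain transcripts with at least a minimum number of mutations
#'
#' Transcripts with too few mutations carry no usable selection signal
#' (their category fractions are dominated by sampling noise); the main
#' analyses use a threshold of 100, with 0/50/100/500 compared by
#' [sensitivity_scan()].
#'
#' @param tallies Tibble from [tally_by_transcript()].
#' @param threshold Minimum mutation count (>= 0).
#' @param mode `"SO"` counts substitutions only; `"SSI"` counts
#'   substitutions plus subtle indels.
#' @return Filtered tally tibble.
#' @export
filter_min_mutations <- function(tallies, threshold = 100, mode = c("SO", "SSI")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0)
  n <- if (mode == "SO") tallies$total_sub else tallies$total_ssi
  tallies[n >= threshold, , drop = FALSE]
}

#' Write / read a tally table (TSV round-trip)
#'
#' @param tallies Tally tibble.
#' @param path Output TSV path.
#' @return `write_tally()` returns `path` invisibly; `read_tally()` the
#'   tibble.
#' @export
write_tally <- function(tallies, path) {
  readr::write_tsv(tallies, path)
  invisible(path)
}

#' @rdname write_tally
#' @export
read_tally <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
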