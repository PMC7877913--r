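#' Hotspot guard parameters
#'
#' @param min_hits Minimum recurrence of the single most-hit silent
#'   position.
#' @param top_k Number of top positions whose combined share is tested.
#' @param min_share Minimum share of all silent hits carried by the top
#'   `top_k` positions.
#' @param demote Demote hotspot-flagged TEG-like calls to
#'   unclassified-candidate.
#' @return Named list.
#' @export
hotspot_params <- function(min_hits = 10, top_k = 3, min_share = 0.5,
                           demote = TRUE) {
  list(min_hits = min_hits, top_k = top_k, min_share = min_share,
       demote = demote)
}

#' Flag transcripts whose silent signal is hotspot-driven
#'
#' A high silent fraction can reflect recurrent synonymous mutation at a
#' handful of CDS positions (a mutational hotspot) rather than purifying
#' selection against amino-acid-changing mutations. A transcript is
#' flagged when its most recurrent silent position carries at least
#' `min_hits` hits AND its top `top_k` positions together carry at least
#' `min_share` of all its silent hits.
#'
#' @param silent_counts Tibble from [silent_site_counts()].
#' @param params See [hotspot_params()].
#' @return Tibble: `transcript_id`, `n_silent`, `top_hits`, `top_share`,
#'   `hotspot`.
#' @export
flag_silent_hotspots <- function(silent_counts, params = hotspot_params()) {
  silent_counts |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_silent = sum(.data$n_hits),
      top_hits = max(.data$n_hits),
      top_share = sum(utils::head(sort(.data$n_hits, decreasing = TRUE), params$top_k)) /
        sum(.data$n_hits),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      hotspot = .data$top_hits >= params$min_hits & .data$top_share >= params$min_share
    )
}
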