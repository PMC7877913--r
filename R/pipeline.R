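#' Run the per-gene selection-signal pipeline end to end
#'
#' Stages: read/parse somatic records, record-level filtering, per-transcript
#' tally, minimum-mutation filter, codon-composition expectations, metric
#' table (SO and SSI modes), central-cluster statistics and SD-set
#' assignment in each parameter space, union of candidate sets, class
#' labeling with the silent-hotspot guard. Every stage logs its row count.
#'
#' @param somatic Path to a COSMIC-like TSV, or an already-loaded data
#'   frame in that layout.
#' @param cds Path to a CDS FASTA, or a named character vector of CDS
#'   sequences.
#' @param dialect See [cosmic_dialect()].
#' @param filter See [filter_config()].
#' @param profile Substitution profile for the expectations.
#' @param min_mutations Minimum mutations per transcript (`NULL` uses
#'   `filter$min_mutations_per_transcript`).
#' @param spaces See [candidate_spaces()].
#' @param k_inner,k_outer SD cutoffs.
#' @param thresholds See [class_thresholds()].
#' @param hotspot See [hotspot_params()]; `NULL` disables the guard.
#' @param out_dir Optional output directory: metric table, candidate
#'   report, cluster stats and a configuration snapshot are written there.
#' @return List with class `"sel_scan"`: `tallies`, `metric_table`,
#'   `cluster_stats`, `sets`, `candidates`, `classes`, `hotspots`,
#'   `drop_counts`, `params`.
#' @export
run_selection_pipeline <- function(somatic, cds,
                                   dialect = cosmic_dialect(),
                                   filter = filter_config(),
                                   profile = tumor_average_profile(),
                                   min_mutations = NULL,
                                   spaces = candidate_spaces(),
                                   k_inner = 1, k_outer = 2,
                                   thresholds = class_thresholds(),
                                   hotspot = hotspot_params(),
                                   out_dir = NULL) {
  min_mutations <- min_mutations %||% filter$min_mutations_per_transcript
  if (is.character(cds) && length(cds) == 1 && file.exists(cds)) {
    cds <- read_cds_fasta(cds)
  }
  records <- if (is.character(somatic)) {
    read_somatic_table(somatic, dialect = dialect, cds = cds)
  } else {
    parse_somatic_records(somatic, dialect = dialect, cds = cds)
  }
  message(sprintf("stage parse: %d records", nrow(records)))
  records <- apply_filters(records, filter)
  tallies <- tally_by_transcript(records)
  message(sprintf("stage tally: %d transcripts", nrow(tallies)))
  tallies <- filter_min_mutations(tallies, threshold = min_mutations)
  message(sprintf("stage min-mutation filter (>= %d): %d transcripts",
                  min_mutations, nrow(tallies)))
  if (nrow(tallies) < 2) {
    message("stage metrics: fewer than 2 transcripts remain; returning empty result")
    empty <- tibble(transcript_id = character(0))
    return(structure(
      list(tallies = tallies, metric_table = empty,
           cluster_stats = list(), sets = empty,
           candidates = tibble(transcript_id = character(0), spaces = character(0),
                               n_spaces = integer(0)),
           classes = tibble(transcript_id = character(0),
                            is_TSG_like = logical(0), is_OG_like = logical(0),
                            is_TEG_like = logical(0)),
           hotspots = NULL, drop_counts = attr(records, "drop_counts"),
           params = list(min_mutations = min_mutations)),
      class = "sel_scan"
    ))
  }
  have_cds <- intersect(tallies$transcript_id, names(cds))
  expectations <- expectation_for_cds(cds[have_cds], profile = profile)
  metric_table <- build_metric_table(tallies, expectations)
  message(sprintf("stage metrics: %d rows", nrow(metric_table)))
  cand <- call_candidates(metric_table, spaces = spaces,
                          k_inner = k_inner, k_outer = k_outer)
  candidates <- union_candidates(cand$sets)
  message(sprintf("stage candidates: %d transcripts in the union candidate list",
                  nrow(candidates)))
  hotspots <- NULL
  if (!is.null(hotspot)) {
    hotspots <- flag_silent_hotspots(silent_site_counts(records), params = hotspot)
  }
  classes <- classify_candidates(
    candidates, metric_table, thresholds = thresholds,
    hotspot_flags = if (!is.null(hotspot) && isTRUE(hotspot$demote)) hotspots else NULL
  )
  message(sprintf("stage classify: %d TSG-like, %d OG-like, %d TEG-like",
                  sum(classes$is_TSG_like), sum(classes$is_OG_like),
                  sum(classes$is_TEG_like)))
  params <- list(
    min_mutations = min_mutations, k_inner = k_inner, k_outer = k_outer,
    thresholds = thresholds, hotspot = hotspot,
    profile = as.list(unclass(profile)), filter = unclass(filter),
    spaces = spaces$space
  )
  res <- structure(
    list(tallies = tallies, metric_table = metric_table,
         cluster_stats = cand$stats, sets = cand$sets,
         candidates = candidates, classes = classes, hotspots = hotspots,
         drop_counts = attr(records, "drop_counts"), params = params),
    class = "sel_scan"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(metric_table, file.path(out_dir, "metric_table.tsv"))
    readr::write_tsv(classes, file.path(out_dir, "candidates.tsv"))
    stats_df <- dplyr::bind_rows(
      lapply(cand$stats, function(s) as.data.frame(unclass(s))),
      .id = "space"
    )
    writeLines(jsonlite::toJSON(stats_df, digits = NA, pretty = TRUE),
               file.path(out_dir, "cluster_stats.json"))
    writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA, pretty = TRUE),
               file.path(out_dir, "params.json"))
  }
  res
}

#' @export
print.sel_scan <- function(x, ...) {
  cat("<sel_scan>\n")
  cat(sprintf("  transcripts analysed: %d\n", nrow(x$tallies)))
  cat(sprintf("  candidate transcripts: %d\n", nrow(x$candidates)))
  cat(sprintf("  TSG-like %d | OG-like %d | TEG-like %d | hotspot-flagged %d\n",
              sum(x$classes$is_TSG_like), sum(x$classes$is_OG_like),
              sum(x$classes$is_TEG_like), sum(x$classes$hotspot)))
  invisible(x)
}

#' Sensitivity of candidate calling to the minimum-mutation threshold
#'
#' Repeats candidate calling at several minimum-mutation thresholds and
#' reports set sizes plus the Jaccard similarity of consecutive candidate
#' lists. Raising the threshold increases statistical power but disfavors
#' negatively selected genes, which tend to be undermutated.
#'
#' @inheritParams run_selection_pipeline
#' @param thresholds Integer vector of minimum-mutation thresholds.
#' @param ... Passed to [run_selection_pipeline()].
#' @return Tibble: `threshold`, `n_transcripts`, `n_candidates`, class
#'   counts, `jaccard_prev` (similarity to the previous threshold's
#'   candidate list).
#' @export
sensitivity_scan <- function(somatic, cds, thresholds = c(0, 50, 100, 500), ...) {
  runs <- lapply(thresholds, function(th) {
    suppressMessages(run_selection_pipeline(somatic, cds, min_mutations = th, ...))
  })
  cand_sets <- lapply(runs, function(r) r$candidates$transcript_id)
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 1 else length(intersect(a, b)) / u
  }
  tibble(
    threshold = thresholds,
    n_transcripts = vapply(runs, function(r) nrow(r$tallies), integer(1)),
    n_candidates = vapply(runs, function(r) nrow(r$candidates), integer(1)),
    n_TSG_like = vapply(runs, function(r) sum(r$classes$is_TSG_like), integer(1)),
    n_OG_like = vapply(runs, function(r) sum(r$classes$is_OG_like), integer(1)),
    n_TEG_like = vapply(runs, function(r) sum(r$classes$is_TEG_like), integer(1)),
    jaccard_prev = c(NA_real_, purrr::map2_dbl(
      cand_sets[-length(cand_sets)], cand_sets[-1], jac
    ))
  )
}
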