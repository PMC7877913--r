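#' Default parameter spaces for candidate calling
#'
#' Six spaces: the fraction space f = (fS, fM, fN), the pairwise-ratio
#' space r2 = (rSM, rNM, rNS) and the one-vs-rest ratio space
#' r3 = (rSMN, rMSN, rNSM), each in SO and SSI mode. Starred variants use
#' the observed/expected columns instead.
#'
#' @param starred Use starred (observed/expected) axes.
#' @return Tibble with columns `space`, `mode`, `axes` (list-column).
#' @export
candidate_spaces <- function(starred = FALSE) {
  ax <- list(
    f  = c("fS", "fM", "fN"),
    r2 = c("rSM", "rNM", "rNS"),
    r3 = c("rSMN", "rMSN", "rNSM")
  )
  if (starred) {
    ax <- list(
      f  = c("rS_star", "rM_star", "rN_star"),
      r2 = c("rSM_star", "rNM_star", "rNS_star"),
      r3 = c("rSMN_star", "rMSN_star", "rNSM_star")
    )
  }
  grid <- expand.grid(family = names(ax), mode = c("SO", "SSI"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble(
    space = paste0(grid$family, "_", grid$mode, if (starred) "_star" else ""),
    mode = grid$mode,
    axes = unname(ax[grid$family])
  )
}

#' Mean and standard deviation of the central cluster axes
#'
#' Unweighted mean and SD per axis over all transcripts with defined values
#' on every axis -- no trimming, no outlier removal, no iteration. The
#' dense central cluster these statistics describe is the passenger
#' population; candidates are transcripts far from it.
#'
#' @param metric_table Metric rows of a single mode.
#' @param axes Character vector of metric column names.
#' @return Tibble with `axis`, `mean`, `sd`; attribute `n` = number of
#'   transcripts used; class `"cluster_stats"`.
#' @export
central_cluster_stats <- function(metric_table, axes) {
  stopifnot(all(axes %in% names(metric_table)))
  x <- as.matrix(metric_table[, axes, drop = FALSE])
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < 2) abort("Need at least 2 transcripts with defined values on all axes.")
  out <- tibble(
    axis = axes,
    mean = unname(colMeans(x)),
    sd = unname(apply(x, 2, stats::sd))
  )
  attr(out, "n") <- nrow(x)
  class(out) <- c("cluster_stats", class(out))
  out
}

#' Assign passenger (inner) and candidate (outer) SD sets in one space
#'
#' A transcript is in the passenger set (PG) when every axis lies within
#' `k_inner` SD of its mean, and in the candidate set (CG) when at least
#' one axis deviates by more than `k_outer` SD (the ANY-axis rule; this is
#' the reading under which one space can flag oncogene-like transcripts,
#' extreme on one axis, and TSG-like transcripts, extreme on another).
#' Ties at exactly k SD fall inward: exactly 1 SD is still PG, exactly
#' 2 SD is not yet CG. Transcripts between the cutoffs belong to neither
#' set; transcripts with an undefined value on any axis are excluded.
#'
#' @param metric_table Metric rows of a single mode.
#' @param stats Tibble from [central_cluster_stats()] on the same axes.
#' @param k_inner,k_outer SD multiples for the inner/outer cutoffs.
#' @param method `"any"` (per-axis, default) or `"euclidean"` (joint
#'   z-distance against `k_outer`, with the same ALL-axes rule for PG).
#' @return Tibble with `transcript_id`, `set` (`"PG"`, `"CG"`,
#'   `"intermediate"`, `"undefined"`) and `max_dev` (largest |z|).
#' @export
assign_sd_sets <- function(metric_table, stats, k_inner = 1, k_outer = 2,
                           method = c("any", "euclidean")) {
  method <- match.arg(method)
  axes <- stats$axis
  x <- as.matrix(metric_table[, axes, drop = FALSE])
  z <- abs(sweep(sweep(x, 2, stats$mean), 2, ifelse(stats$sd > 0, stats$sd, NA_real_), "/"))
  defined <- stats::complete.cases(z)
  max_dev <- apply(z, 1, function(r) if (anyNA(r)) NA_real_ else max(r))
  outer_dev <- if (method == "any") max_dev else sqrt(rowSums(z^2))
  set <- dplyr::case_when(
    !defined ~ "undefined",
    max_dev <= k_inner ~ "PG",
    outer_dev > k_outer ~ "CG",
    TRUE ~ "intermediate"
  )
  tibble(transcript_id = metric_table$transcript_id, set = set, max_dev = max_dev)
}

#' Call candidate sets across parameter spaces
#'
#' For each space: subset the metric table to the space's mode, compute
#' central-cluster statistics and assign SD sets.
#'
#' @param metric_table Tibble from [build_metric_table()] (with a `mode`
#'   column).
#' @param spaces Tibble from [candidate_spaces()].
#' @inheritParams assign_sd_sets
#' @return List with `stats` (named list of cluster_stats) and `sets`
#'   (tibble: `transcript_id`, `space`, `set`, `max_dev`).
#' @export
call_candidates <- function(metric_table, spaces = candidate_spaces(),
                            k_inner = 1, k_outer = 2,
                            method = c("any", "euclidean")) {
  method <- match.arg(method)
  stats_list <- list()
  sets <- purrr::pmap(spaces, function(space, mode, axes) {
    mt <- metric_table[metric_table$mode == mode, , drop = FALSE]
    st <- central_cluster_stats(mt, axes)
    stats_list[[space]] <<- st
    s <- assign_sd_sets(mt, st, k_inner = k_inner, k_outer = k_outer, method = method)
    s$space <- space
    s
  })
  list(stats = stats_list, sets = dplyr::bind_rows(sets))
}

#' Union of candidate sets across spaces
#'
#' @param sets Tibble from [call_candidates()]`$sets` (or a bind of
#'   several).
#' @return Tibble with one row per candidate transcript: `transcript_id`,
#'   `spaces` (semicolon-joined provenance) and `n_spaces`.
#' @export
union_candidates <- function(sets) {
  sets |>
    dplyr::filter(.data$set == "CG") |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      spaces = paste(sort(unique(.data$space)), collapse = ";"),
      n_spaces = dplyr::n_distinct(.data$space),
      .groups = "drop"
    )
}

#' Class thresholds for candidate labeling
#'
#' Unstarred mode: TSG-like requires indel_rNSM > 0.125 (SSI-mode rNSM;
#' the threshold that removes OGs and TEGs from the truncation-selected
#' list); OG-like requires rMSN > 3.00; TEG-like requires rSMN > 0.5.
#' Starred mode: rNSM* > 3, rMSN* > 1.5, rSMN* > 1.5.
#'
#' @param starred Logical.
#' @return Named list of thresholds.
#' @export
class_thresholds <- function(starred = FALSE) {
  if (starred) {
    list(starred = TRUE, tsg_rNSM_star = 3, og_rMSN_star = 1.5, teg_rSMN_star = 1.5)
  } else {
    list(starred = FALSE, tsg_indel_rNSM = 0.125, og_rMSN = 3.00, teg_rSMN = 0.5)
  }
}

#' Classify candidate transcripts as TSG-like, OG-like or TEG-like
#'
#' Applies the class thresholds to the union candidate list. A transcript
#' meeting several thresholds receives all qualifying labels and a
#' multi-label warning flag; a candidate meeting none is
#' `"unclassified-candidate"`. TEG-like calls on transcripts carrying a
#' silent-hotspot flag are demoted to unclassified (flag retained): their
#' high silent fraction reflects recurrent synonymous hits, not purifying
#' selection.
#'
#' @param candidates Tibble from [union_candidates()].
#' @param metric_table Tibble from [build_metric_table()] covering all
#'   candidates (both modes for unstarred classification: the TSG
#'   threshold uses SSI-mode rNSM, i.e. indel_rNSM).
#' @param thresholds See [class_thresholds()].
#' @param hotspot_flags Optional tibble from [flag_silent_hotspots()].
#' @return Tibble: `transcript_id`, `is_TSG_like`, `is_OG_like`,
#'   `is_TEG_like`, `label`, `multi_label`, `hotspot`, plus the metric
#'   values supporting the call.
#' @export
classify_candidates <- function(candidates, metric_table,
                                thresholds = class_thresholds(),
                                hotspot_flags = NULL) {
  so <- metric_table[metric_table$mode == "SO", , drop = FALSE]
  ssi <- metric_table[metric_table$mode == "SSI", , drop = FALSE]
  df <- candidates |>
    dplyr::left_join(
      dplyr::select(so, "transcript_id", dplyr::any_of(c(
        "rMSN", "rSMN", "rNSM", "rMSN_star", "rSMN_star", "rNSM_star"
      ))),
      by = "transcript_id"
    )
  if (nrow(ssi) > 0) {
    df <- dplyr::left_join(
      df,
      dplyr::select(ssi, "transcript_id", indel_rNSM = "rNSM"),
      by = "transcript_id"
    )
  } else {
    df$indel_rNSM <- NA_real_
  }
  gt <- function(x, thr) !is.na(x) & x > thr
  if (isTRUE(thresholds$starred)) {
    df$is_TSG_like <- gt(df$rNSM_star, thresholds$tsg_rNSM_star)
    df$is_OG_like <- gt(df$rMSN_star, thresholds$og_rMSN_star)
    df$is_TEG_like <- gt(df$rSMN_star, thresholds$teg_rSMN_star)
  } else {
    df$is_TSG_like <- gt(df$indel_rNSM, thresholds$tsg_indel_rNSM)
    df$is_OG_like <- gt(df$rMSN, thresholds$og_rMSN)
    df$is_TEG_like <- gt(df$rSMN, thresholds$teg_rSMN)
  }
  df$hotspot <- FALSE
  if (!is.null(hotspot_flags)) {
    flagged <- hotspot_flags$transcript_id[hotspot_flags$hotspot]
    df$hotspot <- df$transcript_id %in% flagged
    demoted <- df$hotspot & df$is_TEG_like
    if (any(demoted)) {
      message(sprintf("classify_candidates: %d TEG-like call(s) demoted by the silent-hotspot guard.",
                      sum(demoted)))
    }
    df$is_TEG_like <- df$is_TEG_like & !df$hotspot
  }
  labels <- purrr::pmap_chr(
    df[, c("is_TSG_like", "is_OG_like", "is_TEG_like")],
    function(is_TSG_like, is_OG_like, is_TEG_like) {
      lab <- c("TSG-like", "OG-like", "TEG-like")[c(is_TSG_like, is_OG_like, is_TEG_like)]
      if (length(lab) == 0) "unclassified-candidate" else paste(lab, collapse = ";")
    }
  )
  df$label <- labels
  df$multi_label <- df$is_TSG_like + df$is_OG_like + df$is_TEG_like > 1
  if (any(df$multi_label)) {
    warning(sprintf("%d candidate(s) meet multiple class thresholds; all qualifying labels kept.",
                    sum(df$multi_label)), call. = FALSE)
  }
  df
}

#' Precision and recall of class calls against planted truth labels
#'
#' Scores a classification (e.g. on a synthetic cohort) against known
#' regime labels. Recall denominators are all truth transcripts of the
#' class that appear in `universe` (default: all truth transcripts).
#'
#' @param classes Tibble from [classify_candidates()].
#' @param truth Tibble with `transcript_id` and `label` in
#'   `{PG, TSG, OG, TEG, HOTSPOT_PG}`.
#' @param universe Optional character vector restricting the evaluation
#'   population (e.g. transcripts passing the min-mutation filter).
#' @return Tibble with `class`, `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
classification_scores <- function(classes, truth, universe = NULL) {
  if (!is.null(universe)) truth <- truth[truth$transcript_id %in% universe, , drop = FALSE]
  map <- c(TSG = "is_TSG_like", OG = "is_OG_like", TEG = "is_TEG_like")
  purrr::imap(map, function(col, cls) {
    called <- classes$transcript_id[classes[[col]]]
    pos <- truth$transcript_id[truth$label == cls]
    tp <- length(intersect(called, pos))
    tibble(
      class = cls, tp = tp, fp = length(called) - tp, fn = length(pos) - tp,
      precision = if (length(called) > 0) tp / length(called) else NA_real_,
      recall = if (length(pos) > 0) tp / length(pos) else NA_real_
    )
  }) |>
    dplyr::bind_rows()
}
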