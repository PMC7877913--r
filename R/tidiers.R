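#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a central-cluster statistics object
#'
#' @param x A `"cluster_stats"` object.
#' @param ... Unused.
#' @return Tibble with `axis`, `mean`, `sd`.
#' @method tidy cluster_stats
#' @export
tidy.cluster_stats <- function(x, ...) {
  tibble(axis = x$axis, mean = x$mean, sd = x$sd)
}

#' @rdname tidy.cluster_stats
#' @return `glance()`: one-row tibble with `n` (transcripts used) and
#'   `n_axes`.
#' @method glance cluster_stats
#' @export
glance.cluster_stats <- function(x, ...) {
  tibble(n = attr(x, "n"), n_axes = nrow(x))
}

#' Tidy a pipeline result
#'
#' @param x A `"sel_scan"` object from [run_selection_pipeline()].
#' @param ... Unused.
#' @return The candidate classification table (one row per candidate).
#' @method tidy sel_scan
#' @export
tidy.sel_scan <- function(x, ...) {
  as_tibble(x$classes)
}

#' @rdname tidy.sel_scan
#' @return `glance()`: one-row summary with population and class counts.
#' @method glance sel_scan
#' @export
glance.sel_scan <- function(x, ...) {
  tibble(
    n_transcripts = nrow(x$tallies),
    n_candidates = nrow(x$candidates),
    n_TSG_like = sum(x$classes$is_TSG_like),
    n_OG_like = sum(x$classes$is_OG_like),
    n_TEG_like = sum(x$classes$is_TEG_like),
    n_hotspot = if (is.null(x$hotspots)) 0L else sum(x$hotspots$hotspot)
  )
}
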