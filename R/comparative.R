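#' Correlate a metric with per-gene scores
#'
#' Product-moment (Pearson) correlation on the intersection of keys;
#' Spearman available as an option. Used e.g. to relate rSMN (purifying
#' selection) to cell-essentiality scores.
#'
#' @param df Data frame holding both columns (join your score table to the
#'   metric table first, e.g. with [dplyr::inner_join()]).
#' @param x,y Column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `estimate`, `p.value`, `n`, `method`.
#' @export
correlate <- function(df, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xs <- df[[x]]
  ys <- df[[y]]
  ok <- stats::complete.cases(xs, ys)
  if (sum(ok) < 3) abort("Need at least 3 complete pairs.")
  ct <- stats::cor.test(xs[ok], ys[ok], method = method, exact = FALSE)
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         n = sum(ok), method = method)
}

#' Two-group comparison of a metric (Welch's t-test)
#'
#' Unequal-variance t-test between two transcript groups, reporting means,
#' SDs and sizes alongside the statistic so every p-value is accompanied by
#' its context.
#'
#' @param df Metric table (one row per transcript for the relevant mode).
#' @param ids_a,ids_b Transcript identifiers of the two groups.
#' @param column Metric column to compare.
#' @param id_col Identifier column, default `"transcript_id"`.
#' @return One-row tibble with group summaries, `estimate`
#'   (mean_a - mean_b), `statistic`, `p.value`, `method`.
#' @export
compare_groups <- function(df, ids_a, ids_b, column, id_col = "transcript_id") {
  a <- df[[column]][df[[id_col]] %in% ids_a]
  b <- df[[column]][df[[id_col]] %in% ids_b]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Both groups need at least 2 observations (variance estimate required).")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble(
    column = column,
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    estimate = mean(a) - mean(b),
    statistic = unname(tt$statistic), p.value = tt$p.value,
    method = "Welch two-sample t-test"
  )
}

#' Contrast somatic and germline selection metrics
#'
#' Pairs per-transcript metrics (default fS, rSM, rSMN) between a somatic
#' and a germline metric table, reports per-metric correlations across the
#' shared transcripts, and -- when a focus set is given (e.g. TEG-like
#' candidates) -- contrasts focus vs rest separately in the somatic and the
#' germline context. Tumor-restricted purifying selection shows up as a
#' focus-vs-rest gap that is large in the somatic context and small in the
#' germline one.
#'
#' @param somatic,germline Metric tables (SO-mode rows are used).
#' @param focus_ids Optional transcript identifiers of the focus group.
#' @param metrics Metric columns to pair.
#' @return List of tibbles: `paired` (suffixes `_s`/`_g` and deltas),
#'   `correlations`, and `contrasts` (when `focus_ids` given; columns
#'   include `context` and the [compare_groups()] fields).
#' @export
somatic_germline_contrast <- function(somatic, germline, focus_ids = NULL,
                                      metrics = c("fS", "rSM", "rSMN")) {
  s <- somatic[somatic$mode == "SO", c("transcript_id", metrics)]
  g <- germline[germline$mode == "SO", c("transcript_id", metrics)]
  paired <- dplyr::inner_join(s, g, by = "transcript_id", suffix = c("_s", "_g"))
  if (nrow(paired) == 0) abort("Somatic and germline tables share no transcripts.")
  for (m in metrics) {
    paired[[paste0("delta_", m)]] <- paired[[paste0(m, "_s")]] - paired[[paste0(m, "_g")]]
  }
  correlations <- dplyr::bind_rows(lapply(metrics, function(m) {
    dplyr::mutate(
      correlate(paired, paste0(m, "_s"), paste0(m, "_g")),
      metric = m, .before = 1
    )
  }))
  contrasts <- NULL
  if (!is.null(focus_ids)) {
    rest <- setdiff(paired$transcript_id, focus_ids)
    contrasts <- dplyr::bind_rows(lapply(metrics, function(m) {
      dplyr::bind_rows(
        dplyr::mutate(
          compare_groups(paired, focus_ids, rest, paste0(m, "_s")),
          metric = m, context = "somatic", .before = 1),
        dplyr::mutate(
          compare_groups(paired, focus_ids, rest, paste0(m, "_g")),
          metric = m, context = "germline", .before = 1)
      )
    }))
  }
  list(paired = paired, correlations = correlations, contrasts = contrasts)
}

#' Overlap of candidate sets with external gene lists
#'
#' Contingency counts and Jaccard indices; no enrichment p-value is
#' computed unless you supply a background universe to a test of your own
#' choosing (overlap reporting here is descriptive).
#'
#' @param candidate_ids Character vector of candidate identifiers.
#' @param resources Named list of character vectors (external gene lists),
#'   identifiers already normalized to the candidate namespace.
#' @return Tibble: `list`, `n_list`, `n_candidates`, `overlap`, `jaccard`.
#' @export
overlap_report <- function(candidate_ids, resources) {
  candidate_ids <- unique(candidate_ids)
  purrr::imap(resources, function(ids, nm) {
    ids <- unique(ids)
    ov <- length(intersect(candidate_ids, ids))
    un <- length(union(candidate_ids, ids))
    tibble(
      list = nm, n_list = length(ids), n_candidates = length(candidate_ids),
      overlap = ov, jaccard = if (un > 0) ov / un else NA_real_
    )
  }) |>
    dplyr::bind_rows()
}

#' Read a gene list (one identifier per line, or first column of a TSV)
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
}

#' Read a two-column essentiality score table (gene, score)
#'
#' More negative scores mean more essential (knockout-screen convention).
#'
#' @param path TSV path with a header.
#' @return Tibble with `gene_id`, `score`.
#' @export
read_essentiality <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble(gene_id = as.character(df[[1]]), score = as.numeric(df[[2]]))
}

#' Expected fraction of tumors without any known driver mutation
#'
#' If a fraction `unknown_fraction` of all cancer driver genes is still
#' unknown and every tumor carries at least `drivers` driver mutations
#' drawn interchangeably from known and unknown drivers, the probability
#' that a tumor shows none of the known drivers is
#' `unknown_fraction ^ drivers`. With half of the drivers unknown and 4-5
#' drivers per tumor this is 0.0625-0.03125, i.e. 3-6% of tumors are
#' expected to lack any known driver.
#'
#' @param unknown_fraction Fraction of driver genes still unknown.
#' @param drivers Integer vector of driver-mutation counts per tumor.
#' @return Tibble with `drivers`, `fraction_no_known_driver`.
#' @export
driver_gap_fraction <- function(unknown_fraction = 0.5, drivers = 4:5) {
  stopifnot(unknown_fraction >= 0, unknown_fraction <= 1, all(drivers >= 1))
  tibble(drivers = drivers,
         fraction_no_known_driver = unknown_fraction ^ drivers)
}
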