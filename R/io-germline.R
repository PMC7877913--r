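#' Column dialect for dbSNP-like germline variant tables
#'
#' @param ... Named overrides.
#' @return Named list of column names.
#' @export
dbsnp_dialect <- function(...) {
  d <- list(
    rsid = "rsID",
    transcript = "Transcript",
    alleles = "Alleles",
    consequence = "Consequence"
  )
  utils::modifyList(d, list(...))
}

.parse_consequence <- function(x) {
  x <- tolower(x)
  dplyr::case_when(
    stringr::str_detect(x, "stop[_ -]?gain|nonsense") ~ "nonsense",
    stringr::str_detect(x, "missense") ~ "missense",
    stringr::str_detect(x, "synonymous|silent") ~ "silent",
    TRUE ~ NA_character_
  )
}

#' Read a dbSNP-like germline variant table
#'
#' Multi-allelic sites (two or three alternate alleles on one rsID, listed
#' comma-separated with matching comma-separated consequences) are expanded
#' so that each variant is one independent record. Categories are
#' restricted to nonsense (stop-gained), missense and synonymous; rows that
#' map to none are reported in the `"rejected"` attribute, not silently
#' dropped.
#'
#' @param path TSV path with rsID, transcript, allele and consequence
#'   columns.
#' @param dialect Column-name map, see [dbsnp_dialect()].
#' @return Tibble with columns `rsid`, `transcript_id`, `alt`, `category`,
#'   and attribute `rejected`.
#' @export
read_germline_table <- function(path, dialect = dbsnp_dialect()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- unlist(dialect)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing mandatory column(s): %s.", paste(missing, collapse = ", ")))
  }
  rec <- tibble(
    rsid = df[[dialect$rsid]],
    transcript_id = df[[dialect$transcript]],
    alt = df[[dialect$alleles]],
    consequence = df[[dialect$consequence]]
  )
  n_alt <- stringr::str_count(rec$alt, ",") + 1L
  n_csq <- stringr::str_count(rec$consequence, ",") + 1L
  malformed <- is.na(rec$alt) | is.na(rec$consequence) | n_alt != n_csq
  if (any(malformed)) {
    warning(sprintf("read_germline_table: %d malformed row(s) reported in the rejected attribute.",
                    sum(malformed)), call. = FALSE)
  }
  good <- rec[!malformed, , drop = FALSE]
  good <- tidyr::separate_longer_delim(good, c("alt", "consequence"), delim = ",")
  good$category <- .parse_consequence(good$consequence)
  unmapped <- good[is.na(good$category), , drop = FALSE]
  out <- good[!is.na(good$category), c("rsid", "transcript_id", "alt", "category")]
  attr(out, "rejected") <- dplyr::bind_rows(rec[malformed, , drop = FALSE], unmapped)
  out
}

#' Tally germline variants per transcript
#'
#' @param records Tibble from [read_germline_table()].
#' @return Tibble with `transcript_id`, `nS`, `nM`, `nN`, `n_inframe = 0`,
#'   `n_frameshift = 0` (germline tables carry substitutions only), so the
#'   result feeds [observed_fractions()] directly.
#' @export
tally_germline <- function(records) {
  records$position <- NA_integer_
  records$class <- NA_character_
  tally_by_transcript(records)
}
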