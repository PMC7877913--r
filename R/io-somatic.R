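#' Column dialect for COSMIC-style somatic mutation tables
#'
#' Maps the reader's logical fields onto the column names of the input TSV.
#' The default matches the CosmicMutantExport layout; override entries for
#' other dialects.
#'
#' @param ... Named overrides, e.g. `transcript = "Transcript_ID"`.
#' @return Named list of column names.
#' @export
cosmic_dialect <- function(...) {
  d <- list(
    gene = "Gene name",
    transcript = "Accession Number",
    description = "Mutation Description",
    cds_change = "Mutation CDS",
    aa_change = "Mutation AA",
    somatic_status = "Mutation somatic status",
    sample_type = "Sample Type",
    snp = "SNP",
    sample_id = "ID_sample",
    site = "Primary site"
  )
  utils::modifyList(d, list(...))
}

# normalize a free-text mutation description to an effect category
.parse_description <- function(x) {
  x <- tolower(x)
  dplyr::case_when(
    stringr::str_detect(x, "frameshift|frame shift") ~ "frameshift",
    stringr::str_detect(x, "(insertion|deletion).*(in ?frame)|in ?frame.*(insertion|deletion)") ~ "inframe",
    stringr::str_detect(x, "coding silent|synonymous") ~ "silent",
    stringr::str_detect(x, "missense") ~ "missense",
    stringr::str_detect(x, "nonsense|stop[_ -]?gain") ~ "nonsense",
    TRUE ~ NA_character_
  )
}

# parse HGVS-like substitution strings "c.123A>G"; returns a data frame
# with position/ref/alt (NA for non-substitutions)
.parse_cds_change <- function(x) {
  m <- stringr::str_match(x, "^c\\.(\\d+)([ACGT])>([ACGT])$")
  data.frame(
    position = as.integer(m[, 2]), ref = m[, 3], alt = m[, 4],
    stringsAsFactors = FALSE
  )
}

#' Read a COSMIC-like somatic mutation table
#'
#' Reads the TSV at `path` and normalizes it to one record per row with a
#' parsed effect category. Substitution positions/alleles are parsed from
#' the HGVS-like CDS change. Rows whose effect cannot be classified are
#' excluded and returned in the `"rejected"` attribute (silent
#' misclassification would bias the category fractions); when `cds` is
#' supplied, substitution rows with an unparseable description are instead
#' classified by translating the mutant codon.
#'
#' @param path TSV path with a header naming the dialect's columns.
#' @param dialect Column-name map, see [cosmic_dialect()].
#' @param cds Optional named character vector of CDS sequences used as a
#'   classification fallback.
#' @return Tibble of normalized records (`gene_id`, `transcript_id`,
#'   `category`, `position`, `ref`, `alt`, `class`, `somatic_status`,
#'   `sample_type`, `snp`, `cds_change`, `sample_id`, `site`), with
#'   attributes `rejected` (tibble of dropped rows) .
#' @export
read_somatic_table <- function(path, dialect = cosmic_dialect(), cds = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  parse_somatic_records(df, dialect = dialect, cds = cds)
}

#' @rdname read_somatic_table
#' @param df An already-loaded data frame in the dialect's column layout.
#' @export
parse_somatic_records <- function(df, dialect = cosmic_dialect(), cds = NULL) {
  need <- unlist(dialect[c("gene", "transcript", "description", "cds_change",
                           "somatic_status", "sample_type", "snp", "sample_id")])
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing mandatory column(s): %s.", paste(missing, collapse = ", ")))
  }
  col <- function(field) {
    nm <- dialect[[field]]
    if (!is.null(nm) && nm %in% names(df)) as.character(df[[nm]]) else rep(NA_character_, nrow(df))
  }
  rec <- tibble(
    gene_id = col("gene"),
    transcript_id = col("transcript"),
    category = .parse_description(col("description")),
    cds_change = col("cds_change"),
    somatic_status = col("somatic_status"),
    sample_type = col("sample_type"),
    snp = tolower(col("snp")),
    sample_id = col("sample_id"),
    site = col("site")
  )
  sub <- .parse_cds_change(rec$cds_change)
  rec$position <- sub$position
  rec$ref <- sub$ref
  rec$alt <- sub$alt
  # fallback: derive the category from the CDS change and codon context
  needs_fix <- is.na(rec$category) & !is.na(rec$position)
  if (!is.null(cds) && any(needs_fix)) {
    idx <- which(needs_fix & rec$transcript_id %in% names(cds))
    if (length(idx) > 0) {
      seqs <- cds[rec$transcript_id[idx]]
      pos <- rec$position[idx]
      codon_i <- (pos - 1L) %/% 3L
      codon <- substr(seqs, codon_i * 3L + 1L, codon_i * 3L + 3L)
      within <- pos - codon_i * 3L
      ok <- nchar(codon) == 3L & !(codon %in% .STOP_CODONS) &
        substr(codon, within, within) == rec$ref[idx] &
        rec$ref[idx] != rec$alt[idx]
      if (any(ok)) {
        rec$category[idx[ok]] <- effect_of_substitution(
          codon[ok], within[ok], rec$alt[idx[ok]]
        )
      }
    }
  }
  is_sub <- rec$category %in% c("silent", "missense", "nonsense")
  rec$class <- NA_character_
  has_alleles <- is_sub & !is.na(rec$ref) & !is.na(rec$alt) & rec$ref != rec$alt
  if (any(has_alleles)) {
    rec$class[has_alleles] <- class_of_change(rec$ref[has_alleles], rec$alt[has_alleles])
  }
  rejected <- rec[is.na(rec$category), , drop = FALSE]
  kept <- rec[!is.na(rec$category), , drop = FALSE]
  if (nrow(rejected) > 0) {
    message(sprintf("parse_somatic_records: %d row(s) with unclassifiable effect routed to the rejected-records report.", nrow(rejected)))
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Somatic record filter configuration
#'
#' Defaults mirror the curation used for tumor-tissue analyses: confirmed
#' somatic mutations only; cell-line, organoid-culture and xenograft
#' samples excluded (they misrepresent tumor evolution in the organism and
#' carry repeated-deposition artifacts); records flagged as SNPs dropped;
#' only the five coding effect categories kept; duplicate reports of the
#' same change in the same sample collapsed.
#'
#' @param require_confirmed_somatic Keep only records whose somatic status
#'   contains "confirmed somatic" (case-insensitive).
#' @param exclude_sample_types Sample types to drop (matched
#'   case-insensitively after normalizing spaces/underscores to dashes).
#' @param snp_flag_required Required SNP flag value (`"n"`), or `NULL` to
#'   skip the check.
#' @param allowed_categories Effect categories retained.
#' @param deduplicate Collapse duplicate (sample, transcript, CDS-change)
#'   records.
#' @param min_mutations_per_transcript Default threshold used by
#'   [filter_min_mutations()] in the pipeline.
#' @return A list with class `"filter_config"`.
#' @export
filter_config <- function(require_confirmed_somatic = TRUE,
                          exclude_sample_types = c("cell-line", "organoid-culture", "xenograft"),
                          snp_flag_required = "n",
                          allowed_categories = c("silent", "missense", "nonsense", "inframe", "frameshift"),
                          deduplicate = TRUE,
                          min_mutations_per_transcript = 100L) {
  stopifnot(min_mutations_per_transcript >= 0)
  structure(
    list(
      require_confirmed_somatic = require_confirmed_somatic,
      exclude_sample_types = exclude_sample_types,
      snp_flag_required = snp_flag_required,
      allowed_categories = allowed_categories,
      deduplicate = deduplicate,
      min_mutations_per_transcript = as.integer(min_mutations_per_transcript)
    ),
    class = "filter_config"
  )
}

.norm_sample_type <- function(x) gsub("[ _]+", "-", tolower(trimws(x)))

#' Apply record-level filters to somatic mutation records
#'
#' Filters are applied in sequence (somatic status, sample type, SNP flag,
#' effect category, deduplication); per-filter drop counts are messaged and
#' attached as the `"drop_counts"` attribute. Filtering is total: no record
#' errors, every record is either kept or counted against one filter.
#'
#' @param records Tibble from [read_somatic_table()].
#' @param config See [filter_config()].
#' @return Filtered tibble with a `drop_counts` attribute (named integer).
#' @export
apply_filters <- function(records, config = filter_config()) {
  drops <- c(somatic_status = 0L, sample_type = 0L, snp_flag = 0L,
             category = 0L, duplicate = 0L)
  n0 <- nrow(records)
  if (isTRUE(config$require_confirmed_somatic)) {
    keep <- stringr::str_detect(tolower(records$somatic_status %||% ""), "confirmed somatic")
    keep[is.na(keep)] <- FALSE
    drops["somatic_status"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  if (length(config$exclude_sample_types) > 0) {
    keep <- !(.norm_sample_type(records$sample_type) %in%
                .norm_sample_type(config$exclude_sample_types))
    drops["sample_type"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  if (!is.null(config$snp_flag_required)) {
    keep <- records$snp %in% tolower(config$snp_flag_required)
    drops["snp_flag"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  keep <- records$category %in% config$allowed_categories
  drops["category"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (isTRUE(config$deduplicate)) {
    keep <- !duplicated(records[, c("sample_id", "transcript_id", "cds_change")])
    drops["duplicate"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  message(sprintf(
    "apply_filters: %d -> %d records (dropped: %s)",
    n0, nrow(records),
    paste(sprintf("%s %d", names(drops), drops), collapse = ", ")
  ))
  attr(records, "drop_counts") <- drops
  records
}
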