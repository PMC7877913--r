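#' @importFrom rlang abort .data %||%
#' @importFrom tibble tibble as_tibble
NULL

.pkg_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The six pyrimidine-centric substitution classes
#'
#' Every directed single-base change is named by the pyrimidine of the
#' mutated Watson-Crick pair, giving six classes: C>A, C>G, C>T, T>A, T>C,
#' T>G. Changes with a purine reference (e.g. G>A) are complement-folded to
#' their pyrimidine-strand equivalent (C>T).
#'
#' @return Character vector of the six class labels, in canonical order.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' The 61 sense codons of the standard genetic code
#'
#' @return Character vector of the 61 codons that encode an amino acid
#'   (all 64 triplets minus the stop codons TAA, TAG, TGA).
#' @export
sense_codons <- function() {
  all64 <- names(Biostrings::GENETIC_CODE)
  setdiff(all64, .STOP_CODONS)
}

.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.check_sense_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || any(is.na(codon))) {
    abort(sprintf("`%s` must be a character vector of codons.", arg))
  }
  bad_form <- nchar(codon) != 3L |
    !vapply(strsplit(codon, ""), function(b) all(b %in% .BASES), logical(1))
  if (any(bad_form)) {
    abort(sprintf(
      "Malformed codon(s): %s. Codons must be 3 characters over A/C/G/T; ambiguity codes are rejected, not skipped.",
      paste(unique(codon[bad_form]), collapse = ", ")
    ))
  }
  is_stop <- codon %in% .STOP_CODONS
  if (any(is_stop)) {
    abort(sprintf(
      "Stop codon(s) supplied where a sense codon is required: %s.",
      paste(unique(codon[is_stop]), collapse = ", ")
    ))
  }
  invisible(codon)
}

#' Substitution class of a directed base change
#'
#' @param ref,alt Reference and alternate bases (A/C/G/T), vectorised.
#'   `ref` and `alt` must differ element-wise.
#' @return Character vector of class labels (see [substitution_classes()]).
#'   Purine-reference changes are complemented before labeling, so
#'   `class_of_change("G", "A")` is `"C>T"`.
#' @export
class_of_change <- function(ref, alt) {
  if (length(ref) != length(alt)) abort("`ref` and `alt` must have equal length.")
  ok <- ref %in% .BASES & alt %in% .BASES
  if (!all(ok)) abort("`ref` and `alt` must be single DNA bases (A/C/G/T).")
  if (any(ref == alt)) abort("`ref` and `alt` must differ (no self-substitution).")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, unname(.COMPLEMENT[ref]), ref)
  a <- ifelse(purine, unname(.COMPLEMENT[alt]), alt)
  paste0(r, ">", a)
}

#' Enumerate the nine single-base substitutions of a sense codon
#'
#' Each sense codon can undergo 3 positions x 3 alternative bases = 9
#' substitutions; each is assigned a functional effect (silent, missense,
#' nonsense) by translating the mutant codon under the standard genetic
#' code, and a substitution class by [class_of_change()] on the reference
#' base. Effects are computed on the coding strand; complement folding
#' applies only to the class label.
#'
#' @param codon Character vector of sense codons (stop codons and
#'   malformed/ambiguous codons are rejected with an error).
#' @return A tibble with columns `codon`, `position` (1-3), `ref`, `alt`,
#'   `effect` (`"silent"`, `"missense"`, `"nonsense"`) and `class`; 9 rows
#'   per input codon.
#' @examples
#' enumerate_substitutions("TGG")  # 7 missense, 2 nonsense
#' @export
enumerate_substitutions <- function(codon) {
  .check_sense_codon(codon)
  tab <- substitution_table()
  out <- tab[match_all(tab$codon, codon), , drop = FALSE]
  as_tibble(out)
}

# indices of `values` whose entries equal any of `targets`, preserving the
# order of `targets` (so repeated codons yield repeated blocks)
match_all <- function(values, targets) {
  idx <- split(seq_along(values), values)
  unlist(idx[targets], use.names = FALSE)
}

#' Full substitution table of the standard genetic code
#'
#' All 549 single-base substitutions of the 61 sense codons, with effect
#' and substitution class. Computed once and cached.
#'
#' @return A 549-row tibble (columns as in [enumerate_substitutions()]).
#' @export
substitution_table <- function() {
  if (!is.null(.pkg_cache$subst_table)) return(.pkg_cache$subst_table)
  codons <- sense_codons()
  grid <- expand.grid(
    codon = codons, position = 1:3, alt = .BASES,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid$ref <- substr(grid$codon, grid$position, grid$position)
  grid <- grid[grid$ref != grid$alt, , drop = FALSE]
  mutant <- grid$codon
  substr(mutant, grid$position, grid$position) <- grid$alt
  aa_wt <- .translate_codon(grid$codon)
  aa_mut <- .translate_codon(mutant)
  grid$effect <- ifelse(aa_mut == "*", "nonsense",
    ifelse(aa_mut == aa_wt, "silent", "missense")
  )
  grid$class <- class_of_change(grid$ref, grid$alt)
  grid <- grid[order(grid$codon, grid$position, grid$alt), ]
  out <- as_tibble(grid[, c("codon", "position", "ref", "alt", "effect", "class")])
  .pkg_cache$subst_table <- out
  out
}

#' Census of substitution effects over a set of codons
#'
#' Aggregates [enumerate_substitutions()] over a codon set. Over the full
#' standard code (the default) the census is 549 substitutions: 392
#' missense, 134 silent and 23 nonsense.
#'
#' @param codons Character vector of sense codons (default: all 61).
#'   An empty vector yields an all-zero census.
#' @return One-row tibble with `n_codons`, `total`, `n_missense`,
#'   `n_silent`, `n_nonsense`.
#' @export
code_census <- function(codons = sense_codons()) {
  if (length(codons) == 0) {
    return(tibble(
      n_codons = 0L, total = 0L,
      n_missense = 0L, n_silent = 0L, n_nonsense = 0L
    ))
  }
  subs <- enumerate_substitutions(codons)
  tibble(
    n_codons = length(codons),
    total = nrow(subs),
    n_missense = sum(subs$effect == "missense"),
    n_silent = sum(subs$effect == "silent"),
    n_nonsense = sum(subs$effect == "nonsense")
  )
}

#' Effect of a single specified substitution
#'
#' @param codon Sense codon(s).
#' @param position Position within the codon (1-3), vectorised.
#' @param alt Alternative base, must differ from the reference base at
#'   `position`.
#' @return Character vector: `"silent"`, `"missense"` or `"nonsense"`.
#' @export
effect_of_substitution <- function(codon, position, alt) {
  .check_sense_codon(codon)
  if (!all(position %in% 1:3)) abort("`position` must be 1, 2 or 3.")
  if (!all(alt %in% .BASES)) abort("`alt` must be a DNA base (A/C/G/T).")
  ref <- substr(codon, position, position)
  if (any(ref == alt)) {
    abort("`alt` equals the reference base at `position` for some entries.")
  }
  tab <- substitution_table()
  key <- paste(tab$codon, tab$position, tab$alt)
  eff <- tab$effect[match(paste(codon, position, alt), key)]
  eff
}
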