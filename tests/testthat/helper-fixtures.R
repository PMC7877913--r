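# In-code fixtures: a small COSMIC-dialect somatic table with known
# composition, and a matching dbSNP-dialect germline table.

somatic_fixture <- function() {
  tibble::tibble(
    `Gene name` = "G1",
    `Accession Number` = "TX1",
    `Mutation Description` = c(
      rep("Substitution - Missense", 3),
      rep("Substitution - coding silent", 2),
      "Substitution - Nonsense",
      rep("Deletion - Frameshift", 2),
      rep("Insertion - In frame", 2)
    ),
    `Mutation CDS` = c(
      "c.4A>G", "c.5T>C", "c.7G>T", "c.9C>T", "c.12G>A", "c.10A>T",
      "c.20del", "c.21del", "c.30_32ins", "c.33_35ins"
    ),
    `Mutation AA` = "p.?",
    `Mutation somatic status` = "Confirmed somatic variant",
    `Sample Type` = "Tumour Sample",
    SNP = "n",
    ID_sample = paste0("S", 1:10),
    `Primary site` = "lung"
  )
}

write_fixture_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}

# small planted cohort for pipeline-level tests
small_cohort <- function(n = 300, seed = 7, ...) {
  simulate_cohort(simulation_config(n_transcripts = n, seed = seed, ...))
}
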