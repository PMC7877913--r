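# Independent oracle for the genetic-code and expectation machinery.
# The codon -> amino-acid table is entered by hand (not taken from any
# package) so oracle and implementation share no code path.

ORACLE_BASES <- c("A", "C", "G", "T")

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_sense_codons <- function() names(ORACLE_CODE)[ORACLE_CODE != "*"]

oracle_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    ref <- comp[[ref]]
    alt <- comp[[alt]]
  }
  paste0(ref, ">", alt)
}

# brute-force re-enumeration of the nine changes of one codon
oracle_enumerate <- function(codon) {
  out <- NULL
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (alt in setdiff(ORACLE_BASES, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      aa_wt <- ORACLE_CODE[[codon]]
      aa_mut <- ORACLE_CODE[[mut]]
      effect <- if (aa_mut == "*") "nonsense"
        else if (aa_mut == aa_wt) "silent" else "missense"
      out <- rbind(out, data.frame(
        codon = codon, position = pos, ref = ref, alt = alt,
        effect = effect, class = oracle_class(ref, alt),
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}

# brute-force expected fractions: explicit per-change weight accumulation
oracle_expected_fractions <- function(counts, profile) {
  mass <- c(silent = 0, missense = 0, nonsense = 0)
  for (codon in names(counts)) {
    en <- oracle_enumerate(codon)
    for (i in seq_len(nrow(en))) {
      mass[[en$effect[i]]] <- mass[[en$effect[i]]] +
        counts[[codon]] * profile[[en$class[i]]]
    }
  }
  mass / sum(mass)
}
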