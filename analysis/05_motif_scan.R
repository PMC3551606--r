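#!/usr/bin/env Rscript
# Scan the conserved propeptide aromatic motif against sequences. Because no
# alignment is bundled, the scan is demonstrated on synthetic propeptide-
# length sequences with the motif planted (recovery check) and on pure
# random sequences (chance-hit rate). Writes results/motif_hits.tsv.

library(foldshift)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

motif <- parse_motif(AROMATIC_CORE_MOTIF)
cat("motif:", motif$source_text, "\n")
cat("span:", motif$span, "residues;",
    sum(vapply(motif$elements, is.character, logical(1))),
    "constrained aromatic slots\n\n")

# planted recovery on propeptide-length (79 aa) synthetic sequences
planted <- gen_sequences(50, 79, planted_motif = motif, seed = 42)
fasta <- "scratch/synthetic_propeptides.fasta"
write_fasta(planted, fasta)
hits <- scan_fasta(motif, read_fasta(fasta))
write.table(hits, "results/motif_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
recovered <- sum(mapply(function(id, at)
  any(hits$sequence_id == id & hits$start == at),
  planted$id, planted$planted_at))
cat(sprintf("planted-motif recovery: %d/%d sequences\n", recovered,
            nrow(planted)))

# chance-hit rate in unconstrained random sequences of the same length
bg <- gen_sequences(2000, 79, seed = 43)
bg_hits <- sum(vapply(bg$sequence,
                      function(s) nrow(scan_motif(motif, s)), integer(1)))
cat(sprintf("background hits in 2000 random 79-mers: %d\n", bg_hits))
cat("(five constrained aromatic slots make chance matches vanishingly rare,\n")
cat(" so a hit in a real propeptide is informative)\n")
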