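#!/usr/bin/env Rscript
# Simulate one reference genome and its packaged virions for each of the
# six packaging strategies, shear them into paired-end reads, and write
# the draft contigs, reads and ground truth under results/simulation/.
#
# Each strategy leaves its characteristic fingerprint in the packaged
# molecules: terminally redundant permuted monomers (headful), unit-length
# monomers with cohesive ends plus library end-chemistry (cos), a
# duplicated terminal repeat (DTR), fixed inverted-repeat ends (ITR), and
# variable host-DNA flanks (Mu-like).

library(phagestd)

out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- pipeline_config(seed = 7L)

for (st in cfg$strategies) {
  case <- simulate_genome_case(st, cfg, with_genes = FALSE)
  prefix <- file.path(out, st)
  write_fasta(case$genome, paste0(prefix, "_reference.fasta"))
  write_fasta(case$contig, paste0(prefix, "_draft_contig.fasta"))
  write_read_pairs(case$reads, prefix)
  write_virion_truth(case$virions, paste0(prefix, "_virion_truth.tsv"))
  cat(sprintf("%-12s %d virions, %d read pairs, draft contig %d bp\n",
              st, length(case$virions), nrow(case$reads),
              nchar(case$contig$sequence)))
}
cat("wrote", out, "\n")
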