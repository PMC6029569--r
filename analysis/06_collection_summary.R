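#!/usr/bin/env Rscript
# Collection-level statistics over the bundled register of 283 curated
# genome records, plus a strain-name round-trip check. Writes
# results/summary/.

library(phagestd)

out <- "results/summary"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

reg <- read_collection_register()
s <- collection_summary(reg)

cat(sprintf("rows: %d (%d unique isolates, %d sub-lineage/replicate)\n",
            s$n_rows, s$n_unique, s$n_sublineage))
cat(sprintf("genome length: %s - %s bp (medians: %s unique / %s all)\n",
            format(s$length_min, big.mark = ","),
            format(s$length_max, big.mark = ","),
            format(s$length_median_unique, big.mark = ","),
            format(s$length_median_all, big.mark = ",")))
cat(sprintf("GC%%: %.1f - %.1f (rounds to %d-%d), median %.1f\n",
            s$gc_min, s$gc_max, s$gc_range_rounded[1],
            s$gc_range_rounded[2], s$gc_median))
cat(sprintf("tRNA-carrying rows: %d; CRISPR-carrying rows: %d\n",
            s$n_with_trna, s$n_with_crispr))

ok <- vapply(reg$virus_name, function(nm)
  identical(format_strain_name(parse_strain_name(nm)), nm), logical(1))
cat(sprintf("strain names round-tripping exactly: %d / %d\n",
            sum(ok), length(ok)))

writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE, digits = NA),
           file.path(out, "collection_summary.json"))
cat("wrote", out, "\n")
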