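#!/usr/bin/env Rscript
# Single-gene-deletion screen of the mini phototroph under the
# photoautotrophic light condition, classified against the shipped
# synthetic in vivo viability table (10% of wild-type growth cutoff).

suppressPackageStartupMessages(library(cyanoflux))
dir.create("results", showWarnings = FALSE)

mini <- make_mini_phototroph()
m <- read_sbml("results/fixtures/mini_phototroph.xml")
viab <- system.file("extdata", "synthetic_mini_phototroph_viability.tsv",
                    package = "cyanoflux")

res <- run_essentiality(m, mini$scenarios$light, viab,
                        diurnal_sets = mini$diurnal_sets)
write.table(res$calls, "results/essentiality_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(res$summary, "results/essentiality_summary.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

cat("Per-gene calls:\n"); print(res$calls, row.names = FALSE)
cat("\nCategory counts: ")
print(res$summary$counts)
cat("specificity:", res$summary$specificity,
    " sensitivity:", res$summary$sensitivity, "\n")
cat("\nPlanted essential set recovered:",
    setequal(res$calls$gene[res$calls$in_silico == "NG"],
             mini$truth$essential_genes_light), "\n")
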