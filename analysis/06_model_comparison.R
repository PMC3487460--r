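#!/usr/bin/env Rscript
# Model-to-model comparison by shared/unique reaction and metabolite ids
# (the Venn-diagram bookkeeping used when contrasting two related
# reconstructions), demonstrated between the mini phototroph and a
# variant with its nitrogenase branch swapped for a hydrogenase-style
# duplicate.

suppressPackageStartupMessages(library(cyanoflux))
dir.create("results", showWarnings = FALSE)

a <- read_sbml("results/fixtures/mini_phototroph.xml")

# variant organism: drop the glycogen-synthesis isozyme pair, add a
# direct NADPH-driven hydrogenase (no ATP cost)
b <- a
b$id <- "mini_phototroph_variant"
keep <- setdiff(b$reactions$id, "GLYS")
met <- b$metabolites
rxn <- rbind(b$reactions[b$reactions$id %in% keep, ],
             data.frame(id = "HYD", name = "HYD", lower = 0, upper = 1000,
                        kind = "metabolic", gpr = "gHox"))
S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
S[rownames(a$stoich), intersect(colnames(a$stoich), keep)] <-
  a$stoich[, intersect(colnames(a$stoich), keep)]
S[c("nadph_c", "h2_c"), "HYD"] <- c(-1, 1)
b <- metabolic_model(met, rxn, S, biomass = a$biomass,
                     id = "mini_phototroph_variant")

cmp <- compare_models(a, b)
print(cmp)
write_comparison(cmp, "results/model_comparison")
cat("\nShared reactions:", length(cmp$reactions$shared),
    "| unique to", cmp$a, ":", length(cmp$reactions$unique_to_a),
    "| unique to", cmp$b, ":", length(cmp$reactions$unique_to_b), "\n")
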