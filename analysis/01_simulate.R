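#!/usr/bin/env Rscript
# Generate the synthetic study bundle: a six-strain batch-cultivation
# dataset (triplicate, heteroscedastic noise), an expression matrix with
# genes planted to correlate with the protein production rate and with
# biomass, the salvage toy network, and annotation maps for enrichment.

suppressMessages(library(proload))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

st <- simulate_study(base = batch_params(seed = 42))
write_cultivation(st$dataset, file.path(out, "cultivation.tsv"))

ep <- expression_sim_params(n_genes = 400, n_planted_per_parameter = 40,
                            target_correlation = 0.9, seed = 43)
sim <- simulate_expression(ep, st$parameters[c("protein_rate", "cdw")])
write_expression(sim$expr, file.path(out, "expression.tsv"))
write.table(sim$labels, file.path(out, "planted_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_model(make_toy_model("salvage"), file.path(out, "model.tsv"))
write_ground_truth(simulate_batch(batch_params(seed = 42)),
                   file.path(out, "ground_truth.json"))

planted <- sim$labels[sim$labels$parameter != "background", ]
ann <- data.frame(term = paste0("planted_", planted$parameter),
                  item = planted$gene)
write.table(ann, file.path(out, "annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("strains:", length(st$strains),
    "| cultivation records:", nrow(st$dataset$records),
    "| genes:", ep$n_genes,
    "(", nrow(planted), "planted )\n")
cat("bundle written to", out, "\n")
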