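#!/usr/bin/env Rscript
# Run the full SynCom screening and assembly pipeline on the tables written
# by 01_simulate.R. All results (associations, functional groups, network,
# SynCom membership, Mantel/ANOSIM stats, Raup-Crick matrices, NMDS,
# assembly summaries, manifest) land under results/screen/.

suppressMessages(library(syncomscreen))

inp <- "results/data"
stopifnot(file.exists(file.path(inp, "abundance.tsv")))

res <- run_screen("results/screen",
                  abundance_path = file.path(inp, "abundance.tsv"),
                  compound_path = file.path(inp, "compounds.tsv"),
                  metadata_path = file.path(inp, "metadata.tsv"),
                  rc_reps = 999, seed = 1)

cat("SynCom members:", paste(res$syncom$final, collapse = ", "), "\n")
cat("network edges:", nrow(res$network$edges),
    " hubs:", paste(res$groups$cooccurring, collapse = ", "), "\n")
cat("Mantel (bacteria vs compounds): r =",
    round(res$stats$mantel$bacteria_vs_compounds$r, 3),
    "p =", res$stats$mantel$bacteria_vs_compounds$p, "\n")
cat("ANOSIM (compounds, CK vs Lpscw): R =",
    round(res$stats$anosim_compounds_between_arms$R, 3),
    "p =", res$stats$anosim_compounds_between_arms$p, "\n")
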