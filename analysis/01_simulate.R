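#!/usr/bin/env Rscript
# Generate the simulated two-arm fermentation dataset (spontaneous CK vs
# inoculated Lpscw) and write the three input tables plus the generator's
# ground truth under results/data/.

suppressMessages(library(syncomscreen))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# two of the three planted hubs coincide with producers: keystone taxa that
# are simultaneously flavor-associated, nodal and abundant are exactly what
# the cross-reference screen is designed to select
cfg <- syncom_config(seed = 1, producer_hub_overlap = 2)
ds <- generate_dataset(cfg)

write_table_tsv(ds$abundance, file.path(out, "abundance.tsv"))
write_table_tsv(ds$compounds, file.path(out, "compounds.tsv"))
write_table_tsv(ds$metadata, file.path(out, "metadata.tsv"))
jsonlite::write_json(
  ds$truth[c("producers", "hubs", "partners", "major", "shuffled_fungi")],
  file.path(out, "ground_truth.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("wrote", length(list.files(out)), "files to", out, "\n")
cat("taxa:", nrow(ds$abundance$values),
    " samples:", ncol(ds$abundance$values),
    " compounds:", nrow(ds$compounds$values), "\n")
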