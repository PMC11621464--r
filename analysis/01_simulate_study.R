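#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic dataset.
#
# 22 species on a pure-birth chronogram; per species 4 colonies recorded
# twice (14.5 h at 30 s) and 4 isolated individuals (8.5 h), every recording
# produced by a noise-driven FitzHugh-Nagumo oscillator whose rhythm
# strength and target period evolve by Brownian motion along the tree.
# Colony-level rhythm strength evolves at 3x the individual-level SD — the
# planted "emergent evolution" signal that later stages should recover.
#
# Usage: Rscript analysis/01_simulate_study.R [--seed N] [--out DIR]

suppressPackageStartupMessages(library(rhythmevo))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
seed <- as.integer(arg("--seed", "1"))
out <- arg("--out", "results/study")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config(seed = seed)
message(sprintf("simulating %d species x (%d colonies x %d recordings + %d individuals) ...",
                cfg$n_species, cfg$colonies_per_species,
                cfg$recordings_per_colony, cfg$individuals_per_species))
ds <- simulate_study_dataset(cfg)

write_series_csv(ds$series, file.path(out, "series.csv"))
ape::write.tree(ds$tree, file.path(out, "chronogram.nwk"))
write.csv(ds$provenance, file.path(out, "provenance.csv"), row.names = FALSE)
jsonlite::write_json(unclass(cfg), file.path(out, "study_config.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("wrote %d series (%s), tree with %d tips, and provenance to %s",
                length(ds$series),
                paste(range(vapply(ds$series, length, 0L)), collapse = "-"),
                length(ds$tree$tip.label), out))
message("ground truth: colony rhythm-strength SD = ",
        cfg$interspecific_sd_colony[["rhythm"]],
        ", individual = ", cfg$interspecific_sd_individual[["rhythm"]],
        " (period SDs equal at ", cfg$interspecific_sd_colony[["period"]], ")")
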