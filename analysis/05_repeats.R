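#!/usr/bin/env Rscript
# Stage 5: ampliconic repeat structure — lay out repeat units into a
# contig, detect direct/inverted repeat arms from the 10 nt word dot-plot,
# compute arm-to-arm identities, and demonstrate overlap assembly of an
# exact tiling of a large synthetic contig.
suppressMessages(library(ygenefam))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 7L
outdir <- if (length(args) >= 2) args[2] else "results/run"

cfg <- run_config(seed = seed)
run_pipeline(cfg, "repeats", outdir = outdir)

arms <- read_tsv(file.path(outdir, "repeat_arms.tsv"))
cat("Detected", nrow(arms), "repeat arm pairs:\n")
if (nrow(arms) > 0) {
  arms$identity <- round(arms$identity, 2)
  print(arms)
}
layout <- read_tsv(file.path(outdir, "assembly_layout.tsv"))
cat("Overlap assembly layout (", length(unique(layout$contig_id)),
    "contig(s) ):\n")
print(layout)
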