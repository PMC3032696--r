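#!/usr/bin/env Rscript
# Stage 2: splice-aware coding assessment of every simulated transcript
# against its family's reference CDS — indels, frameshifts, premature
# stops, structural types (full-length / insertion- / deletion-frameshifted)
# and the active/pseudogene call — then a confusion table against truth.
suppressMessages(library(ygenefam))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 7L
outdir <- if (length(args) >= 2) args[2] else "results/run"

cfg <- run_config(seed = seed)
run_pipeline(cfg, "annotate", outdir = outdir)

res <- read_tsv(file.path(outdir, "assessments.tsv"))
truth <- read_tsv(file.path(outdir, "truth_loci.tsv"))
truth <- truth[match(res$locus_id, truth$locus_id), ]

cat("Structural types:\n")
print(table(res$structural_type))
cat("Classification vs truth:\n")
conf <- table(truth_active = truth$is_active, called = res$status)
print(conf)
write_tsv(as.data.frame(conf), file.path(outdir, "confusion.tsv"))
cat("All truth-active loci called active:",
    all(res$status[truth$is_active] == "active"), "\n")
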