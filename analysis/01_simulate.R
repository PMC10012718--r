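#!/usr/bin/env Rscript
# Simulate a clade-labelled study system with known truth: founder introns
# retrotransposing, being lost (sometimes fossilizing), and carrying decaying
# maturases. Writes per-tip genomes (FASTA + feature TSV), the pooled intron
# records, and the truth tables under results/sim/.
suppressPackageStartupMessages(library(intronfam))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 101L

outdir <- file.path("results", "sim")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tree <- paste0("((LIV:0.05,MOS:0.05):0.03,(HOR:0.04,(LYC:0.03,(FER:0.02,",
               "(GYM:0.02,ANG:0.02):0.02):0.02):0.02):0.03):0.02;")
params <- simulation_params(tree = tree, seed = seed)
sim <- simulate_introns(params)

for (tip in names(sim$genomes)) {
  g <- sim$genomes[[tip]]
  write_fasta(stats::setNames(g$sequence, g$id),
              file.path(outdir, paste0(tip, ".fasta")))
  utils::write.table(g$features, file.path(outdir, paste0(tip, ".features.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
utils::write.table(sim$records[, setdiff(names(sim$records), "sequence")],
                   file.path(outdir, "records.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_fasta(stats::setNames(sim$records$sequence,
                            paste(sim$records$site, sim$records$taxon, sep = ".")),
            file.path(outdir, "introns.fasta"))
utils::write.table(sim$truth$events, file.path(outdir, "truth_events.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(sim, file.path(outdir, "sim.rds"))  # scratch object for later steps
write_manifest(file.path(outdir, "manifest.json"),
               config = list(tree = tree, stage = "simulate"), seed = seed)

cat(sprintf("simulated %d intron copies at %d sites across %d tips; %s\n",
            nrow(sim$records), length(unique(sim$records$site)),
            length(sim$genomes),
            paste(names(table(sim$truth$events$type)),
                  table(sim$truth$events$type), sep = "=", collapse = ", ")))
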