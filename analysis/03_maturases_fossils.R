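#!/usr/bin/env Rscript
# Maturase annotation (ORFs, domain grades, protein clusters), superfamily
# assembly, and fossil scans of the simulated tip genomes. Writes maturase
# and fossil tables under results/.
suppressPackageStartupMessages(library(intronfam))

sim <- readRDS(file.path("results", "sim", "sim.rds"))
fams <- utils::read.delim(file.path("results", "families", "families.tsv"),
                          stringsAsFactors = FALSE)

outdir <- file.path("results", "maturases")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
motifs <- default_motif_set()

## maturase ORFs per unique site (best-conserved representative per site)
mats <- list()
for (sk in unique(sim$records$site)) {
  recs <- sim$records[sim$records$site == sk, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(recs))) {
    orfs <- find_maturase_orf(recs$sequence[i], frameshift_tolerant = TRUE)
    if (nrow(orfs) > 0 && (is.null(best) ||
                           nchar(orfs$protein[1]) > nchar(best$protein)))
      best <- list(protein = orfs$protein[1], taxon = recs$taxon[i],
                   start = orfs$start[1], end = orfs$end[1],
                   n_parts = orfs$n_parts[1])
  }
  if (!is.null(best)) {
    g <- grade_domains(best$protein, motifs)
    mats[[sk]] <- data.frame(site = sk, taxon = best$taxon,
                             orf_start = best$start, orf_end = best$end,
                             n_parts = best$n_parts, rt_x = g$rt_x,
                             en = g$en, protein = best$protein,
                             stringsAsFactors = FALSE)
  }
}
mat_df <- do.call(rbind, mats)
if (is.null(mat_df)) {
  cat("no maturase ORFs found\n")
} else {
  clusters <- cluster_maturases(stats::setNames(mat_df$protein, mat_df$site))
  mat_df <- merge(mat_df, clusters, by = "site")
  utils::write.table(mat_df[, setdiff(names(mat_df), "protein")],
                     file.path(outdir, "maturases.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(stats::setNames(mat_df$protein, mat_df$site),
              file.path(outdir, "maturases.fasta"))
  ext <- assemble_superfamilies(fams, clusters)
  utils::write.table(ext, file.path(outdir, "families_extended.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("maturases at %d sites in %d protein clusters; %d superfamily assignments\n",
              nrow(mat_df), max(clusters$cluster),
              sum(nzchar(ext$superfamily))))
}

## fossil scans, one per tip genome
fdir <- file.path("results", "fossils")
dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
queries <- stats::setNames(sim$records$sequence, sim$records$site)
queries <- queries[!duplicated(names(queries))]
all_hits <- list()
for (tip in names(sim$genomes)) {
  hits <- scan_intergenic(queries, sim$genomes[[tip]])
  if (nrow(hits) > 0) {
    hits$fraction_pct <- fossil_fraction(sim$genomes[[tip]], hits)
    all_hits[[tip]] <- hits
  }
}
fossils <- if (length(all_hits) > 0) do.call(rbind, all_hits) else
  data.frame()
utils::write.table(fossils, file.path(fdir, "fossil_hits.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
truth_fossils <- sim$truth$events[sim$truth$events$type == "fossil", ]
cat(sprintf("fossil hits: %d recovered across tips (%d fossilization events simulated)\n",
            nrow(fossils), nrow(truth_fossils)))
write_manifest(file.path(fdir, "manifest.json"),
               config = list(stage = "maturases_fossils"),
               seed = sim$params$seed)
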