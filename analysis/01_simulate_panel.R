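#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Builds (a) a gapped promoter alignment of a reference plus three contigs
# with planted deletions (7-2388 bp, including a partially overlapping
# pair), insertions (8-3800 bp), 40 SNP loci and unaligned contig ends, and
# (b) a 626-line mostly-selfing diploid panel genotyped at 20 markers and
# phenotyped for three ordered phenology traits (BE/SF/EF) in two seasons
# with 3-10 replicates. Everything downstream consumes these files.

suppressPackageStartupMessages(library(ftindelscan))

seed <- 42L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_alignment(seed = seed)
write_alignment(sim$aln, file.path(out, "alignment.fasta"))
write.table(sim$truth$indels, file.path(out, "truth_indels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$snps, file.path(out, "truth_snps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

panel <- simulate_panel(sim_config(), seed = seed)
write.table(cbind(line_id = rownames(panel$geno), as.data.frame(panel$geno)),
            file.path(out, "genotypes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(panel$pheno, file.path(out, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated alignment:", length(sim$aln$seqs), "sequences x",
    sim$aln$length, "columns;", nrow(sim$truth$indels), "planted indels,",
    nrow(sim$truth$snps), "planted SNPs\n")
cat("Simulated panel:", nrow(panel$geno), "lines x", ncol(panel$geno),
    "markers;", nrow(panel$pheno), "phenotype observations\n")
cat("Causal marker:", names(panel$truth$causal_effects), "with effect",
    unname(panel$truth$causal_effects), "days per allele\n")
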