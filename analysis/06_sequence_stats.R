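#!/usr/bin/env Rscript
# Sequence statistics on the synthetic element alignment: trinucleotide
# substitution spectrum, strand-asymmetry bootstrap, four-gamete
# recombination scan, C/D boundary LD, divergence dating under both clock
# conventions, and the genomic-compartment and coincidence Monte-Carlo
# tests with the printed inputs.

suppressPackageStartupMessages(library(ervkit))
in_dir <- "results/synthetic"
out_dir <- "results"

vars <- read_tsv_file(file.path(in_dir, "element_variants.tsv"))
cons <- read_alignment_fasta(file.path(in_dir, "elements.fasta"))[["consensus"]]
geno_raw <- read_tsv_file(file.path(in_dir, "element_genotypes.tsv"))
geno <- t(as.matrix(geno_raw[, -(1:4)]))
colnames(geno) <- geno_raw$variant_id
classes <- read_tsv_file(file.path(in_dir, "element_classes.tsv"))

## substitution spectrum and strand asymmetry
enr <- spectrum_enrichment(vars, cons)
write_tsv_file(data.frame(type = rownames(enr), enr, check.names = FALSE),
               file.path(out_dir, "spectrum_enrichment.tsv"))
obs <- attr(enr, "observed")
top <- which(enr == max(enr[obs > 5], na.rm = TRUE), arr.ind = TRUE)[1, ]
cat(sprintf("strongest enrichment: %s in context %s (%.1f-fold)\n",
            rownames(enr)[top["row"]], colnames(enr)[top["col"]],
            max(enr[obs > 5], na.rm = TRUE)))

mir <- mirror_asymmetry_test(vars, cons, B = 2000, seed = 61)
write_tsv_file(mir, file.path(out_dir, "mirror_asymmetry.tsv"))
ga <- mir[mir$type_a == "G>A" & mir$stratum == "nonCpG", ]
cat(sprintf("G>A vs C>T (non-CpG): diff %.3g, two-sided p = %.3g\n",
            ga$diff, ga$p))

## recombination evidence
fg <- four_gamete_scan(geno)
write_tsv_file(fg, file.path(out_dir, "four_gamete.tsv"))
cat(sprintf("four-gamete violations: %d of %d variant pairs (%d true recombinants)\n",
            sum(fg$four_gamete), nrow(fg),
            nrow(jsonlite::read_json(file.path(in_dir, "alignment_truth.json"),
                                     simplifyVector = TRUE)$recombinations)))

cdld <- cd_boundary_ld(classes$class[match(rownames(geno), classes$element_id)],
                       geno)
write_tsv_file(cdld, file.path(out_dir, "cd_boundary_ld.tsv"))

## divergence dating with the printed inputs
cd_date <- divergence_dating(38.4, 250, 1e-8, "total-branch")
ltr_date <- divergence_dating(round((1 - 0.983) * 1287), 1287, 1e-8,
                              "per-lineage")
cat(sprintf("C vs D split: %.2f million generations (total-branch)\n",
            cd_date$generations / 1e6))
cat(sprintf("most divergent LTR pair: %.0f generations (per-lineage)\n",
            ltr_date$generations))

## compartment enrichment with the printed insertion counts; the expected
## probabilities are a required input (genomic compartment sizes)
probs <- c(intergenic = 611, genic_sense = 159, genic_antisense = 159,
           other = 1222 - 929) / 1222
obs_counts <- c(intergenic = 904, genic_sense = 109, genic_antisense = 209,
                other = 0)
comp <- compartment_enrichment_test(obs_counts, probs, n_reps = 1e6, seed = 62)
write_tsv_file(comp, file.path(out_dir, "compartment_enrichment.tsv"))
cat(sprintf("intergenic excess: p %s\n",
            ifelse(comp$below_floor[1], sprintf("< %g", 1 / 1e6),
                   sprintf("= %g", comp$p[1]))))

## coincidence of GWAS hits with ERV elements: eight urns
p_urns <- rep(0.1, 8)
coin <- coincidence_test(p_urns, k_threshold = 4, n_reps = 1e6, seed = 63)
cat(sprintf("P(>= 4 of 8 coincidences): exact %.3g, Monte Carlo %.3g\n",
            coin$p_exact, coin$p_mc))
write_truth_json(list(cd_generations = cd_date$generations,
                      ltr_generations = ltr_date$generations,
                      coincidence = coin[c("p_exact", "p_mc")]),
                 file.path(out_dir, "sequence_stats.json"))
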