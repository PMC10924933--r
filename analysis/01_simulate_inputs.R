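#!/usr/bin/env Rscript
# Generate the synthetic study inputs with recorded ground truth:
# a capture cohort (two LTR-side panels), clipped-read records around known
# insertions, per-bull tag catalogs with de novo tag observations, and an
# element alignment with a context-biased substitution spectrum and
# recombination.  Everything downstream (02-06) consumes these files.

suppressPackageStartupMessages(library(ervkit))
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(20260922)

## capture cohort: 60 constitutive loci x 40 bulls, one table per LTR side.
## The panels are technical replicates of the same bulls: the true
## mobilization rates are shared, while capture efficiencies and DNA input
## differ between panels.
cohort_truth <- list()
sim5 <- generate_capture_table(60, 40, noise_sd = 2, seed = 101)
sim3 <- generate_capture_table(60, 40, noise_sd = 2, seed = 102,
                               true_rates = sim5$truth$true_rates)
for (side in c("5p", "3p")) {
  sim <- if (side == "5p") sim5 else sim3
  write_capture_table(sim$table, file.path(out_dir, paste0("capture_", side, ".tsv")))
  write_tsv_file(
    data.frame(sample_id = names(sim$n_denovo), n_denovo = sim$n_denovo),
    file.path(out_dir, paste0("denovo_counts_", side, ".tsv")))
  cohort_truth[[side]] <- sim$truth
}
write_truth_json(cohort_truth, file.path(out_dir, "capture_truth.json"))
cat("capture tables: 60 loci x 40 bulls per LTR side\n")

## clipped reads: two samples, constitutive + de novo insertions
insertions <- rbind(
  data.frame(chrom = "chr19", is_position = 50466809L, orientation = "sense",
             sample_id = rep(c("bullA", "bullB"), each = 1),
             n_molecules = c(40L, 35L), status = "constitutive"),
  data.frame(chrom = "chr4", is_position = 9100000L, orientation = "antisense",
             sample_id = c("bullA", "bullB"), n_molecules = c(22L, 18L),
             status = "constitutive"),
  data.frame(chrom = "chr2", is_position = 129626969L, orientation = "sense",
             sample_id = "bullA", n_molecules = 1L, status = "de_novo"),
  data.frame(chrom = "chr11", is_position = 3300000L, orientation = "sense",
             sample_id = "bullB", n_molecules = 2L, status = "de_novo")
)
reads <- generate_clipped_reads(insertions, depth = 8, frac_low_mq = 0.05,
                                frac_short_clip = 0.05, seed = 103)
write_tsv_file(reads$records, file.path(out_dir, "clipped_reads_5p.tsv"))
write_tsv_file(
  data.frame(chrom = c("chr19", "chr4"), position = c(50466809L, 9100000L)),
  file.path(out_dir, "constitutive_loci.tsv"))
cat(sprintf("clipped reads: %d records over %d true insertions\n",
            nrow(reads$records), nrow(insertions)))

## tag catalogs and de novo observations for three bulls (bull-1-like sizes)
bulls <- list(b1 = list(n_el = 26, n_hap = 13, n_c = 12, n_ev = 178),
              b2 = list(n_el = 34, n_hap = 17, n_c = 11, n_ev = 73),
              b3 = list(n_el = 33, n_hap = 17, n_c = 13, n_ev = 147))
for (b in names(bulls)) {
  cfg <- bulls[[b]]
  cat_b <- generate_tag_catalog(cfg$n_el, cfg$n_hap, cfg$n_c / cfg$n_el,
                                seed = 200 + match(b, names(bulls)))
  # de novo insertions dominated by a couple of D-type haplotypes
  haps <- cat_b$haplotypes$haplotype_id
  frac_c <- vapply(haps, function(h) {
    mean(cat_b$elements$class[cat_b$elements$haplotype_id == h] == "C")
  }, numeric(1))
  w <- ifelse(frac_c == 0, 4, 1)   # D haplotypes outcompete C ones
  p <- w / sum(w)
  names(p) <- haps
  obs <- generate_denovo_observations(cat_b, p, cfg$n_ev,
                                      seed = 300 + match(b, names(bulls)))
  write_tsv_file(cbind(animal = b, cat_b$haplotypes),
                 file.path(out_dir, paste0("catalog_haplotypes_", b, ".tsv")))
  write_tsv_file(cbind(animal = b, cat_b$elements),
                 file.path(out_dir, paste0("catalog_elements_", b, ".tsv")))
  write_tsv_file(obs, file.path(out_dir, paste0("denovo_tags_", b, ".tsv")))
  write_truth_json(list(contributions = as.list(p)),
                   file.path(out_dir, paste0("em_truth_", b, ".json")))
}
cat("tag catalogs and observations for 3 bulls written\n")

## element alignment: CpG-transition excess + G-to-A editing + recombination
sp <- uniform_spectrum()
sp["C>T", c("A.G", "C.G", "G.G", "T.G")] <- 6   # methyl-CpG deamination
sp["G>A", c("C.A", "C.C", "C.G", "C.T")] <- 6   # CpG seen from the other strand
sp["G>A", ] <- sp["G>A", ] * 2                  # strand-specific editing excess
aln <- generate_element_alignment(80, 2500, spectrum_params = sp,
                                  recomb_rate = 0.25, seed = 400,
                                  n_substitutions = 797)
write_alignment(aln, file.path(out_dir, "elements.fasta"),
                file.path(out_dir, "element_variants.tsv"))
write_tsv_file(data.frame(element_id = names(aln$classes),
                          class = unname(aln$classes)),
               file.path(out_dir, "element_classes.tsv"))
write_tsv_file(cbind(aln$variants,
                     t(aln$matrix)[aln$variants$variant_id, , drop = FALSE]),
               file.path(out_dir, "element_genotypes.tsv"))
write_truth_json(list(recombinations = aln$truth$recombinations,
                      seed = 400),
                 file.path(out_dir, "alignment_truth.json"))
cat(sprintf("alignment: 80 elements, %d substitutions, %d recombinants\n",
            nrow(aln$variants), nrow(aln$truth$recombinations)))
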