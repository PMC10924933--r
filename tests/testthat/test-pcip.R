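test_that("read filters are inclusive at the documented thresholds", {
  boundary <- read_record(mapping_quality = 40L, clipped_length = 10L,
                          tag_alignment_score = 0.60)
  expect_equal(nrow(filter_reads(boundary)), 1L)
  expect_equal(nrow(filter_reads(read_record(mapping_quality = 39L))), 0L)
  expect_equal(nrow(filter_reads(read_record(clipped_length = 9L))), 0L)
  expect_equal(nrow(filter_reads(read_record(tag_alignment_score = 0.59))), 0L)
})

test_that("a mixed table is filtered record by record", {
  set.seed(21)
  good <- do.call(rbind, replicate(70, read_record(), simplify = FALSE))
  fail_one <- function(i) {
    switch(i,
           read_record(mapping_quality = sample(0:39, 1)),
           read_record(clipped_length = sample(1:9, 1)),
           read_record(tag_alignment_score = runif(1, 0, 0.59)))
  }
  bad <- do.call(rbind, lapply(sample(1:3, 30, replace = TRUE), fail_one))
  mixed <- rbind(good, bad)[sample(100), ]
  expect_equal(nrow(filter_reads(mixed)), 70L)
})

test_that("breakpoint merging collapses identical positions and respects the window", {
  two_same <- rbind(read_record(role = "IS", clip_position = 500L),
                    read_record(role = "IS", clip_position = 500L))
  cl <- merge_breakpoints(two_same)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 2L)

  adjacent <- rbind(read_record(clip_position = 100L),
                    read_record(clip_position = 101L))
  expect_equal(nrow(merge_breakpoints(adjacent, window_bp = 0)), 2L)

  five <- do.call(rbind, lapply(c(100L, 100L, 101L, 180L, 180L),
                                function(p) read_record(clip_position = p)))
  cl2 <- merge_breakpoints(five, window_bp = 2)
  expect_equal(nrow(cl2), 2L)
  expect_equal(sort(cl2$support), c(2L, 3L))
  expect_equal(sort(cl2$position), c(100L, 180L))  # modal positions
})

test_that("IS-SS pairing respects orientation and the 5 kb limit", {
  is_cl <- merge_breakpoints(read_record(role = "IS", clip_position = 10000L,
                                         genome_strand = "+"))
  # sense element, 5' panel: SS upstream pairs, downstream does not
  ss_up <- merge_breakpoints(read_record(role = "SS", clip_position = 8000L))
  expect_equal(nrow(pair_is_ss(is_cl, ss_up, side = "5p")), 1L)
  ss_down <- merge_breakpoints(read_record(role = "SS", clip_position = 12000L))
  expect_equal(nrow(pair_is_ss(is_cl, ss_down, side = "5p")), 0L)
  expect_equal(nrow(pair_is_ss(is_cl, ss_down, side = "3p")), 1L)
  # beyond 5 kb: dropped
  ss_far <- merge_breakpoints(read_record(role = "SS", clip_position = 4000L))
  expect_equal(nrow(pair_is_ss(is_cl, ss_far, side = "5p")), 0L)
  # two SS on the valid side -> one call with two molecules
  ss_two <- merge_breakpoints(rbind(
    read_record(role = "SS", clip_position = 9000L),
    read_record(role = "SS", clip_position = 7000L)))
  call <- pair_is_ss(is_cl, ss_two, side = "5p")
  expect_equal(nrow(call), 1L)
  expect_equal(call$n_molecules, 2L)
  # unpaired IS is reported, not silently lost
  unp <- pair_is_ss(is_cl, ss_far, side = "5p")
  expect_equal(nrow(attr(unp, "unpaired")), 1L)
})

test_that("n_molecules is invariant to PCR duplication of read records", {
  reads <- rbind(
    read_record(role = "IS", clip_position = 10000L),
    read_record(role = "SS", clip_position = 9000L),
    read_record(role = "SS", clip_position = 7000L)
  )
  dup <- rbind(reads, reads[2, ], reads[2, ], reads[3, ])
  call_a <- pair_is_ss(
    merge_breakpoints(reads[reads$role == "IS", ]),
    merge_breakpoints(reads[reads$role == "SS", ]), side = "5p")
  call_b <- pair_is_ss(
    merge_breakpoints(dup[dup$role == "IS", ]),
    merge_breakpoints(dup[dup$role == "SS", ]), side = "5p")
  expect_equal(call_a$n_molecules, call_b$n_molecules)
})

test_that("de novo classification needs distance from loci and a single animal", {
  loci <- data.frame(chrom = "chr1", position = 50000L)
  calls <- data.frame(
    chrom = "chr1",
    is_position = c(52000L, 100000L, 100000L, 200000L),
    orientation = "sense",
    sample_id = c("s1", "s1", "s2", "s1"),
    n_molecules = 1L, support = 1L,
    stringsAsFactors = FALSE
  )
  out <- classify_calls(calls, loci)
  expect_equal(out$status, c("constitutive", "rejected", "rejected", "de_novo"))
})

test_that("classification set arithmetic: 10 candidates, 3 near loci, 2 shared", {
  loci <- data.frame(chrom = "chr2", position = c(10000L, 30000L, 60000L))
  near <- data.frame(chrom = "chr2", is_position = c(11000L, 29000L, 61000L),
                     sample_id = c("s1", "s2", "s3"))
  shared <- data.frame(chrom = "chr2", is_position = rep(c(100000L, 150000L), 2),
                       sample_id = rep(c("s1", "s2"), each = 2))
  solo <- data.frame(chrom = "chr2",
                     is_position = seq(200000L, by = 50000L, length.out = 5),
                     sample_id = "s1")
  calls <- rbind(near, shared, solo)
  calls$orientation <- "sense"; calls$n_molecules <- 1L; calls$support <- 1L
  out <- classify_calls(calls, loci)
  expect_equal(sum(out$status == "de_novo"), 5L)
  expect_equal(sum(out$status == "constitutive"), 3L)
})

test_that("the simulated-read pipeline recovers a single de novo insertion", {
  truth <- data.frame(chrom = "chr3", is_position = 500000L,
                      orientation = "sense", sample_id = "bull1",
                      n_molecules = 1L, stringsAsFactors = FALSE)
  sim <- generate_clipped_reads(truth, depth = 20, seed = 31)
  loci <- data.frame(chrom = "chr3", position = 900000L)
  calls <- call_insertions(sim$records, loci, side = "5p")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$status, "de_novo")
  expect_equal(calls$n_molecules, 1L)
  expect_equal(calls$is_position, 500000L)
})

test_that("clean simulated reads all survive filtering; duplicates collapse", {
  truth <- data.frame(chrom = "chr1", is_position = 100000L,
                      orientation = "antisense", sample_id = "s1",
                      n_molecules = 3L, stringsAsFactors = FALSE)
  sim <- generate_clipped_reads(truth, depth = 10, frac_low_mq = 0,
                                frac_short_clip = 0, seed = 32)
  expect_equal(nrow(filter_reads(sim$records)), nrow(sim$records))
  calls <- call_insertions(sim$records, data.frame(chrom = "x", position = 1L))
  expect_equal(calls$n_molecules, 3L)  # 30 SS reads, 3 distinct molecules
})

test_that("failing fractions remove reads at the expected scale", {
  truth <- data.frame(chrom = "chr1", is_position = 100000L,
                      orientation = "sense", sample_id = "s1",
                      n_molecules = 50L, stringsAsFactors = FALSE)
  sim <- generate_clipped_reads(truth, depth = 4, frac_low_mq = 0.5,
                                seed = 33)
  frac_kept <- nrow(filter_reads(sim$records)) / nrow(sim$records)
  expect_gt(frac_kept, 0.4)
  expect_lt(frac_kept, 0.6)
})

test_that("genotyping maps ratio clusters onto allele dosages", {
  g <- genotype_constitutive(c(0, 0, 0.5, 0.5, 1.0))
  expect_equal(as.character(g$genotype),
               c("+/+", "+/+", "+/ERV", "+/ERV", "ERV/ERV"))
  # fixed locus: everyone near the homozygote level
  fixed <- genotype_constitutive(c(0.99, 1.01, 1.0, 0.98, 1.02))
  expect_true(all(fixed$genotype == "ERV/ERV"))
  # degenerate input warns
  expect_warning(genotype_constitutive(rep(0.5, 4)), "distinct")
})

test_that("genotype recovery on a simulated het/hom mixture exceeds 95%", {
  set.seed(34)
  n <- 120
  dosage <- sample(1:2, n, replace = TRUE, prob = c(2, 1))
  ratios <- dosage / 2 + rnorm(n, 0, 0.04)
  g <- genotype_constitutive(ratios)
  expect_gt(mean(g$dosage == dosage), 0.95)
})
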