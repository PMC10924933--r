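test_that("spectrum enrichment is 1-centred under the null generator", {
  aln <- generate_element_alignment(60, 3000, seed = 101,
                                    n_substitutions = 1500)
  enr <- spectrum_enrichment(aln$variants, aln$consensus)
  obs <- attr(enr, "observed")
  expfr <- attr(enr, "expected_frac")
  # exact bookkeeping identity: enrichment x expected fraction sums to 1
  expect_equal(sum((enr * expfr)[obs > 0]), 1, tolerance = 1e-9)
  # null generator: cell enrichments scatter around 1
  expect_equal(mean(enr[obs > 0]), 1, tolerance = 0.25)
  expect_equal(stats::weighted.mean(enr[expfr > 0], expfr[expfr > 0]), 1,
               tolerance = 0.1)
})

test_that("an elevated CpG transition rate tops the enrichment table", {
  sp <- uniform_spectrum()
  sp["C>T", c("A.G", "C.G", "G.G", "T.G")] <- 8
  sp["G>A", c("C.A", "C.C", "C.G", "C.T")] <- 8
  aln <- generate_element_alignment(60, 3000, spectrum_params = sp,
                                    seed = 102, n_substitutions = 1500)
  enr <- spectrum_enrichment(aln$variants, aln$consensus)
  obs <- attr(enr, "observed")
  top <- which(enr == max(enr[obs > 5], na.rm = TRUE), arr.ind = TRUE)
  top_type <- rownames(enr)[top[1, "row"]]
  top_ctx <- colnames(enr)[top[1, "col"]]
  is_cpg_cell <- (top_type == "C>T" && grepl("\\.G$", top_ctx)) ||
    (top_type == "G>A" && grepl("^C\\.", top_ctx))
  expect_true(is_cpg_cell)
})

test_that("a single substitution has enrichment 1 over its context fraction", {
  cons <- "ACGTACGTAC"
  sub <- data.frame(position = 3, ref = "G", alt = "A")
  enr <- spectrum_enrichment(sub, cons)
  expfr <- attr(enr, "expected_frac")
  expect_equal(enr["G>A", "C.T"], 1 / expfr["G>A", "C.T"])
  expect_error(
    spectrum_enrichment(data.frame(position = 3, ref = "T", alt = "A"), cons),
    "disagrees")
})

test_that("four-gamete counts, D' and r2 follow the standard definitions", {
  # complete association: only three haplotypes, D' = 1, no flag
  x <- c(rep(1, 4), rep(0, 6)); y <- c(rep(1, 4), rep(1, 3), rep(0, 3))
  m <- cbind(a = x, b = y)
  res <- four_gamete_scan(m)
  expect_false(res$four_gamete)
  expect_equal(res$Dprime, 1)
  # the fully worked numeric case
  m2 <- cbind(a = rep(c(1, 1, 0, 0), c(3, 2, 2, 3)),
              b = rep(c(1, 0, 1, 0), c(3, 2, 2, 3)))
  res2 <- four_gamete_scan(m2)
  expect_true(res2$four_gamete)
  expect_equal(res2$D, 0.05)
  expect_equal(res2$Dprime, 0.2)
  expect_equal(res2$r2, 0.04)
})

test_that("LD measures are invariant to allele relabeling and stay in [0, 1]", {
  set.seed(103)
  m <- matrix(rbinom(200, 1, 0.4), 20, 10)
  res <- four_gamete_scan(m)
  res_flip <- four_gamete_scan(1 - m)
  expect_equal(res$Dprime, res_flip$Dprime)
  expect_equal(res$r2, res_flip$r2)
  expect_equal(res$four_gamete, res_flip$four_gamete)
  expect_true(all(res$Dprime >= 0 & res$Dprime <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(res$r2 >= 0 & res$r2 <= 1 + 1e-12))
})

test_that("recombination in the generator creates four-gamete violations", {
  clonal <- generate_element_alignment(40, 600, seed = 104,
                                       n_substitutions = 120, recomb_rate = 0)
  res0 <- four_gamete_scan(clonal$matrix)
  expect_false(any(res0$four_gamete))  # perfect phylogeny: never 4 haplotypes

  rec <- generate_element_alignment(40, 600, seed = 105,
                                    n_substitutions = 120, recomb_rate = 0.4)
  expect_gt(nrow(rec$truth$recombinations), 0)
  res1 <- four_gamete_scan(rec$matrix)
  expect_gt(sum(res1$four_gamete), 0)
  # flagged pairs span a recombination breakpoint
  pos <- stats::setNames(rec$variants$position, rec$variants$variant_id)
  flagged <- res1[res1$four_gamete, ]
  spans <- mapply(function(a, b) {
    any(rec$truth$recombinations$breakpoint > min(pos[a], pos[b]) &
          rec$truth$recombinations$breakpoint <= max(pos[a], pos[b]))
  }, flagged$var_a, flagged$var_b)
  expect_true(all(spans))
})

test_that("class-boundary LD profiles flag perfect and absent co-segregation", {
  cls <- rep(c("C", "D"), each = 10)
  perfect <- as.integer(cls == "C")
  set.seed(106)
  independent <- rbinom(20, 1, 0.5)
  m <- cbind(linked = perfect, free = independent)
  prof <- cd_boundary_ld(cls, m)
  expect_equal(prof$r2[prof$position == "linked"], 1)
  expect_lt(prof$r2[prof$position == "free"], 0.4)
  expect_error(cd_boundary_ld(rep("C", 20), m), "both C and D")
})

test_that("attrition near the class boundary shows as an r2 gradient", {
  set.seed(107)
  n <- 60
  cls <- rep(c("C", "D"), each = n / 2)
  core <- as.integer(cls == "C")                     # co-segregates fully
  drift <- ifelse(runif(n) < 0.3, 1 - core, core)    # recombined repeatedly
  prof <- cd_boundary_ld(cls, cbind(near = core, far = drift))
  expect_gt(prof$r2[prof$position == "near"] - prof$r2[prof$position == "far"],
            0.2)
})

test_that("divergence dating applies both molecular-clock conventions", {
  cd <- divergence_dating(38.4, 250, 1e-8, "total-branch")
  expect_equal(cd$generations, 15.36e6)
  ltr <- divergence_dating(0.017 * 1287, 1287, 1e-8, "per-lineage")
  expect_equal(ltr$generations, 8.5e5)
  expect_equal(divergence_dating(0, 100, 1e-8)$generations, 0)
})

test_that("the multinomial enrichment test calibrates and flags extremes", {
  probs <- c(intergenic = 0.5, sense = 0.13, antisense = 0.13, other = 0.24)
  expected <- round(1222 * probs)
  null_res <- compartment_enrichment_test(expected, probs, n_reps = 2e5,
                                          seed = 108)
  expect_true(all(null_res$p > 0.2))
  obs <- c(intergenic = 900, sense = 100, antisense = 222, other = 0)
  res <- compartment_enrichment_test(obs, probs, n_reps = 2e5, seed = 109)
  expect_true(res$below_floor[res$category == "intergenic"])
  expect_equal(res$p[res$category == "intergenic"], 1 / 2e5)
  # normal-approximation oracle agrees that the excess is astronomically far
  z <- (900 - 611) / sqrt(1222 * 0.5 * 0.5)
  expect_gt(z, 10)
  res2 <- compartment_enrichment_test(obs, probs, n_reps = 2e5, seed = 109)
  expect_identical(res, res2)
})

test_that("coincidence test: exact Poisson-binomial and Monte Carlo agree", {
  out <- coincidence_test(rep(0.1, 8), k_threshold = 4, n_reps = 2e5,
                          seed = 110)
  exact <- 1 - pbinom(3, 8, 0.1)  # independent binomial-tail oracle
  expect_equal(out$p_exact, exact, tolerance = 1e-12)
  expect_equal(out$p_exact, 5.02e-3, tolerance = 0.01)
  se <- sqrt(exact * (1 - exact) / 2e5)
  expect_lt(abs(out$p_mc - exact), 4 * se)
  # degenerate cases
  expect_equal(coincidence_test(rep(0, 5), 1, n_reps = 1e3, seed = 1)$p_exact, 0)
  expect_equal(coincidence_test(runif(5), 0, n_reps = 1e3, seed = 1)$p_exact, 1)
})

test_that("unequal urn probabilities keep the exact and simulated tails together", {
  p <- c(0.02, 0.3, 0.11, 0.07, 0.5, 0.009, 0.2, 0.15)
  out <- coincidence_test(p, k_threshold = 3, n_reps = 2e5, seed = 111)
  expect_equal(sum(out$exact_distribution), 1, tolerance = 1e-12)
  se <- sqrt(out$p_exact * (1 - out$p_exact) / 2e5)
  expect_lt(abs(out$p_mc - out$p_exact), 4 * se)
})

test_that("the allele-frequency shift test behaves at the extremes", {
  same <- afs_shift_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_gt(same$p, 0.9)
  apart <- afs_shift_test(1:6 / 100, 51:56 / 100)
  # minimal attainable p for two samples of 6 without ties
  expect_equal(apart$p, 2 / choose(12, 6))
  expect_error(afs_shift_test(numeric(0), 1:3), "non-empty")
})

test_that("shift-test power increases with the displacement", {
  set.seed(112)
  power_at <- function(delta) {
    mean(replicate(60, {
      afs_shift_test(runif(25), runif(25) + delta)$p < 0.05
    }))
  }
  p_small <- power_at(0.05)
  p_big <- power_at(0.4)
  expect_gt(p_big, p_small)
  expect_gt(p_big, 0.9)
})

test_that("strand-asymmetric editing is detected; symmetric data is not", {
  sp <- uniform_spectrum()
  sp["G>A", ] <- 8  # strand-specific G-to-A editing excess
  aln <- generate_element_alignment(60, 3000, spectrum_params = sp,
                                    seed = 113, n_substitutions = 800)
  res <- mirror_asymmetry_test(aln$variants, aln$consensus, B = 2000,
                               seed = 114)
  ga <- res[res$type_a == "G>A" & res$stratum == "nonCpG", ]
  expect_lte(ga$p, 0.001)
  expect_gt(ga$diff, 0)

  null_aln <- generate_element_alignment(60, 3000, seed = 115,
                                         n_substitutions = 800)
  res0 <- mirror_asymmetry_test(null_aln$variants, null_aln$consensus,
                                B = 1000, seed = 116)
  expect_gt(res0$p[res0$type_a == "G>A" & res0$stratum == "nonCpG"], 0.01)
  res0b <- mirror_asymmetry_test(null_aln$variants, null_aln$consensus,
                                 B = 1000, seed = 116)
  expect_identical(res0, res0b)
})
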