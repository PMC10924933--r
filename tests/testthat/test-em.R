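test_that("compatibility matches observed tag slots only", {
  cat <- toy_catalog()
  # full 4-slot observation of A77: unique match
  expect_equal(build_compatibility(obs_row("z", 4, 3, 4, 4), cat), "A77")
  # 5'-side only (tags 1,1): shared by A41 and A44
  expect_setequal(build_compatibility(obs_row("z", 1, 1), cat),
                  c("A41", "A44"))
  # contradicting every haplotype: empty, not forced
  expect_length(build_compatibility(obs_row("z", 9, 9), cat), 0)
  # tag3 shared by A63 and A33
  expect_setequal(build_compatibility(obs_row("z", tag3 = 3), cat),
                  c("A63", "A33"))
  # an all-NA observation is invalid
  expect_error(build_compatibility(obs_row("z"), cat), "observed tag")
})

test_that("animal restriction limits the candidate haplotypes", {
  cat <- toy_catalog()
  expect_equal(build_compatibility(obs_row("z", 1, 1), cat,
                                   haplotypes = c("A41", "A77")), "A41")
})

test_that("EM starts uniform and splits an ambiguous event evenly", {
  cat <- toy_catalog()
  # a single event compatible with A41 and A44 stays at 0.5 / 0.5
  fit <- em_contributions(obs_row("z", 1, 1), cat)
  expect_equal(unname(fit$p[c("A41", "A44")]), c(0.5, 0.5))
  expect_equal(sum(fit$p), 1, tolerance = 1e-9)
  # 13 haplotypes -> uniform start of 1/13 = 0.077
  expect_equal(round(1 / 13, 3), 0.077)
})

test_that("EM matches the grid-search maximum-likelihood oracle", {
  # 2 events compatible with {A, B}, 1 with {A}: ML puts everything on A
  compat <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 3, 2,
                   dimnames = list(paste0("ev", 1:3), c("A", "B")))
  fit <- ervkit:::em_from_compat(compat)
  oracle <- grid_ml_two_hap(compat * 1)
  expect_equal(unname(fit$p["A"]), oracle, tolerance = 1e-3)
  expect_equal(unname(fit$p["A"]), 1, tolerance = 1e-3)

  # a mixed problem: 6 events {A}, 4 {B}, 10 {A, B}
  compat2 <- rbind(
    matrix(c(TRUE, FALSE), 6, 2, byrow = TRUE),
    matrix(c(FALSE, TRUE), 4, 2, byrow = TRUE),
    matrix(TRUE, 10, 2)
  )
  colnames(compat2) <- c("A", "B")
  fit2 <- ervkit:::em_from_compat(compat2)
  oracle2 <- grid_ml_two_hap(compat2 * 1)
  expect_equal(unname(fit2$p["A"]), oracle2, tolerance = 1e-3)
})

test_that("the observed-data log-likelihood never decreases", {
  cat <- toy_catalog()
  set.seed(41)
  p_true <- c(A41 = 0.3, A44 = 0.1, A63 = 0.2, A33 = 0.25, A77 = 0.15)
  obs <- generate_denovo_observations(cat, p_true, 300, seed = 41)
  fit <- em_contributions(obs, cat)
  expect_true(all(diff(fit$loglik) >= -1e-10))
  expect_gt(fit$n_iterations, 1)
})

test_that("unmatched events are excluded and counted, not assigned", {
  cat <- toy_catalog()
  obs <- rbind(obs_row("a", 1, 1), obs_row("b", 9, 9))
  fit <- em_contributions(obs, cat)
  expect_equal(fit$n_unmatched, 1L)
  expect_equal(fit$n_events, 1L)
  expect_error(em_contributions(obs_row("c", 9, 9), cat), "compatible")
})

test_that("relabeling haplotypes permutes the estimates identically", {
  cat <- toy_catalog()
  obs <- generate_denovo_observations(
    cat, c(A41 = 0.4, A44 = 0.2, A63 = 0.1, A33 = 0.1, A77 = 0.2),
    200, seed = 42)
  fit <- em_contributions(obs, cat)
  perm <- c("A77", "A41", "A33", "A63", "A44")
  cat2 <- cat
  cat2$haplotypes <- cat$haplotypes[match(perm, cat$haplotypes$haplotype_id), ]
  fit2 <- em_contributions(obs, cat2)
  expect_equal(fit$p[perm], fit2$p[perm], tolerance = 1e-12)
})

test_that("EM recovers contributions from fully observed events (n = 500)", {
  set.seed(43)
  failures <- 0
  for (rep in 1:20) {
    cat <- generate_tag_catalog(26, 13, 12 / 26, seed = 4300 + rep)
    p_true <- as.vector(stats::rgamma(13, 2))
    p_true <- p_true / sum(p_true)
    names(p_true) <- cat$haplotypes$haplotype_id
    obs <- generate_denovo_observations(cat, p_true, 500,
                                        p_5only = 0, p_3only = 0, p_both = 1,
                                        seed = 4400 + rep)
    fit <- em_contributions(obs, cat)
    if (max(abs(fit$p[names(p_true)] - p_true)) >= 0.05) failures <- failures + 1
  }
  expect_lte(failures, 1)  # >= 95% of catalogs recovered
})

test_that("multinomial sampling of events matches the contribution simplex", {
  cat <- generate_tag_catalog(40, 20, 0.3, seed = 44)
  p <- rep(1 / 20, 20)
  names(p) <- cat$haplotypes$haplotype_id
  obs <- generate_denovo_observations(cat, p, 10000, seed = 45)
  freq <- table(factor(obs$true_haplotype, names(p))) / 10000
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_true(all(abs(freq - 0.05) < 3 * se + 0.002))
})

test_that("observation masking fractions follow the requested mix", {
  cat <- toy_catalog()
  p <- c(A41 = 0.5, A77 = 0.5)
  obs <- generate_denovo_observations(cat, p, 5000, seed = 46)
  expect_equal(mean(obs$mode == "both"), 0.04, tolerance = 0.35)
  both <- obs[obs$mode == "both", ]
  expect_true(all(!is.na(both$tag1) & !is.na(both$tag4)))
  five <- obs[obs$mode == "5only", ]
  expect_true(all(is.na(five$tag3) & is.na(five$tag4)))
})

test_that("bootstrap CIs are seed-stable and collapse for unambiguous data", {
  cat <- toy_catalog()
  obs <- do.call(rbind, lapply(1:30, function(i) obs_row(paste0("e", i), 4, 3, 4, 4)))
  bs <- bootstrap_contributions(obs, cat, B = 100, seed = 47)
  expect_equal(unname(bs$ci["A77", ]), c(1, 1))
  bs2 <- bootstrap_contributions(obs, cat, B = 100, seed = 47)
  expect_identical(bs, bs2)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  cat <- toy_catalog()
  set.seed(48)
  p_true <- c(A41 = 0.5, A63 = 0.5)
  width_at <- function(n) {
    obs <- generate_denovo_observations(cat, p_true, n, p_5only = 0,
                                        p_3only = 0, p_both = 1,
                                        seed = 480 + n)
    ci <- bootstrap_contributions(obs, cat, B = 200, seed = 49)$ci
    unname(ci["A41", "upper"] - ci["A41", "lower"])
  }
  w100 <- width_at(100)
  w400 <- width_at(400)
  # binomial CI comparison: quadrupling n should halve the width (loosely)
  expect_lt(w400, w100 * 0.75)
})

test_that("C/D apportioning splits mixed haplotypes by member ratio", {
  cat <- toy_catalog()
  # A41 mixed 1C + 1D; others pure
  p <- c(A41 = 0.4, A44 = 0.1, A63 = 0.1, A33 = 0.2, A77 = 0.2)
  shares <- cd_apportion(p, cat)
  expect_equal(sum(shares), 1)
  expect_equal(unname(shares["C"]), 0.4 * 0.5 + 0.2)
  # all-D restriction
  d_only <- c(A44 = 0.5, A63 = 0.5)
  expect_equal(unname(cd_apportion(d_only, cat)["D"]), 1)
})

test_that("the C/D shift test detects a strong excess and is seed-stable", {
  cat <- toy_catalog()
  # inherited: 3 C / 5 D; de novo drawn almost entirely from D haplotypes
  obs <- generate_denovo_observations(
    cat, c(A33 = 0.9, A77 = 0.1), 300,
    p_5only = 0, p_3only = 0, p_both = 1, seed = 50)
  out <- test_cd_shift(obs, cat, B = 1000, seed = 51)
  expect_lte(out$p, 0.01)
  expect_gt(out$d_share_denovo, out$d_frac_inherited)
  out2 <- test_cd_shift(obs, cat, B = 1000, seed = 51)
  expect_equal(out, out2)
  expect_error(test_cd_shift(obs[0, ], cat, B = 1000), "no de novo")
})

test_that("generator truth for the D share is recovered within the bootstrap CI", {
  cat <- generate_tag_catalog(30, 15, 0.3, seed = 52)
  haps <- cat$haplotypes$haplotype_id
  # build contributions worth 70% D by drawing from pure-D haplotypes
  frac_c <- vapply(haps, function(h) {
    mean(cat$elements$class[cat$elements$haplotype_id == h] == "C")
  }, numeric(1))
  p <- ifelse(frac_c == 0, 0.7, ifelse(frac_c == 1, 0.3, 0))
  p <- p / sum(p)
  d_true <- sum(p * (1 - frac_c))
  names(p) <- haps
  obs <- generate_denovo_observations(cat, p, 400, p_5only = 0, p_3only = 0,
                                      p_both = 1, seed = 53)
  out <- test_cd_shift(obs, cat, B = 1000, seed = 54)
  expect_lt(abs(out$d_share_denovo - d_true), 0.1)
})
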