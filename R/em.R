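#' Haplotypes compatible with a partial tag observation
#'
#' A haplotype is compatible with a de novo insertion's tag record when its
#' tag 4-tuple matches every observed slot (unobserved slots are
#' unconstrained).  An observation matching no inherited haplotype is
#' flagged rather than forced: such events are reported separately and
#' excluded from the attribution.
#'
#' @param observation One row of a tag-observation data frame (columns
#'   `tag1`..`tag4`, `NA` for unobserved).
#' @param catalog An `erv_catalog`.
#' @param haplotypes Optional character vector restricting to the animal's
#'   inherited haplotypes (default: all catalog haplotypes).
#' @return Character vector of compatible haplotype ids (possibly empty).
#' @export
build_compatibility <- function(observation, catalog, haplotypes = NULL) {
  m <- compatibility_matrix(observation, catalog, haplotypes)
  colnames(m)[m[1, ]]
}

# events x haplotypes logical matrix
compatibility_matrix <- function(observations, catalog, haplotypes = NULL) {
  hp <- catalog$haplotypes
  if (!is.null(haplotypes)) {
    hp <- hp[hp$haplotype_id %in% haplotypes, , drop = FALSE]
    if (nrow(hp) == 0L) stop_param("animal has no inherited haplotypes")
  }
  slots <- c("tag1", "tag2", "tag3", "tag4")
  n_obs_slots <- rowSums(!is.na(as.matrix(observations[slots])))
  if (any(n_obs_slots == 0L)) {
    stop_param("every observation must have at least one observed tag slot")
  }
  ok <- matrix(TRUE, nrow(observations), nrow(hp),
               dimnames = list(observations$event_id, hp$haplotype_id))
  for (s in slots) {
    obs <- observations[[s]]
    cmp <- outer(obs, hp[[s]], `==`)
    cmp[is.na(obs), ] <- TRUE  # unobserved slot constrains nothing
    ok <- ok & cmp
  }
  ok
}

#' EM estimate of haplotype contributions to de novo insertions
#'
#' Estimates the proportional contribution `p[h]` of each inherited
#' haplotype to the observed de novo insertions as a mixture model fitted by
#' expectation-maximization.  Starting from uniform contributions, the
#' E-step assigns event `z` to compatible haplotype `h` with coefficient
#' `c[z, h] = p[h] / sum(p[h'] over h' compatible with z)` (0 when
#' incompatible); the M-step sets `p[h]` to the mean coefficient across
#' events.  Iterations continue until the largest absolute change in any
#' `p[h]` falls below `tol` or `max_iter` is reached.  The observed-data
#' log-likelihood `sum(log(sum(p[h] over compat)))` is tracked and is
#' non-decreasing; contributions that reach 0 stay at 0 (EM boundary).
#'
#' Events compatible with no haplotype are excluded and counted in
#' `n_unmatched` (they may arise by recombination and are reported, not
#' modeled).
#'
#' @param observations Tag-observation data frame (`tag1`..`tag4`).
#' @param catalog An `erv_catalog`.
#' @param haplotypes Optional restriction to the animal's haplotypes.
#' @param max_iter,tol Convergence controls (defaults 1000 and 1e-6).
#' @return An `erv_em` list: `p` (named simplex), `n_iterations`, `loglik`
#'   (per-iteration trace), `n_events`, `n_unmatched`, `compat` (the
#'   event-by-haplotype compatibility matrix used).
#' @export
em_contributions <- function(observations, catalog, haplotypes = NULL,
                             max_iter = 1000, tol = 1e-6) {
  compat <- compatibility_matrix(observations, catalog, haplotypes)
  em_from_compat(compat, max_iter = max_iter, tol = tol)
}

em_from_compat <- function(compat, max_iter = 1000, tol = 1e-6) {
  matched <- rowSums(compat) > 0
  n_unmatched <- sum(!matched)
  compat_use <- compat[matched, , drop = FALSE]
  n <- nrow(compat_use)
  if (n == 0L) stop_param("no event is compatible with any haplotype")
  h <- ncol(compat_use)
  p <- rep(1 / h, h)
  loglik <- numeric(0)
  cmp <- compat_use * 1  # numeric for fast matrix products
  for (it in seq_len(max_iter)) {
    denom <- as.vector(cmp %*% p)
    loglik <- c(loglik, sum(log(denom)))
    coefs <- cmp * rep(p, each = n) / denom
    p_new <- colSums(coefs) / n
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  structure(
    list(p = stats::setNames(p, colnames(compat_use)),
         n_iterations = length(loglik),
         loglik = loglik,
         n_events = n,
         n_unmatched = n_unmatched,
         compat = compat),
    class = "erv_em"
  )
}

#' Bootstrap confidence intervals for haplotype contributions
#'
#' Resamples events with replacement, reruns the EM on each replicate and
#' reports percentile 95% intervals per haplotype.
#'
#' @inheritParams em_contributions
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return List with `ci` (matrix haplotypes x `c(lower, upper)`),
#'   `boot` (B x haplotypes replicate estimates) and the point `estimate`.
#' @export
bootstrap_contributions <- function(observations, catalog, haplotypes = NULL,
                                    B = 1000, seed = NULL,
                                    max_iter = 1000, tol = 1e-6) {
  check_scalar_number(B, "B", lower = 100)
  compat <- compatibility_matrix(observations, catalog, haplotypes)
  compat <- compat[rowSums(compat) > 0, , drop = FALSE]
  est <- em_from_compat(compat, max_iter, tol)
  seed_rng(seed)
  n <- nrow(compat)
  boot <- matrix(NA_real_, B, ncol(compat),
                 dimnames = list(NULL, colnames(compat)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- em_from_compat(compat[idx, , drop = FALSE], max_iter, tol)$p
  }
  ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, boot = boot, estimate = est$p)
}

#' Apportion estimated contributions to C and D element classes
#'
#' Haplotypes composed purely of Competent (or Defective) elements
#' contribute wholly to that class; mixed haplotypes are split according to
#' the inherited C:D member count ratio within the haplotype.
#'
#' @param estimate An `erv_em` fit or a named contribution simplex.
#' @param catalog An `erv_catalog`.
#' @param elements Optional restriction to the animal's inherited elements
#'   (character vector of element ids).
#' @return Named numeric `c(C = , D = )` summing to 1.
#' @export
cd_apportion <- function(estimate, catalog, elements = NULL) {
  p <- if (inherits(estimate, "erv_em")) estimate$p else estimate
  check_simplex(p, "estimate")
  el <- catalog$elements
  if (!is.null(elements)) el <- el[el$element_id %in% elements, , drop = FALSE]
  shares <- c(C = 0, D = 0)
  for (h in names(p)) {
    members <- el[el$haplotype_id == h, , drop = FALSE]
    if (nrow(members) == 0L) {
      stop_param("haplotype %s has no inherited member element", h)
    }
    frac_c <- mean(members$class == "C")
    shares["C"] <- shares["C"] + p[h] * frac_c
    shares["D"] <- shares["D"] + p[h] * (1 - frac_c)
  }
  shares
}

#' Bootstrap test for a C/D composition shift in de novo insertions
#'
#' Compares the Defective-class share of de novo insertions (EM estimate
#' apportioned with [cd_apportion()]) to the D fraction among inherited
#' elements.  Events are resampled with replacement `B` times; the
#' two-sided p-value is `2 * min` of the bootstrap tail fractions on either
#' side of the inherited fraction, floored at `2 / B` and capped at 1.
#'
#' @inheritParams bootstrap_contributions
#' @param inherited_cd Named counts `c(C = , D = )` of inherited elements;
#'   defaults to the catalog's (restricted) element counts.
#' @param elements Optional restriction to the animal's elements.
#' @return List with `d_share_denovo`, `d_frac_inherited`, `p`, `boot`
#'   (bootstrap D shares).
#' @export
test_cd_shift <- function(observations, catalog, elements = NULL,
                          inherited_cd = NULL, B = 1000, seed = NULL) {
  check_scalar_number(B, "B", lower = 1000)
  if (nrow(observations) == 0L) stop_param("no de novo events supplied")
  el <- catalog$elements
  if (!is.null(elements)) el <- el[el$element_id %in% elements, , drop = FALSE]
  if (is.null(inherited_cd)) {
    inherited_cd <- c(C = sum(el$class == "C"), D = sum(el$class == "D"))
  }
  d_inh <- inherited_cd[["D"]] / sum(inherited_cd)

  haps <- unique(el$haplotype_id)
  compat <- compatibility_matrix(observations, catalog, haps)
  compat <- compat[rowSums(compat) > 0, , drop = FALSE]
  fit <- em_from_compat(compat)
  d_hat <- cd_apportion(fit$p, catalog, elements = el$element_id)[["D"]]

  seed_rng(seed)
  n <- nrow(compat)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- em_from_compat(compat[idx, , drop = FALSE])$p
    boot[b] <- cd_apportion(pb, catalog, elements = el$element_id)[["D"]]
  }
  p <- 2 * min(mean(boot <= d_inh), mean(boot >= d_inh))
  p <- min(max(p, 2 / B), 1)
  list(d_share_denovo = d_hat, d_frac_inherited = d_inh, p = p, boot = boot)
}
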