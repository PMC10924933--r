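BASES <- c("A", "C", "G", "T")
SUB_TYPES <- as.vector(t(outer(BASES, BASES, paste, sep = ">")))[
  as.vector(t(outer(BASES, BASES, `!=`)))]
CONTEXTS <- as.vector(outer(BASES, BASES, paste, sep = "."))

split_consensus <- function(consensus) {
  if (length(consensus) == 1L && is.character(consensus)) {
    strsplit(toupper(consensus), "")[[1]]
  } else {
    toupper(as.character(consensus))
  }
}

context_at <- function(cons, pos) {
  paste(cons[pos - 1], cons[pos + 1], sep = ".")
}

#' Trinucleotide substitution-spectrum enrichment
#'
#' Tabulates substitutions by type (ref>alt, 12 types) and trinucleotide
#' context (5' and 3' neighbours on the consensus, 16 contexts) and
#' expresses each cell as a fold enrichment: the cell's share of all
#' substitutions divided by its expected share under a context-blind null —
#' the context's abundance fraction in the consensus times 1/3 (each base
#' has three possible substitutions).  A value of 1 means the substitution
#' occurs at the rate expected from context abundance alone.
#'
#' Substitutions at the first or last consensus position have no
#' trinucleotide context and are dropped with a warning.
#'
#' @param substitutions Data frame with columns `position` (1-based on the
#'   consensus), `ref`, `alt`.
#' @param consensus Consensus sequence (single string or character vector
#'   of bases), length >= 3.
#' @return 12 x 16 matrix of fold enrichments (`NA` where the context does
#'   not occur in the consensus), with attributes `observed` (counts) and
#'   `expected_frac` (per-cell expected substitution shares, summing to 1),
#'   so `sum(enrichment * expected_frac)` over populated cells equals 1.
#' @export
spectrum_enrichment <- function(substitutions, consensus) {
  cons <- split_consensus(consensus)
  L <- length(cons)
  if (L < 3L) stop_param("consensus must be at least 3 bases")
  sub <- substitutions
  if (any(sub$position < 1 | sub$position > L)) {
    stop_param("substitution positions outside the consensus")
  }
  edge <- sub$position == 1L | sub$position == L
  if (any(edge)) {
    warning(sum(edge), " substitution(s) at consensus ends dropped (no context)")
    sub <- sub[!edge, , drop = FALSE]
  }
  if (any(toupper(sub$ref) != cons[sub$position])) {
    stop_param("`ref` disagrees with the consensus at some positions")
  }

  # context abundance in the consensus, per central base
  inner <- 2:(L - 1)
  tri_key <- paste(cons[inner], cons[inner - 1], cons[inner + 1])
  abund <- matrix(0, 4, 16, dimnames = list(BASES, CONTEXTS))
  tab <- table(tri_key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  abund[cbind(parts[, 1], paste(parts[, 2], parts[, 3], sep = "."))] <- as.vector(tab)
  total_tri <- L - 2

  type <- paste(toupper(sub$ref), toupper(sub$alt), sep = ">")
  ctx <- context_at(cons, sub$position)
  observed <- matrix(0, length(SUB_TYPES), length(CONTEXTS),
                     dimnames = list(SUB_TYPES, CONTEXTS))
  if (nrow(sub)) {
    tab2 <- table(factor(type, SUB_TYPES), factor(ctx, CONTEXTS))
    observed[] <- as.vector(tab2)
  }
  total_obs <- sum(observed)

  central <- substr(SUB_TYPES, 1, 1)
  # expected per-cell share: context abundance x uniform choice of the alt
  exp_frac <- abund[central, , drop = FALSE] / total_tri / 3
  dimnames(exp_frac) <- dimnames(observed)
  if (any(observed > 0 & exp_frac == 0)) {
    stop_param("observed substitutions in a context absent from the consensus")
  }
  enrich <- (observed / total_obs) / exp_frac
  enrich[exp_frac == 0] <- NA_real_
  attr(enrich, "observed") <- observed
  attr(enrich, "expected_frac") <- exp_frac
  enrich
}

# is each substitution at a CpG-overlapping site (C followed by G, or G
# preceded by C, on the consensus)?
is_cpg_site <- function(cons, pos) {
  L <- length(cons)
  nxt <- ifelse(pos < L, cons[pmin(pos + 1, L)], NA_character_)
  prv <- ifelse(pos > 1, cons[pmax(pos - 1, 1)], NA_character_)
  (cons[pos] == "C" & !is.na(nxt) & nxt == "G") |
    (cons[pos] == "G" & !is.na(prv) & prv == "C")
}

MIRROR_PAIRS <- list(
  c("G>A", "C>T"), c("G>T", "C>A"), c("G>C", "C>G"),
  c("A>G", "T>C"), c("A>T", "T>A"), c("A>C", "T>G")
)

#' Strand-asymmetry bootstrap test of mirror substitution pairs
#'
#' A strand-agnostic mutational process produces complementary ("mirror")
#' substitutions — e.g. G>A and C>T — at equal per-site rates; an excess of
#' one member (such as G>A from APOBEC-type editing of one strand) is a
#' strand-specific signature.  For each of the six mirror pairs, in CpG and
#' non-CpG strata separately where the central base can be part of a CpG,
#' the per-eligible-site rates of the two types are compared.
#' Substitution records are resampled with replacement `B` times; the
#' two-sided p-value is twice the smaller bootstrap tail fraction around
#' zero difference (floored at `2/B`), with a percentile 95% CI on the
#' difference.
#'
#' @param substitutions Data frame `position`, `ref`, `alt`.
#' @param consensus Consensus sequence.
#' @param B Bootstrap replicates (>= 1000).
#' @param seed Integer seed.
#' @return Data frame with `type_a`, `type_b`, `stratum`, `n_a`, `n_b`,
#'   `diff` (rate_a - rate_b), `ci_lower`, `ci_upper`, `p` (`NA`,
#'   flagged, when both counts are zero).
#' @export
mirror_asymmetry_test <- function(substitutions, consensus, B = 1000,
                                  seed = NULL) {
  check_scalar_number(B, "B", lower = 1000)
  cons <- split_consensus(consensus)
  L <- length(cons)
  sub <- substitutions[substitutions$position > 1 & substitutions$position < L, ,
                       drop = FALSE]
  type <- paste(toupper(sub$ref), toupper(sub$alt), sep = ">")
  cpg <- is_cpg_site(cons, sub$position)
  site_cpg <- is_cpg_site(cons, seq_along(cons))
  n_sites <- function(base, stratum) {
    at <- cons == base
    if (stratum == "CpG") sum(at & site_cpg)
    else if (stratum == "nonCpG") sum(at & !site_cpg)
    else sum(at)
  }
  seed_rng(seed)
  n <- nrow(sub)
  boot_idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)

  rows <- list()
  for (pair in MIRROR_PAIRS) {
    ref_a <- substr(pair[1], 1, 1)
    strata <- if (ref_a %in% c("C", "G")) c("CpG", "nonCpG") else "all"
    for (st in strata) {
      in_stratum <- if (st == "CpG") cpg else if (st == "nonCpG") !cpg else TRUE
      sel_a <- type == pair[1] & in_stratum
      sel_b <- type == pair[2] & in_stratum
      denom_a <- n_sites(ref_a, st)
      denom_b <- n_sites(substr(pair[2], 1, 1), st)
      n_a <- sum(sel_a); n_b <- sum(sel_b)
      if ((n_a + n_b) == 0L || denom_a == 0L || denom_b == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          type_a = pair[1], type_b = pair[2], stratum = st,
          n_a = n_a, n_b = n_b, diff = NA_real_,
          ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      d_obs <- n_a / denom_a - n_b / denom_b
      d_boot <- vapply(seq_len(B), function(b) {
        idx <- boot_idx[, b]
        sum(sel_a[idx]) / denom_a - sum(sel_b[idx]) / denom_b
      }, numeric(1))
      p <- 2 * min(mean(d_boot <= 0), mean(d_boot >= 0))
      p <- min(max(p, 2 / B), 1)
      ci <- stats::quantile(d_boot, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        type_a = pair[1], type_b = pair[2], stratum = st,
        n_a = n_a, n_b = n_b, diff = d_obs,
        ci_lower = ci[1], ci_upper = ci[2], p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# D, D', r2 and the four-haplotype flag for two binary vectors (no NA)
ld_pair <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  pA <- mean(x); pB <- mean(y)
  D <- n11 / n - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (d_max > 0) abs(D) / d_max else NA_real_
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
       D = D, Dprime = dprime, r2 = r2,
       four_gamete = n00 > 0 && n01 > 0 && n10 > 0 && n11 > 0)
}

#' Four-gamete and linkage-disequilibrium scan over variant pairs
#'
#' A new variant arises on one element haplotype, so only three of the four
#' possible two-locus haplotypes can exist without recombination (or
#' recurrent mutation); observing all four ("four-gamete rule") flags a
#' past recombination between the two positions.  For every pair of
#' biallelic variants the four haplotype counts, `D`, `D' = |D| / D_max`
#' and `r^2` are computed on pairwise-complete elements.
#'
#' @param haplotype_matrix Elements x variants matrix of 0/1 alleles (`NA`
#'   allowed; pairs use complete rows only).
#' @param include_singletons Keep variants whose minor allele occurs once
#'   (default `TRUE`; singletons cannot create a fourth haplotype but do
#'   enter D'/r^2 summaries).
#' @return Data frame with one row per retained pair: `var_a`, `var_b`,
#'   haplotype counts `n00`..`n11`, `D`, `Dprime`, `r2`, `four_gamete`.
#'   Monomorphic-in-subset pairs are skipped.
#' @export
four_gamete_scan <- function(haplotype_matrix, include_singletons = TRUE) {
  m <- as.matrix(haplotype_matrix)
  vn <- colnames(m) %||% paste0("v", seq_len(ncol(m)))
  if (!include_singletons) {
    mac <- apply(m, 2, function(x) {
      x <- x[!is.na(x)]
      min(sum(x == 1), sum(x == 0))
    })
    m <- m[, mac > 1, drop = FALSE]
    vn <- vn[mac > 1]
  }
  k <- ncol(m)
  rows <- list()
  for (i in seq_len(max(0, k - 1))) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(m[, i], m[, j])
      x <- m[ok, i]; y <- m[ok, j]
      if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
      ld <- ld_pair(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = vn[i], var_b = vn[j],
        n00 = ld$n00, n01 = ld$n01, n10 = ld$n10, n11 = ld$n11,
        D = ld$D, Dprime = ld$Dprime, r2 = ld$r2,
        four_gamete = ld$four_gamete, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(var_a = character(), var_b = character(),
                      n00 = integer(), n01 = integer(), n10 = integer(),
                      n11 = integer(), D = numeric(), Dprime = numeric(),
                      r2 = numeric(), four_gamete = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' LD between element class and flanking variants
#'
#' Treats the Competent/Defective status of each element as a binary
#' variant and profiles `D'` and `r^2` between the class and every variant
#' in the flanking segments; `r^2 ~ 1` close to the class boundary with
#' decay away from it indicates suppressed recombination ("attrition")
#' near the boundary.
#'
#' @param cd_labels Character vector `"C"`/`"D"` per element.
#' @param flanking_variants Elements x positions 0/1 matrix (`NA` allowed).
#' @return Data frame `position` (column name), `Dprime`, `r2`,
#'   `four_gamete`.
#' @export
cd_boundary_ld <- function(cd_labels, flanking_variants) {
  m <- as.matrix(flanking_variants)
  if (length(unique(cd_labels[!is.na(cd_labels)])) < 2L) {
    stop_param("both C and D elements are required")
  }
  cls <- as.integer(cd_labels == "C")
  pos <- colnames(m) %||% paste0("p", seq_len(ncol(m)))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    ok <- !is.na(m[, j]) & !is.na(cls)
    x <- cls[ok]; y <- m[ok, j]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
      return(data.frame(position = pos[j], Dprime = NA_real_, r2 = NA_real_,
                        four_gamete = NA, stringsAsFactors = FALSE))
    }
    ld <- ld_pair(x, y)
    data.frame(position = pos[j], Dprime = ld$Dprime, r2 = ld$r2,
               four_gamete = ld$four_gamete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Molecular-clock dating from sequence divergence
#'
#' Converts a pairwise difference count into generations under a constant
#' per-site mutation rate.  Two conventions: `"total-branch"` divides the
#' per-site divergence by `mu` (both lineages accumulate mutations but the
#' count is interpreted as the total along the path, as when dating the
#' split of two element subclades); `"per-lineage"` divides by `2 * mu`
#' (each of the two copies mutates independently since a shared origin, as
#' for the 5' and 3' LTRs of one provirus, identical at insertion).
#'
#' @param n_differences Observed differences between the two sequences.
#' @param length Alignment length in bp (> 0).
#' @param mu Mutation rate per bp per generation (> 0).
#' @param convention `"total-branch"` or `"per-lineage"`.
#' @return List with `n_differences`, `length`, `mu`, `convention`,
#'   `d` (per-site divergence) and `generations`.
#' @export
divergence_dating <- function(n_differences, length, mu,
                              convention = c("total-branch", "per-lineage")) {
  convention <- match.arg(convention)
  check_scalar_number(length, "length", lower = 1e-12)
  check_scalar_number(mu, "mu", lower = 1e-300)
  check_scalar_number(n_differences, "n_differences", lower = 0)
  d <- n_differences / length
  gens <- if (convention == "total-branch") d / mu else d / (2 * mu)
  list(n_differences = n_differences, length = length, mu = mu,
       convention = convention, d = d, generations = gens)
}

#' Monte-Carlo multinomial enrichment test of category counts
#'
#' Draws `n_reps` multinomial samples of the observed total under the
#' expected category probabilities and reports, per category, a two-sided
#' empirical p-value `2 * min(P(sim >= obs), P(sim <= obs))`, capped at 1
#' and floored at `1 / n_reps` (categories at the floor are flagged:
#' "< 1/n_reps").
#'
#' @param observed_counts Named integer vector of observed counts.
#' @param expected_probs Probability simplex over the same categories (may
#'   include extra categories with no observed counterpart — pass observed
#'   0 for them).
#' @param n_reps Monte-Carlo replicates (>= 1e5, default 1e6).
#' @param seed Integer seed.
#' @return Data frame `category`, `observed`, `expected`, `p`,
#'   `below_floor`.
#' @export
compartment_enrichment_test <- function(observed_counts, expected_probs,
                                        n_reps = 1e6, seed = NULL) {
  check_scalar_number(n_reps, "n_reps", lower = 1e5)
  check_simplex(expected_probs, "expected_probs")
  if (length(observed_counts) != length(expected_probs)) {
    stop_param("`observed_counts` and `expected_probs` lengths differ")
  }
  seed_rng(seed)
  total <- sum(observed_counts)
  sims <- stats::rmultinom(n_reps, total, expected_probs)
  p <- numeric(length(observed_counts))
  below <- logical(length(observed_counts))
  for (i in seq_along(observed_counts)) {
    hi <- mean(sims[i, ] >= observed_counts[i])
    lo <- mean(sims[i, ] <= observed_counts[i])
    pp <- 2 * min(hi, lo)
    below[i] <- pp == 0
    p[i] <- min(max(pp, 1 / n_reps), 1)
  }
  data.frame(
    category = names(observed_counts) %||% paste0("cat", seq_along(p)),
    observed = as.vector(observed_counts),
    expected = total * expected_probs,
    p = p, below_floor = below,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Coincidence probability over independent success urns
#'
#' One object is sampled from each of several "urns" with its own success
#' probability; the number of successes follows a Poisson-binomial
#' distribution.  Reports both a Monte-Carlo estimate of
#' `P(successes >= k)` and the exact Poisson-binomial value computed by
#' dynamic programming (iterated convolution), together with the full
#' distributions.
#'
#' @param success_probs Per-urn success probabilities in `[0, 1]`.
#' @param k_threshold Success count threshold (0..number of urns).
#' @param n_reps Monte-Carlo replicates (default 1e6).
#' @param seed Integer seed.
#' @return List with `p_mc`, `p_exact` (upper tails at `k_threshold`),
#'   `mc_distribution`, `exact_distribution` (P(successes = 0..n)),
#'   `n_reps`.
#' @export
coincidence_test <- function(success_probs, k_threshold, n_reps = 1e6,
                             seed = NULL) {
  if (any(success_probs < 0 | success_probs > 1)) {
    stop_param("`success_probs` must lie in [0, 1]")
  }
  n_urn <- length(success_probs)
  check_scalar_number(k_threshold, "k_threshold", lower = 0, upper = n_urn)
  check_scalar_number(n_reps, "n_reps", lower = 1)

  # exact Poisson-binomial by convolution
  pmf <- 1
  for (p in success_probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  names(pmf) <- 0:n_urn
  p_exact <- sum(pmf[as.integer(names(pmf)) >= k_threshold])

  seed_rng(seed)
  counts <- integer(n_urn + 1)
  done <- 0
  while (done < n_reps) {
    chunk <- min(n_reps - done, 2e5)
    hits <- matrix(stats::runif(chunk * n_urn) < rep(success_probs, each = chunk),
                   chunk, n_urn)
    k <- rowSums(hits)
    counts <- counts + tabulate(k + 1L, n_urn + 1L)
    done <- done + chunk
  }
  mc_dist <- counts / n_reps
  names(mc_dist) <- 0:n_urn
  list(p_mc = sum(mc_dist[as.integer(names(mc_dist)) >= k_threshold]),
       p_exact = unname(p_exact),
       mc_distribution = mc_dist,
       exact_distribution = pmf,
       n_reps = n_reps)
}

#' Rank-based test of an allele-frequency spectrum shift
#'
#' Two-sided rank-sum (Wilcoxon) test of a location shift between two
#' allele-frequency distributions — the exact permutation distribution of
#' the rank-sum statistic for small tie-free samples, a normal
#' approximation otherwise.
#'
#' @param freqs_a,freqs_b Non-empty numeric vectors of allele frequencies.
#' @return List with `p`, `statistic`, `method`.
#' @export
afs_shift_test <- function(freqs_a, freqs_b) {
  if (length(freqs_a) == 0L || length(freqs_b) == 0L) {
    stop_param("both frequency vectors must be non-empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(freqs_a, freqs_b, alternative = "two.sided")
  )
  list(p = wt$p.value, statistic = unname(wt$statistic), method = wt$method)
}
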