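# Hand-built fixtures shared across test files.

# Minimal tag catalog with a known compatibility structure:
#   A41 and A44 share the 5'-side tags (1, 1) and differ on the 3' side;
#   A63 and A33 share tag3 but differ elsewhere; A77 is unique everywhere.
toy_catalog <- function() {
  haplotypes <- data.frame(
    haplotype_id = c("A41", "A44", "A63", "A33", "A77"),
    tag1 = c(1, 1, 2, 3, 4),
    tag2 = c(1, 1, 2, 2, 3),
    tag3 = c(1, 2, 3, 3, 4),
    tag4 = c(1, 1, 2, 3, 4),
    stringsAsFactors = FALSE
  )
  elements <- data.frame(
    element_id = paste0("e", 1:8),
    haplotype_id = c("A41", "A41", "A44", "A63", "A33", "A33", "A77", "A77"),
    class = c("C", "D", "D", "D", "D", "D", "C", "C"),
    stringsAsFactors = FALSE
  )
  structure(list(haplotypes = haplotypes, elements = elements),
            class = "erv_catalog")
}

# one tag observation row
obs_row <- function(event_id, tag1 = NA, tag2 = NA, tag3 = NA, tag4 = NA) {
  data.frame(event_id = event_id, tag1 = tag1, tag2 = tag2,
             tag3 = tag3, tag4 = tag4, stringsAsFactors = FALSE)
}

# read record with overridable fields
read_record <- function(chrom = "chr1", clip_position = 100L,
                        genome_strand = "+", clip_side = "left",
                        mapping_quality = 60L, clipped_length = 30L,
                        tag_id = 1L, tag_alignment_score = 0.9,
                        role = "SS", sample_id = "s1",
                        experiment_id = "exp1") {
  data.frame(chrom = chrom, clip_position = clip_position,
             genome_strand = genome_strand, clip_side = clip_side,
             mapping_quality = mapping_quality,
             clipped_length = clipped_length, tag_id = tag_id,
             tag_alignment_score = tag_alignment_score, role = role,
             sample_id = sample_id, experiment_id = experiment_id,
             stringsAsFactors = FALSE)
}

# independent least-squares oracle for the additive capture model: explicit
# dense design matrix with the sum-to-zero locus constraint, solved through
# the normal equations (never through lm)
normal_equations_fit <- function(long) {
  loci <- sort(unique(long$locus))
  inds <- sort(unique(long$individual))
  n_l <- length(loci); n_s <- length(inds)
  # parameters: ERV_1..ERV_{n_l - 1} (last = -sum of others), ID_1..ID_{n_s}
  X <- matrix(0, nrow(long), n_l - 1 + n_s)
  for (r in seq_len(nrow(long))) {
    li <- match(long$locus[r], loci)
    if (li < n_l) X[r, li] <- 1 else X[r, seq_len(n_l - 1)] <- -1
    X[r, n_l - 1 + match(long$individual[r], inds)] <- 1
  }
  beta <- solve(crossprod(X), crossprod(X, long$ssc))
  erv <- c(beta[seq_len(n_l - 1)], -sum(beta[seq_len(n_l - 1)]))
  id <- beta[n_l:(n_l - 1 + n_s)]
  list(locus_effects = stats::setNames(as.vector(erv), loci),
       individual_effects = stats::setNames(as.vector(id), inds))
}

# grid-search maximum-likelihood oracle on the 1-simplex for two haplotypes
grid_ml_two_hap <- function(compat, step = 1e-4) {
  stopifnot(ncol(compat) == 2)
  p_grid <- seq(0, 1, by = step)
  ll <- vapply(p_grid, function(p) {
    probs <- compat %*% c(p, 1 - p)
    if (any(probs <= 0)) -Inf else sum(log(probs))
  }, numeric(1))
  p_grid[which.max(ll)]
}
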