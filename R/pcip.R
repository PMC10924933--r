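#' Filter clipped-read records
#'
#' Applies the read-level quality filters of the capture pipeline: a record
#' survives when its mapping quality, number of clipped bases and proviral
#' tag alignment score all reach their thresholds (inclusive).
#'
#' @param records Data frame of clipped-read records with columns
#'   `mapping_quality`, `clipped_length`, `tag_alignment_score` (plus any
#'   others, carried through).
#' @param min_mq Minimum mapping quality (default 40).
#' @param min_clip Minimum clipped bases (default 10).
#' @param min_tag_score Minimum tag alignment score to declare a hit
#'   (default 0.6).
#' @return The surviving rows of `records` (possibly zero rows).
#' @export
filter_reads <- function(records, min_mq = 40, min_clip = 10,
                         min_tag_score = 0.6) {
  keep <- records$mapping_quality >= min_mq &
    records$clipped_length >= min_clip &
    records$tag_alignment_score >= min_tag_score
  records[keep & !is.na(keep), , drop = FALSE]
}

#' Merge reads sharing a breakpoint into candidate sites
#'
#' Reads of the same role (insertion-site or shearing-site), side, sample
#' and chromosome whose clip positions coincide within `window_bp` collapse
#' (single linkage) into one candidate site supported by multiple concordant
#' reads.  The default window of 0 bp requires the exact same breakpoint.
#'
#' @param records Filtered clipped-read records with columns `chrom`,
#'   `clip_position`, `genome_strand`, `clip_side`, `role`, `sample_id`.
#' @param window_bp Maximum gap (bp) between positions merged into one
#'   cluster (default 0).
#' @return Data frame of clusters: `chrom`, `sample_id`, `role`,
#'   `clip_side`, `position` (modal read position), `strand` (majority),
#'   `support` (read count).
#' @export
merge_breakpoints <- function(records, window_bp = 0) {
  check_scalar_number(window_bp, "window_bp", lower = 0)
  if (nrow(records) == 0L) {
    return(data.frame(chrom = character(), sample_id = character(),
                      role = character(), clip_side = character(),
                      position = integer(), strand = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  key <- interaction(records$chrom, records$sample_id, records$role,
                     records$clip_side, drop = TRUE)
  out <- lapply(split(records, key), function(grp) {
    ord <- order(grp$clip_position)
    pos <- grp$clip_position[ord]
    brk <- c(TRUE, diff(pos) > window_bp)
    cl <- cumsum(brk)
    do.call(rbind, lapply(split(seq_along(pos), cl), function(ix) {
      p <- pos[ix]
      tab <- table(p)
      modal <- as.integer(names(tab)[which.max(tab)])
      strands <- grp$genome_strand[ord][ix]
      data.frame(
        chrom = grp$chrom[1], sample_id = grp$sample_id[1],
        role = grp$role[1], clip_side = grp$clip_side[1],
        position = modal,
        strand = names(which.max(table(strands))),
        support = length(ix),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$position), , drop = FALSE]
}

#' Pair insertion-site clusters with their shearing sites
#'
#' Each insertion-site (IS) cluster is paired with every shearing-site (SS)
#' cluster of the same sample and chromosome lying on the
#' orientation-consistent side within `max_distance`.  For a 5' capture
#' panel, the SS of a sense-oriented element lies upstream of the IS and
#' downstream for an antisense element; the rule flips for the 3' panel.
#' Distinct paired SS are molecular identifiers: PCR duplicates share a
#' shearing site, so `n_molecules` counts distinct SS clusters.  An IS with
#' no compatible SS is reported in the `unpaired` attribute and excluded.
#'
#' @param is_clusters,ss_clusters Cluster data frames from
#'   [merge_breakpoints()] with roles `"IS"` and `"SS"`.
#' @param side Capture panel, `"5p"` or `"3p"`.
#' @param max_distance Maximum IS-SS distance in bp (default 5000).
#' @return Data frame of insertion calls: `chrom`, `is_position`,
#'   `orientation` (`sense`/`antisense`), `sample_id`, `n_molecules`,
#'   `support`, plus a list column `ss_positions`.  Attribute `unpaired`
#'   holds the IS clusters left without SS.
#' @export
pair_is_ss <- function(is_clusters, ss_clusters, side = c("5p", "3p"),
                       max_distance = 5000) {
  side <- match.arg(side)
  check_scalar_number(max_distance, "max_distance", lower = 0)
  calls <- vector("list", nrow(is_clusters))
  unpaired <- logical(nrow(is_clusters))
  for (k in seq_len(nrow(is_clusters))) {
    is_row <- is_clusters[k, ]
    orientation <- if (is_row$strand == "+") "sense" else "antisense"
    ss_upstream <- xor(orientation == "antisense", side == "5p")
    cand <- ss_clusters[ss_clusters$chrom == is_row$chrom &
                          ss_clusters$sample_id == is_row$sample_id, ,
                        drop = FALSE]
    delta <- cand$position - is_row$position
    ok <- abs(delta) <= max_distance &
      if (ss_upstream) delta < 0 else delta > 0
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) {
      unpaired[k] <- TRUE
      next
    }
    calls[[k]] <- data.frame(
      chrom = is_row$chrom, is_position = is_row$position,
      orientation = orientation, sample_id = is_row$sample_id,
      n_molecules = length(unique(cand$position)),
      support = is_row$support,
      stringsAsFactors = FALSE
    )
    calls[[k]]$ss_positions <- list(sort(unique(cand$position)))
  }
  out <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), is_position = integer(),
                      orientation = character(), sample_id = character(),
                      n_molecules = integer(), support = integer(),
                      stringsAsFactors = FALSE)
    out$ss_positions <- list()
  }
  rownames(out) <- NULL
  attr(out, "unpaired") <- is_clusters[unpaired, , drop = FALSE]
  out
}

#' Classify insertion calls as constitutive or de novo
#'
#' A candidate call is labeled de novo only when it lies more than
#' `min_distance` bp from every constitutive locus AND is observed in
#' exactly one animal; calls at constitutive loci are labeled
#' `"constitutive"`, the rest `"rejected"`.
#'
#' @param calls Insertion-call data frame (from [pair_is_ss()], possibly
#'   concatenated over samples).
#' @param constitutive_loci Data frame with columns `chrom`, `position`.
#' @param min_distance De novo calls must exceed this distance from every
#'   constitutive locus (default 3000 bp).
#' @return `calls` with an added `status` column.
#' @export
classify_calls <- function(calls, constitutive_loci, min_distance = 3000) {
  if (nrow(calls) == 0L) {
    calls$status <- character(0)
    return(calls)
  }
  near <- vapply(seq_len(nrow(calls)), function(k) {
    loci <- constitutive_loci[constitutive_loci$chrom == calls$chrom[k], ,
                              drop = FALSE]
    nrow(loci) > 0L && any(abs(loci$position - calls$is_position[k]) <= min_distance)
  }, logical(1))
  site <- paste(calls$chrom, calls$is_position)
  n_animals <- vapply(split(calls$sample_id, site),
                      function(s) length(unique(s)), integer(1))[site]
  calls$status <- ifelse(near, "constitutive",
                         ifelse(n_animals == 1L, "de_novo", "rejected"))
  calls
}

#' Run the read-to-call pipeline
#'
#' Convenience wrapper chaining [filter_reads()], [merge_breakpoints()],
#' [pair_is_ss()] and [classify_calls()].
#'
#' @inheritParams filter_reads
#' @inheritParams merge_breakpoints
#' @inheritParams pair_is_ss
#' @inheritParams classify_calls
#' @return Classified insertion-call data frame (all samples pooled).
#' @export
call_insertions <- function(records, constitutive_loci, side = c("5p", "3p"),
                            window_bp = 0, max_distance = 5000,
                            min_distance = 3000) {
  side <- match.arg(side)
  kept <- filter_reads(records)
  clusters <- merge_breakpoints(kept, window_bp = window_bp)
  calls <- pair_is_ss(clusters[clusters$role == "IS", , drop = FALSE],
                      clusters[clusters$role == "SS", , drop = FALSE],
                      side = side, max_distance = max_distance)
  classify_calls(calls, constitutive_loci, min_distance = min_distance)
}

#' Build a capture table from classified calls
#'
#' Assigns constitutive calls to their nearest panel locus and tabulates
#' distinct shearing-site counts (`n_molecules`) per locus and individual —
#' the input to [fit_normalization()].
#'
#' @param calls Classified calls (status `"constitutive"` rows are used).
#' @param constitutive_loci Data frame `chrom`, `position`; row order
#'   defines the table rows.
#' @param max_distance Maximum call-to-locus distance (default 3000 bp).
#' @return Integer matrix loci x individuals of SSC counts (0 where a locus
#'   was not captured in an individual).
#' @export
build_capture_table <- function(calls, constitutive_loci, max_distance = 3000) {
  samples <- sort(unique(calls$sample_id))
  loci_id <- paste0(constitutive_loci$chrom, ":", constitutive_loci$position)
  tab <- matrix(0L, nrow(constitutive_loci), length(samples),
                dimnames = list(loci_id, samples))
  const <- calls[calls$status == "constitutive", , drop = FALSE]
  for (k in seq_len(nrow(const))) {
    same <- which(constitutive_loci$chrom == const$chrom[k])
    if (!length(same)) next
    d <- abs(constitutive_loci$position[same] - const$is_position[k])
    if (min(d) > max_distance) next
    i <- same[which.min(d)]
    j <- match(const$sample_id[k], samples)
    tab[i, j] <- tab[i, j] + const$n_molecules[k]
  }
  tab
}

#' Genotype a constitutive locus from capture ratios
#'
#' The ratio between observed shearing sites and explored haploid genomes
#' at a locus scales with the allele dosage: about 0 for `+/+`, half the
#' homozygote level for `+/ERV`, and the full level for `ERV/ERV`.  Ratios
#' are clustered in one dimension (k-means with k in 1..3 picked by average
#' silhouette width, ties to fewer clusters) and each cluster is mapped to
#' the dosage whose expected ratio (0, `hom_ratio / 2`, `hom_ratio`) is
#' nearest its mean.
#'
#' @param ratios Numeric vector of per-individual SS / explored-genome
#'   ratios at one locus.
#' @param hom_ratio Expected ratio of an `ERV/ERV` homozygote; defaults to
#'   the largest cluster mean (assumes the top cluster is homozygous, which
#'   holds whenever the locus is captured at full dosage in some animal).
#' @return List with `genotype` (factor `+/+`, `+/ERV`, `ERV/ERV` per
#'   individual), `dosage` (0/1/2), `k` (clusters used), `cluster_means`.
#' @export
genotype_constitutive <- function(ratios, hom_ratio = NULL) {
  if (!is.numeric(ratios) || length(ratios) < 1L || anyNA(ratios)) {
    stop_param("`ratios` must be a numeric vector without NA")
  }
  n_distinct <- length(unique(ratios))
  if (n_distinct < 2L) {
    warning("fewer than 2 distinct ratio values: single-genotype call")
    cl <- rep(1L, length(ratios))
    means <- mean(ratios)
    k <- 1L
  } else {
    ks <- seq_len(min(3L, n_distinct))
    fits <- lapply(ks, function(k) {
      stats::kmeans(ratios, centers = k, nstart = 10)
    })
    sil <- vapply(seq_along(ks), function(i) {
      if (ks[i] == 1L) return(0)
      sw <- cluster::silhouette(fits[[i]]$cluster, stats::dist(ratios))
      mean(sw[, "sil_width"])
    }, numeric(1))
    best <- which(sil >= max(sil) - 1e-12)[1]  # tie -> fewer clusters
    k <- ks[best]
    cl <- fits[[best]]$cluster
    means <- as.vector(fits[[best]]$centers)
  }
  ord <- order(means)
  rank_of <- match(cl, ord)          # clusters reindexed by ascending mean
  means_sorted <- means[ord]
  if (is.null(hom_ratio)) hom_ratio <- max(means_sorted)
  if (hom_ratio <= 0) stop_param("`hom_ratio` must be positive")
  targets <- c(0, hom_ratio / 2, hom_ratio)
  dos_of_cluster <- vapply(means_sorted,
                           function(m) which.min(abs(targets - m)) - 1L,
                           integer(1))
  dosage <- dos_of_cluster[rank_of]
  geno <- factor(c("+/+", "+/ERV", "ERV/ERV")[dosage + 1L],
                 levels = c("+/+", "+/ERV", "ERV/ERV"))
  list(genotype = geno, dosage = dosage, k = k, cluster_means = means_sorted)
}
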