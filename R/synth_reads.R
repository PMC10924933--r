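#' Simulate abstracted clipped-read records around true insertions
#'
#' Produces the tabular read records the calling pipeline consumes, from a
#' ground-truth set of insertions.  Each insertion is represented by
#' `n_molecules` distinct DNA molecules; every molecule gets its own
#' shearing site (SS) on the orientation-consistent side of the insertion
#' site (IS) within the pairing distance, and contributes `depth` PCR
#' duplicate reads — duplicates share the identical SS, which is what lets
#' the pipeline collapse them.  Controllable fractions of reads fail each
#' quality filter (mapping quality < 40, clipped bases < 10, tag score
#' < 0.6).
#'
#' @param insertion_truth Data frame with one row per insertion and sample:
#'   columns `chrom`, `is_position`, `orientation` (`sense`/`antisense`),
#'   `sample_id`, and optionally `n_molecules` (default 1) and
#'   `experiment_id` (default `"exp1"`).
#' @param depth Reads per molecule (>= 1); reads beyond the first are PCR
#'   duplicates.
#' @param frac_low_mq,frac_short_clip,frac_low_tag Fractions of reads
#'   failing the mapping-quality, clip-length and tag-score filters.
#' @param seed Integer seed.
#' @param side Capture panel simulated, `"5p"` or `"3p"`.
#' @param max_ss_distance SS are placed uniformly within
#'   `[50, max_ss_distance]` bp of the IS (default 4500, inside the 5 kb
#'   pairing window).
#' @return List with `records` (clipped-read data frame) and `truth`
#'   (`insertion_truth` with the simulated `ss_positions` list column and
#'   the seed).
#' @export
generate_clipped_reads <- function(insertion_truth, depth,
                                   frac_low_mq = 0, frac_short_clip = 0,
                                   frac_low_tag = 0, seed = NULL,
                                   side = c("5p", "3p"),
                                   max_ss_distance = 4500) {
  side <- match.arg(side)
  check_scalar_number(depth, "depth", lower = 1)
  for (nm in c("frac_low_mq", "frac_short_clip", "frac_low_tag")) {
    check_scalar_number(get(nm), nm, lower = 0, upper = 1)
  }
  seed_rng(seed)
  if (is.null(insertion_truth$n_molecules)) insertion_truth$n_molecules <- 1L
  if (is.null(insertion_truth$experiment_id)) insertion_truth$experiment_id <- "exp1"

  rows <- vector("list", nrow(insertion_truth))
  ss_list <- vector("list", nrow(insertion_truth))
  for (k in seq_len(nrow(insertion_truth))) {
    tr <- insertion_truth[k, ]
    sense <- tr$orientation == "sense"
    ss_upstream <- xor(!sense, side == "5p")
    offsets <- sample(50:max_ss_distance, tr$n_molecules)
    ss_pos <- tr$is_position + if (ss_upstream) -offsets else offsets
    ss_list[[k]] <- sort(ss_pos)
    strand <- if (sense) "+" else "-"
    n_reads <- tr$n_molecules * depth
    per_read <- function(role, positions) {
      data.frame(
        chrom = tr$chrom,
        clip_position = positions,
        genome_strand = strand,
        clip_side = if (role == "IS") "right" else "left",
        mapping_quality = 60L,
        clipped_length = sample(20:40, n_reads, replace = TRUE),
        tag_id = sample(if (side == "5p") 1:2 else 3:4, n_reads, replace = TRUE),
        tag_alignment_score = stats::runif(n_reads, 0.8, 1),
        role = role,
        sample_id = tr$sample_id,
        experiment_id = tr$experiment_id,
        stringsAsFactors = FALSE
      )
    }
    reads <- rbind(
      per_read("IS", rep(tr$is_position, n_reads)),
      per_read("SS", rep(ss_pos, each = depth))
    )
    fail_mq <- stats::runif(nrow(reads)) < frac_low_mq
    fail_clip <- stats::runif(nrow(reads)) < frac_short_clip
    fail_tag <- stats::runif(nrow(reads)) < frac_low_tag
    reads$mapping_quality[fail_mq] <- sample(0:39, sum(fail_mq), replace = TRUE)
    reads$clipped_length[fail_clip] <- sample(1:9, sum(fail_clip), replace = TRUE)
    reads$tag_alignment_score[fail_tag] <- stats::runif(sum(fail_tag), 0, 0.59)
    rows[[k]] <- reads
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  truth <- insertion_truth
  truth$ss_positions <- ss_list
  list(records = records, truth = truth, seed = seed)
}
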