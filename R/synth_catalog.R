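#' Simulate a tag-haplotype catalog of inherited ERV elements
#'
#' Capture sequencing reads two short proviral tags on the 5' side and two
#' on the 3' side of each element; the 4-tuple of tag variants is the
#' element's haplotype.  Different elements can share a haplotype, and a
#' shared haplotype can mix Competent (C) and Defective (D) elements.  The
#' generator assigns each element one of `n_haplotypes` distinct tag
#' combinations (every haplotype gets at least one member) and a C/D label;
#' when both classes are present and haplotypes are shared, at least one
#' mixed haplotype is guaranteed.
#'
#' @param n_elements Number of inherited elements (>= `n_haplotypes`).
#' @param n_haplotypes Number of distinct tag haplotypes.
#' @param c_fraction Fraction of elements of Competent type.
#' @param seed Integer seed.
#' @param slot_levels Number of tag variants per slot.  The default
#'   `c(7, 4, 8, 5)` yields 28 distinct 5'-side and 40 3'-side
#'   combinations, the scale observed in real catalogs.
#' @return An `erv_catalog`: list with `haplotypes` (data frame
#'   `haplotype_id`, `tag1`..`tag4`) and `elements` (data frame
#'   `element_id`, `haplotype_id`, `class`).
#' @export
generate_tag_catalog <- function(n_elements, n_haplotypes, c_fraction,
                                 seed = NULL, slot_levels = c(7, 4, 8, 5)) {
  check_scalar_number(n_elements, "n_elements", lower = 1)
  check_scalar_number(n_haplotypes, "n_haplotypes", lower = 1, upper = n_elements)
  check_scalar_number(c_fraction, "c_fraction", lower = 0, upper = 1)
  n_combos <- prod(slot_levels)
  if (n_haplotypes > n_combos) {
    stop_param("n_haplotypes (%d) exceeds the %d distinguishable tag combinations",
               n_haplotypes, n_combos)
  }
  seed_rng(seed)

  combo_idx <- sample.int(n_combos, n_haplotypes)
  tags <- arrayInd(combo_idx, slot_levels)
  haplotypes <- data.frame(
    haplotype_id = paste0("A", seq_len(n_haplotypes)),
    tag1 = tags[, 1], tag2 = tags[, 2], tag3 = tags[, 3], tag4 = tags[, 4],
    stringsAsFactors = FALSE
  )

  hap_of <- c(seq_len(n_haplotypes),
              sample.int(n_haplotypes, n_elements - n_haplotypes, replace = TRUE))
  hap_of <- sample(hap_of)  # shuffle so element order carries no signal
  n_c <- round(c_fraction * n_elements)
  class <- sample(rep(c("C", "D"), c(n_c, n_elements - n_c)))

  # guarantee a mixed haplotype when possible
  if (n_c > 0 && n_c < n_elements) {
    mixed <- tapply(class, hap_of, function(x) length(unique(x)) > 1)
    if (!any(mixed)) {
      sizes <- table(hap_of)
      big <- as.integer(names(sizes)[sizes >= 2])
      if (length(big)) {
        members <- which(hap_of == big[1])
        other_class <- setdiff(c("C", "D"), class[members[1]])
        donor <- which(class == other_class & hap_of != big[1])[1]
        if (!is.na(donor)) {  # swap labels: counts preserved, haplotype mixed
          class[donor] <- class[members[2]]
          class[members[2]] <- other_class
        }
      }
    }
  }

  elements <- data.frame(
    element_id = paste0("e", seq_len(n_elements)),
    haplotype_id = haplotypes$haplotype_id[hap_of],
    class = class,
    stringsAsFactors = FALSE
  )
  structure(list(haplotypes = haplotypes, elements = elements),
            class = "erv_catalog")
}

#' Simulate partially observed tag records for de novo insertions
#'
#' Each de novo insertion descends from one inherited haplotype (drawn from
#' `contributions`), but capture reads typically recover only the 5'-side
#' or 3'-side tags, exceptionally both.  The generator draws the true
#' haplotype, then masks the tag 4-tuple to the observed side(s); the truth
#' is retained for scoring.
#'
#' @param catalog An `erv_catalog`.
#' @param contributions Named simplex over (a subset of) the catalog's
#'   haplotype ids: the true proportional contribution of each haplotype.
#' @param n_events Number of de novo insertions to simulate.
#' @param p_5only,p_3only,p_both Probabilities of observing only the
#'   5'-side tags (slots 1-2), only the 3'-side tags (slots 3-4), or all
#'   four; must sum to 1.  The field-realistic default is ~48%/48%/4%.
#' @param seed Integer seed.
#' @return Data frame with `event_id`, `true_haplotype`, `mode`, and
#'   `tag1`..`tag4` (`NA` for unobserved slots).
#' @export
generate_denovo_observations <- function(catalog, contributions, n_events,
                                         p_5only = 0.48, p_3only = 0.48,
                                         p_both = 0.04, seed = NULL) {
  check_scalar_number(n_events, "n_events", lower = 1)
  if (abs(p_5only + p_3only + p_both - 1) > 1e-9) {
    stop_param("p_5only + p_3only + p_both must equal 1")
  }
  check_simplex(contributions, "contributions")
  haps <- names(contributions)
  if (is.null(haps) || !all(haps %in% catalog$haplotypes$haplotype_id)) {
    stop_param("`contributions` must be named with catalog haplotype ids")
  }
  seed_rng(seed)

  true_hap <- sample(haps, n_events, replace = TRUE, prob = contributions)
  mode <- sample(c("5only", "3only", "both"), n_events, replace = TRUE,
                 prob = c(p_5only, p_3only, p_both))
  tag_rows <- catalog$haplotypes[match(true_hap, catalog$haplotypes$haplotype_id), ]
  obs <- data.frame(
    event_id = paste0("ev", seq_len(n_events)),
    true_haplotype = true_hap,
    mode = mode,
    tag1 = tag_rows$tag1, tag2 = tag_rows$tag2,
    tag3 = tag_rows$tag3, tag4 = tag_rows$tag4,
    stringsAsFactors = FALSE
  )
  obs[obs$mode == "5only", c("tag3", "tag4")] <- NA
  obs[obs$mode == "3only", c("tag1", "tag2")] <- NA
  obs
}
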