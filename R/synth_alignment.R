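#' Uniform substitution-rate matrix
#'
#' A 12 x 16 matrix of relative substitution rates (type x trinucleotide
#' context) all equal to 1 — the null spectrum.  Modify cells to encode
#' context biases, e.g. `m["C>T", c("A.G","C.G","G.G","T.G")] <- 6` for a
#' 6-fold CpG transition excess (contexts are named `"5'base.3'base"`).
#'
#' @return Numeric matrix with rownames the 12 substitution types and
#'   colnames the 16 contexts.
#' @export
uniform_spectrum <- function() {
  matrix(1, length(SUB_TYPES), length(CONTEXTS),
         dimnames = list(SUB_TYPES, CONTEXTS))
}

# recursively bipartition ids; returns the list of strict sub-clades (every
# edge of a random bifurcating genealogy, tips included)
random_clades <- function(ids) {
  if (length(ids) <= 1L) return(list())
  k <- sample.int(length(ids) - 1L, 1L)
  left <- sample(ids, k)
  right <- setdiff(ids, left)
  c(list(left, right), random_clades(left), random_clades(right))
}

#' Simulate an alignment of ERV element sequences
#'
#' Generates a consensus sequence and `n_elements` aligned element
#' sequences that diverge from it by substitutions placed on a random
#' bifurcating genealogy (perfect phylogeny, infinite sites): each
#' substitution is assigned to one clade and carried by all its members, so
#' without recombination no variant pair can show all four haplotypes.
#' Substitution positions and types are drawn with probabilities
#' proportional to `spectrum_params`, making context biases (e.g. CpG
#' transitions) recoverable by [spectrum_enrichment()].  The two clades of
#' the root split are labeled C and D (the competent/defective subclades).
#' Optionally, each element is replaced with probability `recomb_rate` by a
#' recombinant: its alleles beyond a uniform breakpoint are copied from a
#' random donor element, which creates four-gamete violations across the
#' breakpoint.
#'
#' @param n_elements Number of element sequences (>= 2).
#' @param length Alignment length in bp (>= 3).
#' @param spectrum_params 12 x 16 relative-rate matrix (see
#'   [uniform_spectrum()]); default uniform.
#' @param recomb_rate Per-element probability of one recombination event
#'   (default 0).
#' @param seed Integer seed.
#' @param n_substitutions Total substitutions to place (default
#'   `3 * n_elements`, capped at the number of interior positions).
#' @param c_fraction Fraction of elements in the C-labeled root clade
#'   (default 0.3).
#' @return An `erv_alignment` list: `consensus` (string), `sequences`
#'   (named character vector), `variants` (data frame `variant_id`,
#'   `position`, `ref`, `alt`), `matrix` (elements x variants 0/1),
#'   `classes` (named C/D labels), `truth` (list with `carriers` per
#'   variant before recombination, `recombinations` data frame, `seed`).
#' @export
generate_element_alignment <- function(n_elements, length,
                                       spectrum_params = NULL,
                                       recomb_rate = 0, seed = NULL,
                                       n_substitutions = 3 * n_elements,
                                       c_fraction = 0.3) {
  check_scalar_number(n_elements, "n_elements", lower = 2)
  check_scalar_number(length, "length", lower = 3)
  check_scalar_number(recomb_rate, "recomb_rate", lower = 0, upper = 1)
  if (is.null(spectrum_params)) spectrum_params <- uniform_spectrum()
  if (any(spectrum_params < 0)) stop_param("spectrum rates must be >= 0")
  seed_rng(seed)

  cons <- sample(BASES, length, replace = TRUE)
  elements <- paste0("e", seq_len(n_elements))

  # root split defines the C/D classes; deeper structure is random
  n_c <- max(1L, min(n_elements - 1L, round(c_fraction * n_elements)))
  c_ids <- sample(elements, n_c)
  d_ids <- setdiff(elements, c_ids)
  classes <- stats::setNames(ifelse(elements %in% c_ids, "C", "D"), elements)
  clades <- c(list(c_ids, d_ids), random_clades(c_ids), random_clades(d_ids))

  # position sampling weights from the context-dependent spectrum
  interior <- 2:(length - 1)
  ctx <- paste(cons[interior - 1], cons[interior + 1], sep = ".")
  ref <- cons[interior]
  type_rows <- lapply(BASES, function(b) which(substr(SUB_TYPES, 1, 1) == b))
  names(type_rows) <- BASES
  pos_weight <- vapply(seq_along(interior), function(i) {
    sum(spectrum_params[type_rows[[ref[i]]], ctx[i]])
  }, numeric(1))

  n_sub <- min(n_substitutions, sum(pos_weight > 0))
  picked <- sample(seq_along(interior), n_sub, prob = pos_weight)
  variants <- data.frame(
    variant_id = paste0("v", seq_len(n_sub)),
    position = interior[picked],
    ref = ref[picked],
    alt = vapply(picked, function(i) {
      rows <- type_rows[[ref[i]]]
      w <- spectrum_params[rows, ctx[i]]
      substr(sample(SUB_TYPES[rows], 1, prob = w), 3, 3)
    }, character(1)),
    stringsAsFactors = FALSE
  )

  carriers <- replicate(n_sub, sample(clades, 1)[[1]], simplify = FALSE)
  geno <- matrix(0L, n_elements, n_sub,
                 dimnames = list(elements, variants$variant_id))
  for (v in seq_len(n_sub)) geno[carriers[[v]], v] <- 1L

  # inter-element recombination: suffix swap from a random donor
  recomb <- data.frame(element = character(), donor = character(),
                       breakpoint = integer(), stringsAsFactors = FALSE)
  if (recomb_rate > 0 && n_elements >= 2) {
    hit <- which(stats::runif(n_elements) < recomb_rate)
    for (e in hit) {
      donor <- sample(setdiff(seq_len(n_elements), e), 1)
      brk <- sample(2:(length - 1), 1)
      swap <- variants$position >= brk
      geno[e, swap] <- geno[donor, swap]
      recomb <- rbind(recomb, data.frame(
        element = elements[e], donor = elements[donor], breakpoint = brk,
        stringsAsFactors = FALSE))
    }
  }

  sequences <- vapply(seq_len(n_elements), function(e) {
    sq <- cons
    carried <- which(geno[e, ] == 1L)
    sq[variants$position[carried]] <- variants$alt[carried]
    paste(sq, collapse = "")
  }, character(1))
  names(sequences) <- elements

  structure(
    list(consensus = paste(cons, collapse = ""),
         sequences = sequences,
         variants = variants,
         matrix = geno,
         classes = classes,
         truth = list(carriers = carriers, recombinations = recomb,
                      seed = seed)),
    class = "erv_alignment"
  )
}
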