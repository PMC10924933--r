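#' Simulate a capture table of shearing-site counts
#'
#' Generates the locus-by-individual matrix of distinct shearing-site counts
#' (`SSC`) that a junction-capture experiment produces for a panel of
#' constitutive ERV loci.  Counts follow the additive two-factor model
#' `SSC[i, s] = ERV[i] + ID[s] + eps[i, s]`, where `ERV[i]` is a
#' locus-specific capture-efficiency effect (mean zero), `ID[s]` is the
#' individual-specific effect equal to half the number of effectively
#' captured haploid genomes, and `eps` is Gaussian noise.  Simulated counts
#' are rounded and clamped at zero (counts are non-negative); clamped cells
#' are flagged in the returned truth.  Each individual additionally receives
#' a Poisson number of de novo insertion events with mean
#' `rate * 2 * ID[s]`, the generative counterpart of the mobilization-rate
#' estimator `TR = N / (2 * ID)`.
#'
#' @param n_individuals,n_loci Table dimensions (both >= 2).
#' @param noise_sd Standard deviation of the Gaussian cell noise (>= 0).
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   table exactly.
#' @param locus_effects Optional numeric vector of length `n_loci` of true
#'   locus effects; drawn `Normal(0, locus_sd)` and centred when omitted.
#' @param individual_inputs Optional numeric vector of length
#'   `n_individuals` of true individual effects (`ID`, effective captured
#'   haploid genomes / 2); drawn uniformly on `id_range` when omitted.
#' @param true_rates Optional per-individual mobilization rates (events per
#'   gamete, in `[0, 1]`); drawn uniformly on `rate_range` when omitted.
#' @param locus_sd Spread of simulated locus effects.  Default 500: capture
#'   efficiency varies markedly between loci.
#' @param id_range Range of simulated `ID` values.  Default `c(2500, 5000)`,
#'   i.e. 5000-10000 explored haploid genomes per individual, the depth at
#'   which sperm-sample capture experiments typically operate.
#' @param rate_range Range of simulated mobilization rates per gamete.
#'   Default `c(0, 0.04)` spans zero to one event per 25 gametes.
#'
#' @return A list with components:
#'   * `table`: integer matrix `n_loci x n_individuals` of SSC counts,
#'     dimnames `locus_1..`/`ind_1..`.
#'   * `n_denovo`: integer vector of simulated de novo event counts per
#'     individual.
#'   * `truth`: list with `locus_efficiencies`, `individual_inputs`,
#'     `true_rates`, `clamped` (logical matrix of cells truncated at 0) and
#'     `seed`.
#' @export
generate_capture_table <- function(n_loci, n_individuals, noise_sd, seed = NULL,
                                   locus_effects = NULL,
                                   individual_inputs = NULL,
                                   true_rates = NULL,
                                   locus_sd = 500,
                                   id_range = c(2500, 5000),
                                   rate_range = c(0, 0.04)) {
  check_scalar_number(n_loci, "n_loci", lower = 2)
  check_scalar_number(n_individuals, "n_individuals", lower = 2)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  seed_rng(seed)

  if (is.null(locus_effects)) {
    locus_effects <- stats::rnorm(n_loci, 0, locus_sd)
    locus_effects <- locus_effects - mean(locus_effects)
  } else if (length(locus_effects) != n_loci) {
    stop_param("`locus_effects` must have length n_loci")
  }
  if (is.null(individual_inputs)) {
    individual_inputs <- stats::runif(n_individuals, id_range[1], id_range[2])
  } else if (length(individual_inputs) != n_individuals) {
    stop_param("`individual_inputs` must have length n_individuals")
  }
  if (any(individual_inputs <= 0)) {
    stop_param("`individual_inputs` must be positive")
  }
  if (is.null(true_rates)) {
    true_rates <- stats::runif(n_individuals, rate_range[1], rate_range[2])
  } else if (length(true_rates) != n_individuals) {
    stop_param("`true_rates` must have length n_individuals")
  }
  if (any(true_rates < 0 | true_rates > 1)) {
    stop_param("`true_rates` must lie in [0, 1]")
  }

  mu <- outer(locus_effects, individual_inputs, `+`)
  eps <- if (noise_sd > 0) {
    matrix(stats::rnorm(n_loci * n_individuals, 0, noise_sd), n_loci)
  } else {
    matrix(0, n_loci, n_individuals)
  }
  raw <- round(mu + eps)
  clamped <- raw < 0
  ssc <- pmax(raw, 0)
  storage.mode(ssc) <- "integer"
  dimnames(ssc) <- list(paste0("locus_", seq_len(n_loci)),
                        paste0("ind_", seq_len(n_individuals)))

  n_denovo <- stats::rpois(n_individuals, true_rates * 2 * individual_inputs)
  names(n_denovo) <- colnames(ssc)

  list(
    table = ssc,
    n_denovo = n_denovo,
    truth = list(
      locus_efficiencies = stats::setNames(locus_effects, rownames(ssc)),
      individual_inputs = stats::setNames(individual_inputs, colnames(ssc)),
      true_rates = stats::setNames(true_rates, colnames(ssc)),
      clamped = clamped,
      seed = seed
    )
  )
}
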