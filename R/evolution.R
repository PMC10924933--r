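#' Host fitness as a function of ERV copy number
#'
#' Purifying selection against ERV load: `f = 1 - (t / t_max)^p`, clamped
#' to 0 once the copy number reaches the tolerated maximum `t_max`.  The
#' exponent sets the stringency: `"linear"` (p = 1) is harshest at low copy
#' number, `"cubic"` (p = 3) most permissive; `"none"` removes selection
#' (f = 1 regardless of load).
#'
#' @param t_i Total ERV elements in the genome (vectorized, >= 0).
#' @param mode `"linear"`, `"quadratic"`, `"cubic"` or `"none"`.
#' @param t_max Maximum tolerated copy number (default 250).
#' @return Fitness values in `[0, 1]`.
#' @export
erv_fitness <- function(t_i, mode = c("linear", "quadratic", "cubic", "none"),
                        t_max = 250) {
  mode <- match.arg(mode)
  if (any(t_i < 0)) stop_param("`t_i` must be non-negative")
  if (mode == "none") return(rep(1, length(t_i)))
  p <- c(linear = 1, quadratic = 2, cubic = 3)[[mode]]
  pmax(0, 1 - (t_i / t_max)^p)
}

#' Germline mobilization rate from competent copy number
#'
#' The per-element mobilization machinery is supplied by competent
#' elements; the individual's rate saturates with their count:
#' `r = (1 - exp(-0.1 * c)) * r_max`.
#'
#' @param c_i Competent element count (vectorized, >= 0).
#' @param r_max Asymptotic mobilization rate (default 0.05).
#' @param scale Exponential saturation scale (default 0.1).
#' @return Mobilization rates in `[0, r_max)`.
#' @export
mobilization_rate <- function(c_i, r_max = 0.05, scale = 0.1) {
  if (any(c_i < 0)) stop_param("`c_i` must be non-negative")
  (1 - exp(-scale * c_i)) * r_max
}

#' Construct a simulated genome
#'
#' @param competent Logical vector, one entry per element.
#' @param affinity Non-negative numeric vector of affinities for the
#'   mobilization machinery (same length).
#' @return An `erv_genome` list with `competent` and `affinity`.
#' @export
erv_genome <- function(competent = logical(0), affinity = numeric(0)) {
  stopifnot(length(competent) == length(affinity))
  if (any(affinity < 0)) stop_param("affinities must be non-negative")
  structure(list(competent = as.logical(competent),
                 affinity = as.numeric(affinity)),
            class = "erv_genome")
}

#' Produce one offspring genome from two parents
#'
#' Each parental element is transmitted to the gamete independently with
#' probability 0.5 (Mendelian segregation, unlinked elements).  In
#' addition, every parental element — transmitted or not — spawns a de novo
#' copy of itself in the gamete with probability
#' `q_ij = r_i * a_ij / sum_j(a_ij)`, where `r_i` is the parent's
#' mobilization rate (a function of its competent count) and `a_ij` the
#' element's affinity for the shared machinery: high-affinity elements
#' monopolize the drive.  A parent whose affinities sum to 0 has no drive
#' substrate (`q = 0`).  Copies inherit competence and affinity; mutation
#' is applied separately ([mutate_genome()]).
#'
#' @param parent1,parent2 `erv_genome` objects.
#' @param r_max,scale Passed to [mobilization_rate()].
#' @return The offspring `erv_genome` (union of the two gametes).
#' @export
breed <- function(parent1, parent2, r_max = 0.05, scale = 0.1) {
  gam <- function(p) {
    n <- length(p$competent)
    if (n == 0L) return(erv_genome())
    r_i <- mobilization_rate(sum(p$competent), r_max, scale)
    sum_aff <- sum(p$affinity)
    q <- if (sum_aff > 0) r_i * p$affinity / sum_aff else rep(0, n)
    inherit <- stats::runif(n) < 0.5
    copy <- stats::runif(n) < q
    keep <- c(which(inherit), which(copy))
    erv_genome(p$competent[keep], p$affinity[keep])
  }
  g1 <- gam(parent1)
  g2 <- gam(parent2)
  erv_genome(c(g1$competent, g2$competent), c(g1$affinity, g2$affinity))
}

#' Mutate the elements of a genome
#'
#' Each element mutates independently with probability `mu`.  Mutation can
#' only destroy competence (a competent element becomes defective, a
#' defective one stays defective).  When affinity mutation is allowed, a
#' mutating element with positive affinity adds a standard-normal draw to
#' its affinity, floored at 0; an affinity already at 0 stays at 0.
#'
#' @param genome An `erv_genome`.
#' @param mu Per-element mutation probability.
#' @param allow_affinity_mutation Whether affinities can change.
#' @return The mutated `erv_genome`.
#' @export
mutate_genome <- function(genome, mu, allow_affinity_mutation = TRUE) {
  check_scalar_number(mu, "mu", lower = 0, upper = 1)
  n <- length(genome$competent)
  if (n == 0L || mu == 0) return(genome)
  hit <- stats::runif(n) < mu
  genome$competent[hit] <- FALSE
  if (allow_affinity_mutation) {
    adj <- hit & genome$affinity > 0
    genome$affinity[adj] <- pmax(0, genome$affinity[adj] + stats::rnorm(sum(adj)))
  }
  genome
}

#' Forward simulation of an ERV family in a panmictic population
#'
#' Simulates `N` haploid-genome-carrying individuals over `G`
#' non-overlapping generations.  Generation 1 seeds a proportion `s` of
#' individuals with one competent element of affinity 1.  Each subsequent
#' generation draws `N` offspring; for each, two parents are sampled with
#' replacement with probability proportional to fitness (selfing allowed —
#' sex is not modeled).  Transmission and de novo copying follow
#' [breed()], then every element of the offspring is exposed to mutation
#' as in [mutate_genome()].  The trajectory records per-generation mean
#' copy numbers of competent elements, defective elements with affinity
#' at or below `high_affinity_threshold` ("low affinity"), and defective
#' elements above it ("high affinity").
#'
#' If every individual reaches zero fitness the simulation halts with an
#' extinction report (attribute `halted`).
#'
#' @param N Population size.
#' @param G Generations to simulate.
#' @param s Seeding proportion (0 < s <= 1).
#' @param mode Selection mode, see [erv_fitness()].
#' @param mu Per-element mutation rate.
#' @param allow_affinity_mutation Whether mutation can change affinities.
#' @param t_max,r_max,scale Model constants (defaults 250, 0.05, 0.1).
#' @param high_affinity_threshold Reporting cutoff separating low- from
#'   high-affinity defective elements (default 1, the seeding affinity).
#' @param seed Integer seed.
#' @return Data frame with columns `generation`, `mean_total`,
#'   `mean_competent`, `mean_def_low`, `mean_def_high`.  Attribute
#'   `halted` is `TRUE` with message attribute `halt_reason` if the
#'   population hit all-zero fitness.
#' @export
run_simulation <- function(N, G, s, mode = c("quadratic", "linear", "cubic", "none"),
                           mu = 0.001, allow_affinity_mutation = TRUE,
                           t_max = 250, r_max = 0.05, scale = 0.1,
                           high_affinity_threshold = 1, seed = NULL) {
  mode <- match.arg(mode)
  check_scalar_number(N, "N", lower = 1)
  check_scalar_number(G, "G", lower = 1)
  check_scalar_number(s, "s", lower = 0, upper = 1)
  if (s <= 0) stop_param("`s` must be positive")
  check_scalar_number(mu, "mu", lower = 0, upper = 1)
  seed_rng(seed)
  p_exp <- c(linear = 1, quadratic = 2, cubic = 3, none = 0)[[mode]]
  res <- evolve_cpp(as.integer(N), as.integer(G), s, p_exp, mode == "none",
                    mu, isTRUE(allow_affinity_mutation), t_max, r_max, scale,
                    high_affinity_threshold)
  traj <- data.frame(
    generation = seq_len(nrow(res)),
    mean_total = res[, 1], mean_competent = res[, 2],
    mean_def_low = res[, 3], mean_def_high = res[, 4]
  )
  if (nrow(res) < G) {
    attr(traj, "halted") <- TRUE
    attr(traj, "halt_reason") <-
      "extinction: all individuals reached zero fitness"
  } else {
    attr(traj, "halted") <- FALSE
  }
  traj
}
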