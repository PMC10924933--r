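#' Dosage of an insertion arising at a given cell generation
#'
#' The spermatogenesis model has 21 cell generations: 20 binary divisions
#' expand one primordial precursor into 2^20 = 1,048,576 spermatogonial
#' stem cells.  An insertion arising at generation `k` is carried by a
#' clone of `2^(21 - k)` stem cells, i.e. a fraction `2^-k` of haploid
#' sperm genomes: dosage 0.5 at generation 1, ~0.00097 at generation 10,
#' ~4.8e-7 at generation 21.
#'
#' @param k Cell generation(s), in `1..n_generations`.
#' @param n_generations Number of cell generations (default 21).
#' @return Numeric vector of dosages `2^-k`.
#' @export
dosage <- function(k, n_generations = 21) {
  if (any(k < 1 | k > n_generations)) {
    stop_param("`k` must lie in 1..%d", n_generations)
  }
  2^-k
}

#' Per-generation mobilization weights of a developmental window
#'
#' A mobilization window is centred on a focal cell generation with an odd
#' width: per-cell mutability follows a symmetric binomial mass
#' (`width - 1` trials, p = 0.5) peaking at the focal generation, truncated
#' to generations `1..n_generations` and renormalized.  The probability
#' that an event arises in a generation is the product of that generation's
#' mutability and its cell count (which doubles every generation,
#' `2^(k-1)` cells at generation `k`), renormalized.
#'
#' @param focal Focal generation (1..`n_generations`).
#' @param width Odd window width (number of generations spanned).
#' @param n_generations Number of cell generations (default 21).
#' @param cell_weighted Multiply mutability by per-generation cell counts
#'   (default `TRUE`); `FALSE` returns the truncated binomial mutability
#'   itself.
#' @return Numeric vector of length `n_generations` summing to 1.
#' @export
window_weights <- function(focal, width, n_generations = 21,
                           cell_weighted = TRUE) {
  check_scalar_number(focal, "focal", lower = 1, upper = n_generations)
  check_scalar_number(width, "width", lower = 1)
  if (width %% 2 != 1) stop_param("`width` must be odd, got %s", width)
  half <- (width - 1) / 2
  gens <- (focal - half):(focal + half)
  mass <- stats::dbinom(0:(width - 1), width - 1, 0.5)
  w <- numeric(n_generations)
  inside <- gens >= 1 & gens <= n_generations
  w[gens[inside]] <- mass[inside]
  w <- w / sum(w)
  if (cell_weighted) {
    w <- w * 2^(seq_len(n_generations) - 1)
    w <- w / sum(w)
  }
  w
}

#' Simulate de novo insertions up to a target burden
#'
#' Draws insertion events one at a time, each assigned a cell generation
#' from the window weights and hence a dosage of `2^-k`, until the summed
#' dosage reaches the per-haploid-genome insertion burden `t/g`; the final
#' overshooting insertion is kept.
#'
#' @param window Weight vector over generations (from [window_weights()]).
#' @param burden Target number of de novo insertions per explored haploid
#'   genome (0 < burden < 1).
#' @param seed Integer seed.
#' @return List with `dosages`, `generations` (per insertion) and `burden`.
#' @export
simulate_insertions <- function(window, burden, seed = NULL) {
  check_scalar_number(burden, "burden", lower = 0, upper = 1)
  if (burden <= 0 || burden >= 1) stop_param("`burden` must be in (0, 1)")
  seed_rng(seed)
  n_gen <- length(window)
  mean_dose <- sum(window * 2^-(seq_len(n_gen)))
  gens <- integer(0)
  total <- 0
  while (total < burden) {
    chunk <- max(50L, ceiling(1.2 * (burden - total) / mean_dose))
    draw <- sample.int(n_gen, chunk, replace = TRUE, prob = window)
    doses <- 2^-draw
    cum <- total + cumsum(doses)
    if (cum[length(cum)] >= burden) {
      stop_at <- which(cum >= burden)[1]
      gens <- c(gens, draw[seq_len(stop_at)])
      total <- cum[stop_at]
    } else {
      gens <- c(gens, draw)
      total <- cum[length(cum)]
    }
  }
  list(dosages = 2^-gens, generations = gens, burden = burden)
}

#' Sample the recapture distribution of simulated insertions
#'
#' Capture is modeled as an urn: one ball per insertion with sampling
#' probability equal to its dosage, plus an insertion-free ball with
#' probability `1 - burden`; `g` balls are drawn with replacement and the
#' per-insertion capture counts are tabulated into the categories captured
#' 1x, 2x, 3x, 4x and >4x.
#'
#' @param dosages Per-insertion dosages (may be empty).
#' @param burden The insertion burden `t/g` used to build the urn.
#' @param g Number of explored haploid genomes (>= 1).
#' @param seed Integer seed.
#' @return List with `f` (named counts `1`,`2`,`3`,`4`,`>4`), `u`
#'   (distinct insertions captured), `t` (total captures), `g`, and
#'   `counts` (raw per-insertion capture counts).
#' @export
sample_urn <- function(dosages, burden, g, seed = NULL) {
  check_scalar_number(g, "g", lower = 1)
  if (sum(dosages) > 1 + 1e-6) {
    stop_param("insertion sampling probabilities sum to %.4f > 1", sum(dosages))
  }
  seed_rng(seed)
  probs <- c(dosages, max(0, 1 - burden))
  draws <- stats::rmultinom(1, g, probs)[, 1]
  counts <- if (length(dosages)) draws[seq_along(dosages)] else integer(0)
  f <- c(sum(counts == 1), sum(counts == 2), sum(counts == 3),
         sum(counts == 4), sum(counts > 4))
  names(f) <- c("1", "2", "3", "4", ">4")
  list(f = f, u = sum(counts > 0), t = sum(counts), g = g, counts = counts)
}

#' Average recapture profile of a developmental window
#'
#' Runs the insertion and urn simulation `reps` times for one individual
#' and averages the category counts.  Uses the current RNG stream; seed the
#' caller for reproducibility.
#'
#' @inheritParams window_weights
#' @param g Explored haploid genomes.
#' @param burden Insertion burden `t/g`.
#' @param reps Number of replicates.
#' @return Named numeric of mean counts for categories 1x..4x, >4x.
#' @export
recapture_profile <- function(focal, width, g, burden, reps = 50,
                              n_generations = 21) {
  w <- window_weights(focal, width, n_generations)
  acc <- numeric(5)
  for (r in seq_len(reps)) {
    sim <- simulate_insertions(w, burden)
    acc <- acc + sample_urn(sim$dosages, burden, g)$f
  }
  stats::setNames(acc / reps, c("1", "2", "3", "4", ">4"))
}

#' Fit the developmental window to observed recapture distributions
#'
#' Grid search over window widths and focal generations: for each
#' candidate window, each individual's recapture categories are simulated
#' `reps` times and averaged; the score is the summed absolute difference
#' between simulated and observed category counts, summed across
#' individuals.  The window minimizing the total score is returned together
#' with the full score grid.
#'
#' @param real_counts Matrix of observed category counts, individuals in
#'   rows and columns `1`,`2`,`3`,`4`,`>4`.
#' @param g_list,burden_list Per-individual explored haploid genomes and
#'   insertion burdens.
#' @param widths Odd window widths to scan (default `c(1, 3, 5, 7, 9)`).
#' @param focals Focal generations to scan (default all 21).
#' @param reps Simulation replicates per window and individual (default 50).
#' @param seed Integer seed (one stream for the whole grid; same seed,
#'   same grid).
#' @param n_generations Number of cell generations (default 21).
#' @return List with `best` (`focal`, `width`, `score`) and `scores`
#'   (data frame `width`, `focal`, `score`).
#' @export
fit_window <- function(real_counts, g_list, burden_list,
                       widths = c(1, 3, 5, 7, 9), focals = NULL,
                       reps = 50, seed = NULL, n_generations = 21) {
  real_counts <- as.matrix(real_counts)
  n_ind <- nrow(real_counts)
  stopifnot(length(g_list) == n_ind, length(burden_list) == n_ind)
  check_scalar_number(reps, "reps", lower = 1)
  if (is.null(focals)) focals <- seq_len(n_generations)
  seed_rng(seed)
  grid <- expand.grid(width = widths, focal = focals)
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    total <- 0
    for (b in seq_len(n_ind)) {
      sim_mean <- recapture_profile(grid$focal[i], grid$width[i],
                                    g_list[b], burden_list[b], reps,
                                    n_generations)
      total <- total + sum(abs(sim_mean - real_counts[b, ]))
    }
    grid$score[i] <- total
  }
  best <- grid[which.min(grid$score), ]
  list(best = list(focal = best$focal, width = best$width, score = best$score),
       scores = grid)
}
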