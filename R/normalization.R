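#' Fit the two-factor capture normalization model
#'
#' Models observed shearing-site counts as
#' `SSC[i, s] = ERV[i] + ID[s] + eps[i, s]` and finds the least-squares
#' solution (via [stats::lm()]).  The additive model is unidentifiable up to
#' a constant shifted between the two factors, so the locus effects are
#' constrained to sum to zero; the individual effect `ID[s]` then carries
#' the individual's overall capture level, and `2 * ID[s]` is interpretable
#' as the number of effectively captured haploid genomes — the normalization
#' factor for mobilization-rate estimation.
#'
#' Missing cells (`NA`) are dropped from the fit, not imputed.  The observed
#' cells must connect all loci and individuals into a single bipartite
#' component; otherwise the relative levels of the blocks are undefined and
#' the fit aborts, naming the disconnected block.
#'
#' @param capture_table Numeric matrix of SSC counts, loci in rows and
#'   individuals in columns (`NA` allowed), or a data frame with columns
#'   `locus`, `individual`, `ssc`.
#' @return An object of class `erv_normfit`: a list with `locus_effects`
#'   (`ERV[i]`, summing to zero), `individual_effects` (`ID[s]`),
#'   `fitted`, `residuals` (matrices shaped like the input),
#'   `constraint_used = "sum_to_zero_locus"`.
#' @seealso [estimate_rates()]
#' @export
fit_normalization <- function(capture_table) {
  long <- as_capture_long(capture_table)
  if (nrow(long) == 0L) stop_param("capture table has no observed cells")
  loci <- unique(long$locus)
  inds <- unique(long$individual)
  if (length(loci) < 2L || length(inds) < 2L) {
    stop_param("need at least 2 loci and 2 individuals with observations")
  }
  check_connected(long)

  long$locus <- factor(long$locus, levels = loci)
  long$individual <- factor(long$individual, levels = inds)
  fit <- stats::lm(ssc ~ 0 + locus + individual, data = long)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop_param("normalization design is rank deficient")
  l_eff <- cf[seq_along(loci)]
  s_eff <- c(0, cf[-seq_along(loci)])  # first individual is the baseline
  erv <- l_eff - mean(l_eff)
  id <- s_eff + mean(l_eff)
  names(erv) <- loci
  names(id) <- inds

  fitted_mat <- outer(erv, id, `+`)
  obs_mat <- matrix(NA_real_, length(loci), length(inds),
                    dimnames = list(loci, inds))
  obs_mat[cbind(match(long$locus, loci), match(long$individual, inds))] <- long$ssc
  resid_mat <- obs_mat - fitted_mat

  structure(
    list(locus_effects = erv, individual_effects = id,
         fitted = fitted_mat, residuals = resid_mat,
         constraint_used = "sum_to_zero_locus"),
    class = "erv_normfit"
  )
}

as_capture_long <- function(x) {
  if (is.matrix(x)) {
    loci <- rownames(x) %||% paste0("locus_", seq_len(nrow(x)))
    inds <- colnames(x) %||% paste0("ind_", seq_len(ncol(x)))
    out <- data.frame(
      locus = rep(loci, times = ncol(x)),
      individual = rep(inds, each = nrow(x)),
      ssc = as.vector(x),
      stringsAsFactors = FALSE
    )
    return(out[!is.na(out$ssc), , drop = FALSE])
  }
  if (is.data.frame(x)) {
    need <- c("locus", "individual", "ssc")
    if (!all(need %in% names(x))) {
      stop_param("capture data frame needs columns locus, individual, ssc")
    }
    x <- x[!is.na(x$ssc), need, drop = FALSE]
    x$locus <- as.character(x$locus)
    x$individual <- as.character(x$individual)
    return(x)
  }
  stop_param("`capture_table` must be a matrix or data frame")
}

# The observed cells define a bipartite graph loci <-> individuals; a
# disconnected component makes the relative factor levels unidentifiable.
check_connected <- function(long) {
  loci <- unique(long$locus)
  inds <- unique(long$individual)
  n_l <- length(loci)
  node <- c(loci, inds)
  comp <- seq_along(node)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  li <- match(long$locus, loci)
  si <- n_l + match(long$individual, inds)
  for (k in seq_len(nrow(long))) {
    a <- find(li[k]); b <- find(si[k])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_along(node), find, integer(1))
  if (length(unique(roots)) > 1L) {
    block <- node[roots == roots[1]]
    stop_param(
      "capture table is disconnected: block {%s} shares no cells with the rest",
      paste(block, collapse = ", ")
    )
  }
  invisible(NULL)
}

#' Estimate per-individual mobilization rates
#'
#' Converts de novo event counts into events per gamete using the
#' normalization fit: `TR[s] = N[s] / (2 * ID[s])`, where `2 * ID[s]` is the
#' number of effectively captured haploid genomes.  Individuals with
#' non-positive `ID` get an `NA` rate (flagged missing, never zero).
#'
#' @param n_events Named integer vector of de novo event counts; names must
#'   match individuals in `fit`.
#' @param fit An `erv_normfit` from [fit_normalization()], or a named
#'   numeric vector of `ID` values.
#' @return Data frame with columns `sample_id`, `n_events`, `id`,
#'   `genomes` (`2 * ID`), `rate`.
#' @export
estimate_rates <- function(n_events, fit) {
  id <- if (inherits(fit, "erv_normfit")) fit$individual_effects else fit
  if (is.null(names(n_events)) || is.null(names(id))) {
    if (length(n_events) != length(id)) {
      stop_param("unnamed `n_events` must align with `fit` individuals")
    }
    names(n_events) <- names(id) <- names(id) %||% paste0("ind_", seq_along(id))
  }
  missing <- setdiff(names(n_events), names(id))
  if (length(missing)) {
    stop_param("no ID estimate for: %s", paste(missing, collapse = ", "))
  }
  id <- id[names(n_events)]
  rate <- ifelse(id > 0, n_events / (2 * id), NA_real_)
  if (any(id <= 0)) {
    warning("non-positive ID for some individuals; their rates are NA")
  }
  data.frame(
    sample_id = names(n_events),
    n_events = as.integer(n_events),
    id = unname(id),
    genomes = unname(2 * id),
    rate = unname(rate),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Average technical-replicate rate estimates
#'
#' The 5' and 3' LTR capture panels give two independent rate estimates per
#' individual; the reported rate is their mean (an individual missing from
#' one panel keeps the other panel's estimate).
#'
#' @param rates_5p,rates_3p Data frames from [estimate_rates()].
#' @return Data frame `sample_id`, `rate` (panel average).
#' @export
average_panel_rates <- function(rates_5p, rates_3p) {
  all_ids <- union(rates_5p$sample_id, rates_3p$sample_id)
  r5 <- rates_5p$rate[match(all_ids, rates_5p$sample_id)]
  r3 <- rates_3p$rate[match(all_ids, rates_3p$sample_id)]
  rate <- rowMeans(cbind(r5, r3), na.rm = TRUE)
  rate[is.nan(rate)] <- NA_real_
  data.frame(sample_id = all_ids, rate = rate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Repeatability of paired rate estimates
#'
#' Spearman rank correlation between two measurement series on the same
#' individuals (e.g. young vs old semen samples), the upper bound of the
#' heritability of the trait.
#'
#' @param rates_a,rates_b Paired numeric vectors, `n >= 3`.
#' @return List with `rho`, `p` (two-sided), `n`.  A constant input vector
#'   makes the rank correlation undefined: `rho` and `p` are `NA` and a
#'   warning is raised.
#' @export
repeatability <- function(rates_a, rates_b) {
  ok <- stats::complete.cases(rates_a, rates_b)
  a <- rates_a[ok]; b <- rates_b[ok]
  if (length(a) < 3L) stop_param("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input vector: rank correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(a)))
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", alternative = "two.sided")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Germline mobilization rate from pedigree counts
#'
#' Rate arithmetic for de novo insertions ascertained in three-generation
#' pedigrees: each parent-offspring transmission screens two gametes (one
#' paternal, one maternal), so `n_offspring` trio offspring represent
#' `2 * n_offspring` gametes.  Optionally excludes an outlier's events and
#' the gametes that carried them (e.g. one exceptional sire contributing
#' several events).
#'
#' @param n_events De novo insertion events observed.
#' @param n_offspring Number of trio offspring screened.
#' @param gametes_per_offspring Gametes examined per offspring (default 2).
#' @param exclude_events,exclude_gametes Events and event-carrying gametes
#'   to drop before computing the rate.
#' @return List with `events`, `gametes`, `rate` (events per gamete) and
#'   `one_in` (gametes per event).
#' @export
pedigree_rate <- function(n_events, n_offspring, gametes_per_offspring = 2,
                          exclude_events = 0, exclude_gametes = 0) {
  gametes <- n_offspring * gametes_per_offspring - exclude_gametes
  events <- n_events - exclude_events
  if (events < 0 || gametes <= 0) stop_param("exclusions exceed the data")
  list(events = events, gametes = gametes,
       rate = events / gametes,
       one_in = gametes / events)
}
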