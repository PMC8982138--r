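# Synthetic data generator: lognormal concentrations, lognormal
# efficiencies, Poisson concentrations, multinomial reads with
# discrete-uniform depths, plus the abundance exclusion and observed-taxon
# selection rules used in the simulation studies.

#' Configuration for the synthetic-data generator
#'
#' Defaults reflect a community profiled at typical amplicon depths:
#' `n = 100` samples, read depths uniform on `[1e4, 1e5]`, mean log
#' concentrations `beta_j ~ N(0, 50)`, unit lognormal dispersion
#' (`Sigma = I`), and exclusion of taxa whose true mean concentration is
#' below one unit.
#'
#' @param q Number of taxa simulated.
#' @param qobs Number of taxa with observed concentrations; capped at the
#'   number of retained taxa (with a warning) if the abundance filter
#'   leaves fewer.
#' @param n Number of samples.
#' @param sigma_e Standard deviation of log efficiencies; `0` gives
#'   `e_j = 1` exactly.
#' @param beta_var Variance of the mean log concentrations `beta_j`.
#' @param Sigma_diag Length-`q` variances of log concentrations around
#'   `beta` (default all one).
#' @param M_low,M_high Read-depth bounds (discrete uniform).
#' @param abundance_floor Exclude taxa whose true concentration, averaged
#'   over samples, falls below this value.
#' @param seed Integer master seed; independent substreams are derived for
#'   each stage so that, e.g., changing `sigma_e` does not perturb the
#'   concentration draws.
#' @param beta Optional fixed `beta` vector (otherwise redrawn per call).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(q, qobs, n = 100, sigma_e = 0, beta_var = 50,
                              Sigma_diag = rep(1, q), M_low = 1e4,
                              M_high = 1e5, abundance_floor = 1, seed = 1,
                              beta = NULL) {
  stopifnot(q >= 2, qobs >= 1, qobs <= q, n >= 1, sigma_e >= 0,
            beta_var >= 0, length(Sigma_diag) == q, all(Sigma_diag >= 0),
            M_low <= M_high, M_low >= 1, abundance_floor >= 0)
  if (!is.null(beta)) stopifnot(length(beta) == q)
  structure(
    list(q = as.integer(q), qobs = as.integer(qobs), n = as.integer(n),
         sigma_e = sigma_e, beta_var = beta_var, Sigma_diag = Sigma_diag,
         M_low = M_low, M_high = M_high, abundance_floor = abundance_floor,
         seed = as.integer(seed), beta = beta),
    class = "simulation_config"
  )
}

#' Exclude low-abundance taxa by true mean concentration
#'
#' @param mu `n x q` matrix of true concentrations.
#' @param floor Retain taxa with column mean at least `floor`.
#' @return Integer indices of the retained taxa.
#' @export
abundance_filter <- function(mu, floor) {
  which(colMeans(mu) >= floor)
}

#' Select the observed taxa
#'
#' The `qobs` taxa with the largest mean read count across samples, mirroring
#' the practice of designing concentration assays for the most abundant
#' taxa. Ties are broken by column order (first wins).
#'
#' @param W `n x q` read-count matrix.
#' @param qobs Number of taxa to select.
#' @return Integer indices of the selected columns, in decreasing order of
#'   mean count.
#' @export
select_observed <- function(W, qobs) {
  if (qobs > ncol(W)) {
    stop("qobs (", qobs, ") exceeds the number of taxa (", ncol(W), ")",
         call. = FALSE)
  }
  order(colMeans(W), decreasing = TRUE)[seq_len(qobs)]
}

#' Generate one synthetic paired dataset
#'
#' Draws `beta_j ~ N(0, beta_var)`, `log mu_i. ~ N_q(beta, Sigma)`,
#' `e_j ~ Lognormal(0, sigma_e^2)`, depths `M_i ~ DiscreteUniform(M_low,
#' M_high)`, concentrations `V_ij ~ Poisson(mu_ij)` for every taxon, and
#' reads `W_i. ~ Multinomial(M_i, p_i.)` with efficiency-weighted
#' probabilities. Taxa below the abundance floor are then excluded from the
#' analyzed tables (read depths recomputed over the retained taxa), and the
#' `qobs` most abundant retained taxa by mean read count become the
#' observed set, stored in the leading columns.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `abundance_sim`: `paired` (a `paired_abundance`
#'   ready for fitting), `truth` (full `mu`, `e`, `beta`, `V_full`, `M`,
#'   `retained_taxa`, `observed_taxa`, and `taxon_order` mapping the paired
#'   columns to original taxon indices), and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  q <- cfg$q; n <- cfg$n
  set.seed(cfg$seed)
  sub <- sample.int(2^31 - 2, 6)

  set.seed(sub[1])
  beta <- if (is.null(cfg$beta)) {
    stats::rnorm(q, 0, sqrt(cfg$beta_var))
  } else {
    cfg$beta
  }
  set.seed(sub[2])
  e <- if (cfg$sigma_e == 0) rep(1, q) else exp(stats::rnorm(q, 0, cfg$sigma_e))
  set.seed(sub[3])
  log_mu <- matrix(stats::rnorm(n * q, rep(beta, each = n),
                                rep(sqrt(cfg$Sigma_diag), each = n)),
                   n, q)
  mu <- exp(log_mu)
  set.seed(sub[4])
  M <- floor(stats::runif(n, cfg$M_low, cfg$M_high + 1))
  set.seed(sub[5])
  V_full <- matrix(rpois_large(n * q, mu), n, q)
  set.seed(sub[6])
  W <- t(vapply(seq_len(n), function(i) {
    stats::rmultinom(1, M[i], relative_abundance_probs(mu[i, ], e))[, 1]
  }, numeric(q)))

  taxon_ids <- sprintf("taxon%03d", seq_len(q))
  sample_ids <- sprintf("sample%03d", seq_len(n))
  retained <- abundance_filter(mu, cfg$abundance_floor)
  if (length(retained) == 0) {
    stop("all taxa fell below the abundance floor; lower abundance_floor ",
         "or change the seed", call. = FALSE)
  }
  qobs <- cfg$qobs
  if (qobs >= length(retained)) {
    qobs <- max(1L, length(retained) - 1L)
    warning("qobs reduced to ", qobs, " (only ", length(retained),
            " taxa retained; at least one unobserved taxon is required)")
  }
  W_ret <- W[, retained, drop = FALSE]
  observed_local <- select_observed(W_ret, qobs)
  observed <- retained[observed_local]
  order_local <- c(observed_local, setdiff(seq_along(retained),
                                           observed_local))
  taxon_order <- retained[order_local]

  counts <- count_table(W[, taxon_order, drop = FALSE],
                        sample_ids = sample_ids,
                        taxon_ids = taxon_ids[taxon_order])
  conc <- concentration_table(V_full[, observed, drop = FALSE],
                              sample_ids = sample_ids,
                              taxon_ids = taxon_ids[observed])
  paired <- structure(
    list(counts = counts, conc = conc, qobs = qobs,
         taxon_perm = seq_along(taxon_order)),
    class = "paired_abundance"
  )
  truth <- list(mu = mu, e = e, beta = beta, Sigma_diag = cfg$Sigma_diag,
                V_full = V_full, M = M, retained_taxa = retained,
                observed_taxa = observed, taxon_order = taxon_order,
                taxon_ids = taxon_ids)
  structure(list(paired = paired, truth = truth, config = cfg),
            class = "abundance_sim")
}

#' True values aligned to the analyzed table
#'
#' Restrict a full-truth matrix (e.g., `mu` or `V_full`) to the retained
#' taxa in the column order of the paired dataset.
#'
#' @param sim An `abundance_sim`.
#' @param what `"mu"` or `"V_full"`.
#' @return An `n x q_retained` matrix aligned with `sim$paired$counts$W`.
#' @export
aligned_truth <- function(sim, what = c("mu", "V_full")) {
  what <- match.arg(what)
  m <- sim$truth[[what]][, sim$truth$taxon_order, drop = FALSE]
  dimnames(m) <- dimnames(sim$paired$counts$W)
  m
}
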