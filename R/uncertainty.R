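# Probabilistic and deterministic sensitivity analysis. Every non-fixed
# input is resampled from its moment-fitted distribution (beta for
# probabilities/utilities, gamma for costs, lognormal for relative risks);
# parameters are sampled independently (no correlation information is
# published) and draws are shared across strategies within an iteration.

#' Fit the sampling distribution of every parameter
#'
#' @param table A `parameter_table`.
#' @return Named list of `dist_params`, one per parameter. Parameters with
#'   `se = 0` or a `fixed` family become degenerate (always their mean).
#' @export
fit_all_distributions <- function(table) {
  stopifnot(inherits(table, "parameter_table"))
  fits <- lapply(seq_len(nrow(table)), function(i) {
    fit_parameter_distribution(table$mean[i], table$se[i], table$distribution[i])
  })
  stats::setNames(fits, table$name)
}

#' Draw one joint parameter set
#'
#' Each non-fixed parameter is drawn independently from its fitted
#' distribution; fixed parameters pass through. Draws respect the domain of
#' each family by construction (beta in `[0,1]`, gamma and lognormal on the
#' positive half-line).
#'
#' @param fits Named list from [fit_all_distributions()].
#' @return Named numeric vector of sampled parameter values.
#' @export
sample_parameter_set <- function(fits) {
  vapply(fits, dist_draw, numeric(1), n = 1)
}

#' Probabilistic sensitivity analysis
#'
#' Runs the cohort model `n_iterations` times; in each iteration one joint
#' parameter draw drives all strategies (common random parameters across
#' arms), and lifetime discounted cost and QALYs are recorded per strategy.
#'
#' @param config A `model_config`.
#' @param n_iterations Number of Monte-Carlo iterations (published analysis:
#'   5000).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param strategies Strategies to simulate (default all four).
#' @param perspective Costing perspective (defaults to the config setting).
#' @return A list of class `psa_result`: `outcomes` (data frame iteration x
#'   strategy with cost, ly, qaly), `draws` (iteration x parameter matrix),
#'   `seed`, `n_iterations`, `perspective`, `settings`.
#' @examples
#' cfg <- load_model_config()
#' psa <- run_psa(cfg, n_iterations = 20, seed = 1)
#' head(psa$outcomes)
#' @export
run_psa <- function(config, n_iterations, seed = 20180801L,
                    strategies = STRATEGIES,
                    perspective = config$settings$perspective) {
  stopifnot(inherits(config, "model_config"), n_iterations >= 1)
  fits <- fit_all_distributions(config$parameters)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  p <- length(fits)
  draws <- matrix(NA_real_, n_iterations, p,
    dimnames = list(NULL, names(fits))
  )
  for (j in seq_len(p)) draws[, j] <- dist_draw(fits[[j]], n_iterations)

  rows <- vector("list", n_iterations * length(strategies))
  k <- 0
  for (i in seq_len(n_iterations)) {
    cfg_i <- set_parameter_values(config, draws[i, ])
    for (st in strategies) {
      out <- accumulate_outcomes(
        suppressWarnings(run_cohort(st, cfg_i)), perspective
      )
      k <- k + 1
      rows[[k]] <- data.frame(
        iteration = i, strategy = st,
        cost = out$cost, ly = out$ly, qaly = out$qaly
      )
    }
  }
  structure(
    list(
      outcomes = do.call(rbind, rows), draws = draws,
      seed = as.integer(seed), n_iterations = n_iterations,
      perspective = perspective, settings = config$settings
    ),
    class = "psa_result"
  )
}

#' Incremental cost/QALY cloud versus a reference strategy
#'
#' Per-iteration incremental cost and QALYs, the pairs plotted on a
#' cost-effectiveness plane.
#'
#' @param psa A `psa_result`.
#' @param reference_strategy Reference strategy name.
#' @return Data frame with `iteration`, `strategy`, `inc_cost`, `inc_qaly`.
#' @export
psa_incremental <- function(psa, reference_strategy) {
  stopifnot(inherits(psa, "psa_result"))
  out <- psa$outcomes
  ref <- out[out$strategy == reference_strategy, ]
  if (nrow(ref) == 0) stop("reference strategy not in PSA outcomes")
  ref <- ref[order(ref$iteration), ]
  rest <- out[out$strategy != reference_strategy, ]
  i <- match(rest$iteration, ref$iteration)
  data.frame(
    iteration = rest$iteration, strategy = rest$strategy,
    inc_cost = rest$cost - ref$cost[i],
    inc_qaly = rest$qaly - ref$qaly[i]
  )
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold the probability that a strategy is
#' cost-effective is the fraction of PSA iterations in which it attains the
#' maximal net monetary benefit (ties split evenly), so probabilities
#' partition to one across strategies. A pairwise variant — the probability
#' of a positive incremental NMB versus the reference strategy — is also
#' returned, mirroring the published figure.
#'
#' @param psa A `psa_result`.
#' @param thresholds Numeric vector of thresholds (IDR per QALY); default
#'   grid 0 to 5e8 in 101 steps.
#' @param reference_strategy Reference for the pairwise variant.
#' @return Data frame of class `ceac_curve`: `threshold`, `strategy`,
#'   `probability` (max-NMB definition) and `probability_vs_reference`.
#' @export
compute_ceac <- function(psa, thresholds = seq(0, 5e8, length.out = 101),
                         reference_strategy = "FOLFIRI") {
  stopifnot(inherits(psa, "psa_result"))
  if (length(thresholds) == 0) stop("empty threshold grid")
  out <- psa$outcomes
  strategies <- unique(out$strategy)
  n_iter <- psa$n_iterations
  cost <- matrix(out$cost[order(match(out$strategy, strategies), out$iteration)],
    nrow = n_iter, ncol = length(strategies),
    dimnames = list(NULL, strategies)
  )
  qaly <- matrix(out$qaly[order(match(out$strategy, strategies), out$iteration)],
    nrow = n_iter, ncol = length(strategies),
    dimnames = list(NULL, strategies)
  )
  ref_idx <- match(reference_strategy, strategies)
  res <- lapply(thresholds, function(lambda) {
    nmb <- net_monetary_benefit(cost, qaly, lambda)
    best <- nmb == matrixStats_rowMax(nmb)
    win <- best / rowSums(best) # ties split evenly
    prob <- colMeans(win)
    pvr <- if (!is.na(ref_idx)) {
      colMeans(nmb > nmb[, ref_idx])
    } else {
      rep(NA_real_, length(strategies))
    }
    data.frame(
      threshold = lambda, strategy = strategies,
      probability = prob, probability_vs_reference = pvr
    )
  })
  structure(do.call(rbind, res), class = c("ceac_curve", "data.frame"))
}

# row maxima without a matrixStats dependency
matrixStats_rowMax <- function(m) {
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter in turn is set to its lower and upper bound
#' (mean -/+ `z` standard errors, clipped to the parameter's domain: `[0,1]`
#' for probabilities and utilities, `>= 0` for costs, `> 0` for relative
#' risks) while all other parameters stay at base case, and the ICER of
#' `strategy` versus `reference_strategy` is recomputed. Entries are sorted
#' by descending ICER range.
#'
#' @param config A `model_config`.
#' @param parameter_names Parameters to vary; default all non-fixed ones.
#' @param strategy,reference_strategy The ICER comparison of interest.
#' @param perspective Costing perspective.
#' @param z Half-width in standard errors (default 1.96, a 95% interval).
#' @return Data frame of class `tornado_table`: parameter, bounds, ICER at
#'   each bound, `range` (absolute ICER spread), sorted descending.
#' @export
one_way_dsa <- function(config, parameter_names = NULL,
                        strategy = "CETUX_FOLFOX",
                        reference_strategy = config$settings$reference_strategy,
                        perspective = config$settings$perspective,
                        z = 1.96) {
  stopifnot(inherits(config, "model_config"))
  tab <- config$parameters
  if (is.null(parameter_names)) {
    parameter_names <- tab$name[tab$distribution != "fixed"]
  }
  missing <- setdiff(parameter_names, tab$name)
  if (length(missing) > 0) {
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  }
  icer_at <- function(cfg) {
    outs <- run_base_case(cfg, c(strategy, reference_strategy), perspective)
    ce <- incremental_analysis(outs, reference_strategy)
    ce$icer_qaly[ce$strategy == strategy]
  }
  base_icer <- icer_at(config)
  rows <- lapply(parameter_names, function(nm) {
    i <- which(tab$name == nm)
    lo <- tab$mean[i] - z * tab$se[i]
    hi <- tab$mean[i] + z * tab$se[i]
    if (tab$role[i] %in% c("transition_probability", "utility")) {
      lo <- max(lo, 0); hi <- min(hi, 1)
    } else if (tab$role[i] == "cost") {
      lo <- max(lo, 0)
    } else if (tab$role[i] == "relative_risk") {
      lo <- max(lo, 1e-6)
    }
    icer_lo <- icer_at(suppressWarnings(set_parameter_values(config, stats::setNames(lo, nm))))
    icer_hi <- icer_at(suppressWarnings(set_parameter_values(config, stats::setNames(hi, nm))))
    data.frame(
      parameter = nm, low_value = lo, high_value = hi,
      icer_low = icer_lo, icer_high = icer_hi,
      range = abs(icer_hi - icer_lo)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  structure(out,
    class = c("tornado_table", "data.frame"),
    base_icer = base_icer, strategy = strategy,
    reference_strategy = reference_strategy
  )
}
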