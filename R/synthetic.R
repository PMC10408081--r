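# Seed-deterministic synthetic stand-ins for the study's primary data
# sources: interview cost records, EQ-5D-5L utility records and two-arm
# trial tables. The generators emulate the statistical structure the
# analysis assumes (gamma-distributed cost components, an additive EQ-5D
# value set, binomial trial arms); they do not emulate billing formats or
# case-report forms, and component independence is assumed throughout.

EQ5D_DIMENSIONS <- c(
  "mobility", "self_care", "usual_activities", "pain_discomfort",
  "anxiety_depression"
)

#' Synthetic EQ-5D-5L value set
#'
#' The Indonesian EQ-5D-5L value-set coefficients are not published in the
#' source material, so this package ships a clearly-labelled synthetic
#' additive value set with the usual qualitative shape (zero decrement at
#' level 1, decrements growing with level, pain/discomfort and mobility
#' weighted heaviest, worst state below zero). Any additive value set with
#' the same layout can be supplied in its place.
#'
#' @return Matrix of utility decrements, dimensions x levels 1-5; level-1
#'   column all zero.
#' @export
synthetic_value_set <- function() {
  m <- rbind(
    mobility = c(0, 0.046, 0.103, 0.183, 0.274),
    self_care = c(0, 0.038, 0.089, 0.157, 0.224),
    usual_activities = c(0, 0.041, 0.094, 0.166, 0.237),
    pain_discomfort = c(0, 0.053, 0.118, 0.209, 0.293),
    anxiety_depression = c(0, 0.034, 0.081, 0.143, 0.206)
  )
  colnames(m) <- paste0("level", 1:5)
  m
}

#' Value an EQ-5D-5L profile
#'
#' Additive valuation: `1 - sum(decrements)`. The full-health profile
#' (1,1,1,1,1) anchors at 1; the worst profile may fall below zero.
#'
#' @param profile Integer vector of length 5 (levels 1-5, dimension order
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression).
#' @param value_set Decrement matrix as from [synthetic_value_set()].
#' @return Utility value.
#' @examples
#' value_eq5d_profile(c(1, 1, 1, 1, 1), synthetic_value_set())
#' @export
value_eq5d_profile <- function(profile, value_set = synthetic_value_set()) {
  if (length(profile) != 5 || any(profile < 1) || any(profile > 5) ||
    any(profile != round(profile))) {
    stop("profile must be five integer levels in 1-5")
  }
  1 - sum(value_set[cbind(seq_len(5), profile)])
}

# utilities of all 5^5 profiles under a value set, with the profile matrix
all_profile_utilities <- function(value_set) {
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))
  colnames(grid) <- EQ5D_DIMENSIONS
  dec <- sapply(seq_len(5), function(d) value_set[d, grid[, d]])
  list(profiles = grid, utility = 1 - rowSums(dec))
}

#' Generate synthetic EQ-5D-5L interview records
#'
#' Draws target utilities from a beta distribution rescaled to the value
#' set's attainable range and moment-matched to (`target_mean`,
#' `target_sd`), then maps each to the profile with the nearest valued
#' utility, so the valued sample mean converges to the target as `n` grows.
#'
#' @param n Number of respondents.
#' @param state Health state label attached to the records (`"STABLE"` or
#'   `"PROGRESSIVE"`).
#' @param target_mean,target_sd Target moments of the valued utilities
#'   (defaults: the published state means 0.798 / 0.443, with record-level
#'   SDs recovered from the published standard errors and interview counts,
#'   8 stable and 3 progressive respondents).
#' @param seed Integer seed; identical seeds give identical records.
#' @param value_set Additive value set matrix.
#' @return Data frame with `patient_id`, `state`, the five dimension levels
#'   and `utility`; attribute `provenance` records the generator inputs.
#' @export
generate_eq5d_records <- function(n, state = c("STABLE", "PROGRESSIVE"),
                                  target_mean = NULL, target_sd = NULL,
                                  seed = 1L,
                                  value_set = synthetic_value_set()) {
  state <- match.arg(state)
  if (is.null(target_mean)) {
    target_mean <- if (state == "STABLE") 0.798 else 0.443
  }
  if (is.null(target_sd)) {
    target_sd <- if (state == "STABLE") 0.031 * sqrt(8) else 0.154 * sqrt(3)
  }
  pool <- all_profile_utilities(value_set)
  u_min <- min(pool$utility)
  if (target_mean <= u_min || target_mean >= 1) {
    stop(sprintf(
      "target mean %.3f outside the attainable utility range (%.3f, 1)",
      target_mean, u_min
    ))
  }
  width <- 1 - u_min
  b <- fit_beta_from_moments((target_mean - u_min) / width, target_sd / width)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  target_u <- u_min + width * dist_draw(b, n)
  ord <- order(pool$utility)
  u_sorted <- pool$utility[ord]
  # nearest valued profile for each target utility
  pos <- findInterval(target_u, u_sorted, all.inside = TRUE)
  pick <- ifelse(
    abs(u_sorted[pos] - target_u) <= abs(u_sorted[pmin(pos + 1, length(u_sorted))] - target_u),
    pos, pmin(pos + 1, length(u_sorted))
  )
  idx <- ord[pick]
  out <- data.frame(
    patient_id = seq_len(n), state = state,
    pool$profiles[idx, , drop = FALSE],
    utility = pool$utility[idx]
  )
  rownames(out) <- NULL
  structure(out, provenance = list(
    generator = "generate_eq5d_records", seed = as.integer(seed), n = n,
    state = state, target_mean = target_mean, target_sd = target_sd
  ))
}

#' Generate synthetic interview cost records
#'
#' Emulates the structured cost interviews behind the state-level cost
#' inputs: per respondent a direct medical amount, a travel cost composed
#' as round-trip distance x number of visits x fuel price, an accommodation
#' cost, and income losses for patient and caregiver built from days lost
#' and a daily wage. Respondents whose wage is missing (a configurable
#' share) are imputed at the provincial minimum daily wage. Component means
#' are anchored to the packaged state-level cost table for the chosen
#' strategy and the record-level spread is scaled from the published
#' standard errors and the interview size (n = 22).
#'
#' @param n Number of records.
#' @param state `"STABLE"` or `"PROGRESSIVE"`.
#' @param config A `model_config` providing the target cost means/SEs.
#' @param strategy Strategy whose stable-state costs anchor the targets.
#' @param seed Integer seed.
#' @param options List overriding `fuel_price_per_km` (IDR), `visit_mean`,
#'   `days_lost_mean`, `p_wage_missing`, `min_wage_daily` (IDR),
#'   `interview_n` (the size behind the published SEs), `travel_share`,
#'   `caregiver_share`, and the component coefficients of variation
#'   `cv_distance`, `cv_accommodation`, `cv_days`, `cv_wage` (set to zero
#'   for degenerate components).
#' @return Data frame of cost records with component amounts (IDR) and the
#'   `wage_missing` imputation flag; attribute `provenance`.
#' @export
generate_cost_records <- function(n, state = c("STABLE", "PROGRESSIVE"),
                                  config = load_model_config(),
                                  strategy = "CETUX_FOLFIRI", seed = 1L,
                                  options = list()) {
  state <- match.arg(state)
  opt <- utils::modifyList(list(
    fuel_price_per_km = 10000, visit_mean = 6, days_lost_mean = 8,
    p_wage_missing = 0.2, min_wage_daily = 150000, interview_n = 22,
    travel_share = 0.7, caregiver_share = 0.4,
    cv_distance = 0.3, cv_accommodation = 0.5, cv_days = 0.4, cv_wage = 0.4
  ), options)
  tab <- config$parameters
  pick <- function(component) {
    sel <- tab$role == "cost" & tab$component == component &
      tab$from_state == state &
      tab$strategy %in% if (state == "STABLE") strategy else "ALL"
    row <- tab[which(sel)[1], ]
    if (is.na(row$name)) stop("no ", component, " cost for state ", state)
    list(mean = row$mean, sd = row$se * sqrt(opt$interview_n))
  }
  dm <- pick("direct_medical")
  dnm <- pick("direct_nonmedical")
  ind <- pick("indirect")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  direct_medical <- dist_draw(
    fit_parameter_distribution(dm$mean, dm$sd, "gamma"), n
  )

  # travel: distance x visits x fuel price, mean anchored to its share of
  # the direct non-medical target
  visits <- 1 + stats::rpois(n, opt$visit_mean - 1)
  travel_target <- opt$travel_share * dnm$mean
  dist_mean <- travel_target / (opt$visit_mean * opt$fuel_price_per_km)
  distance_km <- dist_draw(
    fit_parameter_distribution(dist_mean, opt$cv_distance * dist_mean, "gamma"), n
  )
  travel <- distance_km * visits * opt$fuel_price_per_km
  accom_target <- (1 - opt$travel_share) * dnm$mean
  accommodation <- dist_draw(
    fit_parameter_distribution(accom_target, opt$cv_accommodation * accom_target, "gamma"), n
  )

  # income loss: days lost x daily wage, with minimum-wage imputation for
  # missing wages; the observed-wage mean is solved so the overall mean
  # hits the indirect-cost target
  days_lost <- dist_draw(
    fit_parameter_distribution(opt$days_lost_mean, opt$cv_days * opt$days_lost_mean, "gamma"), n
  )
  per_day_target <- ind$mean / opt$days_lost_mean
  wage_obs_mean <- (per_day_target - opt$p_wage_missing * opt$min_wage_daily) /
    (1 - opt$p_wage_missing)
  if (wage_obs_mean <= 0) stop("infeasible wage calibration; lower p_wage_missing")
  wage_missing <- stats::runif(n) < opt$p_wage_missing
  wage_daily <- ifelse(
    wage_missing, opt$min_wage_daily,
    dist_draw(fit_parameter_distribution(wage_obs_mean, opt$cv_wage * wage_obs_mean, "gamma"), n)
  )
  income_loss <- days_lost * wage_daily
  income_loss_patient <- (1 - opt$caregiver_share) * income_loss
  income_loss_caregiver <- opt$caregiver_share * income_loss

  out <- data.frame(
    patient_id = seq_len(n), state = state, visits = visits,
    distance_km = distance_km, direct_medical = direct_medical,
    travel = travel, accommodation = accommodation,
    income_loss_patient = income_loss_patient,
    income_loss_caregiver = income_loss_caregiver,
    wage_missing = wage_missing
  )
  structure(out, provenance = list(
    generator = "generate_cost_records", seed = as.integer(seed), n = n,
    state = state, strategy = strategy, options = opt
  ))
}

#' Summarize cost records into model parameter entries
#'
#' Collapses record-level interview data to state-level cost parameters
#' (mean and SE = SD/sqrt(n)) in the schema accepted by
#' [load_parameter_table()]: direct medical; direct non-medical = travel +
#' accommodation; indirect = patient + caregiver income loss.
#'
#' @param records Data frame from [generate_cost_records()] (possibly
#'   covering several states).
#' @param strategy Strategy tag for the stable-state entries.
#' @return Data frame of parameter entries (`name`, `mean`, `se`,
#'   `distribution`, `role`, `strategy`, `from_state`, `component`).
#' @export
summarize_records_to_params <- function(records, strategy = "CETUX_FOLFIRI") {
  suffix <- c(
    FOLFOX = "folfox", FOLFIRI = "folfiri",
    CETUX_FOLFOX = "cetuxfolfox", CETUX_FOLFIRI = "cetuxfolfiri"
  )[[strategy]]
  rows <- list()
  for (state in unique(records$state)) {
    sub <- records[records$state == state, ]
    if (nrow(sub) < 2) {
      stop("need >= 2 records per state to estimate a standard error (",
        state, " has ", nrow(sub), ")")
    }
    comp <- list(
      direct_medical = sub$direct_medical,
      direct_nonmedical = sub$travel + sub$accommodation,
      indirect = sub$income_loss_patient + sub$income_loss_caregiver
    )
    tag <- c(direct_medical = "DM", direct_nonmedical = "DnM", indirect = "In")
    for (k in names(comp)) {
      nm <- if (state == "STABLE") {
        sprintf("Cost%s_S_%s", tag[[k]], suffix)
      } else {
        sprintf("Cost%s_P_progressive", tag[[k]])
      }
      rows[[nm]] <- data.frame(
        name = nm, mean = mean(comp[[k]]),
        se = stats::sd(comp[[k]]) / sqrt(nrow(sub)),
        distribution = "gamma", role = "cost",
        strategy = if (state == "STABLE") strategy else "ALL",
        from_state = state, to_state = NA_character_,
        band_start = NA_integer_, band_end = NA_integer_, component = k,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic star-network trial table
#'
#' Simulates one two-arm trial per non-reference treatment against the
#' common comparator, with binomial event counts at the given baseline risk
#' and true relative risks — the structure behind the packaged pooled
#' relative risks.
#'
#' @param true_rrs Named vector of true RRs per treatment (vs the
#'   reference).
#' @param baseline_risk Event risk in the reference arm, in (0, 1).
#' @param n_per_arm Patients per arm.
#' @param seed Integer seed.
#' @param reference Reference treatment label.
#' @param outcome Outcome label.
#' @return Arm-level data frame (`study`, `arm`, `events`, `n`, `outcome`)
#'   with attribute `provenance`.
#' @export
generate_nma_trials <- function(true_rrs, baseline_risk, n_per_arm,
                                seed = 1L, reference = "FOLFOX",
                                outcome = "response_rate") {
  if (baseline_risk <= 0 || baseline_risk >= 1) stop("baseline risk must be in (0,1)")
  if (any(true_rrs <= 0)) stop("relative risks must be > 0")
  risks <- baseline_risk * true_rrs
  if (any(risks > 1)) {
    stop("infeasible risk: rr x baseline exceeds 1 for ",
      paste(names(true_rrs)[risks > 1], collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(true_rrs), function(i) {
    trt <- names(true_rrs)[i]
    data.frame(
      study = sprintf("synthetic_trial_%02d", i),
      arm = c(reference, trt),
      events = c(
        stats::rbinom(1, n_per_arm, baseline_risk),
        stats::rbinom(1, n_per_arm, risks[i])
      ),
      n = n_per_arm, outcome = outcome, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  structure(out, provenance = list(
    generator = "generate_nma_trials", seed = as.integer(seed),
    true_rrs = true_rrs, baseline_risk = baseline_risk, n_per_arm = n_per_arm
  ))
}
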