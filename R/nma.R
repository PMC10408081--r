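# Fixed-effect network meta-analysis of relative risks on the log scale.
# Contrasts are inverse-variance weighted and pooled by weighted least
# squares over the treatment design matrix; on a star network this reduces
# to pairwise pooling per edge plus Bucher indirect comparisons through the
# common comparator. The four-trial star behind the packaged relative risks
# is too small for a stable random-effects fit, so only the fixed-effect
# model is implemented, with Cochran's Q reported for heterogeneity
# diagnostics.

#' Relative-risk contrast from 2x2 arm counts
#'
#' `logRR = log((e_t/n_t)/(e_c/n_c))` with the large-sample standard error
#' `sqrt(1/e_t - 1/n_t + 1/e_c - 1/n_c)`. Zero cells in one arm receive the
#' usual 0.5 continuity correction (added to both cells of both arms); a
#' contrast with zero events in both arms carries no information and is
#' rejected with a warning.
#'
#' @param study Study identifier.
#' @param treatment,comparator Arm labels.
#' @param events_t,n_t Events and sample size in the treatment arm.
#' @param events_c,n_c Events and sample size in the comparator arm.
#' @param outcome Outcome label (e.g. `"response_rate"`, `"mortality"`).
#' @return One-row data frame of class `trial_contrast`: `study`,
#'   `treatment`, `comparator`, `log_rr`, `se`, `outcome`; or `NULL` (with a
#'   warning) for a double-zero table.
#' @examples
#' contrast_from_counts("s1", "A", "B", 20, 100, 10, 100)
#' @export
contrast_from_counts <- function(study, treatment, comparator,
                                 events_t, n_t, events_c, n_c,
                                 outcome = "response_rate") {
  stopifnot(n_t > 0, n_c > 0, events_t >= 0, events_c >= 0,
    events_t <= n_t, events_c <= n_c)
  if (events_t == 0 && events_c == 0) {
    warning("study ", study, ": zero events in both arms; contrast excluded")
    return(NULL)
  }
  if (events_t == 0 || events_c == 0) {
    events_t <- events_t + 0.5; n_t <- n_t + 1
    events_c <- events_c + 0.5; n_c <- n_c + 1
  }
  log_rr <- log((events_t / n_t) / (events_c / n_c))
  se <- sqrt(1 / events_t - 1 / n_t + 1 / events_c - 1 / n_c)
  structure(
    data.frame(
      study = study, treatment = treatment, comparator = comparator,
      log_rr = log_rr, se = se, outcome = outcome,
      stringsAsFactors = FALSE
    ),
    class = c("trial_contrast", "data.frame")
  )
}

#' Build contrasts from an arm-level trial table
#'
#' @param trials Data frame with columns `study`, `arm`, `events`, `n`,
#'   `outcome`; each (study, outcome) must have exactly two arms, the first
#'   taken as comparator.
#' @param comparator_arm Optional arm name forced as comparator where present.
#' @return Data frame of contrasts (one per study and outcome).
#' @export
contrasts_from_trials <- function(trials, comparator_arm = NULL) {
  req <- c("study", "arm", "events", "n", "outcome")
  if (!all(req %in% names(trials))) {
    stop("trial table must have columns: ", paste(req, collapse = ", "))
  }
  keys <- unique(trials[, c("study", "outcome")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- trials[trials$study == keys$study[i] & trials$outcome == keys$outcome[i], ]
    if (nrow(sub) != 2) {
      stop("study ", keys$study[i], " / ", keys$outcome[i],
        " must have exactly two arms")
    }
    if (!is.null(comparator_arm) && comparator_arm %in% sub$arm) {
      sub <- sub[order(sub$arm != comparator_arm), ]
    }
    contrast_from_counts(
      keys$study[i], sub$arm[2], sub$arm[1],
      sub$events[2], sub$n[2], sub$events[1], sub$n[1],
      outcome = keys$outcome[i]
    )
  })
  do.call(rbind, rows)
}

# connectivity of the contrast network to the reference (simple BFS)
check_connected <- function(contrasts, reference) {
  nodes <- unique(c(contrasts$treatment, contrasts$comparator, reference))
  reached <- reference
  repeat {
    nxt <- unique(c(
      contrasts$treatment[contrasts$comparator %in% reached],
      contrasts$comparator[contrasts$treatment %in% reached]
    ))
    new <- setdiff(nxt, reached)
    if (length(new) == 0) break
    reached <- c(reached, new)
  }
  isolated <- setdiff(nodes, reached)
  if (length(isolated) > 0) {
    stop("network disconnected from reference '", reference, "': ",
      paste(isolated, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fixed-effect network meta-analysis of relative risks
#'
#' Inverse-variance weighted least squares of the log-RR contrasts on the
#' treatment design matrix (one column per non-reference treatment, +1 for
#' the contrast's treatment, -1 for its comparator). Returns pooled RRs
#' versus the reference with Wald confidence intervals and p-values, and
#' Cochran's Q as a heterogeneity/inconsistency diagnostic.
#'
#' @param contrasts Data frame of contrasts (see [contrast_from_counts()]),
#'   single outcome.
#' @param reference Reference treatment (pooled RR fixed at 1).
#' @param conf_level Confidence level for the Wald intervals.
#' @return Data frame of class `nma_result`: `treatment`, `rr`, `ci_lower`,
#'   `ci_upper`, `p_value` (reference row included with RR 1), with
#'   attributes `Q`, `Q_df`.
#' @export
fixed_effect_nma <- function(contrasts, reference, conf_level = 0.95) {
  if (is.null(contrasts) || nrow(contrasts) == 0) stop("no contrasts supplied")
  if (any(contrasts$se <= 0)) stop("contrast standard errors must be > 0")
  if (length(unique(contrasts$outcome)) > 1) {
    stop("pool one outcome at a time")
  }
  check_connected(contrasts, reference)
  treatments <- setdiff(
    unique(c(contrasts$treatment, contrasts$comparator)), reference
  )
  X <- matrix(0, nrow(contrasts), length(treatments),
    dimnames = list(NULL, treatments)
  )
  for (i in seq_len(nrow(contrasts))) {
    if (contrasts$treatment[i] != reference) X[i, contrasts$treatment[i]] <- 1
    if (contrasts$comparator[i] != reference) X[i, contrasts$comparator[i]] <- -1
  }
  w <- 1 / contrasts$se^2
  y <- contrasts$log_rr
  XtWX <- crossprod(X, X * w)
  est <- solve(XtWX, crossprod(X, y * w))[, 1]
  vcov <- solve(XtWX)
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  resid <- y - X %*% est
  Q <- sum(w * resid^2)
  out <- data.frame(
    treatment = c(reference, treatments),
    rr = c(1, exp(est)),
    ci_lower = c(1, exp(est - z * se)),
    ci_upper = c(1, exp(est + z * se)),
    p_value = c(NA, 2 * stats::pnorm(-abs(est / se))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
    class = c("nma_result", "data.frame"),
    Q = Q, Q_df = max(nrow(contrasts) - length(treatments), 0),
    reference = reference
  )
}
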