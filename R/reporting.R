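# End-to-end orchestration: base-case cost-effectiveness in all
# perspectives, tornado DSA, PSA with CEAC, and the budget-impact
# projection, written as full-precision CSVs plus a rendered markdown
# report. Report numbers are formatted from the same objects written to
# CSV; nothing is recomputed in the renderer.

#' Run the full analysis pipeline
#'
#' Executes the base-case cost-effectiveness analysis (societal, healthcare
#' and payer perspectives), the one-way deterministic sensitivity analysis,
#' the probabilistic sensitivity analysis with CEAC, and the budget-impact
#' projection, writing `ce_table.csv`, `trace_<strategy>.csv`,
#' `tornado.csv`, `psa_outcomes.csv`, `psa_draws.csv`, `ceac.csv`,
#' `bia.csv`, `bia_incremental.csv`, `report.md` and `manifest.json` to
#' `out_dir`.
#'
#' @param config_source Passed to [load_model_config()]; `NULL` for the
#'   packaged default.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the PSA.
#' @param psa_iterations PSA iterations (published analysis: 5000; the
#'   scaled preset 1000 matches the published scatter-plot caption).
#' @param skip Character vector of stages to skip among `"psa"`, `"dsa"`,
#'   `"bia"`.
#' @return The run manifest (list with config hash, seed, output files),
#'   invisibly; also written as `manifest.json`.
#' @export
run_full_analysis <- function(config_source = NULL, out_dir,
                              seed = 20180801L, psa_iterations = 1000,
                              skip = character()) {
  config <- load_model_config(config_source)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
    files <<- c(files, name)
    path
  }
  ref <- config$settings$reference_strategy

  # base case, all perspectives
  ce_rows <- list()
  for (persp in PERSPECTIVES) {
    outs <- run_base_case(config, perspective = persp)
    ce <- incremental_analysis(outs, ref)
    ce$perspective <- persp
    ce_rows[[persp]] <- ce
  }
  ce_all <- do.call(rbind, lapply(ce_rows, as.data.frame))
  emit(ce_all, "ce_table.csv")
  for (st in STRATEGIES) {
    emit(run_cohort(st, config), sprintf("trace_%s.csv", st))
  }

  tornado <- NULL
  if (!"dsa" %in% skip) {
    tornado <- one_way_dsa(config)
    emit(tornado, "tornado.csv")
  }
  psa <- ceac <- NULL
  if (!"psa" %in% skip) {
    psa <- run_psa(config, psa_iterations, seed = seed)
    emit(psa$outcomes, "psa_outcomes.csv")
    emit(as.data.frame(psa$draws), "psa_draws.csv")
    ceac <- compute_ceac(psa, reference_strategy = ref)
    emit(ceac, "ceac.csv")
  }
  bia <- NULL
  if (!"bia" %in% skip) {
    bia <- run_bia(config)
    emit(bia$comparison[, c("year", "cost_scenario_1", "cost_scenario_2")],
      "bia.csv")
    emit(bia$comparison[, c("year", "increment")], "bia_incremental.csv")
  }

  report <- render_ce_report(
    ce_rows$societal, default_thresholds(config),
    ceac = ceac, tornado = tornado, bia = bia
  )
  writeLines(report, file.path(out_dir, "report.md"))
  files <- c(files, "report.md")

  manifest <- list(
    config_hash = config_digest(config),
    seed = as.integer(seed),
    psa_iterations = if ("psa" %in% skip) NULL else psa_iterations,
    reference_strategy = ref,
    package_version = as.character(utils::packageVersion("cetuxcea")),
    outputs = files
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

# order-stable content hash of the configuration (no external digest dep)
config_digest <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- as.numeric(utf8ToInt(as.character(s)))
  h <- c(17, 31) # double-precision rolling hash; intermediates stay < 2^53
  for (b in bytes) {
    h[1] <- (h[1] * 131 + b) %% 1000000007
    h[2] <- (h[2] * 137 + b) %% 998244353
  }
  sprintf("%09.0f%09.0f", h[1], h[2])
}

#' Render the cost-effectiveness report
#'
#' Formats a cost-effectiveness table with per-threshold verdicts as
#' markdown. Values come straight from the supplied objects; display
#' rounding happens only here.
#'
#' @param ce_table A `ce_table` from [incremental_analysis()].
#' @param thresholds Data frame with `label` and `value` columns.
#' @param ceac,tornado,bia Optional stage outputs summarized in the report.
#' @return Character vector of markdown lines.
#' @export
render_ce_report <- function(ce_table, thresholds, ceac = NULL,
                             tornado = NULL, bia = NULL) {
  ref <- attr(ce_table, "reference_strategy")
  fmt <- function(x, digits = 0) {
    ifelse(is.na(x), "", formatC(x, format = "f", digits = digits, big.mark = ","))
  }
  lines <- c(
    "# Cost-effectiveness results",
    "",
    sprintf("Reference strategy: %s (societal perspective).", ref),
    "",
    "| Strategy | Cost (IDR) | LY | QALY | ICER/LY | ICER/QALY |",
    "|---|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(ce_table))) {
    r <- ce_table[i, ]
    lines <- c(lines, sprintf(
      "| %s%s | %s | %s | %s | %s | %s |",
      r$strategy, if (r$reference) " (ref)" else "",
      fmt(r$cost), fmt(r$ly, 2), fmt(r$qaly, 2),
      fmt(r$icer_ly), fmt(r$icer_qaly)
    ))
  }
  lines <- c(lines, "", "## Decision at willingness-to-pay thresholds", "")
  for (j in seq_len(nrow(thresholds))) {
    lam <- thresholds$value[j]
    for (i in which(!ce_table$reference)) {
      verdict <- if (classify_cost_effective(ce_table$icer_qaly[i], lam) &&
        ce_table$dominance[i] == "none") {
        "cost-effective"
      } else {
        "not cost-effective"
      }
      lines <- c(lines, sprintf(
        "- %s at %s (%s IDR/QALY): %s",
        ce_table$strategy[i], thresholds$label[j], fmt(lam), verdict
      ))
    }
  }
  if (!is.null(ceac)) {
    lam0 <- thresholds$value[1]
    at <- ceac[which.min(abs(ceac$threshold - lam0)), "threshold"][1]
    sub <- ceac[ceac$threshold == at, ]
    cet <- sub[grepl("CETUX", sub$strategy), ]
    lines <- c(lines, "", "## Probabilistic sensitivity analysis", "", sprintf(
      "Combined probability that a cetuximab-containing strategy is optimal at %s IDR/QALY: %.1f%%.",
      fmt(at), 100 * sum(cet$probability)
    ))
  }
  if (!is.null(tornado)) {
    top <- utils::head(tornado$parameter, 5)
    lines <- c(lines, "", "## One-way sensitivity analysis", "", sprintf(
      "Widest ICER ranges: %s.", paste(top, collapse = ", ")
    ))
  }
  if (!is.null(bia)) {
    lines <- c(lines, "", "## Budget impact (payer, 5 years, undiscounted)", "", sprintf(
      "- Cetuximab covered: %s IDR", fmt(attr(bia$comparison, "cumulative_1"))
    ), sprintf(
      "- Chemotherapy only: %s IDR", fmt(attr(bia$comparison, "cumulative_2"))
    ), sprintf(
      "- Incremental: %s IDR", fmt(attr(bia$comparison, "cumulative_increment"))
    ))
  }
  lines
}

#' Scatter of the PSA incremental cloud (cost-effectiveness plane)
#'
#' Optional ggplot2 figure; the analysis never depends on rendered
#' graphics.
#'
#' @param psa A `psa_result`.
#' @param reference_strategy Reference strategy.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, reference_strategy = "FOLFIRI") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  inc <- psa_incremental(psa, reference_strategy)
  ggplot2::ggplot(inc, ggplot2::aes(
    x = .data$inc_qaly, y = .data$inc_cost, colour = .data$strategy
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost (IDR)",
      colour = NULL
    )
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac A `ceac_curve`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(ceac, ggplot2::aes(
    x = .data$threshold, y = .data$probability, colour = .data$strategy
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Willingness to pay (IDR/QALY)",
      y = "Probability cost-effective", colour = NULL
    )
}
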