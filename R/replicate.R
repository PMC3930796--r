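# End-to-end pipeline: design -> simulate -> fit -> post-estimation ->
# survey analyses -> report, fully reproducible from one master seed.

#' Derive a stage seed from the master seed
#'
#' Stable hash of (master seed, stage name) so stages can be re-run
#' independently yet reproducibly. Always returns a positive integer below
#' 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param stage Stage name (character).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(master)) * 7919 + h) %% 2147483629 + 1)
}

#' Pipeline configuration
#'
#' @param schema Attribute schema (default [build_default_schema()]).
#' @param n_blocks,scenarios_per_block Design shape (default 8 x 8).
#' @param population A `population_spec` (default
#'   [importance_calibration()]: 252 respondents, heterogeneity 0.25 I).
#' @param sampler An `hb_config`; its seed is overridden by a stage seed
#'   derived from `master_seed`.
#' @param base_a,base_b Base-case products for the sensitivity analysis, as
#'   named level-label vectors. Defaults: every attribute at its middle
#'   level with cost $50 (A) and $100 (B).
#' @param prices A `price_config`.
#' @param statements Attitude statements (default [attitude_statements()]).
#' @param attitude_group_effects Optional per-group mean shifts for the
#'   attitude generator.
#' @param master_seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(schema = build_default_schema(),
                       n_blocks = 8L, scenarios_per_block = 8L,
                       population = importance_calibration(schema),
                       sampler = hb_config(),
                       base_a = NULL, base_b = NULL,
                       prices = price_config(),
                       statements = attitude_statements(),
                       attitude_group_effects = c("Treated" = 0.25,
                                                  "Treatment-naive" = 0),
                       master_seed = 1L) {
  mid <- function(cost_label) {
    labs <- vapply(schema$attributes, function(a) {
      a$levels[ceiling(a$n_levels / 2)]
    }, character(1))
    if ("cost" %in% names(labs)) labs["cost"] <- cost_label
    labs
  }
  if (is.null(base_a)) base_a <- mid("$50")
  if (is.null(base_b)) base_b <- mid("$100")
  structure(list(schema = schema, n_blocks = as.integer(n_blocks),
                 scenarios_per_block = as.integer(scenarios_per_block),
                 population = population, sampler = sampler,
                 base_a = base_a, base_b = base_b, prices = prices,
                 statements = statements,
                 attitude_group_effects = attitude_group_effects,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Run the full replication pipeline
#'
#' Chains design generation, block assignment, respondent/choice/price/
#' attitude simulation, the hierarchical Bayesian fit, importance / share /
#' sensitivity post-estimation and the cost and attitude analyses, writing
#' all artifacts plus a machine-readable `report.json` and a human-readable
#' `report.md` to `out_dir`. Re-running with the same configuration
#' reproduces identical outputs. A stage failure halts the run with the
#' stage name; artifacts written so far are retained and listed in
#' `manifest.json`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files and return results only.
#' @return Invisibly, a list with every stage result plus `report` (the
#'   report structure).
#' @export
replicate_study <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  written <- character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_csv <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    write_manifest()
  }
  write_manifest <- function() {
    if (is.null(out_dir)) return(invisible(NULL))
    jsonlite::write_json(list(files = basename(written)),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sd <- function(nm) derive_seed(config$master_seed, nm)

  plan <- stage("design", generate_design(
    config$schema, config$n_blocks, config$scenarios_per_block,
    seed = sd("design")))
  bal <- balance_report(plan)
  if (!is.null(out_dir)) {
    written <- c(written, write_design(plan, file.path(out_dir, "design")))
    write_manifest()
  }

  profiles <- stage("respondents",
                    simulate_respondents(config$population,
                                         seed = sd("respondents")))
  assignment <- stage("assign",
                      assign_blocks(plan, profiles$info,
                                    seed = sd("assign")))

  choices <- stage("choices",
                   simulate_choices(profiles, plan, assignment,
                                    seed = sd("choices")))
  emit_csv(merge(choices, assignment[, c("respondent_id", "block")],
                 by = c("respondent_id", "block")), "choices.csv")

  price_records <- stage("prices",
                         simulate_price_responses(profiles, config$prices,
                                                  seed = sd("prices")))
  emit_csv(price_records, "prices.csv")

  attitude_records <- stage("attitudes", simulate_attitudes(
    profiles, config$statements,
    group_effects = config$attitude_group_effects,
    seed = sd("attitudes")))
  emit_csv(attitude_records, "attitudes.csv")

  sampler <- config$sampler
  sampler$seed <- sd("mcmc")
  dataset <- stage("coding", choice_dataset(choices, plan))
  draws <- stage("mcmc", run_mcmc(dataset, sampler))
  est <- posterior_point_estimates(draws)
  diag <- diagnostics(draws)
  betas_df <- data.frame(respondent_id = rownames(est$beta),
                         group = profiles$info$group[
                           match(rownames(est$beta),
                                 profiles$info$respondent_id)],
                         est$beta)
  names(betas_df)[-(1:2)] <- paste0("b", seq_len(ncol(est$beta)))
  emit_csv(betas_df, "betas.csv")

  imp <- stage("importance", relative_importance(est$beta, config$schema))
  by_group <- lapply(split(seq_len(nrow(est$beta)),
                           profiles$info$group), function(idx) {
    relative_importance(est$beta[idx, , drop = FALSE],
                        config$schema)$aggregate
  })
  imp_table <- data.frame(attribute = names(imp$aggregate),
                          total = unname(imp$aggregate))
  for (g in names(by_group)) imp_table[[make.names(g)]] <- by_group[[g]]
  emit_csv(imp_table, "importance.csv")

  shares <- stage("shares", preference_shares(
    est$beta, list(A = config$base_a, B = config$base_b), config$schema))
  emit_csv(data.frame(product = names(shares$aggregate),
                      share_pct = unname(shares$aggregate)), "shares.csv")

  sens <- stage("sensitivity", sensitivity_analysis(
    est$beta, config$base_a, config$base_b, config$schema))
  emit_csv(sens, "sensitivity.csv")

  curve <- stage("cost_curve", willingness_curve(price_records))
  emit_csv(curve, "cost_curve.csv")
  betas_cost <- lapply(c(list(NULL),
                         as.list(sort(unique(price_records$group)))),
                       function(g) {
    cb <- cost_beta(price_records, group = g,
                    price_window = c(100, 250))
    data.frame(group = cb$group, slope = cb$slope,
               intercept = cb$intercept, se = cb$se,
               window_lo = cb$price_window[1],
               window_hi = cb$price_window[2], n_obs = cb$n_obs)
  })
  cost_table <- do.call(rbind, betas_cost)
  emit_csv(cost_table, "cost_beta.csv")

  groups <- sort(unique(attitude_records$group))
  att <- stage("attitude_tests",
               compare_attitudes(attitude_records, groups[1], groups[2]))
  emit_csv(att, "attitudes_summary.csv")

  report <- list(
    master_seed = config$master_seed,
    design = list(n_scenarios = nrow(plan$scenarios),
                  n_blocks = plan$n_blocks,
                  scenarios_per_block = plan$scenarios_per_block,
                  n_duplicates = bal$n_duplicates,
                  max_imbalance = max(bal$imbalance$imbalance)),
    mcmc = list(n_chains = sampler$n_chains, n_iter = sampler$n_iter,
                n_burnin = sampler$n_burnin, thin = sampler$thin,
                max_rhat = max(diag$rhat, na.rm = TRUE),
                min_ess = min(diag$ess, na.rm = TRUE),
                mean_accept = mean(unlist(lapply(draws$chains,
                                                 `[[`, "accept_rate")))),
    importance = imp_table,
    shares = as.list(shares$aggregate),
    sensitivity = sens,
    cost = list(beta = cost_table,
                pct_willing_at_100 =
                  curve$pct_willing[curve$group == "All" &
                                      curve$price_usd == 100],
                pct_willing_at_150 =
                  curve$pct_willing[curve$group == "All" &
                                      curve$price_usd == 150]),
    attitudes = att)

  if (!is.null(out_dir)) {
    rp <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = 10,
                         dataframe = "rows")
    written <- c(written, rp)
    md <- file.path(out_dir, "report.md")
    writeLines(format_report_md(report), md)
    written <- c(written, md)
    write_manifest()
  }

  invisible(list(plan = plan, balance = bal, profiles = profiles,
                 assignment = assignment, choices = choices,
                 prices = price_records, attitudes = attitude_records,
                 draws = draws, estimates = est, diagnostics = diag,
                 importance = imp, importance_table = imp_table,
                 shares = shares, sensitivity = sens, cost_curve = curve,
                 cost_beta = cost_table, attitude_tests = att,
                 report = report))
}

format_report_md <- function(report) {
  pct <- function(x) sprintf("%.1f", x)
  lines <- c(
    "# Treatment-preference replication report",
    "",
    sprintf("Master seed: %d", report$master_seed),
    "",
    "## Design",
    sprintf("- %d scenarios in %d blocks of %d; duplicates: %d; max per-block level imbalance: %d",
            report$design$n_scenarios, report$design$n_blocks,
            report$design$scenarios_per_block, report$design$n_duplicates,
            report$design$max_imbalance),
    "",
    "## MCMC",
    sprintf("- %d chains x %d iterations (burn-in %d, thin %d); max R-hat %.3f; min ESS %.0f; mean acceptance %.2f",
            report$mcmc$n_chains, report$mcmc$n_iter, report$mcmc$n_burnin,
            report$mcmc$thin, report$mcmc$max_rhat, report$mcmc$min_ess,
            report$mcmc$mean_accept),
    "",
    "## Relative importance (% of total)",
    paste0("| attribute | ",
           paste(setdiff(names(report$importance), "attribute"),
                 collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(report$importance)), collapse = "|"),
           "|"))
  for (i in seq_len(nrow(report$importance))) {
    row <- report$importance[i, ]
    lines <- c(lines, paste0(
      "| ", row$attribute, " | ",
      paste(vapply(row[-1], function(v) pct(as.numeric(v)), character(1)),
            collapse = " | "), " |"))
  }
  lines <- c(lines, "",
             "## Base-case shares (%)",
             paste(sprintf("- %s: %s", names(report$shares),
                           vapply(report$shares, pct, character(1))),
                   collapse = "\n"),
             "",
             "## Cost sensitivity",
             sprintf("- willingness (top-2-box) at $100: %s %%; at $150: %s %%",
                     pct(report$cost$pct_willing_at_100),
                     pct(report$cost$pct_willing_at_150)))
  for (i in seq_len(nrow(report$cost$beta))) {
    b <- report$cost$beta[i, ]
    lines <- c(lines, sprintf(
      "- OLS slope (%s, $%g-$%g): %.4f score points per dollar (se %.4f)",
      b$group, b$window_lo, b$window_hi, b$slope, b$se))
  }
  lines
}

#' Validate pipeline input files
#'
#' Checks column schemas, Likert score ranges, level-label membership and
#' block/scenario referential integrity of `choices.csv`, `prices.csv` and
#' `attitudes.csv` against a design plan and schema. Violations are data,
#' not errors.
#'
#' @param dir Directory containing the CSV files (any may be absent).
#' @param schema An `attribute_schema`.
#' @param plan A `design_plan` (for scenario/block integrity and level
#'   labels in `design.csv`).
#' @return Data frame of violations (file, rule, detail); zero rows when
#'   clean.
#' @export
validate_inputs <- function(dir, schema, plan = NULL) {
  v <- list()
  bad <- function(file, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(file = file, rule = rule,
                                       detail = detail)
  }
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      bad(file, "missing_columns", paste(miss, collapse = ","))
      FALSE
    } else TRUE
  }

  cpath <- file.path(dir, "choices.csv")
  if (file.exists(cpath)) {
    ch <- utils::read.csv(cpath)
    if (need(ch, c("respondent_id", "block", "scenario_id", "choice"),
             "choices.csv")) {
      if (!all(ch$choice %in% c("A", "B"))) {
        bad("choices.csv", "invalid_choice",
            paste(unique(setdiff(ch$choice, c("A", "B"))), collapse = ","))
      }
      if (!is.null(plan)) {
        unknown <- setdiff(ch$scenario_id, plan$scenarios$scenario_id)
        for (u in unknown) {
          bad("choices.csv", "unknown_scenario", as.character(u))
        }
        ok <- ch$scenario_id %in% plan$scenarios$scenario_id
        blk <- plan$scenarios$block[match(ch$scenario_id,
                                          plan$scenarios$scenario_id)]
        mism <- ok & !is.na(blk) & blk != ch$block
        if (any(mism)) {
          bad("choices.csv", "block_scenario_mismatch",
              paste(utils::head(ch$scenario_id[mism], 5L), collapse = ","))
        }
      }
    }
  }

  ppath <- file.path(dir, "prices.csv")
  if (file.exists(ppath)) {
    pr <- utils::read.csv(ppath)
    if (need(pr, c("respondent_id", "group", "price_usd", "score"),
             "prices.csv")) {
      if (!all(pr$score %in% 1:5)) {
        bad("prices.csv", "score_out_of_range",
            paste(unique(setdiff(pr$score, 1:5)), collapse = ","))
      }
    }
  }

  apath <- file.path(dir, "attitudes.csv")
  if (file.exists(apath)) {
    at <- utils::read.csv(apath)
    if (need(at, c("respondent_id", "group", "statement_id", "score"),
             "attitudes.csv")) {
      if (!all(at$score %in% 1:5)) {
        bad("attitudes.csv", "score_out_of_range",
            paste(unique(setdiff(at$score, 1:5)), collapse = ","))
      }
    }
  }

  dpath <- file.path(dir, "design.csv")
  if (file.exists(dpath)) {
    de <- utils::read.csv(dpath, check.names = FALSE)
    for (nm in names(schema$attributes)) {
      if (!nm %in% names(de)) {
        bad("design.csv", "missing_columns", nm)
        next
      }
      unknown <- setdiff(unique(de[[nm]]), schema$attributes[[nm]]$levels)
      for (u in unknown) {
        bad("design.csv", "unknown_level", paste0(nm, ": '", u, "'"))
      }
    }
  }

  if (!length(v)) {
    data.frame(file = character(0), rule = character(0),
               detail = character(0))
  } else {
    do.call(rbind, v)
  }
}
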