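# Cost-sensitivity and treatment-attitude survey analyses.

#' Willingness (top-2-box) curve over price
#'
#' Per price point and group (and overall), the percentage of respondents
#' scoring in the top two Likert categories ("quite likely"/"definitely",
#' i.e. score >= `cutoff`). When the measured grid contains $250 and $500,
#' the unmeasured $300–$450 points are filled in by linear interpolation
#' between those two measurements and flagged `extrapolated` (the
#' dotted-line portion of the willingness curve).
#'
#' @param records Price-response data frame (respondent_id, group,
#'   price_usd, score); every respondent must score every measured price
#'   (respondents with incomplete coverage are dropped with a warning).
#' @param cutoff Top-box cutoff score (default 4).
#' @param extrapolate_at Prices to fill in between $250 and $500 (default
#'   $300, $350, $400, $450; ignored unless both anchors were measured).
#' @return Data frame: group ("All" plus each group), price_usd,
#'   pct_willing, extrapolated.
#' @export
willingness_curve <- function(records, cutoff = 4L,
                              extrapolate_at = c(300, 350, 400, 450)) {
  stopifnot(all(c("respondent_id", "group", "price_usd", "score") %in%
                  names(records)))
  grid <- sort(unique(records$price_usd))
  cov <- table(records$respondent_id)
  incomplete <- names(cov)[cov < length(grid)]
  if (length(incomplete)) {
    warning(length(incomplete),
            " respondent(s) lack full price coverage; excluded")
    records <- records[!records$respondent_id %in% incomplete, ]
  }
  records$willing <- records$score >= cutoff

  one_curve <- function(df, gname) {
    pct <- vapply(grid, function(pr) {
      100 * mean(df$willing[df$price_usd == pr])
    }, numeric(1))
    out <- data.frame(group = gname, price_usd = grid, pct_willing = pct,
                      extrapolated = FALSE)
    if (all(c(250, 500) %in% grid) && length(extrapolate_at)) {
      v <- stats::approx(c(250, 500),
                         pct[match(c(250, 500), grid)],
                         xout = extrapolate_at)$y
      out <- rbind(out, data.frame(group = gname,
                                   price_usd = extrapolate_at,
                                   pct_willing = v, extrapolated = TRUE))
    }
    out[order(out$price_usd), ]
  }

  out <- one_curve(records, "All")
  for (g in sort(unique(records$group))) {
    out <- rbind(out, one_curve(records[records$group == g, ], g))
  }
  rownames(out) <- NULL
  out
}

#' Linear cost-sensitivity model
#'
#' Ordinary least squares of the Likert likelihood score on price (USD),
#' over respondent-price observations inside a price window — the reported
#' "beta" of the cost-sensitivity analysis. The slope is in score points
#' per dollar (so doubling all prices halves it).
#'
#' @param records Price-response data frame.
#' @param group Optional group label to subset on (default: all records).
#' @param price_window Length-2 numeric, inclusive window on price; default
#'   the full measured range.
#' @return List of class `cost_beta`: group, slope, intercept, se (slope
#'   standard error), price_window, n_obs.
#' @export
cost_beta <- function(records, group = NULL, price_window = NULL) {
  if (!is.null(group)) records <- records[records$group == group, ]
  if (is.null(price_window)) {
    price_window <- range(records$price_usd)
  }
  records <- records[records$price_usd >= price_window[1] &
                       records$price_usd <= price_window[2], ]
  prices <- unique(records$price_usd)
  if (length(prices) < 2L) {
    stop("need at least 2 distinct prices in the window, got ",
         length(prices))
  }
  fit <- stats::lm(score ~ price_usd, data = records)
  # exact lines trigger a harmless "perfect fit" note from summary.lm
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(group = if (is.null(group)) "All" else group,
                 slope = unname(stats::coef(fit)["price_usd"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 se = unname(sm["price_usd", "Std. Error"]),
                 price_window = price_window,
                 n_obs = nrow(records)),
            class = "cost_beta")
}

#' @export
print.cost_beta <- function(x, ...) {
  cat(sprintf(
    "Cost sensitivity (%s): slope %.4f score points/$ (se %.4f), window $%g-$%g, n = %d\n",
    x$group, x$slope, x$se, x$price_window[1], x$price_window[2], x$n_obs))
  invisible(x)
}

#' Summarize stated maximum acceptable prices
#'
#' @param max_prices Numeric vector of per-respondent maximum acceptable
#'   monthly costs (USD, non-negative).
#' @return List: mean, median, n.
#' @export
max_price_summary <- function(max_prices) {
  if (!length(max_prices)) stop("no maximum prices supplied")
  if (any(max_prices < 0)) stop("negative prices are invalid")
  list(mean = mean(max_prices), median = stats::median(max_prices),
       n = length(max_prices))
}

#' Group comparison of attitude statements
#'
#' Per statement, a Welch two-sample two-tailed t-test of mean agreement
#' between two respondent groups, plus top-2-box agreement proportions
#' ("mostly"/"completely agree", score >= 4). When both groups are constant
#' with equal means the comparison is degenerate and reported as t = 0,
#' p = 1.
#'
#' @param records Attitude data frame (respondent_id, group, statement_id,
#'   score).
#' @param group_a,group_b Group labels to compare.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @param adjust `"none"` (default; no multiplicity correction) or
#'   `"bonferroni"` across statements.
#' @return Data frame: statement_id, mean_a, mean_b, top2_pct_a,
#'   top2_pct_b, t, df, p_value, significant.
#' @export
compare_attitudes <- function(records, group_a, group_b, alpha = 0.05,
                              adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("group", "statement_id", "score") %in% names(records)))
  out <- lapply(unique(records$statement_id), function(sid) {
    xa <- records$score[records$statement_id == sid &
                          records$group == group_a]
    xb <- records$score[records$statement_id == sid &
                          records$group == group_b]
    if (!length(xa) || !length(xb)) {
      stop("empty group for statement ", sid)
    }
    va <- stats::var(xa); vb <- stats::var(xb)
    if ((is.na(va) || va == 0) && (is.na(vb) || vb == 0)) {
      # both groups constant: degenerate comparison
      eq <- isTRUE(all.equal(mean(xa), mean(xb)))
      tt <- list(statistic = if (eq) 0 else Inf,
                 parameter = NA_real_, p.value = if (eq) 1 else 0)
    } else {
      ht <- stats::t.test(xa, xb, var.equal = FALSE)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(statement_id = sid,
               mean_a = mean(xa), mean_b = mean(xb),
               top2_pct_a = 100 * mean(xa >= 4),
               top2_pct_b = 100 * mean(xb >= 4),
               t = tt$statistic, df = tt$parameter, p_value = tt$p.value)
  })
  out <- do.call(rbind, out)
  if (adjust == "bonferroni") {
    out$p_value <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  out$significant <- out$p_value < alpha
  out
}
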