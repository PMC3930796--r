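# Post-estimation: range-method relative importance, logit preference
# shares, and one-attribute-at-a-time sensitivity.

#' Per-attribute part-worth ranges
#'
#' Reconstructs every level part-worth from the effect-coded vector (the
#' omitted level equals minus the sum of the others) and returns
#' `max - min` per attribute. Location shifts of an attribute's part-worths
#' leave its range unchanged; scaling all betas by c > 0 scales every range
#' by c.
#'
#' @param beta Effect-coded part-worth vector (length `coding_dim(schema)`).
#' @param schema An `attribute_schema`.
#' @return Named numeric vector of ranges.
#' @export
attribute_ranges <- function(beta, schema) {
  pw <- decode_partworths(schema, beta)
  vapply(pw, function(w) max(w) - min(w), numeric(1))
}

#' Range-method relative importance
#'
#' Per respondent, importance = 100 * range / sum(ranges); both the
#' per-respondent vectors and the aggregate sum to 100. Respondents whose
#' ranges are all zero carry no preference information and are excluded
#' with a warning.
#'
#' @param betas Matrix of per-respondent part-worth vectors (rows), or a
#'   single vector.
#' @param schema An `attribute_schema`.
#' @param aggregate `"normalize_first"` (default: normalize each respondent
#'   to 100, then average — the individual-level emphasis) or
#'   `"range_mean"` (average ranges across respondents, then normalize).
#' @return An `importance_result`: `per_respondent` matrix (percent) and
#'   `aggregate` named vector (percent, summing to 100).
#' @export
relative_importance <- function(betas, schema,
                                aggregate = c("normalize_first",
                                              "range_mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1L)
  stopifnot(nrow(betas) >= 1L)
  ranges <- t(apply(betas, 1L, attribute_ranges, schema = schema))
  tot <- rowSums(ranges)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sum(zero), " respondent(s) with all-zero ranges excluded")
    ranges <- ranges[!zero, , drop = FALSE]
    tot <- tot[!zero]
    if (!nrow(ranges)) stop("no respondents with non-zero ranges")
  }
  per <- 100 * ranges / tot
  agg <- if (aggregate == "normalize_first") colMeans(per)
         else 100 * colMeans(ranges) / sum(colMeans(ranges))
  agg <- 100 * agg / sum(agg)  # guard normalization drift
  structure(list(per_respondent = per, aggregate = agg,
                 aggregate_rule = aggregate),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Relative importance (%% of total, n =",
      nrow(x$per_respondent), "respondents):\n")
  ord <- order(x$aggregate, decreasing = TRUE)
  for (j in ord) {
    cat(sprintf("  %-17s %5.1f\n", names(x$aggregate)[j], x$aggregate[j]))
  }
  invisible(x)
}

# softmax shares of a utility matrix (respondents x products)
softmax_shares <- function(U) {
  U <- U - apply(U, 1L, max)
  E <- exp(U)
  E / rowSums(E)
}

#' Share of preference over a product set
#'
#' Logit rule (default): respondent i's share of product k is
#' `exp(x_k' beta_i) / sum_j exp(x_j' beta_i)`; shares are then averaged
#' over respondents and expressed in percent, so individual and aggregate
#' shares each sum to 100. For two products the logit share equals the
#' logistic of the utility difference, matching the choice likelihood. The
#' `"first_choice"` rule instead gives each respondent's full share to
#' their maximum-utility product (ties split equally).
#'
#' @param betas Matrix of per-respondent part-worth vectors (rows).
#' @param products List of products (integer level-index vectors or named
#'   label vectors accepted by [product_from_labels()]); at least 2,
#'   all distinct.
#' @param schema An `attribute_schema`.
#' @param rule `"logit"` or `"first_choice"`.
#' @return A `share_result`: `per_respondent` matrix and `aggregate` vector
#'   (percent).
#' @export
preference_shares <- function(betas, products, schema,
                              rule = c("logit", "first_choice")) {
  rule <- match.arg(rule)
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1L)
  if (length(products) < 2L) stop("need at least 2 products")
  prods <- lapply(products, function(pr) {
    if (is.character(pr) || is.list(pr)) product_from_labels(schema, pr)
    else validate_product(schema, pr)
  })
  keys <- vapply(prods, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) stop("duplicate products in the set")

  X <- t(vapply(prods, function(pr) encode_product(schema, pr),
                numeric(coding_dim(schema))))
  U <- betas %*% t(X)  # respondents x products
  per <- if (rule == "logit") {
    softmax_shares(U)
  } else {
    t(apply(U, 1L, function(u) {
      w <- as.numeric(u == max(u))
      w / sum(w)
    }))
  }
  nm <- if (!is.null(names(products))) names(products)
        else paste0("product_", seq_along(products))
  colnames(per) <- nm
  structure(list(per_respondent = 100 * per,
                 aggregate = 100 * colMeans(per),
                 products = prods, rule = rule),
            class = "share_result")
}

#' One-attribute-at-a-time sensitivity analysis
#'
#' Starting from base-case configurations of products A and B, flexes one
#' attribute of one product at a time through each of its levels (all other
#' attributes held at base case) and records the aggregate two-product
#' logit shares. The row at the base-case level reproduces the unflexed
#' base-case share exactly.
#'
#' @param betas Matrix of per-respondent part-worth vectors (rows).
#' @param base_a,base_b Base-case products (level-index vectors or named
#'   label vectors).
#' @param schema An `attribute_schema`.
#' @return Data frame: product ("A"/"B"), attribute, level index, level
#'   label, is_base, share_a, share_b (percent, aggregate).
#' @export
sensitivity_analysis <- function(betas, base_a, base_b, schema) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1L)
  as_prod <- function(pr) {
    if (is.character(pr) || is.list(pr)) product_from_labels(schema, pr)
    else validate_product(schema, pr)
  }
  base_a <- as_prod(base_a)
  base_b <- as_prod(base_b)

  two_shares <- function(pa, pb) {
    d <- encode_product(schema, pa) - encode_product(schema, pb)
    sa <- mean(stats::plogis(as.numeric(betas %*% d)))
    c(a = 100 * sa, b = 100 * (1 - sa))
  }

  out <- list()
  for (side in c("A", "B")) {
    for (j in seq_along(schema$attributes)) {
      att <- schema$attributes[[j]]
      for (lv in seq_len(att$n_levels)) {
        pa <- base_a; pb <- base_b
        if (side == "A") pa[j] <- lv else pb[j] <- lv
        sh <- two_shares(pa, pb)
        out[[length(out) + 1L]] <- data.frame(
          product = side, attribute = att$name, level = lv,
          level_label = att$levels[lv],
          is_base = lv == (if (side == "A") base_a[j] else base_b[j]),
          share_a = sh[["a"]], share_b = sh[["b"]])
      }
    }
  }
  do.call(rbind, out)
}
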