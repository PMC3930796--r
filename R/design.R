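# Blocked, level-balanced paired-choice designs.
#
# A plan holds n_blocks x scenarios_per_block paired scenarios. Within each
# block the 2 * scenarios_per_block product slots carry every level of every
# attribute as equally often as divisibility allows (imbalance <= 1), no
# scenario pairs a product with itself, and no scenario is repeated anywhere
# in the plan (compared as unordered product pairs).

scenario_key <- function(a, b) {
  ka <- paste(a, collapse = ",")
  kb <- paste(b, collapse = ",")
  if (ka < kb) paste(ka, kb, sep = "|") else paste(kb, ka, sep = "|")
}

# Balanced level column for one attribute over n_slots: counts differ by <= 1.
balanced_column <- function(n_levels, n_slots) {
  base <- rep(seq_len(n_levels), length.out = n_slots)
  sample(base)
}

# Sum over attribute pairs of absolute deviations of the pairwise level
# cross-tabulation from uniform, over the block's product slots. The swap
# polish minimizes this as an orthogonality proxy.
crosstab_deviation <- function(slots, L) {
  K <- ncol(slots)
  dev <- 0
  n <- nrow(slots)
  for (j in seq_len(K - 1L)) {
    for (k in (j + 1L):K) {
      tab <- table(factor(slots[, j], levels = seq_len(L[j])),
                   factor(slots[, k], levels = seq_len(L[k])))
      dev <- dev + sum(abs(tab - n / (L[j] * L[k])))
    }
  }
  dev
}

block_ok <- function(slots, used_keys) {
  n_scen <- nrow(slots) / 2L
  keys <- character(n_scen)
  for (s in seq_len(n_scen)) {
    a <- slots[2L * s - 1L, ]
    b <- slots[2L * s, ]
    if (all(a == b)) return(NULL)
    keys[s] <- scenario_key(a, b)
  }
  if (anyDuplicated(keys) || any(keys %in% used_keys)) return(NULL)
  keys
}

#' Generate a blocked, level-balanced paired-choice design
#'
#' Builds `n_blocks` blocks of `scenarios_per_block` paired scenarios by a
#' seeded greedy construction: per block, each attribute's levels are spread
#' over the `2 * scenarios_per_block` product slots so occurrence counts
#' differ by at most one, slots are paired into scenarios, and a swap-based
#' polish (exchanging two slots' levels within one attribute, which preserves
#' balance) reduces the deviation of pairwise level cross-tabulations from
#' uniform. Candidate blocks that pair a product with itself or repeat a
#' scenario already in the plan (as an unordered pair) are rejected.
#'
#' @param schema An `attribute_schema`.
#' @param n_blocks Number of blocks (default 8).
#' @param scenarios_per_block Scenarios per block (default 8).
#' @param seed Integer seed; the plan is a pure function of
#'   (schema, shape, seed).
#' @param polish_steps Swap proposals per block for the orthogonality polish.
#' @return A `design_plan`: schema, scenario table, level-index matrices
#'   `a_levels`/`b_levels` (one row per scenario), and the seed.
#' @examples
#' plan <- generate_design(build_default_schema(), 8, 8, seed = 1)
#' nrow(plan$scenarios)  # 64
#' @export
generate_design <- function(schema, n_blocks = 8L, scenarios_per_block = 8L,
                            seed = 1L, polish_steps = 200L) {
  stopifnot(inherits(schema, "attribute_schema"),
            n_blocks >= 1L, scenarios_per_block >= 1L)
  L <- level_counts(schema)
  n_slots <- 2L * scenarios_per_block
  if (n_slots < max(L)) {
    worst <- names(schema$attributes)[which.max(L)]
    stop("cannot balance attribute '", worst, "': ", max(L),
         " levels but only ", n_slots, " product slots per block")
  }
  K <- length(L)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  used_keys <- character(0)
  a_levels <- b_levels <- matrix(0L, 0L, K)
  blocks <- integer(0)

  for (blk in seq_len(n_blocks)) {
    slots <- NULL
    for (attempt in seq_len(1000L)) {
      cand <- vapply(seq_len(K),
                     function(j) balanced_column(L[j], n_slots),
                     integer(n_slots))
      keys <- block_ok(cand, used_keys)
      if (!is.null(keys)) { slots <- cand; break }
    }
    if (is.null(slots)) {
      stop("failed to build block ", blk, " without duplicate scenarios")
    }

    # swap polish: improve orthogonality while keeping balance and validity
    dev <- crosstab_deviation(slots, L)
    for (step in seq_len(polish_steps)) {
      j <- sample.int(K, 1L)
      ij <- sample.int(n_slots, 2L)
      if (slots[ij[1], j] == slots[ij[2], j]) next
      cand <- slots
      cand[ij, j] <- cand[rev(ij), j]
      if (is.null(block_ok(cand, used_keys))) next
      cand_dev <- crosstab_deviation(cand, L)
      if (cand_dev < dev) { slots <- cand; dev <- cand_dev }
    }

    keys <- block_ok(slots, used_keys)
    used_keys <- c(used_keys, keys)
    odd <- seq(1L, n_slots, by = 2L)
    a_levels <- rbind(a_levels, slots[odd, , drop = FALSE])
    b_levels <- rbind(b_levels, slots[odd + 1L, , drop = FALSE])
    blocks <- c(blocks, rep(blk, scenarios_per_block))
  }

  colnames(a_levels) <- colnames(b_levels) <- names(schema$attributes)
  structure(
    list(schema = schema,
         scenarios = data.frame(block = blocks,
                                scenario_id = seq_along(blocks)),
         a_levels = a_levels, b_levels = b_levels,
         n_blocks = as.integer(n_blocks),
         scenarios_per_block = as.integer(scenarios_per_block),
         seed = as.integer(seed)),
    class = "design_plan"
  )
}

#' @export
print.design_plan <- function(x, ...) {
  cat("Paired-choice design plan:", x$n_blocks, "blocks x",
      x$scenarios_per_block, "scenarios (seed", paste0(x$seed, ")\n"))
  rep <- balance_report(x)
  cat("  duplicate scenarios:", rep$n_duplicates,
      "| max per-block imbalance:", max(rep$imbalance$imbalance), "\n")
  invisible(x)
}

#' Balance and orthogonality diagnostics for a design plan
#'
#' @param plan A `design_plan`.
#' @return A list with `level_counts` (block x attribute x level occurrence
#'   counts over product slots), `imbalance` (per block and attribute,
#'   max - min level count), `n_duplicates` (scenarios repeated anywhere in
#'   the plan, as unordered product pairs; 0 for a valid plan), and
#'   `crosstab` (per attribute pair, the summed absolute deviation of the
#'   global pairwise level cross-tab from uniform).
#' @export
balance_report <- function(plan) {
  stopifnot(inherits(plan, "design_plan"))
  schema <- plan$schema
  L <- level_counts(schema)
  K <- length(L)
  attrs <- names(schema$attributes)

  counts <- list(); imb <- list()
  for (blk in sort(unique(plan$scenarios$block))) {
    rows <- plan$scenarios$block == blk
    slots <- rbind(plan$a_levels[rows, , drop = FALSE],
                   plan$b_levels[rows, , drop = FALSE])
    for (j in seq_len(K)) {
      tab <- tabulate(slots[, j], nbins = L[j])
      counts[[length(counts) + 1L]] <- data.frame(
        block = blk, attribute = attrs[j],
        level = schema$attributes[[j]]$levels, count = tab)
      imb[[length(imb) + 1L]] <- data.frame(
        block = blk, attribute = attrs[j],
        imbalance = max(tab) - min(tab))
    }
  }

  keys <- vapply(seq_len(nrow(plan$a_levels)), function(s) {
    scenario_key(plan$a_levels[s, ], plan$b_levels[s, ])
  }, character(1))

  all_slots <- rbind(plan$a_levels, plan$b_levels)
  ct <- list()
  for (j in seq_len(K - 1L)) {
    for (k in (j + 1L):K) {
      tab <- table(factor(all_slots[, j], levels = seq_len(L[j])),
                   factor(all_slots[, k], levels = seq_len(L[k])))
      ct[[length(ct) + 1L]] <- data.frame(
        attribute_1 = attrs[j], attribute_2 = attrs[k],
        abs_deviation = sum(abs(tab - nrow(all_slots) / (L[j] * L[k]))))
    }
  }

  list(level_counts = do.call(rbind, counts),
       imbalance = do.call(rbind, imb),
       n_duplicates = sum(duplicated(keys)),
       crosstab = do.call(rbind, ct))
}

#' Assign respondents to design blocks
#'
#' Round-robin within each respondent group over a seeded shuffle, so that
#' within every group the per-block assignment counts differ by at most one
#' (each block is seen by an equal-as-possible number of Treated and
#' Treatment-naive respondents).
#'
#' @param plan A `design_plan`.
#' @param respondents Data frame with columns `respondent_id` and `group`.
#' @param seed Integer seed.
#' @return `respondents` with an added integer `block` column.
#' @export
assign_blocks <- function(plan, respondents, seed = 1L) {
  stopifnot(inherits(plan, "design_plan"))
  if (!is.data.frame(respondents) || nrow(respondents) == 0L) {
    stop("respondents must be a non-empty data frame")
  }
  stopifnot(all(c("respondent_id", "group") %in% names(respondents)))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  respondents$block <- NA_integer_
  for (g in unique(respondents$group)) {
    idx <- which(respondents$group == g)
    idx <- idx[sample.int(length(idx))]
    respondents$block[idx] <- rep(seq_len(plan$n_blocks),
                                  length.out = length(idx))
  }
  respondents
}

#' Write a design plan to JSON and a flat CSV
#'
#' The JSON carries blocks -> scenarios -> 1-based level indices per product;
#' the CSV is long format (block, scenario_id, alternative A/B, one column
#' per attribute holding the level label).
#'
#' @param plan A `design_plan`.
#' @param prefix Path prefix; writes `<prefix>.json` and `<prefix>.csv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_design <- function(plan, prefix) {
  schema <- plan$schema
  blocks <- lapply(sort(unique(plan$scenarios$block)), function(blk) {
    rows <- which(plan$scenarios$block == blk)
    list(block = blk, scenarios = lapply(rows, function(s) {
      list(scenario_id = plan$scenarios$scenario_id[s],
           product_a = as.integer(plan$a_levels[s, ]),
           product_b = as.integer(plan$b_levels[s, ]))
    }))
  })
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(n_blocks = plan$n_blocks,
         scenarios_per_block = plan$scenarios_per_block,
         seed = plan$seed,
         attributes = names(schema$attributes),
         blocks = blocks),
    json_path, auto_unbox = TRUE, pretty = TRUE)

  lab <- function(mat) {
    out <- as.data.frame(mat)
    for (j in seq_along(schema$attributes)) {
      out[[j]] <- schema$attributes[[j]]$levels[mat[, j]]
    }
    out
  }
  csv <- rbind(
    cbind(plan$scenarios, alternative = "A", lab(plan$a_levels)),
    cbind(plan$scenarios, alternative = "B", lab(plan$b_levels)))
  csv <- csv[order(csv$scenario_id, csv$alternative), ]
  csv_path <- paste0(prefix, ".csv")
  utils::write.csv(csv, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Read a design plan from its JSON form
#'
#' @param path JSON file written by [write_design()].
#' @param schema The `attribute_schema` the plan was built under.
#' @return A `design_plan`.
#' @export
read_design <- function(path, schema) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(unlist(obj$attributes), names(schema$attributes))) {
    stop("design attributes do not match the supplied schema")
  }
  K <- n_attributes(schema)
  blocks <- integer(0); ids <- integer(0)
  a_levels <- b_levels <- matrix(0L, 0L, K)
  for (blk in obj$blocks) {
    for (s in blk$scenarios) {
      blocks <- c(blocks, as.integer(blk$block))
      ids <- c(ids, as.integer(s$scenario_id))
      a_levels <- rbind(a_levels, as.integer(unlist(s$product_a)))
      b_levels <- rbind(b_levels, as.integer(unlist(s$product_b)))
    }
  }
  colnames(a_levels) <- colnames(b_levels) <- names(schema$attributes)
  ord <- order(ids)
  structure(
    list(schema = schema,
         scenarios = data.frame(block = blocks[ord], scenario_id = ids[ord]),
         a_levels = a_levels[ord, , drop = FALSE],
         b_levels = b_levels[ord, , drop = FALSE],
         n_blocks = as.integer(obj$n_blocks),
         scenarios_per_block = as.integer(obj$scenarios_per_block),
         seed = as.integer(obj$seed)),
    class = "design_plan"
  )
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
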