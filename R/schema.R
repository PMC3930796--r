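#' Construct a single conjoint attribute
#'
#' An attribute is a named characteristic of a hypothetical product with an
#' ordered set of 3 or 4 discrete levels (e.g. monthly out-of-pocket cost at
#' $0/$50/$100/$150). Level labels are kept verbatim; no numeric value is
#' imputed for labels such as "< 1 %".
#'
#' @param name Short unique identifier (e.g. `"kidney_risk"`).
#' @param description Free-text description shown to respondents.
#' @param levels Character vector of level display labels, in presentation
#'   order. Must contain 3 or 4 unique labels.
#' @param higher_better Logical; whether larger levels are preferable.
#'   Used only by the calibration generator to orient part-worths; the
#'   choice model itself is fully categorical.
#' @return An object of class `attribute_spec`.
#' @export
attribute_spec <- function(name, description, levels, higher_better = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (anyDuplicated(levels)) {
    stop("duplicate level labels in attribute '", name, "'")
  }
  if (length(levels) < 3L || length(levels) > 4L) {
    stop("attribute '", name, "' must have 3 or 4 levels, got ",
         length(levels))
  }
  structure(
    list(name = name, description = as.character(description),
         levels = levels, n_levels = length(levels),
         higher_better = isTRUE(higher_better)),
    class = "attribute_spec"
  )
}

#' Construct an attribute schema
#'
#' @param attributes List of [attribute_spec()] objects, in the order used
#'   for coding and reporting.
#' @return An object of class `attribute_schema`.
#' @export
attribute_schema <- function(attributes) {
  stopifnot(length(attributes) >= 1L)
  if (!all(vapply(attributes, inherits, logical(1), "attribute_spec"))) {
    stop("all elements must be attribute_spec objects")
  }
  nms <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("attribute names must be unique")
  names(attributes) <- nms
  structure(list(attributes = attributes), class = "attribute_schema")
}

#' The default chronic hepatitis B oral-antiviral attribute schema
#'
#' Six attributes describing hypothetical oral antiviral treatments:
#' long-term (5-year) efficacy, 5-year risk of bone thinning, 5-year risk of
#' kidney damage, number of patients treated worldwide, years approved on the
#' US market, and monthly out-of-pocket cost. Cost has four levels; all other
#' attributes have three.
#'
#' @return An `attribute_schema` with six attributes and 13 free coefficients
#'   under effect coding.
#' @examples
#' sch <- build_default_schema()
#' coding_dim(sch)  # 13
#' @export
build_default_schema <- function() {
  attribute_schema(list(
    attribute_spec(
      "efficacy",
      "Probability that the medicine will continue to work well for 5 years",
      c("71 %", "85 %", "92 %"), higher_better = TRUE),
    attribute_spec(
      "bone_risk",
      "Probability of thinning of bones after 5 years on the medicine",
      c("< 1 %", "7 %", "14 %"), higher_better = FALSE),
    attribute_spec(
      "kidney_risk",
      "Probability of kidney damage after 5 years on the medicine",
      c("< 1 %", "10 %", "20 %"), higher_better = FALSE),
    attribute_spec(
      "patients_treated",
      "Number of patients prescribed the medicine worldwide",
      c("100,000", "200,000", "400,000"), higher_better = TRUE),
    attribute_spec(
      "years_market",
      "Years the medicine has been approved in the US",
      c("2 years", "4 years", "6 years"), higher_better = TRUE),
    attribute_spec(
      "cost",
      "Monthly out-of-pocket cost, assuming at least 12 months of treatment",
      c("$0", "$50", "$100", "$150"), higher_better = FALSE)
  ))
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat("Attribute schema:", length(x$attributes), "attributes,",
      coding_dim(x), "effect-coded coefficients\n")
  for (a in x$attributes) {
    cat(sprintf("  %-17s [%s]\n", a$name, paste(a$levels, collapse = " | ")))
  }
  invisible(x)
}

#' Number of attributes in a schema
#' @param schema An `attribute_schema`.
#' @return Integer.
#' @export
n_attributes <- function(schema) length(schema$attributes)

#' Per-attribute level counts
#' @param schema An `attribute_schema`.
#' @return Named integer vector.
#' @export
level_counts <- function(schema) {
  vapply(schema$attributes, `[[`, integer(1), "n_levels")
}

#' Dimension of the effect-coded coefficient space
#'
#' Each attribute with L levels contributes L - 1 free coefficients under
#' sum-to-zero (effect) coding; the default schema has p = 13.
#'
#' @param schema An `attribute_schema`.
#' @return Integer p.
#' @export
coding_dim <- function(schema) sum(level_counts(schema) - 1L)

# Column offsets of each attribute's coded sub-vector: attribute j occupies
# columns offsets[j] + 1 .. offsets[j] + n_levels[j] - 1.
coding_offsets <- function(schema) {
  L <- level_counts(schema)
  c(0L, cumsum(L - 1L))[seq_along(L)]
}

#' Validate a product against a schema
#'
#' A product is an integer vector of level indices (1-based, one per
#' attribute, in schema order). Attribute names may be used instead via
#' [product_from_labels()].
#'
#' @param schema An `attribute_schema`.
#' @param product Integer vector of level indices.
#' @return The product, as a named integer vector.
#' @export
validate_product <- function(schema, product) {
  L <- level_counts(schema)
  if (length(product) != length(L)) {
    stop("product must have one level index per attribute (",
         length(L), "), got ", length(product))
  }
  product <- as.integer(product)
  bad <- which(product < 1L | product > L)
  if (length(bad)) {
    stop("invalid level index for attribute '",
         schema$attributes[[bad[1]]]$name, "': ", product[bad[1]],
         " (valid: 1..", L[bad[1]], ")")
  }
  stats::setNames(product, names(schema$attributes))
}

#' Build a product from level labels
#'
#' @param schema An `attribute_schema`.
#' @param labels Named character vector or list, `attribute name -> level
#'   label`; every attribute must be present and the label must match a
#'   schema level exactly (including whitespace).
#' @return Named integer vector of level indices.
#' @export
product_from_labels <- function(schema, labels) {
  labels <- unlist(labels)
  idx <- vapply(names(schema$attributes), function(nm) {
    if (!nm %in% names(labels)) stop("missing attribute '", nm, "'")
    i <- match(labels[[nm]], schema$attributes[[nm]]$levels)
    if (is.na(i)) {
      stop("unknown level '", labels[[nm]], "' for attribute '", nm, "'")
    }
    i
  }, integer(1))
  validate_product(schema, idx)
}

#' Effect-code a single product
#'
#' Sum-to-zero coding: within an attribute of L levels, level i < L maps to
#' the indicator sub-vector with 1 at position i, and the last level maps to
#' a sub-vector of all -1. Sub-vectors are concatenated in schema order.
#' Codes for one attribute sum to the zero vector over its levels, and the
#' map is injective over valid products.
#'
#' @param schema An `attribute_schema`.
#' @param product Integer vector of 1-based level indices (one per attribute).
#' @return Numeric vector of length `coding_dim(schema)`.
#' @export
encode_product <- function(schema, product) {
  product <- validate_product(schema, product)
  L <- level_counts(schema)
  out <- numeric(coding_dim(schema))
  off <- coding_offsets(schema)
  for (j in seq_along(L)) {
    cols <- off[j] + seq_len(L[j] - 1L)
    if (product[j] < L[j]) {
      out[cols[product[j]]] <- 1
    } else {
      out[cols] <- -1
    }
  }
  out
}

#' Effect-code a matrix of products
#'
#' @param schema An `attribute_schema`.
#' @param products Integer matrix, one row per product, one column per
#'   attribute.
#' @return Numeric matrix with `coding_dim(schema)` columns.
#' @export
encode_products <- function(schema, products) {
  products <- as.matrix(products)
  t(apply(products, 1L, function(r) encode_product(schema, r)))
}

#' Reconstruct per-level part-worths from an effect-coded vector
#'
#' Inverts the coding: the first L - 1 level part-worths of an attribute are
#' its coded coefficients and the last level equals minus their sum, so each
#' attribute's part-worths sum to zero.
#'
#' @param schema An `attribute_schema`.
#' @param beta Numeric vector of length `coding_dim(schema)`.
#' @return Named list, one numeric vector of level part-worths per attribute
#'   (named by level label).
#' @export
decode_partworths <- function(schema, beta) {
  p <- coding_dim(schema)
  if (length(beta) != p) {
    stop("beta must have length ", p, ", got ", length(beta))
  }
  L <- level_counts(schema)
  off <- coding_offsets(schema)
  out <- vector("list", length(L))
  names(out) <- names(schema$attributes)
  for (j in seq_along(L)) {
    w <- beta[off[j] + seq_len(L[j] - 1L)]
    w <- c(w, -sum(w))
    names(w) <- schema$attributes[[j]]$levels
    out[[j]] <- w
  }
  out
}

#' Write a schema to JSON
#' @param schema An `attribute_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attribute_schema <- function(schema, path) {
  obj <- lapply(schema$attributes, function(a) {
    list(name = a$name, description = a$description, levels = a$levels,
         higher_better = a$higher_better)
  })
  jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a schema from JSON
#' @param path File written by [write_attribute_schema()] (or hand-authored
#'   with fields name, description, levels, optional higher_better).
#' @return An `attribute_schema`.
#' @export
read_attribute_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  attribute_schema(lapply(obj, function(a) {
    attribute_spec(a$name, a$description, unlist(a$levels),
                   higher_better = isTRUE(a$higher_better))
  }))
}
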