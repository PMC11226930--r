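#' Element-wise dissimilarity for a categorical variable
#'
#' Codes are opaque labels compared for equality only: the contribution is
#' 0 when the two codes match and 1 otherwise.
#'
#' @param a,b Codes (coerced to character).
#' @param codes Optional allowed-code set; when supplied, both codes are
#'   checked against it.
#' @return 0 or 1.
#' @export
#' @examples
#' categorical_element_dissimilarity("1", "3") # mismatch -> 1
categorical_element_dissimilarity <- function(a, b, codes = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (!is.null(codes)) {
    bad <- setdiff(c(a, b), as.character(codes))
    if (length(bad)) stop("code(s) outside allowed set: ", paste(bad, collapse = ", "))
  }
  as.numeric(a != b)
}

#' Element-wise dissimilarity for a numerical variable
#'
#' The absolute difference divided by the variable's theoretical range
#' `R`, clipped to \[0, 1\]. A degenerate variable (zero range) falls back
#' to the categorical rule: 0 if equal, 1 otherwise.
#'
#' @param a,b Scores in the variable's native units.
#' @param R Theoretical range (max - min) of the variable.
#' @param degenerate Set `TRUE` for a zero-range variable.
#' @return Contribution in \[0, 1\].
#' @export
#' @examples
#' numerical_element_dissimilarity(3, 5, R = 4) # hospital-size codes -> 0.5
numerical_element_dissimilarity <- function(a, b, R, degenerate = FALSE) {
  if (degenerate) return(as.numeric(a != b))
  if (!is.finite(R) || R <= 0) stop("range R must be > 0 for a non-degenerate variable")
  min(abs(a - b) / R, 1)
}

#' Profile-level dissimilarity with per-element breakdown
#'
#' Sums the element contributions over the requested variables: 0/1 for
#' categorical mismatches, range-scaled absolute differences for
#' numerical variables. Each variable enters with unit weight, so the
#' total lies in \[0, number of variables\]; under the default schema the
#' attainable maximum is 22. Smaller totals mean more similar profiles.
#' Values outside a variable's declared range contribute at most 1 and
#' raise a warning (validation happens at ingest; here robustness wins).
#'
#' @param existing,new `participant_profile`s complete for `vars`.
#' @param schema A `feature_schema`.
#' @param vars Variable names to compare; default all schema variables.
#'   `stage = 2` restricts to the stage-2 subset instead.
#' @param stage Optional recommendation stage (1 or 2) selecting the
#'   variable subset when `vars` is `NULL`.
#' @return A `dissimilarity_breakdown`: list with `per_element` (named
#'   contributions in \[0, 1\]) and `total`.
#' @export
#' @examples
#' pair <- extreme_profile_pair(default_schema())
#' profile_dissimilarity(pair$low, pair$high, default_schema())$total
profile_dissimilarity <- function(existing, new, schema, vars = NULL, stage = NULL) {
  stopifnot(inherits(existing, "participant_profile"),
            inherits(new, "participant_profile"),
            inherits(schema, "feature_schema"))
  if (is.null(vars)) vars <- schema_vars(schema, stage)
  v <- schema$variables
  per <- stats::setNames(numeric(length(vars)), vars)
  warned <- FALSE
  for (nm in vars) {
    i <- schema_var_row(schema, nm)
    if (v$kind[i] == "categorical") {
      a <- existing$categorical_values[[nm]]
      b <- new$categorical_values[[nm]]
      if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) {
        stop("missing value for variable '", nm, "'")
      }
      per[nm] <- categorical_element_dissimilarity(a, b)
    } else {
      a <- existing$numerical_values[[nm]]
      b <- new$numerical_values[[nm]]
      if (is.null(a) || is.null(b) || !is.finite(a) || !is.finite(b)) {
        stop("missing value for variable '", nm, "'")
      }
      if (!warned && (a < v$min[i] || a > v$max[i] || b < v$min[i] || b > v$max[i])) {
        warning("value outside declared range for variable '", nm,
                "'; contribution clipped at 1")
        warned <- TRUE
      }
      per[nm] <- numerical_element_dissimilarity(a, b, v$range[i], v$degenerate[i])
    }
  }
  structure(list(per_element = per, total = sum(per)),
            class = "dissimilarity_breakdown")
}

#' @export
print.dissimilarity_breakdown <- function(x, ...) {
  cat("<dissimilarity_breakdown> total =", format(x$total), "\n")
  print(round(x$per_element, 3))
  invisible(x)
}

#' Rank knowledge-base records by dissimilarity to a new profile
#'
#' Computes the profile dissimilarity between the new participant and the
#' profile stored in every (optionally filtered) valid record, and returns
#' the records in ascending order of total dissimilarity — the smaller the
#' total, the more similar the stored user. Ties are broken by lower
#' insertion index (the earliest stored record) for determinism.
#'
#' An empty candidate set is a cold-start signal, not an error: the
#' returned table has zero rows and `attr(, "cold_start")` is `TRUE`.
#'
#' @param kb A `knowledge_base`.
#' @param new A `participant_profile`.
#' @param stage Recommendation stage (1 or 2) selecting the comparison
#'   variables; ignored when `vars` is given.
#' @param vars Optional explicit variable subset.
#' @param candidate_filter Optional predicate `function(valid_record)`.
#' @return A data frame with one row per candidate record (columns
#'   `rank`, `insertion_index`, `participant_id`, `program`,
#'   `effective_subdimension`, `reduction`, `dissimilarity`), ordered
#'   ascending; attribute `cold_start` marks an empty candidate set.
#' @export
rank_records <- function(kb, new, stage = 1, vars = NULL, candidate_filter = NULL) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(new, "participant_profile"))
  schema <- kb$schema
  if (is.null(vars)) vars <- schema_vars(schema, stage)

  idx <- seq_along(kb$records)
  if (!is.null(candidate_filter) && length(idx)) {
    keep <- vapply(kb$records, function(r) isTRUE(candidate_filter(r)), TRUE)
    idx <- idx[keep]
  }
  if (length(idx) == 0) {
    out <- data.frame(
      rank = integer(0), insertion_index = integer(0),
      participant_id = character(0), program = character(0),
      effective_subdimension = character(0), reduction = numeric(0),
      dissimilarity = numeric(0), stringsAsFactors = FALSE
    )
    attr(out, "cold_start") <- TRUE
    return(out)
  }

  v <- schema$variables
  cols <- match(vars, v$name)
  feats <- kb$features[idx, cols, drop = FALSE]
  newf <- profile_features(new, schema)[cols]

  contrib <- matrix(0, nrow = length(idx), ncol = length(cols))
  for (j in seq_along(cols)) {
    i <- cols[j]
    contrib[, j] <- if (v$kind[i] == "categorical" || v$degenerate[i]) {
      as.numeric(feats[, j] != newf[j])
    } else {
      pmin(abs(feats[, j] - newf[j]) / v$range[i], 1)
    }
  }
  totals <- rowSums(contrib)

  ins <- vapply(kb$records[idx], function(r) r$insertion_index, 0L)
  ord <- order(totals, ins)
  out <- data.frame(
    rank = seq_along(ord),
    insertion_index = ins[ord],
    participant_id = vapply(kb$records[idx][ord],
                            function(r) r$profile$participant_id, ""),
    program = vapply(kb$records[idx][ord], function(r) r$program, ""),
    effective_subdimension = vapply(kb$records[idx][ord],
                                    function(r) r$effective_subdimension, ""),
    reduction = vapply(kb$records[idx][ord], function(r) r$reduction, 0),
    dissimilarity = totals[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "cold_start") <- FALSE
  out
}
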