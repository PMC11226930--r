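#' Construct a validated participant profile
#'
#' One participant's feature vector at a given assessment point. Every
#' schema variable must be present exactly once, categorical codes must
#' belong to the variable's allowed set, and numerical values must fall
#' inside the declared theoretical range.
#'
#' @param schema A `feature_schema`.
#' @param participant_id Opaque identifier (coerced to character).
#' @param categorical Named vector/list of categorical codes.
#' @param numerical Named numeric vector/list of numerical scores.
#' @param assessment_point One of `"pretest"`, `"posttest1"`, `"posttest2"`.
#' @return A `participant_profile`.
#' @export
participant_profile <- function(schema, participant_id, categorical, numerical,
                                assessment_point = "pretest") {
  stopifnot(inherits(schema, "feature_schema"))
  assessment_point <- match.arg(assessment_point, .assessment_points)
  v <- schema$variables

  cat_names <- v$name[v$kind == "categorical"]
  num_names <- v$name[v$kind == "numerical"]

  categorical <- vapply(as.list(categorical), as.character, "")
  numerical <- vapply(as.list(numerical), as.numeric, 0)

  miss <- setdiff(cat_names, names(categorical))
  if (length(miss)) stop("missing categorical value(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(num_names, names(numerical))
  if (length(miss)) stop("missing numerical value(s): ", paste(miss, collapse = ", "))
  extra <- c(setdiff(names(categorical), cat_names), setdiff(names(numerical), num_names))
  if (length(extra)) stop("value(s) for undeclared variable(s): ", paste(extra, collapse = ", "))

  categorical <- categorical[cat_names]
  numerical <- numerical[num_names]

  for (nm in cat_names) {
    if (!categorical[[nm]] %in% schema$codes[[nm]]) {
      stop("code '", categorical[[nm]], "' not allowed for variable '", nm, "'")
    }
  }
  for (nm in num_names) {
    i <- schema_var_row(schema, nm)
    x <- numerical[[nm]]
    if (!is.finite(x)) stop("non-finite value for variable '", nm, "'")
    if (x < v$min[i] || x > v$max[i]) {
      stop("value ", x, " outside [", v$min[i], ", ", v$max[i],
           "] for variable '", nm, "'")
    }
  }

  structure(
    list(
      participant_id = as.character(participant_id),
      categorical_values = categorical,
      numerical_values = numerical,
      assessment_point = assessment_point
    ),
    class = "participant_profile"
  )
}

#' @export
print.participant_profile <- function(x, ...) {
  cat("<participant_profile> id=", x$participant_id,
      " @", x$assessment_point, "\n", sep = "")
  cat("  categorical:",
      paste(names(x$categorical_values), x$categorical_values,
            sep = "=", collapse = " "), "\n")
  cat("  numerical:  ",
      paste(names(x$numerical_values), signif(x$numerical_values, 4),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Numeric feature vector aligned to the schema's variable order;
# categorical codes are encoded by their index in the allowed-code set,
# so equality of encodings is equality of codes.
profile_features <- function(profile, schema) {
  v <- schema$variables
  out <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    nm <- v$name[i]
    out[i] <- if (v$kind[i] == "categorical") {
      match(profile$categorical_values[[nm]], schema$codes[[nm]])
    } else {
      profile$numerical_values[[nm]]
    }
  }
  names(out) <- v$name
  out
}

# Normalized burnout subdimension scores held in a profile's role-tagged
# variables, as c(personal=, work=, client=).
profile_burnout <- function(profile, schema) {
  bv <- burnout_vars(schema)
  stats::setNames(as.numeric(profile$numerical_values[bv]), names(bv))
}

#' Burnout scores stored in a profile
#'
#' Reads the normalized burnout subdimension values from a profile's
#' role-tagged variables and returns them as a `burnout_scores` object.
#'
#' @param profile A `participant_profile`.
#' @param schema A `feature_schema` with burnout role tags.
#' @return A `burnout_scores`.
#' @export
profile_burnout_scores <- function(profile, schema) {
  n <- profile_burnout(profile, schema)
  burnout_from_normalized(n[["personal"]], n[["work"]], n[["client"]])
}

# Copy of a profile with its burnout variables replaced by new normalized
# scores, advanced to the given assessment point.
profile_with_burnout <- function(profile, schema, normalized, assessment_point) {
  bv <- burnout_vars(schema)
  num <- profile$numerical_values
  num[bv] <- as.numeric(normalized[names(bv)])
  participant_profile(schema, profile$participant_id,
                      profile$categorical_values, num, assessment_point)
}

#' Serialize / deserialize a participant profile
#'
#' Lossless JSON round trip used by the stores and the command-line tools.
#'
#' @param profile A `participant_profile`.
#' @param json A JSON string produced by `profile_to_json()`.
#' @param schema A `feature_schema` used to re-validate on read.
#' @return `profile_to_json()`: a JSON string; `profile_from_json()`: a
#'   `participant_profile`.
#' @export
profile_to_json <- function(profile) {
  jsonlite::toJSON(
    list(
      participant_id = profile$participant_id,
      assessment_point = profile$assessment_point,
      categorical_values = as.list(profile$categorical_values),
      numerical_values = as.list(profile$numerical_values)
    ),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname profile_to_json
#' @export
profile_from_json <- function(json, schema) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  participant_profile(schema, x$participant_id,
                      unlist(x$categorical_values), unlist(x$numerical_values),
                      x$assessment_point)
}

#' A maximally different profile pair under a schema
#'
#' Constructs two profiles that mismatch on every categorical variable and
#' sit at opposite ends of every numerical variable's range, so their
#' profile dissimilarity attains the upper bound (number of variables;
#' 22 under the default schema). Requires every categorical variable to
#' declare at least two codes and no degenerate numerical ranges.
#'
#' @param schema A `feature_schema`.
#' @return List of two `participant_profile`s (`low`, `high`).
#' @export
#' @examples
#' pair <- extreme_profile_pair(default_schema())
#' profile_dissimilarity(pair$low, pair$high, default_schema())$total
extreme_profile_pair <- function(schema) {
  v <- schema$variables
  cat_lo <- cat_hi <- character(0)
  for (nm in v$name[v$kind == "categorical"]) {
    cd <- schema$codes[[nm]]
    if (length(cd) < 2) stop("variable '", nm, "' has a single code; no mismatch possible")
    cat_lo[nm] <- cd[1]
    cat_hi[nm] <- cd[2]
  }
  num_idx <- which(v$kind == "numerical")
  num_lo <- stats::setNames(v$min[num_idx], v$name[num_idx])
  num_hi <- stats::setNames(v$max[num_idx], v$name[num_idx])
  list(
    low = participant_profile(schema, "extreme_low", cat_lo, num_lo),
    high = participant_profile(schema, "extreme_high", cat_hi, num_hi)
  )
}
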