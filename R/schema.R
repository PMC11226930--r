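#' Load a feature schema from a configuration file or list
#'
#' A feature schema declares the participant variables the recommender
#' compares: categorical variables carry a set of allowed codes (opaque
#' labels, compared for equality only), numerical variables carry a
#' theoretical `min`/`max` whose difference is the range `R` used to scale
#' absolute differences. Ranges are fixed by the schema, never estimated
#' from data, so dissimilarities stay stable as the knowledge base grows.
#'
#' The configuration is a YAML or JSON file (or an equivalent list) with a
#' top-level `variables` sequence; each entry has `name`, `kind`
#' (`"categorical"` or `"numerical"`), `codes` (categorical) or
#' `min`/`max` (numerical), optional `stage2` (logical; membership in the
#' reduced stage-2 comparison set, default `TRUE` for demographics) and
#' optional `role` (one of `burnout_personal`, `burnout_work`,
#' `burnout_client`) tagging the variables that hold the normalized
#' burnout subdimension scores.
#'
#' @param config Path to a YAML/JSON file, or a list with a `variables`
#'   element.
#' @return A `feature_schema` object.
#' @export
#' @examples
#' sch <- default_schema()
#' sch
load_schema <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("schema config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config) || is.null(config$variables)) {
    stop("schema config must contain a 'variables' list")
  }
  vars <- config$variables
  if (length(vars) == 0) stop("schema declares no variables")

  name <- vapply(vars, function(v) as.character(v$name %||% stop("variable without a name")), "")
  if (anyDuplicated(name)) {
    stop("duplicate variable names in schema: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  kind <- vapply(vars, function(v) {
    k <- as.character(v$kind %||% "")
    if (!k %in% c("categorical", "numerical")) {
      stop("variable '", v$name, "' has unknown kind '", k, "'")
    }
    k
  }, "")

  codes <- vector("list", length(vars))
  vmin <- vmax <- rep(NA_real_, length(vars))
  role <- rep(NA_character_, length(vars))
  stage2 <- rep(TRUE, length(vars))
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    if (!is.null(v$stage2)) stage2[i] <- isTRUE(v$stage2)
    if (!is.null(v$role)) {
      r <- as.character(v$role)
      if (!r %in% paste0("burnout_", burnout_subdimensions())) {
        stop("variable '", name[i], "' has unknown role '", r, "'")
      }
      role[i] <- r
    }
    if (kind[i] == "categorical") {
      if (is.null(v$codes) || length(v$codes) == 0) {
        stop("categorical variable '", name[i], "' declares no codes")
      }
      cd <- as.character(unlist(v$codes))
      if (anyDuplicated(cd)) {
        stop("overlapping codes for categorical variable '", name[i], "'")
      }
      codes[[i]] <- cd
    } else {
      if (is.null(v$min) || is.null(v$max)) {
        stop("numerical variable '", name[i], "' is missing min or max")
      }
      vmin[i] <- as.numeric(v$min)
      vmax[i] <- as.numeric(v$max)
      if (vmax[i] < vmin[i]) {
        stop("numerical variable '", name[i], "' has max < min")
      }
    }
  }
  rng <- vmax - vmin
  degenerate <- kind == "numerical" & !is.na(rng) & rng == 0

  roles_seen <- role[!is.na(role)]
  if (anyDuplicated(roles_seen)) stop("duplicate burnout role in schema")

  structure(
    list(
      variables = data.frame(
        name = name, kind = kind, min = vmin, max = vmax, range = rng,
        degenerate = degenerate, role = role, stage2 = stage2,
        stringsAsFactors = FALSE
      ),
      codes = stats::setNames(codes, name)
    ),
    class = "feature_schema"
  )
}

#' The default shipped feature schema
#'
#' Five categorical variables (sex, marital status, position, department,
#' shift type) and seventeen numerical variables (age, hospital-size code
#' 1-5, clinical-experience band 1-6, overtime band 1-6, turnover
#' intention 0-10, job stress 23-115, stress response 0-88, coping total
#' 33-99 and its three 11-33 subscales, the three normalized 0-100
#' burnout subdimensions, and three reserved 0-100 slots), so the maximum
#' attainable profile dissimilarity is 22. The stage-2 subset keeps the
#' demographic/work variables plus the burnout subdimensions (13
#' variables) and drops the research variables that are only re-measured
#' at the final assessment.
#'
#' @return A `feature_schema`.
#' @export
default_schema <- function() {
  path <- system.file("extdata", "default_schema.yaml", package = "burnrec")
  if (!nzchar(path)) stop("shipped default schema not found")
  load_schema(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.feature_schema <- function(x, ...) {
  v <- x$variables
  cat("<feature_schema> ", sum(v$kind == "categorical"), " categorical + ",
      sum(v$kind == "numerical"), " numerical variables",
      " (stage 2: ", sum(v$stage2), ")\n", sep = "")
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "categorical") {
      cat(sprintf("  %-22s categorical {%s}%s\n", v$name[i],
                  paste(x$codes[[v$name[i]]], collapse = ","),
                  if (v$stage2[i]) " [s2]" else ""))
    } else {
      cat(sprintf("  %-22s numerical [%g, %g] R=%g%s%s\n", v$name[i],
                  v$min[i], v$max[i], v$range[i],
                  if (v$degenerate[i]) " (degenerate)" else "",
                  if (v$stage2[i]) " [s2]" else ""))
    }
  }
  invisible(x)
}

# Names of schema variables, optionally restricted to a recommendation stage.
schema_vars <- function(schema, stage = NULL) {
  v <- schema$variables
  if (!is.null(stage) && stage == 2) v$name[v$stage2] else v$name
}

# Named character vector mapping subdimension -> schema variable name,
# from the role tags. Errors if any of the three roles is missing.
burnout_vars <- function(schema) {
  v <- schema$variables
  out <- character(0)
  for (s in burnout_subdimensions()) {
    nm <- v$name[!is.na(v$role) & v$role == paste0("burnout_", s)]
    if (length(nm) != 1) {
      stop("schema must tag exactly one variable with role 'burnout_", s, "'")
    }
    out[s] <- nm
  }
  out
}

schema_var_row <- function(schema, name) {
  i <- match(name, schema$variables$name)
  if (is.na(i)) stop("unknown schema variable '", name, "'")
  i
}
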