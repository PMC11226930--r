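#' Copenhagen Burnout Inventory subdimension scores
#'
#' Holds the three CBI subdomain scores on their raw instrument scales
#' (personal 0-31.5, work-related 0-37, client-related 0-31.5), the total
#' (their sum, 0-100), and the normalized subdimension scores (each raw
#' score rescaled to 0-100 by its subdomain maximum). The validity
#' criterion and the recommender's dominant-subdimension logic operate on
#' the normalized scale, which makes the three subdomains comparable.
#'
#' @param personal,work,client Raw subdomain scores.
#' @return A `burnout_scores` object with fields `personal`, `work`,
#'   `client`, `total` and `normalized` (named numeric vector, 0-100).
#' @export
#' @examples
#' b <- burnout_scores(15.75, 37, 0)
#' b$normalized
burnout_scores <- function(personal, work, client) {
  raw <- c(personal = as.numeric(personal), work = as.numeric(work),
           client = as.numeric(client))
  for (s in names(raw)) {
    if (!is.finite(raw[[s]]) || raw[[s]] < 0 || raw[[s]] > .subdomain_max[[s]]) {
      stop(s, " burnout score ", raw[[s]], " outside [0, ", .subdomain_max[[s]], "]")
    }
  }
  out <- structure(
    list(personal = raw[["personal"]], work = raw[["work"]],
         client = raw[["client"]], total = sum(raw), normalized = NULL),
    class = "burnout_scores"
  )
  normalize_burnout(out)
}

#' Normalize burnout subdimension scores to the 0-100 scale
#'
#' Each normalized value is `raw / subdomain_max * 100`. Returns the same
#' `burnout_scores` object with its `normalized` field (re)computed.
#'
#' @param raw A `burnout_scores` object.
#' @return The `burnout_scores` object with `normalized` filled in.
#' @export
normalize_burnout <- function(raw) {
  stopifnot(inherits(raw, "burnout_scores"))
  rawv <- c(personal = raw$personal, work = raw$work, client = raw$client)
  raw$normalized <- rawv / .subdomain_max * 100
  raw
}

#' Burnout scores from normalized values
#'
#' Inverse of the normalization: builds a `burnout_scores` object from
#' subdimension scores already on the 0-100 normalized scale.
#'
#' @param personal,work,client Normalized subdimension scores in \[0, 100\].
#' @return A `burnout_scores` object.
#' @export
burnout_from_normalized <- function(personal, work, client) {
  n <- c(personal = as.numeric(personal), work = as.numeric(work),
         client = as.numeric(client))
  if (any(!is.finite(n)) || any(n < 0 | n > 100)) {
    stop("normalized burnout scores must lie in [0, 100]")
  }
  burnout_scores(n[["personal"]] / 100 * .subdomain_max[["personal"]],
                 n[["work"]] / 100 * .subdomain_max[["work"]],
                 n[["client"]] / 100 * .subdomain_max[["client"]])
}

#' @export
print.burnout_scores <- function(x, ...) {
  cat(sprintf(
    "<burnout_scores> personal %.2f  work %.2f  client %.2f  total %.2f\n",
    x$personal, x$work, x$client, x$total))
  cat(sprintf("  normalized: personal %.1f  work %.1f  client %.1f\n",
              x$normalized[["personal"]], x$normalized[["work"]],
              x$normalized[["client"]]))
  invisible(x)
}

# Coerce burnout_scores or a named normalized vector to the named
# normalized triplet c(personal=, work=, client=).
normalized_subscores <- function(x) {
  if (inherits(x, "burnout_scores")) return(x$normalized)
  x <- unlist(x)
  miss <- setdiff(burnout_subdimensions(), names(x))
  if (length(miss)) stop("missing subdimension score(s): ", paste(miss, collapse = ", "))
  stats::setNames(as.numeric(x[burnout_subdimensions()]), burnout_subdimensions())
}

#' A completed program stage and its outcome
#'
#' Bundles the program taken, the burnout scores measured immediately
#' before and after it, and the participant's satisfaction rating.
#'
#' @param program One of [burnout_programs()].
#' @param pre,post `burnout_scores` at the assessments bracketing the
#'   program.
#' @param satisfaction Integer 1-5 (1: very dissatisfied; 5: very
#'   satisfied), or `NA` when not collected.
#' @return A `program_outcome` object.
#' @export
program_outcome <- function(program, pre, post, satisfaction = NA) {
  program <- match.arg(program, burnout_programs())
  stopifnot(inherits(pre, "burnout_scores"), inherits(post, "burnout_scores"))
  if (!is.na(satisfaction)) {
    satisfaction <- as.integer(satisfaction)
    if (!satisfaction %in% 1:5) stop("satisfaction must be an integer in 1..5")
  }
  structure(
    list(program = program, pre = pre, post = post,
         satisfaction = satisfaction),
    class = "program_outcome"
  )
}
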