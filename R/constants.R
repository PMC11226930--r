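#' Candidate intervention programs
#'
#' The four 2-week programs the recommender chooses among: mindfulness
#' meditation, storytelling and reflective writing, laughter therapy, and
#' acceptance and commitment therapy (ACT).
#'
#' @return Character vector of the four program identifiers.
#' @export
#' @examples
#' burnout_programs()
burnout_programs <- function() {
  c("mindfulness", "storytelling", "laughter", "act")
}

#' Burnout subdimensions
#'
#' The three Copenhagen Burnout Inventory (CBI) subdomains.
#'
#' @return Character vector `c("personal", "work", "client")`.
#' @export
burnout_subdimensions <- function() {
  c("personal", "work", "client")
}

# Raw CBI subdomain maxima; they sum to the 0-100 total-scale maximum.
.subdomain_max <- c(personal = 31.5, work = 37, client = 31.5)

#' CBI subdomain score maxima
#'
#' Raw maxima of the three subdomains (personal 31.5, work-related 37,
#' client-related 31.5); they sum to 100, the maximum of the total scale.
#'
#' @return Named numeric vector of subdomain maxima.
#' @export
subdomain_maxima <- function() .subdomain_max

.assessment_points <- c("pretest", "posttest1", "posttest2")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
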