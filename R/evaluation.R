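#' Paired pre/post change test
#'
#' Two-sided paired t test on `pre - post`. A zero-variance difference
#' vector is flagged degenerate instead of producing an infinite
#' statistic: all-zero differences give `t = 0`, `p = 1`; a constant
#' nonzero shift gives a signed infinite `t` with `p = 0`.
#'
#' @param pre,post Equal-length paired score vectors, `n >= 2`.
#' @return List with `n`, `mean_pre`, `mean_post`, `mean_change`
#'   (pre - post), `t`, `df`, `p`, `degenerate`.
#' @export
#' @examples
#' paired_change_test(c(10, 12, 14), c(8, 9, 12))
paired_change_test <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 2) stop("paired test requires n >= 2")
  d <- pre - post
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(n = length(d), mean_pre = mean(pre), mean_post = mean(post),
                mean_change = mean(d), t = t, df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(pre, post, paired = TRUE)
  list(n = length(d), mean_pre = mean(pre), mean_post = mean(post),
       mean_change = mean(d), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value, degenerate = FALSE)
}

#' Spearman correlation of participation order with score change
#'
#' Rank correlation of the order of participation (an ordinal variable)
#' with a change score; a negative correlation for `post - pre` changes
#' means later participants improved more — the signature of an
#' optimizing recommender. Invariant under strictly monotone transforms
#' of the change vector.
#'
#' @param order Participation ranks 1..n.
#' @param change Score-change vector.
#' @return List with `rho`, `p`, `n`.
#' @export
order_correlation <- function(order, change) {
  if (length(order) != length(change)) stop("order and change must have equal length")
  if (length(order) < 3) stop("order correlation requires n >= 3")
  if (stats::sd(change) == 0 || stats::sd(order) == 0) {
    stop("constant vector: correlation undefined")
  }
  ht <- stats::cor.test(order, change, method = "spearman", exact = FALSE)
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(order))
}

#' Satisfaction trend across enrollment groups
#'
#' One-way ANOVA of satisfaction over consecutive enrollment groups
#' (e.g., first/second/third hundred participants) with Scheffe-adjusted
#' pairwise post hoc contrasts. A zero-variance response is returned as a
#' degenerate result with no significant pairs.
#'
#' @param satisfaction Numeric rating vector.
#' @param group Factor (or coercible) of enrollment groups; every group
#'   needs at least 2 observations.
#' @return List with `group_means`, `F`, `df`, `p`, `posthoc` (data frame
#'   of pairwise contrasts with Scheffe-adjusted p values), `degenerate`.
#' @export
grouped_satisfaction_trend <- function(satisfaction, group) {
  group <- as.factor(group)
  if (length(satisfaction) != length(group)) {
    stop("satisfaction and group must have equal length")
  }
  counts <- table(group)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts == 0)) stop("empty group: ", paste(names(counts)[counts == 0], collapse = ", "))
  if (any(counts < 2)) stop("every group needs at least 2 observations")
  means <- tapply(satisfaction, group, mean)

  if (stats::sd(satisfaction) == 0) {
    return(list(group_means = means, F = 0, df = c(length(counts) - 1L,
                length(satisfaction) - length(counts)), p = NA_real_,
                posthoc = data.frame(contrast = character(0),
                                     estimate = numeric(0), p = numeric(0)),
                degenerate = TRUE))
  }

  d <- data.frame(satisfaction = satisfaction, group = group)
  fit <- stats::aov(satisfaction ~ group, data = d)
  an <- summary(fit)[[1]]
  emm <- emmeans::emmeans(fit, "group")
  ph <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "scheffe"))
  list(
    group_means = means,
    F = an[["F value"]][1],
    df = an[["Df"]],
    p = an[["Pr(>F)"]][1],
    posthoc = data.frame(contrast = as.character(ph$contrast),
                         estimate = ph$estimate, p = ph$p.value),
    degenerate = FALSE
  )
}

# Sample skewness and excess-free kurtosis used in the normality screen.
normality_screen <- function(x) {
  c(skewness = e1071::skewness(x), kurtosis = e1071::kurtosis(x) + 3)
}

#' Cut participation orders into consecutive groups
#'
#' @param order Participation order (any strictly increasing labels; only
#'   ranks are used, so offsets do not shift group boundaries).
#' @param size Group size (default 100, giving first/second/third hundred
#'   for a 300-participant cohort).
#' @return Factor of group labels.
#' @export
order_groups <- function(order, size = 100) {
  r <- rank(order, ties.method = "min")
  factor(paste0("g", (r - 1) %/% size + 1))
}

#' Full outcome report for a trial
#'
#' Computes, per stage, the paired burnout change test on total scores;
#' the order correlation of the stage-2 change (`posttest2 - posttest1`)
#' with participation order; the grouped satisfaction trend per stage;
#' and the skewness/kurtosis normality screen of the change scores
#' (reported, not used as a gate).
#'
#' @param trial A `trial_result` (or equivalent data frame).
#' @param group_size Enrollment group size for the satisfaction ANOVA.
#' @return A list report.
#' @export
evaluate_trial <- function(trial, group_size = 100) {
  d <- as.data.frame(trial)
  s1 <- d[d$stage == 1, ]
  s2 <- d[d$stage == 2, ]

  report <- list(
    stage1_burnout = paired_change_test(s1$pre_total, s1$post_total),
    stage2_burnout = paired_change_test(s2$pre_total, s2$post_total),
    stage2_order_correlation = order_correlation(
      s2$order, s2$post_total - s2$pre_total),
    normality = list(
      stage1_change = normality_screen(s1$post_total - s1$pre_total),
      stage2_change = normality_screen(s2$post_total - s2$pre_total)
    )
  )
  for (stage in 1:2) {
    ds <- if (stage == 1) s1 else s2
    grp <- order_groups(ds$order, group_size)
    report[[paste0("stage", stage, "_satisfaction")]] <-
      if (nlevels(droplevels(grp)) >= 2 && all(table(droplevels(grp)) >= 2)) {
        grouped_satisfaction_trend(ds$satisfaction, droplevels(grp))
      } else {
        NULL
      }
  }
  report
}
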