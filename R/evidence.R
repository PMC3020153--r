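#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-study effects (proportions or continuous effects with their
#' variances) with the moment-based DerSimonian-Laird estimator.  With
#' fixed-effect weights \eqn{w_i = 1/v_i} and fixed-effect mean
#' \eqn{\hat\theta_{FE}}, Cochran's heterogeneity statistic is
#' \eqn{Q = \sum w_i (\theta_i - \hat\theta_{FE})^2}, the between-study
#' variance \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 /
#' \sum w_i))}, and the pooled estimate is the mean weighted by
#' \eqn{1/(v_i + \tau^2)}.  The Q p-value comes from a chi-square
#' distribution with \eqn{k-1} degrees of freedom and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100} (0 when \eqn{Q = 0}).
#'
#' @param studies a data frame with columns `study_id`, `estimate` and
#'   `variance` (see [read_study_table()]).
#' @return An object of class `dl_pool`: a list with `pooled`, `se`,
#'   `ci_low`/`ci_high` (95 percent), `tau2`, `Q`, `q_pvalue`, `i2`
#'   (percent), `k` and the input `studies` (with random-effects weights).
#' @examples
#' s <- data.frame(study_id = c("a", "b"),
#'                 estimate = c(0.2, 0.4), variance = c(0.01, 0.02))
#' pool_dl(s)
#' @export
pool_dl <- function(studies) {
  studies <- check_studies(studies)
  k <- nrow(studies)
  if (k < 2L) stop("pool_dl needs at least 2 studies, got ", k)
  th <- studies$estimate
  v <- studies$variance
  w <- 1 / v
  theta_fe <- sum(w * th) / sum(w)
  Q <- sum(w * (th - theta_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  pooled <- sum(wr * th) / sum(wr)
  se <- sqrt(1 / sum(wr))
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  structure(list(
    pooled = pooled, se = se,
    ci_low = pooled - stats::qnorm(0.975) * se,
    ci_high = pooled + stats::qnorm(0.975) * se,
    tau2 = tau2, Q = Q,
    q_pvalue = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
    i2 = i2, k = k,
    studies = transform(studies, weight_re = wr / sum(wr))),
    class = "dl_pool")
}

#' @export
print.dl_pool <- function(x, ...) {
  cat(sprintf("DL random-effects pool of %d studies\n", x$k))
  cat(sprintf("  pooled %.4f (95%% CI %.4f-%.4f), tau2 %.4g\n",
              x$pooled, x$ci_low, x$ci_high, x$tau2))
  cat(sprintf("  Q %.3f (p = %.4f), I2 %.1f%%\n", x$Q, x$q_pvalue, x$i2))
  invisible(x)
}

check_studies <- function(studies) {
  studies <- as.data.frame(studies)
  need <- c("study_id", "estimate", "variance")
  if (!all(need %in% names(studies)))
    stop("study table needs columns ", paste(need, collapse = ", "))
  if (any(!is.finite(studies$variance)) || any(studies$variance <= 0))
    stop("all study variances must be positive")
  studies
}

#' Read a per-study effect table
#'
#' Reads a delimited study table with columns `study_id`, `estimate`,
#' `variance`, or `study_id`, `events`, `n` for binomial proportions: the
#' latter is converted via \eqn{p = events/n} and \eqn{v = p(1-p)/n}, with a
#' 0.5 continuity correction added to events and non-events when either cell
#' is zero.
#'
#' @param path path to a comma- or tab-delimited file.
#' @return A data frame with columns `study_id`, `estimate`, `variance`.
#' @export
read_study_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (all(c("events", "n") %in% names(x))) {
    ev <- x$events; n <- x$n
    zero <- ev == 0 | ev == n
    ev[zero] <- ev[zero] + 0.5
    n[zero] <- n[zero] + 1
    p <- ev / n
    x <- data.frame(study_id = x$study_id, estimate = p,
                    variance = p * (1 - p) / n, stringsAsFactors = FALSE)
  }
  check_studies(x)
}

#' Model parameter estimates
#'
#' A `parameter_estimate` is a named model input carrying a point value, a
#' plausible range (used by the sensitivity analyses) and a provenance tag
#' recording how the value was obtained: `"pooled"` (DL random-effects),
#' `"median"` (heterogeneous studies), `"expert"` (expert opinion) or
#' `"back-calculated"` (complement of its siblings at a chance node).
#'
#' @param name parameter name.
#' @param point point value.
#' @param low,high plausible-range bounds (`low <= point <= high`).
#' @param provenance one of `"pooled"`, `"median"`, `"expert"`,
#'   `"back-calculated"`.
#' @param probability if `TRUE` (default), point and range are clamped to
#'   `[0, 1]`.
#' @export
parameter_estimate <- function(name, point, low = point, high = point,
                               provenance = "expert", probability = TRUE) {
  provenance <- match.arg(provenance,
                          c("pooled", "median", "expert", "back-calculated"))
  if (probability) {
    point <- min(max(point, 0), 1)
    low <- min(max(low, 0), 1)
    high <- min(max(high, 0), 1)
  }
  if (!(low <= point && point <= high))
    stop("parameter '", name, "': need low <= point <= high, got ",
         low, " / ", point, " / ", high)
  structure(list(name = as.character(name), point = point, low = low,
                 high = high, provenance = provenance,
                 probability = probability),
            class = "parameter_estimate")
}

#' @export
print.parameter_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g [%.4g, %.4g] (%s)\n", x$name, x$point, x$low,
              x$high, x$provenance))
  invisible(x)
}

#' Choose a parameter estimate using the pooling decision rules
#'
#' Applies the evidence-synthesis decision rules: with two or more studies
#' whose effects are sufficiently homogeneous, pool them by
#' DerSimonian-Laird and take the plausible range from the pooled 95 percent
#' CI; when the studies are heterogeneous, fall back to the median study
#' estimate (midpoint of the central pair for even counts) with the range
#' spanning the lowest and highest reported study CI bounds; with no usable
#' studies, use expert opinion with its supplied wide range.
#'
#' Homogeneity is declared when the Q-test p-value exceeds `p_threshold`
#' *and* \eqn{I^2} is below `i2_threshold`.  (The usual informal phrasing of
#' these rules mixes the Q statistic with its p-value; the implemented
#' criterion is the standard one consistent with the 0.10 / 25 percent
#' thresholds.)  Forest-plot outliers are not automated; use
#' [forest_data()] for visual inspection.
#'
#' @inheritParams parameter_estimate
#' @param studies optional study table (see [pool_dl()]).
#' @param expert_value,expert_range expert point value and `c(low, high)`
#'   range, used when no study table is given.
#' @param p_threshold,i2_threshold homogeneity thresholds (defaults 0.10 and
#'   25 percent).
#' @return A [parameter_estimate()] with provenance recorded.
#' @export
choose_estimate <- function(name, studies = NULL, expert_value = NULL,
                            expert_range = NULL, probability = TRUE,
                            p_threshold = 0.10, i2_threshold = 25) {
  if (is.null(studies) && is.null(expert_value))
    stop("parameter '", name, "': supply studies or an expert value")
  if (!is.null(studies) && nrow(as.data.frame(studies)) >= 2L) {
    pool <- pool_dl(studies)
    if (pool$q_pvalue > p_threshold && pool$i2 < i2_threshold) {
      return(parameter_estimate(name, pool$pooled, pool$ci_low, pool$ci_high,
                                provenance = "pooled",
                                probability = probability))
    }
    st <- check_studies(studies)
    z <- stats::qnorm(0.975)
    point <- stats::median(st$estimate)
    return(parameter_estimate(
      name, point,
      low = min(st$estimate - z * sqrt(st$variance)),
      high = max(st$estimate + z * sqrt(st$variance)),
      provenance = "median", probability = probability))
  }
  if (is.null(expert_value))
    stop("parameter '", name, "': fewer than 2 studies and no expert value")
  if (is.null(expert_range)) expert_range <- c(expert_value, expert_value)
  parameter_estimate(name, expert_value, expert_range[1L], expert_range[2L],
                     provenance = "expert", probability = probability)
}

#' Back-calculate a complement parameter
#'
#' Closes a sibling set at a chance node: the returned estimate is one minus
#' the sum of the sibling points, with the plausible range propagated by
#' interval arithmetic (low = 1 - sum of sibling highs, high = 1 - sum of
#' sibling lows) and clamped to `[0, 1]`.
#'
#' @param siblings list of [parameter_estimate()] objects whose points sum
#'   to at most 1.
#' @param name name for the new parameter.
#' @export
back_calculate_complement <- function(siblings,
                                      name = "complement") {
  stopifnot(length(siblings) >= 1L,
            all(vapply(siblings, inherits, logical(1L), "parameter_estimate")))
  pts <- vapply(siblings, `[[`, numeric(1L), "point")
  if (sum(pts) > 1 + 1e-12)
    stop("sibling points sum to ", format(sum(pts)), " > 1")
  lows <- vapply(siblings, `[[`, numeric(1L), "low")
  highs <- vapply(siblings, `[[`, numeric(1L), "high")
  parameter_estimate(name, 1 - sum(pts),
                     low = max(0, 1 - sum(highs)),
                     high = min(1, 1 - sum(lows)),
                     provenance = "back-calculated")
}

#' Forest-plot data
#'
#' Emits per-study estimates with 95 percent CIs alongside the pooled
#' summary row, as a plain data frame suitable for a forest plot (outlier
#' inspection is left visual by design).
#'
#' @param pool a [pool_dl()] result.
#' @export
forest_data <- function(pool) {
  stopifnot(inherits(pool, "dl_pool"))
  z <- stats::qnorm(0.975)
  st <- pool$studies
  rbind(
    data.frame(study_id = st$study_id, estimate = st$estimate,
               ci_low = st$estimate - z * sqrt(st$variance),
               ci_high = st$estimate + z * sqrt(st$variance),
               weight = st$weight_re, stringsAsFactors = FALSE),
    data.frame(study_id = "RE pooled", estimate = pool$pooled,
               ci_low = pool$ci_low, ci_high = pool$ci_high, weight = 1,
               stringsAsFactors = FALSE))
}
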