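#' Linear time-tradeoff utility
#'
#' Converts a time-tradeoff (TTO) response into a utility weight.  A
#' respondent asked how much life expectancy they would give up to avoid a
#' health state of duration `reference_duration` yields
#' \deqn{u = (reference\_duration - time\_traded) / reference\_duration.}
#' Trading no time gives u = 1; trading exactly the state's duration gives
#' u = 0 (equivalent to death); trading more gives a negative utility, a
#' state worse than death.  The same linear construction is used for the
#' temporary complication month (reference 1 month) and for chronic
#' long-term ECF residence (reference: the severity-specific COPD life
#' expectancy).  Utilities are deliberately not floored at -1; see
#' [floor_utility()] for an opt-in floor.
#'
#' @param time_traded months of life expectancy traded away (>= 0).
#' @param reference_duration duration of the avoided state in months (> 0).
#' @return A utility weight (<= 1, possibly negative).
#' @examples
#' tto_utility(0, 1)    #  1
#' tto_utility(1, 1)    #  0
#' tto_utility(12, 1)   # -11
#' @export
tto_utility <- function(time_traded, reference_duration) {
  if (any(reference_duration <= 0))
    stop("reference_duration must be positive")
  if (any(time_traded < 0)) stop("time_traded must be >= 0")
  (reference_duration - time_traded) / reference_duration
}

#' @param u a utility.
#' @param floor lower bound (default -1).
#' @rdname tto_utility
#' @export
floor_utility <- function(u, floor = -1) pmax(u, floor)

#' Tradeoff ladder
#'
#' Evaluates [tto_utility()] along a ladder of increasing tradeoffs, as used
#' for the axes of the two-way preference grid: each row pairs a tradeoff
#' (months) with its utility, strictly decreasing in the tradeoff.
#'
#' @param tradeoffs nonnegative, sorted (ascending) tradeoffs in months.
#' @inheritParams tto_utility
#' @return A data frame with columns `tradeoff` and `utility` (empty for an
#'   empty ladder).
#' @export
tradeoff_grid <- function(tradeoffs, reference_duration) {
  if (length(tradeoffs) == 0L)
    return(data.frame(tradeoff = numeric(), utility = numeric()))
  if (is.unsorted(tradeoffs, strictly = FALSE))
    stop("tradeoffs must be sorted ascending")
  data.frame(tradeoff = tradeoffs,
             utility = tto_utility(tradeoffs, reference_duration))
}

#' Convert tradeoff durations to months
#'
#' Accepted units: `weeks`, `months`, `years`; 1 year = 12 months and
#' 1 month = 4.345 weeks.
#'
#' @param x numeric duration(s).
#' @param units `"weeks"`, `"months"` or `"years"`.
#' @export
as_months <- function(x, units = c("months", "weeks", "years")) {
  units <- match.arg(units)
  switch(units,
         months = x,
         weeks = x / 4.345,
         years = x * 12)
}

#' Default tradeoff ladder (months)
#'
#' The ladder used for the preference-grid axes: no tradeoff, 1 week,
#' 1, 2, 3 and 6 months, and 1 year, expressed in months.
#'
#' @export
default_tradeoff_ladder <- function() {
  c(0, as_months(1, "weeks"), 1, 2, 3, 6, 12)
}
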