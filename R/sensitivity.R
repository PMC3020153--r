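#' One-way sensitivity analysis
#'
#' Varies a single parameter across its plausible range while holding every
#' other input at its base-case value, and reports the QALY difference
#' (Full Code minus DNI) at both bounds.  When the difference changes sign
#' across the range, the flip value (the parameter value at which the
#' recommended directive changes) is located by bisection to within `1e-6`
#' in parameter units.  Probabilities are swept jointly with their
#' complement edge at the chance node (the complement absorbs the change),
#' so sibling probabilities always sum to 1.
#'
#' The two preference utilities may be swept by name
#' (`"u_ett_complication"`, `"u_longterm_ecf"`); their default ranges span
#' the utilities generated from the tradeoff ladder
#' ([default_tradeoff_ladder()]) for the corresponding time-tradeoff
#' scenario.
#'
#' @inheritParams evaluate_scenario
#' @param parameter name of the parameter to vary.
#' @param range optional `c(low, high)` overriding the parameter's own
#'   plausible range.
#' @return A list of class `ad_oneway`: `parameter`, `low`, `high`,
#'   `delta_low`, `delta_high`, `crosses_zero` and `flip_value` (`NULL`
#'   when the sign does not change).
#' @export
one_way <- function(scenario, params, parameter, range = NULL) {
  base <- sweep_bounds(scenario, params, parameter)
  if (is.null(range)) range <- c(base$low, base$high)
  dlo <- delta_qaly(scenario, params,
                    overrides = stats::setNames(range[1L], parameter))
  dhi <- delta_qaly(scenario, params,
                    overrides = stats::setNames(range[2L], parameter))
  crosses <- dlo == 0 || dhi == 0 || sign(dlo) != sign(dhi)
  flip <- NULL
  if (crosses && range[2L] > range[1L]) {
    flip <- find_threshold(scenario, params, parameter, range)
  } else if (crosses) {
    flip <- range[1L]
  }
  structure(list(parameter = parameter, low = range[1L], high = range[2L],
                 delta_low = dlo, delta_high = dhi,
                 crosses_zero = crosses, flip_value = flip),
            class = "ad_oneway")
}

#' @export
print.ad_oneway <- function(x, ...) {
  cat(sprintf("one-way: %s in [%.4g, %.4g]\n", x$parameter, x$low, x$high))
  cat(sprintf("  delta QALY: %.4f (low) / %.4f (high)\n",
              x$delta_low, x$delta_high))
  if (x$crosses_zero)
    cat(sprintf("  recommended AD flips at %s = %.6f\n",
                x$parameter, x$flip_value))
  invisible(x)
}

# plausible bounds for any sweepable quantity
sweep_bounds <- function(scenario, params, parameter) {
  if (parameter %in% names(params$estimates)) {
    e <- params$estimates[[parameter]]
    return(list(low = e$low, high = e$high))
  }
  ladder <- default_tradeoff_ladder()
  if (parameter == "u_ett_complication") {
    u <- tradeoff_grid(ladder, 1)$utility
    return(list(low = min(u), high = max(u)))
  }
  if (parameter == "u_longterm_ecf") {
    u <- tradeoff_grid(ladder,
                       params$lifetable$le_copd[[scenario$severity]] * 12)
    return(list(low = min(u$utility), high = max(u$utility)))
  }
  stop("unknown parameter '", parameter, "'")
}

#' Tornado analysis
#'
#' Runs [one_way()] for every swept parameter and returns the bars sorted
#' by descending width (the widest bars mark the inputs the recommendation
#' is most sensitive to).  By default all probability and baseline-utility
#' estimates with a nonzero plausible range are swept, together with the
#' two time-tradeoff-derived utilities whose ranges come from the tradeoff
#' ladder.
#'
#' @inheritParams one_way
#' @param parameters character vector of parameters to sweep (default: all
#'   sweepable ones).
#' @return A data frame of class `ad_tornado` with one row per parameter:
#'   `parameter`, `low`, `high`, `delta_low`, `delta_high`, `width`,
#'   `crosses_zero`, sorted by descending `width`.
#' @export
tornado <- function(scenario, params, parameters = NULL) {
  if (is.null(parameters))
    parameters <- c(names(params$estimates),
                    "u_ett_complication", "u_longterm_ecf")
  rows <- lapply(parameters, function(nm) {
    ow <- one_way(scenario, params, nm)
    data.frame(parameter = nm, low = ow$low, high = ow$high,
               delta_low = ow$delta_low, delta_high = ow$delta_high,
               width = abs(ow$delta_high - ow$delta_low),
               crosses_zero = ow$crosses_zero, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("ad_tornado", class(out))
  out
}

#' Two-way preference grid
#'
#' Re-evaluates the recommendation over a grid of hypothetical preferences:
#' each axis is a ladder of time tradeoffs (months of life expectancy the
#' patient would give up), one to avoid permanent extended-care placement
#' and one to avoid a month of intubation complications.  Each cell sets
#' the two utilities from the corresponding [tto_utility()] values (the
#' ECF tradeoff is referenced against the severity-specific COPD life
#' expectancy, the complication tradeoff against its 1-month duration) and
#' records the recommended directive with everything else at base case.
#'
#' @inheritParams evaluate_scenario
#' @param ecf_tradeoffs,complication_tradeoffs ascending tradeoff ladders
#'   in months (default [default_tradeoff_ladder()]).
#' @return An object of class `ad_twoway`: a list with `ecf_tradeoffs`,
#'   `complication_tradeoffs`, the matching utilities, and `grid`, a
#'   character matrix (rows: complication tradeoffs; columns: ECF
#'   tradeoffs) of `"Full Code"` / `"DNI"` / `"indifferent"`.
#' @export
two_way_preference_grid <- function(scenario, params,
                                    ecf_tradeoffs = default_tradeoff_ladder(),
                                    complication_tradeoffs =
                                      default_tradeoff_ladder()) {
  if (is.unsorted(ecf_tradeoffs) || is.unsorted(complication_tradeoffs))
    stop("tradeoff axes must be sorted ascending")
  le_months <- params$lifetable$le_copd[[scenario$severity]] * 12
  u_ecf <- tto_utility(ecf_tradeoffs, le_months)
  u_comp <- tto_utility(complication_tradeoffs, 1)
  grid <- matrix(NA_character_, nrow = length(u_comp), ncol = length(u_ecf),
                 dimnames = list(paste0("comp_", complication_tradeoffs),
                                 paste0("ecf_", ecf_tradeoffs)))
  for (i in seq_along(u_comp))
    for (j in seq_along(u_ecf))
      grid[i, j] <- evaluate_scenario(
        scenario, params,
        overrides = c(u_ett_complication = u_comp[i],
                      u_longterm_ecf = u_ecf[j]))$recommended
  structure(list(ecf_tradeoffs = ecf_tradeoffs,
                 complication_tradeoffs = complication_tradeoffs,
                 u_ecf = u_ecf, u_complication = u_comp, grid = grid,
                 severity = scenario$severity),
            class = "ad_twoway")
}

#' @export
print.ad_twoway <- function(x, ...) {
  cat("Two-way preference grid (", x$severity, " COPD)\n", sep = "")
  cat("rows: months traded to avoid the complication month;",
      "columns: months traded to avoid long-term ECF\n")
  short <- ifelse(x$grid == "Full Code", "FC",
                  ifelse(x$grid == "DNI", "DNI", "~"))
  print(short, quote = FALSE)
  invisible(x)
}

#' Threshold (flip-value) search
#'
#' Locates the value of one parameter at which the QALY difference between
#' Full Code and DNI is zero, by bisection on a bracket whose endpoints
#' give opposite signs.  Stops when `|delta QALY| < 1e-9` or the bracket is
#' narrower than `1e-6` in parameter units.
#'
#' @inheritParams one_way
#' @param bracket `c(lower, upper)` parameter values bracketing the root.
#' @return The flip value.
#' @export
find_threshold <- function(scenario, params, parameter, bracket) {
  f <- function(v)
    delta_qaly(scenario, params, overrides = stats::setNames(v, parameter))
  bisect_root(f, bracket[1L], bracket[2L])
}

# plain bisection honoring both stopping rules: |f| < value_tol or
# bracket width < x_tol; endpoints that are already roots are returned.
bisect_root <- function(f, lower, upper, value_tol = 1e-9, x_tol = 1e-6) {
  fa <- f(lower); fb <- f(upper)
  if (abs(fa) < value_tol) return(lower)
  if (abs(fb) < value_tol) return(upper)
  if (sign(fa) == sign(fb))
    stop("root not bracketed: f has the same sign at both bracket ends")
  while (upper - lower > x_tol) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(fm) < value_tol) return(mid)
    if (sign(fm) == sign(fa)) {
      lower <- mid; fa <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}
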