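#' Declining exponential approximation of life expectancy (DEALE)
#'
#' The DEALE treats survival as a simple declining exponential: a survival
#' fraction `survival` observed at `horizon` years implies a constant
#' mortality rate \eqn{m = -\ln(S)/t} per year, and life expectancy is its
#' reciprocal, \eqn{LE = 1/m}.
#'
#' @param survival proportion surviving to the horizon, in `(0, 1]`.
#' @param horizon horizon in years (> 0).
#' @return `deale_rate()` a mortality rate per year; `deale_le()` years.
#' @examples
#' deale_rate(0.5, 1)            # ln 2
#' deale_le(deale_rate(0.25, 2)) # same hazard as S(1) = 0.5
#' @export
deale_rate <- function(survival, horizon = 1) {
  stopifnot(is.numeric(survival), is.numeric(horizon))
  if (any(horizon <= 0)) stop("horizon must be positive")
  if (any(survival <= 0)) stop("survival must be in (0, 1]")
  if (any(survival > 1)) stop("survival must be in (0, 1]")
  -log(survival) / horizon
}

#' @param rate mortality rate per year (> 0).
#' @rdname deale_rate
#' @export
deale_le <- function(rate) {
  if (any(rate <= 0)) stop("rate must be positive (infinite LE unsupported)")
  1 / rate
}

#' Life-expectancy table
#'
#' Holds the life expectancies the terminal payoffs are built from: COPD
#' life expectancy by GOLD severity stratum and life expectancy in a
#' long-term extended-care facility (ECF).
#'
#' @param le_copd named numeric vector `c(mild = , moderate = , severe = )`
#'   of life expectancies in years.
#' @param le_ecf life expectancy in years after permanent ECF placement.
#' @export
life_table <- function(le_copd, le_ecf) {
  need <- c("mild", "moderate", "severe")
  if (!all(need %in% names(le_copd)))
    stop("le_copd needs entries mild, moderate, severe")
  if (any(le_copd <= 0) || le_ecf <= 0) stop("life expectancies must be > 0")
  structure(list(le_copd = le_copd[need], le_ecf = as.numeric(le_ecf)),
            class = "ad_lifetable")
}

#' Utility set
#'
#' Utility weights for the health states in the model: baseline COPD utility
#' by severity (in `(0, 1]`), the utility of the month spent with
#' complications of invasive ventilation, and the utility of long-term ECF
#' residence.  The latter two may be negative, encoding states worse than
#' death elicited by large time tradeoffs.
#'
#' @param u_copd named numeric vector `c(mild = , moderate = , severe = )`.
#' @param u_complication utility of the ventilation-complication month
#'   (`<= 1`, may be negative).
#' @param u_ecf utility of long-term ECF residence (`<= 1`, may be
#'   negative).
#' @export
utility_set <- function(u_copd, u_complication, u_ecf) {
  need <- c("mild", "moderate", "severe")
  if (!all(need %in% names(u_copd)))
    stop("u_copd needs entries mild, moderate, severe")
  if (any(u_copd <= 0) || any(u_copd > 1))
    stop("u_copd must be in (0, 1]")
  if (u_complication > 1 || u_ecf > 1)
    stop("u_complication and u_ecf must be <= 1")
  structure(list(u_copd = u_copd[need],
                 u_complication = as.numeric(u_complication),
                 u_ecf = as.numeric(u_ecf)),
            class = "ad_utilities")
}

#' Terminal-node QALY payoff
#'
#' Composes the QALY payoff of a terminal node from its disposition, the
#' life table and the utility set.  Death is worth 0.  Discharge home (and
#' short-term ECF, i.e. temporary rehabilitation followed by return home) is
#' worth the severity-specific COPD utility times the severity-specific
#' COPD life expectancy; permanent (long-term) ECF placement is worth the
#' ECF utility times the ECF life expectancy.  A course with ventilation
#' complications adds `complication_months/12 * u_complication` and deducts
#' the same duration from the post-discharge term (floored at zero).
#'
#' @param disposition one of `"death"`, `"home"`, `"short_term_ecf"`,
#'   `"long_term_ecf"`.
#' @param severity COPD severity: `"mild"`, `"moderate"` or `"severe"`.
#' @param lifetable a [life_table()].
#' @param utilities a [utility_set()].
#' @param complication_months months spent with ventilation complications
#'   (>= 0; default 0).
#' @return QALYs (a single number).
#' @examples
#' lt <- life_table(c(mild = 10, moderate = 6, severe = 3), le_ecf = 2)
#' us <- utility_set(c(mild = 0.85, moderate = 0.75, severe = 0.6),
#'                   u_complication = 0.3, u_ecf = 0.4)
#' terminal_qaly("home", "severe", lt, us)  # 0.6 * 3 = 1.8
#' @export
terminal_qaly <- function(disposition, severity, lifetable, utilities,
                          complication_months = 0) {
  disposition <- match.arg(disposition,
                           c("death", "home", "short_term_ecf",
                             "long_term_ecf"))
  if (complication_months < 0) stop("complication_months must be >= 0")
  if (disposition == "death") return(0)
  severity <- match.arg(severity, c("mild", "moderate", "severe"))
  stopifnot(inherits(lifetable, "ad_lifetable"),
            inherits(utilities, "ad_utilities"))
  comp_years <- complication_months / 12
  if (disposition == "long_term_ecf") {
    u <- utilities$u_ecf
    le <- lifetable$le_ecf
  } else {
    u <- utilities$u_copd[[severity]]
    le <- lifetable$le_copd[[severity]]
  }
  comp_years * utilities$u_complication + max(le - comp_years, 0) * u
}
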