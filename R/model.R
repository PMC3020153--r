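#' COPD exacerbation scenario
#'
#' A scenario fixes the baseline COPD severity (GOLD-based mild / moderate /
#' severe) and the exacerbation mix: the probability that the index
#' exacerbation is "severely ill" (pH < 7.29) rather than "moderately ill".
#'
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param exacerbation_mix probability of a severely ill presentation, in
#'   `[0, 1]` (default 0.5).
#' @export
copd_scenario <- function(severity = c("severe", "mild", "moderate"),
                          exacerbation_mix = 0.5) {
  severity <- match.arg(severity)
  if (exacerbation_mix < 0 || exacerbation_mix > 1)
    stop("exacerbation_mix must be in [0, 1]")
  structure(list(severity = severity,
                 exacerbation_mix = exacerbation_mix),
            class = "copd_scenario")
}

#' Build one advance-directive strategy tree
#'
#' Constructs the single-hospitalization decision tree for one directive.
#' Patients present severely or moderately ill and are admitted to the ICU
#' or the ward.  Invasive ventilation (ETT) is offered only in the ICU and
#' only under Full Code; noninvasive ventilation (NIMV) is available in both
#' locations and both directives; treatment without mechanical ventilation
#' only on the ward.  Patients failing NIMV (failure to wean) choose Comfort
#' Measures Only (CMO) or, under Full Code, transfer to the ICU for
#' intubation; under DNI they may instead continue medical treatment.  ETT
#' survivors may suffer a complication month (end-organ damage, infection,
#' or inability to discontinue ventilation).  Long-term extended-care
#' placement is reachable only after ventilation complications, failure to
#' wean, or surviving CMO; uncomplicated survivors go home directly or via
#' short-term rehabilitation.  Terminal payoffs come from [terminal_qaly()].
#'
#' @param directive `"Full Code"` or `"DNI"`.
#' @param scenario a [copd_scenario()].
#' @param params an `ad_parameters` object (see [load_parameters()]).
#' @param overrides optional named numeric vector of point-value overrides
#'   (probabilities by parameter name; `u_ett_complication` /
#'   `u_longterm_ecf` pin the preference utilities directly).
#' @return A validated, audited [strategy()].
#' @export
build_strategy_tree <- function(directive, scenario, params,
                                overrides = NULL) {
  directive <- match.arg(directive, c("Full Code", "DNI"))
  stopifnot(inherits(scenario, "copd_scenario"),
            inherits(params, "ad_parameters"))
  pt <- function(name) param_point(params, name, overrides)
  util <- utilities_for(params, scenario$severity, overrides)
  lt <- params$lifetable
  comp_months <- params$defaults$complication_months
  dir_tag <- if (directive == "Full Code") "fullcode" else "dni"

  leaf <- function(disposition, comp = 0)
    terminal_node(disposition,
                  terminal_qaly(disposition, scenario$severity, lt, util,
                                complication_months = comp))

  uncomplicated <- function() chance_node(
    "disposition",
    edge("short_term_ecf", pt("p_shortterm_ecf"), leaf("short_term_ecf")),
    edge("home", "complement", leaf("home")))

  complicated <- function(comp) chance_node(
    "disposition",
    edge("long_term_ecf", pt("p_longterm_ecf"), leaf("long_term_ecf", comp)),
    edge("home", "complement", leaf("home", comp)))

  cmo <- function(comp) chance_node(
    "cmo_outcome",
    edge("survives_cmo", pt("p_survival_cmo"), complicated(comp)),
    edge("death", "complement", leaf("death")))

  ett <- function() chance_node(
    "ett_outcome",
    edge("death", pt("p_death_ett"), leaf("death")),
    edge("survives", "complement", chance_node(
      "ett_course",
      edge("complication", pt("p_ett_complication"), chance_node(
        "post_complication",
        edge("CMO", pt("p_cmo_after_failed_ventilation"), cmo(comp_months)),
        edge("continue_treatment", "complement", complicated(comp_months)))),
      edge("no_complication", "complement", uncomplicated()))))

  # patients who failed NIMV and cannot escalate face a much higher
  # in-hospital mortality than the general non-ventilated ward population
  medical_outcome <- function(ill, after_failure = FALSE) chance_node(
    "medical_outcome",
    edge("death",
         pt(if (after_failure) "p_death_failed_nimv_medical"
            else paste0("p_death_medical_", ill)),
         leaf("death")),
    edge("survives", "complement",
         if (after_failure) complicated(0) else uncomplicated()))

  post_failure <- function(ill) {
    if (directive == "Full Code") chance_node(
      "post_failure",
      edge("CMO", pt("p_cmo_after_failed_ventilation"), cmo(0)),
      edge("transfer_ICU", "complement",
           chance_node("icu_intubation", edge("ETT", 1, ett()))))
    else chance_node(
      "post_failure",
      edge("CMO", pt("p_cmo_after_failed_ventilation"), cmo(0)),
      edge("continued_medical", "complement",
           medical_outcome(ill, after_failure = TRUE)))
  }

  nimv <- function(ill) chance_node(
    "nimv_outcome",
    edge("death", pt("p_death_nimv"), leaf("death")),
    edge("survives", "complement", chance_node(
      "nimv_wean",
      edge("failure_to_wean", pt(paste0("p_nimv_failure_", ill)),
           post_failure(ill)),
      edge("weaned", "complement", uncomplicated()))))

  icu <- function(ill) {
    if (directive == "Full Code") chance_node(
      "icu_treatment",
      edge("ETT", pt(paste0("p_ett_", ill)), ett()),
      edge("NIMV", "complement", nimv(ill)))
    else chance_node("icu_treatment", edge("NIMV", 1, nimv(ill)))
  }

  ward <- function(ill) chance_node(
    "ward_treatment",
    edge("NIMV", pt(paste0("p_nimv_ward_", dir_tag)), nimv(ill)),
    edge("no_MV", "complement", medical_outcome(ill)))

  admission <- function(ill) chance_node(
    "admission",
    edge("ICU", pt(paste0("p_icu_", dir_tag, "_", ill)), icu(ill)),
    edge("Ward", "complement", ward(ill)))

  root <- chance_node(
    "exacerbation_severity",
    edge("severely_ill", scenario$exacerbation_mix,
         admission("severely_ill")),
    edge("moderately_ill", "complement", admission("moderately_ill")))

  s <- strategy(directive, root)
  audit_strategy(s)
  s
}

#' Structural audit of a strategy tree
#'
#' Checks, over every root-to-leaf path, the five structural constraints of
#' the model: (1) ETT only downstream of an ICU admission or ICU transfer;
#' (2) treatment without mechanical ventilation only on the ward; (3) no ETT
#' anywhere under a DNI strategy; (4) CMO reachable only after ventilation
#' failure (failure to wean or an ETT complication); (5) long-term ECF
#' placement only downstream of ventilation complications, failure to wean,
#' or CMO survival.  Fails with an error naming the violated rule.
#'
#' @param strategy an [strategy()] (directive taken from its name).
#' @return `TRUE`, invisibly.
#' @export
audit_strategy <- function(strategy) {
  stopifnot(inherits(strategy, "ad_strategy"))
  paths <- enumerate_paths(strategy$root)
  labs <- strsplit(paths$path, " > ", fixed = TRUE)
  before <- function(seq, what, markers)
    all(vapply(which(seq == what), function(i)
      any(seq[seq_len(i - 1L)] %in% markers), logical(1L)))
  for (seq in labs) {
    if (!before(seq, "ETT", c("ICU", "transfer_ICU")))
      stop("structural violation: ETT outside the ICU")
    if (!before(seq, "no_MV", "Ward"))
      stop("structural violation: non-ventilatory treatment off the ward")
    if (strategy$name == "DNI" && "ETT" %in% seq)
      stop("structural violation: ETT under a DNI directive")
    if (!before(seq, "CMO", c("failure_to_wean", "complication")))
      stop("structural violation: CMO without preceding ventilation failure")
    if (!before(seq, "long_term_ecf",
                c("complication", "failure_to_wean", "CMO")))
      stop("structural violation: long-term ECF without complications,",
           " failure to wean, or CMO survival")
  }
  invisible(TRUE)
}

#' Evaluate a scenario: Full Code vs DNI
#'
#' Builds both strategy trees for the scenario, rolls each back to its
#' expected QALYs and returns the [recommend()]ation, including the QALY
#' difference (Full Code minus DNI).
#'
#' @inheritParams build_strategy_tree
#' @param tolerance indifference tolerance in QALYs (default `1e-9`).
#' @return An `ad_recommendation`.
#' @export
evaluate_scenario <- function(scenario, params, tolerance = 1e-9,
                              overrides = NULL) {
  recommend(list(
    build_strategy_tree("Full Code", scenario, params, overrides),
    build_strategy_tree("DNI", scenario, params, overrides)),
    tolerance = tolerance)
}

delta_qaly <- function(scenario, params, overrides = NULL) {
  evaluate_scenario(scenario, params, overrides = overrides)$delta_qaly
}
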