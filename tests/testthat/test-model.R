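params <- quiet(base_params())

test_that("generated strategy trees pass the structural audit for every
           severity and directive", {
  for (sev in c("mild", "moderate", "severe"))
    for (dir in c("Full Code", "DNI")) {
      s <- build_strategy_tree(dir, sev_scenario(sev), params)
      expect_true(audit_strategy(s))
    }
})

test_that("a DNI tree contains no ETT edge anywhere", {
  s <- build_strategy_tree("DNI", sev_scenario(), params)
  paths <- enumerate_paths(s$root)
  expect_false(any(grepl("\\bETT\\b", paths$path)))
  fc <- build_strategy_tree("Full Code", sev_scenario(), params)
  expect_true(any(grepl("\\bETT\\b", enumerate_paths(fc$root)$path)))
})

test_that("the audit rejects hand-built trees violating the constraints", {
  home <- terminal_node("home", 1)
  # ETT with no ICU ancestor
  bad1 <- strategy("Full Code", chance_node(
    "root", edge("Ward", 1, chance_node(
      "t", edge("ETT", 1, home)))))
  expect_error(audit_strategy(bad1), "ICU")
  # long-term ECF with no complication, weaning failure or CMO upstream
  bad2 <- strategy("Full Code", chance_node(
    "root", edge("Ward", 1, chance_node(
      "d", edge("long_term_ecf", 1, terminal_node("long_term_ecf", 0.5))))))
  expect_error(audit_strategy(bad2), "long-term ECF")
  bad3 <- strategy("DNI", chance_node(
    "root", edge("ICU", 1, chance_node(
      "t", edge("ETT", 1, home)))))
  expect_error(audit_strategy(bad3), "DNI")
})

test_that("with no deaths, no complications and no institutionalization both
           directives equal baseline quality-adjusted life expectancy", {
  no_risk <- c(p_death_ett = 0, p_death_nimv = 0,
               p_death_medical_severely_ill = 0,
               p_death_medical_moderately_ill = 0,
               p_death_failed_nimv_medical = 0,
               p_ett_complication = 0,
               p_cmo_after_failed_ventilation = 0,
               p_longterm_ecf = 0)
  for (sev in c("mild", "severe")) {
    expected <- params$estimates[[paste0("u_copd_", sev)]]$point *
      params$lifetable$le_copd[[sev]]
    r <- evaluate_scenario(sev_scenario(sev), params, overrides = no_risk)
    expect_equal(unname(r$ev_by_strategy["Full Code"]), expected,
                 tolerance = 1e-9)
    expect_equal(unname(r$ev_by_strategy["DNI"]), expected,
                 tolerance = 1e-9)
    expect_equal(r$recommended, "indifferent")
  }
})

test_that("strategy-tree rollback matches the exhaustive path oracle", {
  for (dir in c("Full Code", "DNI")) {
    s <- build_strategy_tree(dir, sev_scenario("moderate"), params)
    expect_equal(rollback(s$root), oracle_ev(s$root), tolerance = 1e-9)
    paths <- enumerate_paths(s$root)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-9)
    expect_equal(sum(paths$probability * paths$payoff), rollback(s$root),
                 tolerance = 1e-9)
  }
})

test_that("preference extremes drive the recommendation in the direction the
           oracle confirms", {
  sc <- sev_scenario("severe")
  # generous intubation survival, neutral preferences: Full Code
  generous <- c(p_death_ett = 0.05, u_ett_complication = 1,
                u_longterm_ecf = params$estimates$u_copd_severe$point)
  fc <- build_strategy_tree("Full Code", sc, params, generous)
  dni <- build_strategy_tree("DNI", sc, params, generous)
  expect_gt(oracle_ev(fc$root), oracle_ev(dni$root))
  expect_equal(evaluate_scenario(sc, params,
                                 overrides = generous)$recommended,
               "Full Code")
  # certain complications valued far worse than death: DNI
  averse <- c(p_ett_complication = 1, u_ett_complication = -11)
  fc2 <- build_strategy_tree("Full Code", sc, params, averse)
  dni2 <- build_strategy_tree("DNI", sc, params, averse)
  expect_lt(oracle_ev(fc2$root), oracle_ev(dni2$root))
  expect_equal(evaluate_scenario(sc, params, overrides = averse)$recommended,
               "DNI")
})

test_that("directives with identical outcome structure are indifferent", {
  same <- c(p_ett_severely_ill = 0, p_ett_moderately_ill = 0,
            p_nimv_failure_severely_ill = 0,
            p_nimv_failure_moderately_ill = 0,
            p_icu_fullcode_severely_ill =
              params$estimates$p_icu_dni_severely_ill$point,
            p_icu_fullcode_moderately_ill =
              params$estimates$p_icu_dni_moderately_ill$point,
            p_nimv_ward_fullcode = params$estimates$p_nimv_ward_dni$point)
  r <- evaluate_scenario(sev_scenario(), params, overrides = same)
  expect_equal(r$recommended, "indifferent")
  expect_equal(r$delta_qaly, 0, tolerance = 1e-12)
})

test_that("the QALY difference falls as ETT complications become likelier and
           rises with the complication and ECF utilities", {
  sc <- sev_scenario("severe")
  d_comp <- vapply(seq(0, 1, by = 0.1), function(v)
    delta_qaly(sc, params, overrides = c(p_ett_complication = v)),
    numeric(1))
  expect_true(all(diff(d_comp) <= 1e-12))
  d_ucomp <- vapply(c(-11, -5, -1, 0, 0.5, 1), function(v)
    delta_qaly(sc, params, overrides = c(u_ett_complication = v)),
    numeric(1))
  expect_true(all(diff(d_ucomp) >= -1e-12))
  d_uecf <- vapply(c(-2, -1, 0, 0.5, 1), function(v)
    delta_qaly(sc, params, overrides = c(u_longterm_ecf = v)), numeric(1))
  expect_true(all(diff(d_uecf) >= -1e-12))
})

test_that("the Full Code advantage shrinks with COPD severity under neutral
           preferences", {
  d <- vapply(c("mild", "moderate", "severe"), function(sev)
    delta_qaly(sev_scenario(sev), params), numeric(1))
  expect_gt(d[["mild"]], d[["moderate"]])
  expect_gt(d[["moderate"]], d[["severe"]])
  expect_true(all(d > 0))
})

test_that("missing parameters are reported by name", {
  crippled <- params
  crippled$estimates$p_ett_complication <- NULL
  expect_error(
    build_strategy_tree("Full Code", sev_scenario(), crippled),
    "p_ett_complication")
})

test_that("scenario construction validates the exacerbation mix", {
  expect_error(copd_scenario("severe", 1.2), "exacerbation_mix")
  expect_equal(copd_scenario("mild")$exacerbation_mix, 0.5)
})
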