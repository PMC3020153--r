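#' Fit the advance-directive decision model
#'
#' The main entry point: builds the Full Code and DNI strategy trees for a
#' COPD severity scenario, rolls each back to its expected QALYs and
#' returns a fitted model object carrying the recommendation, the full
#' root-to-leaf path tables and the inputs.  Methods: [print.copd_ad()],
#' [summary.copd_ad()] (adds the tornado analysis), [coef.copd_ad()]
#' (named point estimates) and [plot.copd_ad()] (tornado diagram or
#' preference grid).
#'
#' @param params an `ad_parameters` object from [load_parameters()] or
#'   [generate_fixture()]; the default loads the bundled synthetic fixture.
#' @param severity COPD severity: `"mild"`, `"moderate"` or `"severe"`
#'   (default taken from the parameter file's `defaults`).
#' @param exacerbation_mix probability of a severely ill (pH < 7.29)
#'   presentation (default from the parameter file, 0.5 if unspecified).
#' @param tolerance indifference tolerance in QALYs.
#' @return An object of class `copd_ad`.
#' @examples
#' fit <- copd_ad(generate_fixture(1), severity = "severe")
#' fit
#' coef(fit)[1:4]
#' @export
copd_ad <- function(params = fixture_parameters(), severity = NULL,
                    exacerbation_mix = NULL, tolerance = 1e-9) {
  stopifnot(inherits(params, "ad_parameters"))
  if (is.null(severity)) severity <- params$defaults$severity
  if (is.null(exacerbation_mix))
    exacerbation_mix <- params$defaults$exacerbation_mix
  scenario <- copd_scenario(severity, exacerbation_mix)
  strategies <- list(
    `Full Code` = build_strategy_tree("Full Code", scenario, params),
    DNI = build_strategy_tree("DNI", scenario, params))
  rec <- recommend(unname(strategies), tolerance = tolerance)
  paths <- lapply(strategies, function(s) enumerate_paths(s$root))
  structure(list(call = match.call(), scenario = scenario, params = params,
                 strategies = strategies, recommendation = rec,
                 paths = paths, tolerance = tolerance),
            class = "copd_ad")
}

#' Bundled synthetic fixture parameters
#'
#' Loads the synthetic stand-in parameter file shipped with the package
#' (`extdata/params_fixture.yaml`, generated by [generate_fixture()] with
#' seed 1).
#'
#' @export
fixture_parameters <- function() {
  path <- system.file("extdata", "params_fixture.yaml", package = "copdAD")
  suppressMessages(load_parameters(path))
}

#' @export
print.copd_ad <- function(x, ...) {
  cat("COPD advance-directive decision model\n")
  cat(sprintf("  severity: %s; P(severely ill presentation): %.2f\n",
              x$scenario$severity, x$scenario$exacerbation_mix))
  print(x$recommendation)
  invisible(x)
}

#' @param object,x a `copd_ad` fit.
#' @param ... unused.
#' @rdname copd_ad
#' @export
summary.copd_ad <- function(object, ...) {
  tor <- tornado(object$scenario, object$params)
  structure(list(fit = object, tornado = tor), class = "summary.copd_ad")
}

#' @export
print.summary.copd_ad <- function(x, ...) {
  print(x$fit)
  cat("\nMost influential parameters (one-way QALY-difference ranges):\n")
  top <- utils::head(x$tornado, 5L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-32s width %.4f%s\n", top$parameter[i], top$width[i],
                if (top$crosses_zero[i]) "  [flips the recommended AD]"
                else ""))
  invisible(x)
}

#' @rdname copd_ad
#' @export
coef.copd_ad <- function(object, ...) {
  vapply(object$params$estimates, `[[`, numeric(1L), "point")
}

#' @param type `"tornado"` or `"grid"`.
#' @rdname copd_ad
#' @export
plot.copd_ad <- function(x, type = c("tornado", "grid"), ...) {
  type <- match.arg(type)
  if (type == "tornado") {
    tor <- tornado(x$scenario, x$params)
    tor <- tor[rev(seq_len(nrow(tor))), ]
    old <- graphics::par(mar = c(4, 14, 2, 1))
    on.exit(graphics::par(old))
    graphics::plot(NULL, xlim = range(c(tor$delta_low, tor$delta_high, 0)),
                   ylim = c(0.5, nrow(tor) + 0.5), yaxt = "n",
                   xlab = "QALY difference (Full Code - DNI)", ylab = "",
                   main = paste("Tornado:", x$scenario$severity, "COPD"))
    graphics::axis(2, at = seq_len(nrow(tor)), labels = tor$parameter,
                   las = 1, cex.axis = 0.7)
    graphics::segments(pmin(tor$delta_low, tor$delta_high),
                       seq_len(nrow(tor)),
                       pmax(tor$delta_low, tor$delta_high),
                       seq_len(nrow(tor)), lwd = 6, col = "steelblue")
    graphics::abline(v = c(0, x$recommendation$delta_qaly),
                     lty = c(2, 3))
  } else {
    g <- two_way_preference_grid(x$scenario, x$params)
    z <- matrix(as.numeric(g$grid == "DNI"), nrow = nrow(g$grid))
    graphics::image(seq_along(g$ecf_tradeoffs),
                    seq_along(g$complication_tradeoffs), t(z),
                    col = c("white", "grey60"), xaxt = "n", yaxt = "n",
                    xlab = "months traded to avoid long-term ECF",
                    ylab = "months traded to avoid complication month",
                    main = paste("Preference grid (shaded = DNI):",
                                 x$scenario$severity, "COPD"))
    graphics::axis(1, seq_along(g$ecf_tradeoffs),
                   signif(g$ecf_tradeoffs, 3))
    graphics::axis(2, seq_along(g$complication_tradeoffs),
                   signif(g$complication_tradeoffs, 3))
  }
  invisible(x)
}

#' Write a full run report
#'
#' Emits the model's outputs as plain delimited files in `dir`: the
#' recommendation (`recommendation.csv`), the per-strategy path tables
#' (`paths_<strategy>.csv`), and, when requested, the tornado table
#' (`tornado.csv`) and the two-way preference grid (`grid.csv`), plus a run
#' log (`run_log.txt`) recording package version, scenario and the
#' provenance of every parameter.
#'
#' @inheritParams evaluate_scenario
#' @param analyses subset of `c("paths", "tornado", "grid")`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @export
run_report <- function(scenario, params, analyses = c("paths", "tornado",
                                                      "grid"),
                       dir = ".") {
  stopifnot(inherits(scenario, "copd_scenario"),
            inherits(params, "ad_parameters"))
  if (length(analyses)) analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  fit <- copd_ad(params, scenario$severity, scenario$exacerbation_mix)
  rec <- fit$recommendation
  wr(data.frame(strategy = c(names(rec$ev_by_strategy), "delta", "recommended"),
                value = c(unname(rec$ev_by_strategy), rec$delta_qaly, NA),
                label = c("", "", "", rec$recommended)),
     "recommendation.csv")
  if ("paths" %in% analyses)
    for (nm in names(fit$paths))
      wr(fit$paths[[nm]], paste0("paths_", gsub(" ", "_", tolower(nm)),
                                 ".csv"))
  if ("tornado" %in% analyses)
    wr(as.data.frame(tornado(scenario, params)), "tornado.csv")
  if ("grid" %in% analyses) {
    g <- two_way_preference_grid(scenario, params)
    wr(as.data.frame(g$grid), "grid.csv")
  }
  log <- c(sprintf("copdAD %s", as.character(utils::packageVersion("copdAD"))),
           sprintf("severity: %s; exacerbation_mix: %g", scenario$severity,
                   scenario$exacerbation_mix),
           sprintf("fixture seed: %s",
                   if (is.null(params$metadata$seed)) "none"
                   else params$metadata$seed),
           "parameter provenance:",
           vapply(params$estimates, function(e)
             sprintf("  %s = %g [%g, %g] (%s)", e$name, e$point, e$low,
                     e$high, e$provenance), character(1L)))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(c(files, file.path(dir, "run_log.txt")))
}
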