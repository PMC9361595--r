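#' Canonical worked-example tables
#'
#' These generators rebuild, from the package's own constructors, the
#' three canonical tables of worked examples for sequential testing under
#' bias and ignorance.  Nothing is hard-coded beyond the defining inputs
#' (sensitivities, specificities, bias levels and priors), so a
#' regression anywhere upstream breaks these tables.
#'
#' * `reproduce_table1()`: five two-tester scenarios (perfect second
#'   tester, perfect first test, two imperfect testers, and an ignorant
#'   second tester reading an imperfect or a perfect first test) and
#'   their combined matrices.
#' * `reproduce_table2()`: the same 80%/90% test under seven bias levels
#'   (0, 20, 40, 50, 60, 80, 100%), with the PPV of the diagnosis at a
#'   20% prior and of the alternative diagnosis at the complementary 80%
#'   prior.
#' * `reproduce_table3()`: an 80%/95% test at a 50/50 prior in the hands
#'   of an unbiased, a fully bias-inverted, an informed and an ignorant
#'   (60/30 concordance) tester.
#'
#' @return An object of class `table_report`: list with `layout_id` and
#'   `rows`, a data frame whose integer columns are half-up rounded
#'   percentages ([round_percent()]) and whose `*_frac` columns retain the
#'   matching full-precision fractions.
#' @examples
#' reproduce_table2()
#' @seealso [figure1_curves()], [write_table_report()]
#' @export
reproduce_table1 <- function() {
  scenarios <- list(
    list(label = "Perfect 2nd tester",
         second = make_test_matrix(1.0, 1.0),
         first  = make_test_matrix(0.80, 0.90)),
    list(label = "Perfect 1st tester",
         second = make_test_matrix(0.80, 0.90),
         first  = make_test_matrix(1.0, 1.0)),
    list(label = "Imperfect 2 testers",
         second = make_test_matrix(0.80, 0.90),
         first  = make_test_matrix(0.70, 0.85)),
    list(label = "Ignorant 2nd tester (imperfect 1st)",
         second = make_test_matrix(0.50, 0.50),
         first  = make_test_matrix(0.70, 0.85)),
    list(label = "Ignorant 2nd tester (perfect 1st)",
         second = make_test_matrix(0.50, 0.50),
         first  = make_test_matrix(1.0, 1.0))
  )
  rows <- do.call(rbind, lapply(scenarios, function(s) {
    combined <- compose(s$second, s$first)
    cbind(
      data.frame(scenario = s$label),
      matrix_cols(s$second, "2"), matrix_cols(s$first, "1"),
      matrix_cols(combined, ""), matrix_frac_cols(combined, "")
    )
  }))
  new_table_report(rows, "table1")
}

#' @rdname reproduce_table1
#' @export
reproduce_table2 <- function() {
  bias_levels <- c(0, 0.2, 0.4, 0.5, 0.6, 0.8, 1.0)
  test <- make_test_matrix(0.80, 0.90)
  prior <- 0.20
  rows <- do.call(rbind, lapply(bias_levels, function(b) {
    biased <- compose(make_bias_matrix(b), test)
    v <- ppv(prior, biased)
    cbind(
      data.frame(bias = round_percent(b)),
      matrix_cols(biased, ""),
      data.frame(
        p = round_percent(prior), ppv = round_percent(v),
        p_alt = round_percent(1 - prior), ppv_alt = round_percent(1 - v)
      ),
      matrix_frac_cols(biased, ""),
      data.frame(ppv_frac = v, ppv_alt_frac = 1 - v)
    )
  }))
  new_table_report(rows, "table2")
}

#' @rdname reproduce_table1
#' @export
reproduce_table3 <- function() {
  test <- make_test_matrix(0.80, 0.95)
  prior <- 0.50
  scenarios <- list(
    list(label = "Unbiased tester", modifier = make_bias_matrix(0)),
    list(label = "Biased tester",   modifier = make_bias_matrix(1)),
    list(label = "Informed tester",
         modifier = make_asymmetric_matrix(1.0, 0.0, role = "ignorance")),
    list(label = "Ignorant tester",
         modifier = make_asymmetric_matrix(0.60, 0.30, role = "ignorance"))
  )
  rows <- do.call(rbind, lapply(scenarios, function(s) {
    combined <- if (identical(s$modifier$role, "ignorance"))
      apply_ignorance(s$modifier, test) else compose(s$modifier, test)
    v <- ppv(prior, combined)
    cbind(
      data.frame(scenario = s$label),
      matrix_cols(s$modifier, "_mod"), matrix_cols(test, "_test"),
      matrix_cols(combined, ""),
      data.frame(
        p = round_percent(prior), ppv = round_percent(v),
        p_alt = round_percent(1 - prior), ppv_alt = round_percent(1 - v)
      ),
      matrix_frac_cols(combined, ""),
      data.frame(ppv_frac = v, ppv_alt_frac = 1 - v)
    )
  }))
  new_table_report(rows, "table3")
}

# integer-percent and full-precision column blocks for one matrix
matrix_cols <- function(m, suffix) {
  out <- data.frame(
    round_percent(m$tp), round_percent(m$fp),
    round_percent(m$fn), round_percent(m$tn)
  )
  names(out) <- paste0(c("tp", "fp", "fn", "tn"), suffix)
  out
}

matrix_frac_cols <- function(m, suffix) {
  out <- data.frame(m$tp, m$fp, m$fn, m$tn)
  names(out) <- paste0(c("tp", "fp", "fn", "tn"), suffix, "_frac")
  out
}

new_table_report <- function(rows, layout_id) {
  structure(list(layout_id = layout_id, rows = rows),
            class = "table_report")
}

#' @export
print.table_report <- function(x, ...) {
  cat(sprintf("<table_report \"%s\"> (integer percents; *_frac columns hold full precision)\n",
              x$layout_id))
  print(x$rows[, !grepl("_frac$", names(x$rows)), drop = FALSE],
        row.names = FALSE)
  invisible(x)
}

#' Write a table report to CSV
#'
#' @param report A [table_report][reproduce_table1].
#' @param path Output file path (or a connection such as `stdout()`).
#' @return `path`, invisibly.
#' @export
write_table_report <- function(report, path) {
  if (!inherits(report, "table_report"))
    stop_usage("`report` must be a table_report")
  utils::write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}

#' Posterior trajectories of consecutive biased tests
#'
#' For each bias level, composes the bias matrix with the primary test and
#' iterates Bayes' formula over consecutive positive results, giving the
#' curve family of posterior probability versus number of tests: the
#' posterior of the diagnosis and, pointwise complementary, of the
#' alternative diagnosis.  With no bias an 80%/90% test needs only 2
#' positive results to lift a 20% prior above 90%; a 50% bias pins the
#' posterior at the prior forever; bias beyond 50% drives it downwards, so
#' positive results seemingly confirm the alternative diagnosis.
#'
#' @param bias_levels Fractions in `[0, 1]` (default a 0--100% grid in
#'   steps of 10 points).
#' @param prior Pre-test probability of the diagnosis (default 0.20).
#' @param max_tests Chain length to tabulate (default 6, the range
#'   displayed; use [min_positive_tests()] with its larger default for
#'   threshold searches).
#' @param test The primary [test_matrix][make_test_matrix]
#'   (default sensitivity 80%, specificity 90%).
#' @return A data frame with columns `bias`, `n_tests`, `posterior`,
#'   `alternative_posterior` (fractions).
#' @examples
#' curves <- figure1_curves(c(0, 0.2, 0.5, 1.0))
#' subset(curves, bias == 0.5)  # flat at the prior
#' @export
figure1_curves <- function(bias_levels = seq(0, 1, by = 0.1),
                           prior = 0.20, max_tests = 6L,
                           test = make_test_matrix(0.80, 0.90)) {
  if (!is.numeric(bias_levels) || length(bias_levels) == 0L)
    stop_usage("`bias_levels` must be a non-empty numeric vector")
  prior <- check_prob(prior, "prior")
  validate_test_matrix(test)
  max_tests <- as.integer(max_tests)
  if (is.na(max_tests) || max_tests < 1L)
    stop_usage("`max_tests` must be a positive integer")
  do.call(rbind, lapply(bias_levels, function(b) {
    combined <- compose(make_bias_matrix(b), test)
    tr <- update_sequence(prior, combined, rep("+", max_tests))
    data.frame(
      bias = b,
      n_tests = seq_len(max_tests),
      posterior = tr$posteriors,
      alternative_posterior = 1 - tr$posteriors
    )
  }))
}

#' Plot a family of posterior curves
#'
#' Thin base-graphics layer over [figure1_curves()]: one curve per bias
#' level, posterior of the diagnosis (`panel = "diagnosis"`) or of the
#' alternative diagnosis (`panel = "alternative"`).
#'
#' @param curves Data frame from [figure1_curves()].
#' @param panel `"diagnosis"` or `"alternative"`.
#' @param ... Passed to [graphics::matplot()].
#' @return The input, invisibly.
#' @export
plot_figure1 <- function(curves, panel = c("diagnosis", "alternative"), ...) {
  panel <- match.arg(panel)
  col <- if (panel == "diagnosis") "posterior" else "alternative_posterior"
  wide <- stats::reshape(
    curves[, c("bias", "n_tests", col)], direction = "wide",
    idvar = "n_tests", timevar = "bias")
  graphics::matplot(wide$n_tests, as.matrix(wide[, -1, drop = FALSE]),
                    type = "b", pch = 1, ylim = c(0, 1),
                    xlab = "consecutive positive tests",
                    ylab = sprintf("posterior of %s", panel), ...)
  invisible(curves)
}

#' Deterministic random valid test matrix
#'
#' Property-test fixture: draws `tp` and `fp` independently uniform on
#' `[0, 1]` under the given seed, filling the bottom row by
#' column-stochasticity.  The global random-number state is saved and
#' restored, so the generator is a pure function of its seed.  About half
#' of all draws have a negative Youden index (a "biased-tester" matrix),
#' which is exactly the regime ordinary diagnostic tests never visit.
#'
#' @param seed A single integer.
#' @return A valid [test_matrix][make_test_matrix].
#' @examples
#' identical(random_valid_matrix(7), random_valid_matrix(7))
#' @export
random_valid_matrix <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_usage("`seed` must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  )
  set.seed(as.integer(seed))
  u <- stats::runif(2L)
  make_asymmetric_matrix(u[[1L]], u[[2L]])
}

#' Scenario bundles
#'
#' A scenario names a primary test matrix, an optional modifier (bias or
#' ignorance matrix), a prior, and optionally a result chain and/or a
#' posterior threshold to search for.  `run_scenario()` composes the
#' modifier onto the test, computes the PPV of the diagnosis and of the
#' alternative diagnosis, and -- when requested -- the update trace and
#' the minimum-positive-tests search.
#'
#' @param name Scenario label (unique within a scenario set).
#' @param primary Primary [test_matrix][make_test_matrix].
#' @param prior Pre-test probability in `[0, 1]`.
#' @param modifier Optional bias/ignorance matrix (later-acting, composed
#'   on the left).
#' @param results Optional character vector of `"+"`/`"-"` results.
#' @param threshold Optional posterior threshold in `(0, 1)`.
#' @param max_tests Search limit for the threshold search.
#' @return `scenario()`: an object of class `scenario`;
#'   `run_scenario()`: an object of class `scenario_result` with the
#'   combined matrix, `ppv`, `alternative_ppv`, and optional `trace` and
#'   `chain` components.
#' @examples
#' s <- scenario("biased", make_test_matrix(0.8, 0.95), 0.5,
#'               modifier = make_bias_matrix(1))
#' run_scenario(s)
#' @seealso [parse_scenario_file()]
#' @export
scenario <- function(name, primary, prior, modifier = NULL,
                     results = NULL, threshold = NULL, max_tests = 1000L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_usage("`name` must be a non-empty string")
  validate_test_matrix(primary)
  prior <- check_prob(prior, "prior")
  if (!is.null(modifier)) validate_test_matrix(modifier)
  if (!is.null(results)) {
    results <- as.character(results)
    if (length(results) && !all(results %in% c("+", "-")))
      stop_domain("`results` must contain only \"+\" and \"-\"",
                  field = "results", class = "diagbias_validation_error")
  }
  if (!is.null(threshold)) check_prob(threshold, "threshold")
  structure(
    list(name = name, primary = primary, modifier = modifier, prior = prior,
         results = results, threshold = threshold,
         max_tests = as.integer(max_tests)),
    class = "scenario"
  )
}

#' @rdname scenario
#' @param s A `scenario`.
#' @export
run_scenario <- function(s) {
  if (!inherits(s, "scenario"))
    stop_usage("`s` must be a scenario object")
  combined <- if (is.null(s$modifier)) s$primary
              else compose(s$modifier, s$primary)
  out <- list(
    name = s$name, combined = combined, prior = s$prior,
    ppv = ppv(s$prior, combined),
    alternative_ppv = alternative_ppv(s$prior, combined)
  )
  if (!is.null(s$results))
    out$trace <- update_sequence(s$prior, combined, s$results)
  if (!is.null(s$threshold))
    out$chain <- min_positive_tests(s$prior, combined, s$threshold,
                                    s$max_tests)
  structure(out, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("== %s ==\n", x$name))
  print(x$combined)
  cat(sprintf("prior %d%%  PPV %d%% (%.4f)  alternative PPV %d%% (%.4f)\n",
              round_percent(x$prior),
              round_percent(x$ppv), x$ppv,
              round_percent(x$alternative_ppv), x$alternative_ppv))
  if (!is.null(x$trace)) print(x$trace)
  if (!is.null(x$chain)) print(x$chain)
  invisible(x)
}
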