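#' Bayes updating of a diagnostic probability
#'
#' `ppv()` is Bayes' formula for the positive predictive value -- the
#' post-test probability of the diagnosis after a positive result:
#' \deqn{PPV = \frac{p \cdot TP}{p \cdot TP + (1 - p) \cdot FP}}
#' where `p` is the pre-test probability (prevalence or an a-priori
#' estimate).  `posterior_negative()` is the complementary update after a
#' negative result, \eqn{p\,FN / (p\,FN + (1-p)\,TN)}; the canonical
#' analyses here exercise only positive chains, but the negative update is
#' provided for completeness.  `alternative_ppv()` is the predictive value
#' the same positive result assigns to the alternative (negative)
#' diagnosis, the strict binary complement `1 - ppv()`.
#'
#' `p = 0` and `p = 1` are absorbing whenever the denominator is positive;
#' a genuinely zero denominator (the observed result is impossible under
#' both diagnoses weighted by `p`) raises an undefined-posterior error
#' rather than silently returning a value.
#'
#' @param p Pre-test probability, a fraction in `[0, 1]`.
#' @param m A [test_matrix][make_test_matrix] (typically the combined,
#'   bias- or ignorance-degraded matrix).
#' @return A posterior probability in `[0, 1]`.
#' @examples
#' ppv(0.20, make_test_matrix(0.80, 0.90))          # 0.667: 20% -> 67%
#' ppv(0.20, make_bias_matrix(0.5))                 # 0.20: worthless test
#' alternative_ppv(0.20, make_test_matrix(0.8, 0.9))
#' @seealso [update_sequence()], [min_positive_tests()]
#' @export
ppv <- function(p, m) {
  p <- check_prob(p, "p")
  validate_test_matrix(m)
  num <- p * m$tp
  den <- num + (1 - p) * m$fp
  if (den <= 0)
    stop_domain("posterior undefined: Pr(T+) = 0 under this prior and matrix",
                class = "diagbias_undefined_posterior")
  num / den
}

#' @rdname ppv
#' @export
alternative_ppv <- function(p, m) {
  1 - ppv(p, m)
}

#' @rdname ppv
#' @export
posterior_negative <- function(p, m) {
  p <- check_prob(p, "p")
  validate_test_matrix(m)
  num <- p * m$fn
  den <- num + (1 - p) * m$tn
  if (den <= 0)
    stop_domain("posterior undefined: Pr(T-) = 0 under this prior and matrix",
                class = "diagbias_undefined_posterior")
  num / den
}

#' Iterated Bayes updating over a chain of test results
#'
#' Applies Bayes' formula repetitively: each result's posterior becomes
#' the next result's prior, with the same test characteristics assumed for
#' every consecutive test.  `"+"` results update via [ppv()], `"-"`
#' results via [posterior_negative()].
#'
#' The final posterior is invariant to the order of the results (the
#' likelihood ratios commute), and after `k` positive results has the
#' closed form \eqn{p\,TP^k / (p\,TP^k + (1-p)\,FP^k)}.  A matrix with
#' Youden index 0 leaves the prior unchanged by any sequence.
#'
#' @inheritParams ppv
#' @param results Character vector of result symbols `"+"` / `"-"`
#'   (may be empty).
#' @return An object of class `update_trace`: list with `prior`,
#'   `results`, `posteriors` (one per result) and `matrix`.
#' @examples
#' update_sequence(0.20, make_test_matrix(0.8, 0.9), c("+", "+"))
#' @export
update_sequence <- function(p, m, results) {
  p <- check_prob(p, "p")
  validate_test_matrix(m)
  results <- as.character(results)
  if (length(results) && !all(results %in% c("+", "-")))
    stop_usage("`results` must contain only \"+\" and \"-\" symbols")
  posteriors <- numeric(length(results))
  cur <- p
  for (i in seq_along(results)) {
    cur <- if (results[[i]] == "+") ppv(cur, m) else posterior_negative(cur, m)
    posteriors[[i]] <- cur
  }
  structure(
    list(prior = p, results = results, posteriors = posteriors, matrix = m),
    class = "update_trace"
  )
}

#' @export
print.update_trace <- function(x, ...) {
  cat(sprintf("<update_trace> prior = %.4f, %d result(s)\n",
              x$prior, length(x$results)))
  if (length(x$results))
    print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.update_trace <- function(x, ...) {
  data.frame(
    step = seq_along(x$results),
    result = x$results,
    posterior = x$posteriors,
    posterior_pct = if (length(x$posteriors)) round_percent(x$posteriors)
                    else integer(0)
  )
}

#' @export
plot.update_trace <- function(x, ...) {
  graphics::plot(
    c(0, seq_along(x$posteriors)), c(x$prior, x$posteriors),
    type = "b", ylim = c(0, 1), xlab = "consecutive tests",
    ylab = "posterior probability", ...)
  invisible(x)
}

#' Minimum consecutive positive tests to exceed a posterior threshold
#'
#' Searches for the smallest number `n` of consecutive positive results of
#' the same test such that the iterated posterior strictly exceeds
#' `threshold`, starting from prior `p`.  The comparison is strict
#' (`> threshold`) at full precision.  If the Youden index of `m` is
#' non-positive and `p <= threshold` the posterior can never rise above
#' the prior, so the search returns the sentinel immediately; otherwise it
#' iterates up to `max_tests` and reports the sentinel if the threshold is
#' never crossed (e.g. a 50% bias pins the posterior at the prior
#' forever).
#'
#' @inheritParams ppv
#' @param threshold Target posterior, a fraction in `(0, 1)`.
#' @param max_tests Maximum chain length to try (default 1000).
#' @return An object of class `chain_search`: list with `n_tests`
#'   (positive integer, or `NA` for "unreachable"), `reachable`,
#'   `threshold`, `max_tests` and the full `trace`
#'   ([update_trace][update_sequence]).  When `n_tests` is an integer the
#'   posterior after `n_tests` results strictly exceeds `threshold` and
#'   the posterior after `n_tests - 1` does not.
#' @examples
#' # 2 positive 80/90 tests raise a 20% prior above 90%
#' min_positive_tests(0.20, make_test_matrix(0.8, 0.9), 0.90)
#' # a 50% bias makes the chain worthless
#' biased <- compose(make_bias_matrix(0.5), make_test_matrix(0.8, 0.9))
#' min_positive_tests(0.20, biased, 0.90, max_tests = 50)
#' @export
min_positive_tests <- function(p, m, threshold, max_tests = 1000L) {
  p <- check_prob(p, "p")
  validate_test_matrix(m)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold >= 1)
    stop_usage("`threshold` must be a single fraction strictly inside (0, 1)")
  if (!is.numeric(max_tests) || length(max_tests) != 1L || is.na(max_tests) ||
      max_tests < 1)
    stop_usage("`max_tests` must be a positive integer")
  max_tests <- as.integer(max_tests)

  if (youden(m) <= 0 && p <= threshold) {
    trace <- update_sequence(p, m, character(0))
    return(new_chain_search(NA_integer_, threshold, max_tests, trace))
  }

  posteriors <- numeric(0)
  cur <- p
  n <- NA_integer_
  for (k in seq_len(max_tests)) {
    cur <- ppv(cur, m)
    posteriors[[k]] <- cur
    if (cur > threshold) {
      n <- k
      break
    }
  }
  trace <- structure(
    list(prior = p, results = rep("+", length(posteriors)),
         posteriors = posteriors, matrix = m),
    class = "update_trace"
  )
  new_chain_search(n, threshold, max_tests, trace)
}

new_chain_search <- function(n_tests, threshold, max_tests, trace) {
  structure(
    list(n_tests = n_tests, reachable = !is.na(n_tests),
         threshold = threshold, max_tests = max_tests, trace = trace),
    class = "chain_search"
  )
}

#' @export
print.chain_search <- function(x, ...) {
  if (x$reachable) {
    cat(sprintf(
      "%d consecutive positive test(s) raise the prior %.4f above %.4f (posterior %.4f)\n",
      x$n_tests, x$trace$prior, x$threshold,
      x$trace$posteriors[[x$n_tests]]))
  } else {
    cat(sprintf(
      "unreachable: posterior never exceeds %.4f within %d tests (prior %.4f)\n",
      x$threshold, x$max_tests, x$trace$prior))
  }
  invisible(x)
}
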