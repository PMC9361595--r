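#' Sensitivity-specificity matrices
#'
#' A diagnostic test -- or any dichotomous judgement, including the judgement
#' of a human tester -- is described by a column-stochastic 2x2 matrix of
#' conditional probabilities \eqn{\Pr(\text{result} \mid \text{diagnosis})}:
#' rows are the test result (T+, T-), columns the true diagnosis (Dx+, Dx-).
#' The entries are the true-positive fraction (sensitivity,
#' \eqn{\Pr(T+|Dx+)}), false-positive fraction (\eqn{\Pr(T+|Dx-)}),
#' false-negative fraction (\eqn{\Pr(T-|Dx+)}) and true-negative fraction
#' (specificity, \eqn{\Pr(T-|Dx-)}).  Each column sums to 1.
#'
#' The same structure describes a tester's *bias* (preference for reporting
#' each result given the underlying result) and *ignorance* (concordance
#' between an amateur's and an expert's diagnoses); the `role` field records
#' which interpretation is intended.  Unlike a physical test, a biased human
#' tester may have entries below 0.5 -- diagonal dominance is not required.
#'
#' @param sens,spec Sensitivity and specificity, fractions in `[0, 1]`.
#' @param role Free-text role label, one of `"test"`, `"bias"`,
#'   `"ignorance"`, `"combined"`.
#' @return An object of class `test_matrix`: a list with numeric fields
#'   `tp`, `fp`, `fn`, `tn` and a character `role`.
#' @examples
#' make_test_matrix(0.80, 0.90)
#' make_bias_matrix(0.2)              # 20% preference for false results
#' make_asymmetric_matrix(0.60, 0.30, role = "ignorance")
#' @seealso [compose()], [ppv()], [youden()]
#' @export
make_test_matrix <- function(sens, spec, role = "test") {
  sens <- check_prob(sens, "sens")
  spec <- check_prob(spec, "spec")
  new_test_matrix(tp = sens, fp = 1 - spec, fn = 1 - sens, tn = spec,
                  role = role)
}

#' @rdname make_test_matrix
#' @param bias Preference weight in `[0, 1]` given to false results.
#'   `bias = 0` is the unbiased (identity) tester: absolute preference for
#'   true positive/negative results.  `bias = 1` is the fully inverted
#'   tester, the anti-identity matrix.  `bias = 0.5` destroys all
#'   discriminatory power.
#' @export
make_bias_matrix <- function(bias, role = "bias") {
  bias <- check_prob(bias, "bias")
  new_test_matrix(tp = 1 - bias, fp = bias, fn = bias, tn = 1 - bias,
                  role = role)
}

#' @rdname make_test_matrix
#' @param tp,fp Top-row entries \eqn{\Pr(T+|Dx+)} and \eqn{\Pr(T+|Dx-)};
#'   the bottom row is filled in by column-stochasticity.  This is the
#'   general constructor: ignorance matrices need not be symmetric.
#' @export
make_asymmetric_matrix <- function(tp, fp, role = "test") {
  tp <- check_prob(tp, "tp")
  fp <- check_prob(fp, "fp")
  new_test_matrix(tp = tp, fp = fp, fn = 1 - tp, tn = 1 - fp, role = role)
}

# internal low-level constructor + validator
new_test_matrix <- function(tp, fp, fn, tn, role = "test") {
  m <- structure(
    list(tp = as.numeric(tp), fp = as.numeric(fp),
         fn = as.numeric(fn), tn = as.numeric(tn),
         role = as.character(role)),
    class = "test_matrix"
  )
  validate_test_matrix(m)
}

#' Validate a sensitivity-specificity matrix
#'
#' Checks that all four entries lie in `[0, 1]` and that both columns are
#' stochastic (`tp + fn = 1`, `fp + tn = 1`) within `tol`.
#'
#' @param m A [test_matrix][make_test_matrix].
#' @param tol Numeric tolerance for the column sums.
#' @return `m`, invisibly, or a validation error.
#' @export
validate_test_matrix <- function(m, tol = 1e-12) {
  if (!inherits(m, "test_matrix"))
    stop_domain("expected a `test_matrix` object",
                class = "diagbias_validation_error")
  for (f in c("tp", "fp", "fn", "tn")) {
    v <- m[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_domain(sprintf("entry `%s` must be in [0, 1], got %s",
                          f, paste(format(v), collapse = ", ")),
                  field = f, class = "diagbias_validation_error")
  }
  if (abs(m$tp + m$fn - 1) > tol)
    stop_domain(sprintf("column Dx+ not stochastic: tp + fn = %.15g",
                        m$tp + m$fn),
                class = "diagbias_validation_error")
  if (abs(m$fp + m$tn - 1) > tol)
    stop_domain(sprintf("column Dx- not stochastic: fp + tn = %.15g",
                        m$fp + m$tn),
                class = "diagbias_validation_error")
  invisible(m)
}

#' Youden index of a test matrix
#'
#' `youden(m)` returns sensitivity + specificity - 1, equivalently
#' `tp - fp`, a value in `[-1, 1]`.  It is 1 for a perfect test, 0 for a
#' worthless one, and negative for a bias-inverted tester whose positive
#' results argue *against* the diagnosis.  The Youden index multiplies
#' under sequential composition, which makes precise the observation that
#' a chain of testers is at best as good as its weakest link.
#'
#' @param m A [test_matrix][make_test_matrix].
#' @return A number in `[-1, 1]`.
#' @examples
#' youden(make_test_matrix(0.8, 0.9))   # 0.7
#' youden(make_bias_matrix(0.5))        # 0: worthless
#' @export
youden <- function(m) {
  validate_test_matrix(m)
  m$tp - m$fp
}

#' Round a fraction to an integer percent
#'
#' Display helper: half-up rounding of `100 * x`, the convention used when
#' rendering matrices and predictive values as integer-percent tables.
#' All computation is carried at full precision; rounding happens only at
#' the output boundary.
#'
#' @param x Numeric vector of fractions in `[0, 1]`.
#' @return Integer vector of percentages.
#' @examples
#' round_percent(0.6316)  # 63
#' round_percent(0.205)   # 21 (half rounds up)
#' @export
round_percent <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop_domain("`x` must be fractions in [0, 1]", field = "x")
  # small guard so values that are exactly k + 0.5 up to representation
  # error round half-up regardless of the sign of that error
  as.integer(floor(100 * x + 0.5 + 1e-9))
}

#' @export
as.matrix.test_matrix <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2L,
         dimnames = list(c("T+", "T-"), c("Dx+", "Dx-")))
}

#' @export
format.test_matrix <- function(x, percent = TRUE, ...) {
  m <- as.matrix(x)
  if (percent) {
    out <- matrix(as.character(round_percent(c(m))), 2L, 2L,
                  dimnames = dimnames(m))
  } else {
    out <- matrix(format(c(m), ...), 2L, 2L, dimnames = dimnames(m))
  }
  out
}

#' @export
print.test_matrix <- function(x, ...) {
  cat(sprintf("<test_matrix role=\"%s\"> (column percentages)\n", x$role))
  print(format(x), quote = FALSE)
  cat(sprintf("fractions: tp=%g fp=%g fn=%g tn=%g   youden=%g\n",
              x$tp, x$fp, x$fn, x$tn, x$tp - x$fp))
  invisible(x)
}

#' Serialize / parse a test matrix as JSON
#'
#' The interchange format carries the top-row entries in percent
#' (full precision) plus the role; the bottom row is reconstructed by
#' column-stochasticity on read.  `matrix_from_list()` also accepts the
#' scenario-file shorthands `{"sens": 80, "spec": 90}` and
#' `{"bias": 20}`; all values are percentages and are divided by 100.
#'
#' @param m A [test_matrix][make_test_matrix].
#' @return `matrix_to_json()`: a JSON string; `matrix_from_json()`,
#'   `matrix_from_list()`: a `test_matrix`.
#' @examples
#' m <- make_test_matrix(0.8, 0.9)
#' matrix_from_json(matrix_to_json(m))
#' @export
matrix_to_json <- function(m) {
  validate_test_matrix(m)
  jsonlite::toJSON(list(tp = 100 * m$tp, fp = 100 * m$fp, role = m$role),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname matrix_to_json
#' @param txt A JSON string as produced by `matrix_to_json()`.
#' @export
matrix_from_json <- function(txt) {
  matrix_from_list(jsonlite::fromJSON(txt, simplifyVector = FALSE), "matrix")
}

#' @rdname matrix_to_json
#' @param x A named list with percent-valued entries: either
#'   `sens`/`spec`, or `bias`, or `tp`/`fp` (optionally with `role`).
#' @param where Label used in error messages (e.g. the JSON field path).
#' @export
matrix_from_list <- function(x, where = "matrix") {
  if (!is.list(x))
    stop_domain(sprintf("`%s` must be an object", where), field = where,
                class = "diagbias_validation_error")
  pc <- function(key) {
    v <- x[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop_domain(sprintf("`%s.%s` must be a single number (percent)",
                          where, key),
                  field = key, class = "diagbias_validation_error")
    v / 100
  }
  if (!is.null(x$sens) || !is.null(x$spec)) {
    if (is.null(x$sens) || is.null(x$spec))
      stop_domain(sprintf("`%s` needs both `sens` and `spec`", where),
                  field = where, class = "diagbias_validation_error")
    make_test_matrix(pc("sens"), pc("spec"), role = x$role %||% "test")
  } else if (!is.null(x$bias)) {
    make_bias_matrix(pc("bias"))
  } else if (!is.null(x$tp) && !is.null(x$fp)) {
    make_asymmetric_matrix(pc("tp"), pc("fp"), role = x$role %||% "test")
  } else {
    stop_domain(sprintf(
      "`%s` must contain either sens/spec, bias, or tp/fp", where),
      field = where, class = "diagbias_validation_error")
  }
}
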