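#' Sequential composition of test matrices
#'
#' When the output of one test feeds a second tester (an attending reading
#' a resident's report, an editor relying on a reviewer, a clinician
#' interpreting an imaging finding), the chain's overall test
#' characteristics are the matrix product of the later tester's matrix
#' with the earlier test's matrix:
#' \deqn{TP_s = TP_2 TP_1 + FP_2 FN_1,\quad FP_s = TP_2 FP_1 + FP_2 TN_1,}
#' \deqn{FN_s = FN_2 TP_1 + TN_2 FN_1,\quad TN_s = FN_2 FP_1 + TN_2 TN_1.}
#' Column-stochasticity is preserved by the arithmetic itself (no
#' renormalization is applied), and the Youden index multiplies:
#' `youden(compose(A, B)) == youden(A) * youden(B)`.  Since
#' `|youden| <= 1`, a chain is never better than its weakest member, and
#' one worthless link (`youden == 0`) destroys the whole chain.
#'
#' The modifier acts on the left: `compose(second, first)` with the
#' later-acting matrix first in the argument list.  Bias and ignorance are
#' modelled as exactly this kind of add-on sequential test, so a biased
#' tester's effective matrix is `compose(make_bias_matrix(b), test)`.
#'
#' @param second The later-acting [test_matrix][make_test_matrix]
#'   (the interpreting tester, bias, or ignorance matrix).
#' @param first The earlier-acting test matrix.
#' @return A `test_matrix` with role `"combined"`.
#' @examples
#' compose(make_test_matrix(0.80, 0.90), make_test_matrix(0.70, 0.85))
#' # a 20% bias degrades an 80/90 test to 68/74:
#' compose(make_bias_matrix(0.2), make_test_matrix(0.80, 0.90))
#' @seealso [compose_chain()], [apply_ignorance()], [youden()]
#' @export
compose <- function(second, first) {
  validate_test_matrix(second)
  validate_test_matrix(first)
  new_test_matrix(
    tp = second$tp * first$tp + second$fp * first$fn,
    fp = second$tp * first$fp + second$fp * first$tn,
    fn = second$fn * first$tp + second$tn * first$fn,
    tn = second$fn * first$fp + second$tn * first$tn,
    role = "combined"
  )
}

#' @rdname compose
#' @param matrices A non-empty list of test matrices ordered
#'   later-acting first (the last observer in the chain is the first list
#'   element); the result is the left fold
#'   `compose(compose(m[[1]], m[[2]]), m[[3]]) ...`.  Matrix
#'   multiplication is associative, so any bracketing gives the same
#'   chain.  A singleton list returns its element.
#' @export
compose_chain <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop_usage("`matrices` must be a non-empty list of test matrices")
  if (length(matrices) == 1L) {
    validate_test_matrix(matrices[[1L]])
    return(matrices[[1L]])
  }
  Reduce(compose, matrices)
}

#' @rdname compose
#' @param ignorance A test matrix with role `"ignorance"`: the concordance
#'   between an amateur's and an expert's diagnoses.  Numerically this is
#'   `compose(ignorance, test)`; the separate name keeps the conceptual
#'   distinction between a preference (bias) and a lack of understanding
#'   (ignorance), which degrade the test through the same algebra.
#' @param test The primary test matrix.
#' @export
apply_ignorance <- function(ignorance, test) {
  validate_test_matrix(ignorance)
  if (!identical(ignorance$role, "ignorance"))
    stop_domain(
      sprintf("`ignorance` must have role \"ignorance\", got \"%s\"",
              ignorance$role),
      field = "role", class = "diagbias_validation_error")
  compose(ignorance, test)
}
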