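# Independent oracles, deliberately written against the probability model
# rather than the package's matrix arithmetic.

# Combined test characteristics of "first test feeds second tester" by
# exhaustive enumeration of the joint distribution over
# {Dx+,Dx-} x {T1+,T1-} x {report+,report-}.
brute_force_compose <- function(second, first, prior = 0.3) {
  grid <- expand.grid(dx = c(TRUE, FALSE), t1 = c(TRUE, FALSE),
                      t2 = c(TRUE, FALSE))
  pr_dx <- ifelse(grid$dx, prior, 1 - prior)
  pr_t1 <- ifelse(grid$dx,
                  ifelse(grid$t1, first$tp, first$fn),
                  ifelse(grid$t1, first$fp, first$tn))
  pr_t2 <- ifelse(grid$t1,
                  ifelse(grid$t2, second$tp, second$fn),
                  ifelse(grid$t2, second$fp, second$tn))
  joint <- pr_dx * pr_t1 * pr_t2
  list(
    tp = sum(joint[grid$t2 & grid$dx]) / sum(joint[grid$dx]),
    fp = sum(joint[grid$t2 & !grid$dx]) / sum(joint[!grid$dx]),
    fn = sum(joint[!grid$t2 & grid$dx]) / sum(joint[grid$dx]),
    tn = sum(joint[!grid$t2 & !grid$dx]) / sum(joint[!grid$dx])
  )
}

# Closed-form posterior after k positive results of the same test.
closed_form_k_posterior <- function(p, m, k) {
  p * m$tp^k / (p * m$tp^k + (1 - p) * m$fp^k)
}

# Posterior of an arbitrary result sequence via the likelihood-ratio
# product on the odds scale.
lr_posterior <- function(p, m, results) {
  lr <- prod(ifelse(results == "+", m$tp / m$fp, m$fn / m$tn))
  odds <- p / (1 - p) * lr
  odds / (1 + odds)
}

# Smallest k with the closed-form posterior strictly above the threshold.
closed_form_min_tests <- function(p, m, threshold, max_tests = 1000L) {
  for (k in seq_len(max_tests)) {
    if (closed_form_k_posterior(p, m, k) > threshold) return(k)
  }
  NA_integer_
}

random_matrix_pair <- function() {
  u <- runif(4)
  list(make_asymmetric_matrix(u[1], u[2]),
       make_asymmetric_matrix(u[3], u[4]))
}
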