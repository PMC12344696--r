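# Shared fixtures built in code.

# ANS/protein displacement lifetime table: tau_i (ns), alpha_i, printed
# tau_av (ns), one row per ligand addition step.
ans_lifetime_table <- data.frame(
  label  = c("protein only", "+7.3 uM", "+12 uM", "+17.8 uM", "+24.6 uM",
             "+32.2 uM", "+40.7 uM", "+50.8 uM", "+60.5 uM"),
  tau1   = c(0.51, 0.65, 0.65, 0.63, 0.66, 0.66, 0.66, 0.61, 0.56),
  alpha1 = c(0.39, 0.48, 0.53, 0.58, 0.63, 0.68, 0.74, 0.80, 0.84),
  tau2   = c(7.67, 6.43, 6.15, 5.63, 5.42, 5.26, 5.03, 4.54, 4.30),
  alpha2 = c(0.20, 0.25, 0.24, 0.23, 0.21, 0.19, 0.16, 0.13, 0.10),
  tau3   = c(18.86, 18.10, 17.90, 17.51, 17.40, 17.30, 17.17, 17.06, 17.10),
  alpha3 = c(0.41, 0.27, 0.23, 0.19, 0.16, 0.13, 0.10, 0.07, 0.05),
  tau_av = c(9.4, 6.753, 5.9, 5.05, 4.32, 3.72, 3.06, 2.34, 1.84)
)

# noiseless Hill curve at the default generator operating point
make_hill_curve <- function(start = 0.8, end = 0.5, kd = 0.75, n = 1.32,
                            x = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1, 1.25,
                                  1.5, 2, 2.5, 3)) {
  list(x = x, y = start + (end - start) * x^n / (kd^n + x^n),
       start = start, end = end, kd = kd, n = n)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected),
                                                       .Machine$double.eps)),
              label = sprintf("relative error %g within %g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-300)), tol))
}
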