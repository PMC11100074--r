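# Shared fixtures and independent oracles for the test suite.

# brute-force AUC: exhaustive concordance counting over all case-control
# pairs, half credit on ties
auc_bruteforce <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  total / (length(x) * length(y))
}

# naive O(mn) DeLong structural components (independent of the rank-based
# implementation inside the package)
delong_components_naive <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- vapply(x, function(xi) mean(vapply(y, function(yj) psi(xi, yj), 0)), 0)
  v01 <- vapply(y, function(yj) mean(vapply(x, function(xi) psi(xi, yj), 0)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

# tiny subject frame with explicit fields; genotype columns appended from ...
make_subjects <- function(status, smoking = 0, drinking = 0,
                          family_history = 0, age = 50, sex = "male", ...) {
  n <- length(status)
  df <- data.frame(id = sprintf("s%03d", seq_len(n)), status = status,
                   age = rep_len(age, n), sex = rep_len(sex, n),
                   smoking = rep_len(smoking, n),
                   drinking = rep_len(drinking, n),
                   family_history = rep_len(family_history, n))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# expand a 2x2 table (a exposed cases, b unexposed cases, c exposed
# controls, d unexposed controls) into subject-level rows
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    status = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
    exposed = rep(c(1, 0, 1, 0), times = c(a, b, c, d))
  )
}

demo_panel <- function() {
  list(snp_spec("rsA", "T", p = 0.3, or = 2),
       snp_spec("rsB", "G", p = 0.5, or = 0.7))
}
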