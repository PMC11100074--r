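#' Random train/validation split
#'
#' Simple random split without stratification, reproducible by seed. With a
#' 0.6 fraction on 500 cases / 500 controls the arm sizes land near the
#' study's 301/299 vs 199/201 layout.
#'
#' @param subjects subject data frame.
#' @param fraction training fraction in (0, 1]; fraction 1 leaves the
#'   validation set empty (flagged with a warning).
#' @param seed integer seed.
#' @return List with \code{training} and \code{validation} data frames.
#' @export
split_data <- function(subjects, fraction = 0.6, seed = 1L) {
  if (!nrow(subjects)) stop("empty subject table", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  n <- nrow(subjects)
  idx <- sample.int(n, size = round(fraction * n))
  if (length(idx) == n)
    warning("fraction = 1: validation set is empty")
  list(training = subjects[idx, , drop = FALSE],
       validation = subjects[setdiff(seq_len(n), idx), , drop = FALSE])
}

# term sets of the three risk models; the non-genetic model carries the
# smoking x drinking interaction without a drinking main effect, exactly
# as the published equations do (non-hierarchical; see vignette)
model_terms <- function(name) {
  switch(match.arg(name, c("genetic", "non_genetic", "combined")),
    genetic = "wgrs",
    non_genetic = c("smoking", "family_history", "smoking_x_drinking"),
    combined = c("wgrs", "smoking", "family_history",
                 "smoking_x_drinking"))
}

# design frame with the interaction column materialized
model_frame <- function(subjects, terms) {
  if ("smoking_x_drinking" %in% terms &&
      !"smoking_x_drinking" %in% names(subjects))
    subjects$smoking_x_drinking <- subjects$smoking * subjects$drinking
  missing <- setdiff(terms, names(subjects))
  if (length(missing))
    stop("subjects lack model terms: ", paste(missing, collapse = ", "),
         call. = FALSE)
  subjects
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via \code{stats::glm}, convergence tolerance 1e-10). Named
#' model presets supply the published term sets: \code{"genetic"}
#' (wGRS only), \code{"non_genetic"} (smoking, family history,
#' smoking x drinking interaction), \code{"combined"} (their union).
#' Complete separation is detected from diverging coefficients and raised
#' as an explicit error rather than returned silently.
#'
#' @param subjects subject data frame with a \code{status} column (and
#'   \code{wgrs} where the model needs it, see \code{\link{add_wgrs}}).
#' @param model preset name or a character vector of predictor columns.
#' @return List of class \code{fitted_model}: \code{name}, \code{terms},
#'   \code{coefficients} (intercept first), \code{log_likelihood},
#'   \code{n}, \code{k}, \code{vcov}.
#' @export
fit_logistic <- function(subjects, model = "combined") {
  terms <- if (length(model) == 1 &&
               model %in% c("genetic", "non_genetic", "combined")) {
    model_terms(model)
  } else model
  name <- if (length(model) == 1) model else "custom"
  dat <- model_frame(subjects, terms)
  y <- dat$status
  stopifnot(all(y %in% 0:1))
  if (!any(y == 1) || !any(y == 0))
    stop("outcome must contain both classes", call. = FALSE)
  if (nrow(dat) <= length(terms) + 1)
    stop("need n > number of parameters", call. = FALSE)
  if (length(terms)) {
    X <- as.data.frame(dat[terms])
    qrX <- qr(cbind(1, as.matrix(X)))
    if (qrX$rank < ncol(X) + 1) {
      drop <- colnames(cbind(`(Intercept)` = 1,
                             as.matrix(X)))[-seq_len(qrX$rank)]
      stop("singular design; collinear terms: ",
           paste(drop, collapse = ", "), call. = FALSE)
    }
    fml <- as.formula(paste("status ~", paste(terms, collapse = " + ")))
    mdat <- cbind(status = y, X)
  } else {
    fml <- status ~ 1
    mdat <- data.frame(status = y)
  }
  fit <- glm(fml, family = binomial(), data = mdat,
             control = list(epsilon = 1e-10, maxit = 100))
  if (any(abs(coef(fit)) > 20))
    stop("apparent complete separation: diverging coefficients",
         call. = FALSE)
  structure(list(name = name, terms = terms,
                 coefficients = coef(fit),
                 log_likelihood = as.numeric(logLik(fit)),
                 n = nrow(dat), k = length(coef(fit)),
                 vcov = vcov(fit)),
            class = "fitted_model")
}

#' Predicted risk from a fitted or published model
#'
#' Inverse-logit of the linear predictor
#' \eqn{P = 1 / (1 + \exp(-(\beta_0 + \sum_j \beta_j x_j)))}.
#'
#' @param model a \code{fitted_model} (from \code{\link{fit_logistic}} or
#'   \code{\link{load_printed_model}}).
#' @param subjects subject data frame containing every model term.
#' @return Numeric vector of predicted probabilities.
#' @export
predict_risk <- function(model, subjects) {
  stopifnot(inherits(model, "fitted_model"))
  dat <- model_frame(subjects, model$terms)
  cf <- unname(model$coefficients)
  eta <- rep(cf[1], nrow(dat))
  for (j in seq_along(model$terms)) {
    eta <- eta + cf[j + 1] * dat[[model$terms[j]]]
  }
  1 / (1 + exp(-eta))
}

#' Published model coefficient fixtures
#'
#' The two risk-model equations reported by the source study, frozen as
#' coefficient vectors for regression tests and demonstrations:
#' \code{"non_genetic_paper"} (intercept -0.236; smoking -0.584; family
#' history 2.038; smoking x drinking 1.392) and \code{"combined_paper"}
#' (intercept -1.110; wGRS 0.908; smoking -0.558; family history 1.976;
#' smoking x drinking 1.393).
#'
#' @param name \code{"non_genetic_paper"} or \code{"combined_paper"}.
#' @return A \code{fitted_model} with \code{log_likelihood} NA (not
#'   published).
#' @export
load_printed_model <- function(name) {
  name <- match.arg(name, c("non_genetic_paper", "combined_paper"))
  if (name == "non_genetic_paper") {
    terms <- c("smoking", "family_history", "smoking_x_drinking")
    cf <- c(`(Intercept)` = -0.236, smoking = -0.584,
            family_history = 2.038, smoking_x_drinking = 1.392)
  } else {
    terms <- c("wgrs", "smoking", "family_history", "smoking_x_drinking")
    cf <- c(`(Intercept)` = -1.110, wgrs = 0.908, smoking = -0.558,
            family_history = 1.976, smoking_x_drinking = 1.393)
  }
  structure(list(name = name, terms = terms, coefficients = cf,
                 log_likelihood = NA_real_, n = NA_integer_,
                 k = length(cf), vcov = NULL),
            class = "fitted_model")
}
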