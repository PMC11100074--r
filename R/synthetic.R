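#' Population specification for synthetic case-control data
#'
#' Describes the source population the generator samples from: the SNP
#' panel (with per-SNP generating ORs and genetic models), exposure
#' prevalences, a smoking x drinking interaction OR on disease risk, and
#' the baseline log-odds of disease. Defaults emulate the study design:
#' 500 cases / 500 controls, control exposure prevalences smoking 0.346,
#' drinking 0.296, family history 0.020, 72.6\% male with sex
#' frequency-matching, and a low baseline disease risk so the
#' case-control odds ratios track the generating ones.
#'
#' @param snps list of \code{\link{snp_spec}} objects; each SNP's
#'   \code{or} and \code{model} define its contribution to disease
#'   log-odds (the log OR applied to the model-defining genotype
#'   contrast).
#' @param exposure_prevalences named probabilities for \code{smoking},
#'   \code{drinking}, \code{family_history}.
#' @param exposure_ors named disease odds ratios for the three exposures.
#' @param interaction_or odds ratio for the smoking x drinking product
#'   term (default 1: no interaction on top of the main effects).
#' @param baseline_logit intercept of the disease model. The default -5
#'   (baseline risk ~0.7\%) keeps the disease rare so that marginal
#'   case-control odds ratios are not attenuated by non-collapsibility
#'   and track the conditional generating ORs (see the vignette).
#' @param n_cases,n_controls arm sizes (>= 1).
#' @param p_male probability of male sex (cases; controls are
#'   frequency-matched).
#' @param age_case,age_ctrl \code{c(mean, sd)} of age by arm.
#' @param missing_rate per-genotype missingness injection rate
#'   (default 0).
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(snps = default_panel(),
                            exposure_prevalences = c(smoking = 0.346,
                                                     drinking = 0.296,
                                                     family_history = 0.020),
                            exposure_ors = c(smoking = 1.509,
                                             drinking = 1.508,
                                             family_history = 9.057),
                            interaction_or = 1,
                            baseline_logit = -5,
                            n_cases = 500, n_controls = 500,
                            p_male = 0.726,
                            age_case = c(63.00, 8.33),
                            age_ctrl = c(46.80, 11.55),
                            missing_rate = 0) {
  stopifnot(all(exposure_prevalences >= 0 & exposure_prevalences <= 1),
            all(exposure_ors > 0), interaction_or > 0,
            n_cases >= 1, n_controls >= 1,
            p_male >= 0 && p_male <= 1,
            missing_rate >= 0 && missing_rate <= 1)
  need <- c("smoking", "drinking", "family_history")
  stopifnot(all(need %in% names(exposure_prevalences)),
            all(need %in% names(exposure_ors)))
  structure(list(snps = snps,
                 exposure_prevalences = exposure_prevalences,
                 exposure_ors = exposure_ors,
                 interaction_or = interaction_or,
                 baseline_logit = baseline_logit,
                 n_cases = n_cases, n_controls = n_controls,
                 p_male = p_male, age_case = age_case,
                 age_ctrl = age_ctrl, missing_rate = missing_rate),
            class = "population_spec")
}

#' Default five-SNP risk panel
#'
#' The five susceptibility loci validated by the source case-control
#' study, with their best-fitting genetic models and ORs (rs1042522
#' recessive 0.69; rs1229984 recessive 1.78; rs1801133 dominant 0.41;
#' rs2274223 dominant 1.93; rs671 dominant 2.42). Risk-allele frequencies
#' are not published for the reference population; the values here are
#' illustrative East-Asian-range frequencies and are \emph{not} study
#' values.
#'
#' @return List of \code{\link{snp_spec}}.
#' @export
default_panel <- function() {
  list(
    snp_spec("rs1042522", "C", p = 0.55, or = 0.69, model = "recessive"),
    snp_spec("rs1229984", "C", p = 0.30, or = 1.78, model = "recessive"),
    snp_spec("rs1801133", "T", p = 0.45, or = 0.41, model = "dominant"),
    snp_spec("rs2274223", "G", p = 0.25, or = 1.93, model = "dominant"),
    snp_spec("rs671",     "A", p = 0.20, or = 2.42, model = "dominant")
  )
}

#' Hardy-Weinberg genotype dosages
#'
#' Draws risk-allele dosages with HWE probabilities
#' \eqn{P(0) = (1-p)^2}, \eqn{P(1) = 2p(1-p)}, \eqn{P(2) = p^2}.
#'
#' @param p risk-allele frequency in [0, 1].
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed (omit to use the current RNG state).
#' @return Integer vector of dosages in \{0, 1, 2\}.
#' @export
generate_genotypes <- function(p, n, seed = NULL) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, 2L, p)
}

# per-SNP genetic-model contribution to the disease linear predictor
model_contrast <- function(dosage, model) {
  switch(model,
    allelic      = dosage,
    heterozygous = as.numeric(dosage == 1),
    homozygous   = as.numeric(dosage == 2),
    dominant     = as.numeric(dosage >= 1),
    recessive    = as.numeric(dosage == 2))
}

#' Generate a synthetic case-control dataset
#'
#' Rejection-samples a source population: genotypes under HWE at each
#' SNP's frequency, independent Bernoulli exposures at the stated
#' prevalences, and disease from a logistic model whose log-odds sum the
#' baseline logit, the per-SNP log OR applied to each SNP's
#' model-defining genotype contrast, the exposure log ORs, and the
#' smoking x drinking interaction. Sampling continues until both arm
#' quotas are met. Age is then assigned from the per-arm normal
#' distributions (age is absent from the disease model), and controls'
#' sex is frequency-matched to the realized case sex distribution.
#'
#' @param spec a \code{\link{population_spec}}.
#' @param seed integer seed.
#' @param max_draws cap on source-population draws before giving up.
#' @return Data frame with columns \code{id}, \code{status} (1/0),
#'   \code{age}, \code{sex}, \code{smoking}, \code{drinking},
#'   \code{family_history}, and one dosage column per panel rsID.
#' @export
generate_case_control <- function(spec, seed = 1L, max_draws = 5e6) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  rsids <- vapply(spec$snps, `[[`, "", "rsid")
  prev <- spec$exposure_prevalences
  beta_exp <- log(spec$exposure_ors)
  beta_int <- log(spec$interaction_or)

  cases <- list(); ctrls <- list()
  n_case <- 0L; n_ctrl <- 0L; drawn <- 0L
  batch <- max(2000L, 4L * (spec$n_cases + spec$n_controls))
  while (n_case < spec$n_cases || n_ctrl < spec$n_controls) {
    if (drawn >= max_draws)
      stop("could not reach ", spec$n_cases, " cases within ", max_draws,
           " draws; raise baseline_logit or max_draws", call. = FALSE)
    b <- max(2L, min(batch, max_draws - drawn))
    drawn <- drawn + b
    G <- vapply(spec$snps, function(s) rbinom(b, 2L, s$p),
                integer(b))
    smoking <- rbinom(b, 1L, prev[["smoking"]])
    drinking <- rbinom(b, 1L, prev[["drinking"]])
    famhist <- rbinom(b, 1L, prev[["family_history"]])
    eta <- rep(spec$baseline_logit, b)
    for (j in seq_along(spec$snps)) {
      s <- spec$snps[[j]]
      eta <- eta + log(s$or) * model_contrast(G[, j], s$model)
    }
    eta <- eta + beta_exp[["smoking"]] * smoking +
      beta_exp[["drinking"]] * drinking +
      beta_exp[["family_history"]] * famhist +
      beta_int * smoking * drinking
    status <- rbinom(b, 1L, 1 / (1 + exp(-eta)))
    df <- data.frame(status = status, smoking = smoking,
                     drinking = drinking, family_history = famhist)
    df <- cbind(df, as.data.frame(G))
    names(df)[5:(4 + length(rsids))] <- rsids
    want_case <- spec$n_cases - n_case
    want_ctrl <- spec$n_controls - n_ctrl
    new_cases <- df[df$status == 1, , drop = FALSE]
    new_ctrls <- df[df$status == 0, , drop = FALSE]
    if (nrow(new_cases) > want_case)
      new_cases <- new_cases[seq_len(want_case), , drop = FALSE]
    if (nrow(new_ctrls) > want_ctrl)
      new_ctrls <- new_ctrls[seq_len(want_ctrl), , drop = FALSE]
    if (nrow(new_cases)) cases[[length(cases) + 1L]] <- new_cases
    if (nrow(new_ctrls)) ctrls[[length(ctrls) + 1L]] <- new_ctrls
    n_case <- n_case + nrow(new_cases)
    n_ctrl <- n_ctrl + nrow(new_ctrls)
  }
  out <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
  n <- nrow(out)
  is_case <- out$status == 1

  # sex: cases drawn at p_male; controls frequency-matched to cases
  sex_case <- ifelse(runif(spec$n_cases) < spec$p_male, "male", "female")
  p_male_obs <- mean(sex_case == "male")
  sex_ctrl <- ifelse(runif(spec$n_controls) < p_male_obs, "male", "female")
  out$sex <- NA_character_
  out$sex[is_case] <- sex_case
  out$sex[!is_case] <- sex_ctrl

  # age assigned by arm; not part of the disease model
  out$age <- NA_real_
  out$age[is_case] <- rnorm(spec$n_cases, spec$age_case[1],
                            spec$age_case[2])
  out$age[!is_case] <- rnorm(spec$n_controls, spec$age_ctrl[1],
                             spec$age_ctrl[2])

  if (spec$missing_rate > 0) {
    for (rs in rsids) {
      miss <- runif(n) < spec$missing_rate
      out[[rs]][miss] <- NA_integer_
    }
  }
  out$id <- sprintf("S%05d", seq_len(n))
  rownames(out) <- NULL
  out[, c("id", "status", "age", "sex", "smoking", "drinking",
          "family_history", rsids)]
}

#' Generate a synthetic multi-study genotype-count collection
#'
#' Each study draws a true log OR from Normal(log(true_or), tau2), samples
#' control genotype counts from the HWE multinomial at allele frequency
#' \code{p}, and samples case genotype counts from the control genotype
#' distribution exponentially tilted by the study OR under the given
#' genetic contrast, so the study's collapsed 2x2 odds ratio equals its
#' drawn OR in expectation. \code{tau2 = 0} yields homogeneous studies.
#'
#' @param k number of studies (>= 1).
#' @param true_or common underlying odds ratio (> 0).
#' @param tau2 between-study variance of the log OR (>= 0).
#' @param sizes per-arm study sizes: either a single number, a length-k
#'   vector, or a list of \code{c(n_case, n_control)} pairs.
#' @param p risk-allele frequency in controls.
#' @param model genetic contrast the OR acts on (default
#'   \code{"allelic"}).
#' @param seed integer seed.
#' @return List of studies, each with \code{study_id}, \code{case},
#'   \code{control} genotype count vectors (AA, AB, BB) and
#'   \code{true_log_or}.
#' @export
generate_study_collection <- function(k, true_or, tau2 = 0, sizes = 500,
                                      p = 0.3, model = "allelic",
                                      seed = 1L) {
  stopifnot(k >= 1, true_or > 0)
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  model <- match.arg(model, genetic_models())
  set.seed(seed)
  if (is.list(sizes)) {
    stopifnot(length(sizes) == k)
  } else {
    sizes <- rep_len(sizes, k)
    sizes <- lapply(sizes, function(n) c(n, n))
  }
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  lapply(seq_len(k), function(i) {
    theta <- rnorm(1, log(true_or), sqrt(tau2))
    # tilt the genotype distribution by the per-genotype odds under the
    # contrast; for the allelic contrast odds multiply per allele copy
    tilt <- exp(theta * model_contrast(0:2, model))
    pc <- hwe * tilt / sum(hwe * tilt)
    ctrl <- as.integer(rmultinom(1, sizes[[i]][2], hwe))
    case <- as.integer(rmultinom(1, sizes[[i]][1], pc))
    list(study_id = sprintf("study%02d", i), case = case, control = ctrl,
         true_log_or = theta)
  })
}
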