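#' SNP specification for risk scoring
#'
#' Describes one SNP of the risk panel: its risk allele, the risk-allele
#' frequency \code{p} in the reference population, the odds ratio used as
#' the score weight, and the genetic model under which that OR was
#' estimated (used by the synthetic-data generator and by association
#' reporting; the score itself only needs \code{p} and \code{or}).
#'
#' @param rsid SNP identifier (e.g. \code{"rs671"}).
#' @param risk_allele single-character risk allele label.
#' @param p risk-allele frequency in the reference population, in [0, 1].
#' @param or per-SNP odds ratio used as the score weight (> 0).
#' @param model genetic model associated with the OR; one of
#'   \code{"allelic"}, \code{"heterozygous"}, \code{"homozygous"},
#'   \code{"dominant"}, \code{"recessive"}.
#' @return An object of class \code{snp_spec}.
#' @export
snp_spec <- function(rsid, risk_allele = "B", p, or, model = "allelic") {
  stopifnot(is.character(rsid), length(rsid) == 1L)
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("risk-allele frequency p must be in [0, 1]", call. = FALSE)
  if (!is.numeric(or) || or <= 0)
    stop("odds ratio must be > 0", call. = FALSE)
  model <- match.arg(model, genetic_models())
  structure(list(rsid = rsid, risk_allele = risk_allele,
                 p = p, or = or, model = model),
            class = "snp_spec")
}

#' The five genetic contrast models
#'
#' @return Character vector of the model names.
#' @export
genetic_models <- function() {
  c("allelic", "heterozygous", "homozygous", "dominant", "recessive")
}

#' Per-SNP genotype score table
#'
#' Computes the genotype scores of the weighted genetic risk score for one
#' SNP. With risk-allele frequency \code{p} and per-allele odds ratio
#' \code{OR}, the normalizer is the expected unnormalized score under
#' Hardy-Weinberg equilibrium,
#' \deqn{W = (1-p)^2 + 2p(1-p)\,OR + p^2\,OR^2,}
#' and the genotype scores are \eqn{AA = 1/W}, \eqn{AB = OR/W},
#' \eqn{BB = OR^2/W} (A non-risk, B risk allele). By construction the
#' HWE-expected score is exactly 1, so a panel of independent SNPs has
#' population-mean wGRS 1.
#'
#' @param spec a \code{\link{snp_spec}}.
#' @return A \code{snp_score_table}: list with \code{rsid}, \code{W} and
#'   \code{scores} (named numeric of length 3 for dosages 0, 1, 2).
#' @examples
#' score_snp(snp_spec("rs_demo", "T", p = 0.3, or = 2))
#' @export
score_snp <- function(spec) {
  stopifnot(inherits(spec, "snp_spec"))
  p <- spec$p; or <- spec$or
  W <- (1 - p)^2 + 2 * p * (1 - p) * or + p^2 * or^2
  structure(list(rsid = spec$rsid, W = W,
                 scores = c(`0` = 1 / W, `1` = or / W, `2` = or^2 / W)),
            class = "snp_score_table")
}

#' Per-subject weighted genetic risk score
#'
#' The wGRS is the product over panel SNPs of the subject's genotype score;
#' a missing genotype contributes a neutral factor of 1. Genotypes are
#' risk-allele dosages (0, 1, 2 copies of the risk allele).
#'
#' @param dosages named numeric/integer vector of risk-allele dosages
#'   (names are rsIDs); \code{NA} means missing.
#' @param tables list of \code{snp_score_table} objects covering every
#'   non-missing rsID in \code{dosages}.
#' @return The wGRS value (positive scalar).
#' @export
compute_wgrs <- function(dosages, tables) {
  tab <- setNames(tables, vapply(tables, `[[`, "", "rsid"))
  w <- 1
  for (rs in names(dosages)) {
    d <- dosages[[rs]]
    if (is.na(d)) next  # missing genotype scores 1
    if (is.null(tab[[rs]]))
      stop("no score table for SNP '", rs, "'", call. = FALSE)
    if (!d %in% 0:2)
      stop("dosage for '", rs, "' must be 0, 1, 2 or NA", call. = FALSE)
    w <- w * tab[[rs]]$scores[[as.character(d)]]
  }
  w
}

#' Add a wGRS column to a subject table
#'
#' @param subjects subject data frame (see \code{\link{read_subject_table}});
#'   genotype columns are named by rsID.
#' @param panel list of \code{\link{snp_spec}} objects.
#' @return \code{subjects} with a numeric \code{wgrs} column appended.
#' @export
add_wgrs <- function(subjects, panel) {
  tables <- lapply(panel, score_snp)
  rsids <- vapply(panel, `[[`, "", "rsid")
  missing_cols <- setdiff(rsids, names(subjects))
  if (length(missing_cols))
    stop("subject table lacks genotype columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  # vectorized product over SNPs; NA dosage -> factor 1
  w <- rep(1, nrow(subjects))
  for (i in seq_along(rsids)) {
    sc <- tables[[i]]$scores
    d <- subjects[[rsids[i]]]
    f <- ifelse(is.na(d), 1, sc[d + 1L])
    w <- w * f
  }
  subjects$wgrs <- w
  subjects
}

#' Quartile association of the wGRS with case status
#'
#' Cuts the wGRS at the quartiles of the control distribution (left-closed
#' on the right: ties at a cutpoint fall in the lower quartile) and fits a
#' multivariable logistic regression of case status on the quartile factor,
#' adjusted for age, smoking, drinking and family history, with the lowest
#' quartile as reference. The trend p-value is a Wald test on an ordinal
#' (1-4) quartile score in the same adjusted model.
#'
#' @param subjects subject data frame with a \code{wgrs} column (see
#'   \code{\link{add_wgrs}}) plus \code{status}, \code{age},
#'   \code{smoking}, \code{drinking}, \code{family_history}.
#' @param cutpoints optional numeric length-3 vector of precomputed
#'   quartile cutpoints (e.g. frozen from a training set); default computes
#'   them from this table's controls.
#' @return A list of class \code{wgrs_quartiles} with \code{cutpoints},
#'   \code{table} (per-quartile OR, 95\% CI, p; reference row OR = 1) and
#'   \code{p_trend}.
#' @export
quartile_association <- function(subjects, cutpoints = NULL) {
  stopifnot("wgrs" %in% names(subjects))
  if (is.null(cutpoints)) {
    ctrl <- subjects$wgrs[subjects$status == 0]
    if (length(unique(ctrl)) < 4)
      stop("need >= 4 distinct control wGRS values to form quartiles",
           call. = FALSE)
    cutpoints <- unname(quantile(ctrl, c(0.25, 0.5, 0.75), type = 7))
  }
  stopifnot(length(cutpoints) == 3, !is.unsorted(cutpoints))
  q <- cut(subjects$wgrs, breaks = c(-Inf, cutpoints, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  dat <- data.frame(status = subjects$status, q = q,
                    q_ord = as.numeric(q),
                    age = subjects$age, smoking = subjects$smoking,
                    drinking = subjects$drinking,
                    family_history = subjects$family_history)
  fit <- glm(status ~ q + age + smoking + drinking + family_history,
             family = binomial(), data = dat)
  cf <- coef(summary(fit))
  rows <- paste0("qQ", 2:4)
  est <- se <- pv <- setNames(rep(NA_real_, 3), rows)
  present <- intersect(rows, rownames(cf))
  est[present] <- cf[present, 1]
  se[present] <- cf[present, 2]
  pv[present] <- cf[present, 4]
  tab <- data.frame(
    quartile = c("Q1", "Q2", "Q3", "Q4"),
    n_cases = as.integer(table(q[dat$status == 1])),
    n_controls = as.integer(table(q[dat$status == 0])),
    or = c(1, exp(est)),
    ci_lo = c(NA, exp(est - 1.959964 * se)),
    ci_hi = c(NA, exp(est + 1.959964 * se)),
    p = c(NA, pv),
    row.names = NULL
  )
  tfit <- glm(status ~ q_ord + age + smoking + drinking + family_history,
              family = binomial(), data = dat)
  p_trend <- coef(summary(tfit))["q_ord", 4]
  structure(list(cutpoints = cutpoints, table = tab, p_trend = p_trend),
            class = "wgrs_quartiles")
}
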