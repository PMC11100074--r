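#' Read a per-subject genotype + covariate table
#'
#' Tab-delimited with header: \code{id}, \code{status} (case/control or
#' 1/0), \code{age}, \code{sex} (male/female), \code{smoking},
#' \code{drinking}, \code{family_history} (0/1), then one column per
#' rsID holding risk-allele dosages 0/1/2 with \code{NA}, \code{.} or
#' empty for missing. Validation failures cite the offending line.
#'
#' @param path file path.
#' @return Validated subject data frame (\code{status} recoded to 1/0).
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   na.strings = c("NA", ".", ""),
                   colClasses = NA, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("id", "status", "age", "sex", "smoking", "drinking",
            "family_history")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("subject table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate subject ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  st <- as.character(df$status)
  ok <- st %in% c("case", "control", "1", "0")
  if (!all(ok))
    stop("invalid status on line ", which(!ok)[1] + 1L, call. = FALSE)
  df$status <- as.integer(st %in% c("case", "1"))
  geno_cols <- setdiff(names(df), need)
  for (g in geno_cols) {
    v <- df[[g]]
    bad <- !is.na(v) & !v %in% 0:2
    if (any(bad))
      stop("dosage outside {0,1,2} in column '", g, "' on line ",
           which(bad)[1] + 1L, call. = FALSE)
    df[[g]] <- as.integer(v)
  }
  df
}

#' Write a per-subject table
#'
#' @param subjects subject data frame.
#' @param path output path (tab-delimited, header row).
#' @return \code{path}, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-study genotype-count table
#'
#' Tab-delimited with header columns \code{study_id}, \code{case_AA},
#' \code{case_AB}, \code{case_BB}, \code{ctrl_AA}, \code{ctrl_AB},
#' \code{ctrl_BB}; an optional \code{rsid} column supports the long
#' format with several SNPs per file.
#'
#' @param path file path.
#' @return List of study objects (as in
#'   \code{\link{generate_study_collection}}), or a list of such lists
#'   keyed by rsID when an \code{rsid} column is present.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("study_id", "case_AA", "case_AB", "case_BB",
            "ctrl_AA", "ctrl_AB", "ctrl_BB")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("study table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  to_study <- function(rows) {
    lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      list(study_id = r$study_id,
           case = c(r$case_AA, r$case_AB, r$case_BB),
           control = c(r$ctrl_AA, r$ctrl_AB, r$ctrl_BB))
    })
  }
  if ("rsid" %in% names(df)) {
    split_df <- split(df, df$rsid)
    lapply(split_df, to_study)
  } else {
    to_study(df)
  }
}

#' Write a study collection as a counts table
#'
#' @param studies list of study objects.
#' @param path output path.
#' @param rsid optional rsID to tag every row (long format).
#' @return \code{path}, invisibly.
#' @export
write_study_table <- function(studies, path, rsid = NULL) {
  df <- do.call(rbind, lapply(studies, function(s) {
    data.frame(study_id = s$study_id,
               case_AA = s$case[1], case_AB = s$case[2],
               case_BB = s$case[3],
               ctrl_AA = s$control[1], ctrl_AB = s$control[2],
               ctrl_BB = s$control[3])
  }))
  if (!is.null(rsid)) df <- cbind(rsid = rsid, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP-panel configuration
#'
#' YAML (or JSON) list of SNP entries, each with \code{rsid},
#' \code{risk_allele}, \code{p} (risk-allele frequency), \code{or} and
#' optional \code{model}.
#'
#' @param path file path.
#' @return List of \code{\link{snp_spec}}.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$snps)) raw <- raw$snps
  lapply(raw, function(x)
    snp_spec(x$rsid, x$risk_allele %||% "B", x$p, x$or,
             x$model %||% "allelic"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fitted model to JSON
#'
#' @param model a \code{fitted_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  jsonlite::write_json(
    list(name = model$name, terms = model$terms,
         coefficients = as.list(model$coefficients),
         log_likelihood = model$log_likelihood,
         n = model$n, k = model$k),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path file path.
#' @return A \code{fitted_model}.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(name = x$name, terms = x$terms,
                 coefficients = unlist(x$coefficients),
                 log_likelihood = x$log_likelihood %||% NA_real_,
                 n = x$n %||% NA_integer_, k = x$k, vcov = NULL),
            class = "fitted_model")
}

#' Run the full risk-modelling pipeline
#'
#' Orchestrates the analysis end to end on a subject table: per-SNP
#' association statistics, wGRS computation, train/validation split,
#' the three logistic risk models, per-model evaluation on both sets,
#' and pairwise model comparisons (DeLong + NRI). Deterministic for a
#' fixed seed; when \code{outdir} is given, every stage's table is
#' written (TSV/JSON) together with a plain-text run log.
#'
#' @param subjects subject data frame (e.g. from
#'   \code{\link{generate_case_control}} or
#'   \code{\link{read_subject_table}}).
#' @param panel list of \code{\link{snp_spec}} used for scoring.
#' @param split_fraction training fraction (default 0.6).
#' @param seed global seed; stage substreams derive from it.
#' @param priors FPRP priors.
#' @param outdir optional output directory for stage reports.
#' @return List of class \code{run_report}: \code{baseline},
#'   \code{association}, \code{quartiles}, \code{models},
#'   \code{evaluation} (data frame), \code{comparison} (data frame),
#'   \code{split_sizes}, \code{seed}.
#' @export
run_pipeline <- function(subjects, panel = default_panel(),
                         split_fraction = 0.6, seed = 1L,
                         priors = c(0.25, 0.1, 0.01), outdir = NULL) {
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  baseline <- baseline_table(subjects)
  assoc <- snp_association(subjects, panel, priors = priors)
  subjects <- add_wgrs(subjects, panel)

  sp <- split_data(subjects, split_fraction, stage_seed(seed, "split"))
  train <- sp$training; valid <- sp$validation
  note("split: %d training (%d cases), %d validation (%d cases)",
       nrow(train), sum(train$status), nrow(valid), sum(valid$status))

  quart_train <- quartile_association(train)
  quart_valid <- quartile_association(valid,
                                      cutpoints = quart_train$cutpoints)

  model_names <- c("genetic", "non_genetic", "combined")
  models <- lapply(model_names, function(m) fit_logistic(train, m))
  names(models) <- model_names

  score_set <- function(dat) lapply(models, predict_risk, subjects = dat)
  scores <- list(training = score_set(train), validation = score_set(valid))
  labels <- list(training = train$status, validation = valid$status)

  ev <- do.call(rbind, lapply(c("training", "validation"), function(set) {
    do.call(rbind, lapply(model_names, function(m) {
      e <- evaluate_model(scores[[set]][[m]], labels[[set]],
                          fit = if (set == "training") models[[m]])
      data.frame(set = set, model = m, auc = e$auc,
                 auc_lo = e$ci_lo, auc_hi = e$ci_hi,
                 youden = e$youden, sensitivity = e$sensitivity,
                 specificity = e$specificity, accuracy = e$accuracy,
                 lr_pos = e$lr_pos, lr_neg = e$lr_neg,
                 aic = if (set == "training") e$aic else NA_real_,
                 bic = if (set == "training") e$bic else NA_real_)
    }))
  }))

  pairs <- list(c("genetic", "non_genetic"),
                c("genetic", "combined"),
                c("non_genetic", "combined"))
  cmp <- do.call(rbind, lapply(c("training", "validation"), function(set) {
    do.call(rbind, lapply(pairs, function(pr) {
      dl <- delong_compare(scores[[set]][[pr[1]]], scores[[set]][[pr[2]]],
                           labels[[set]])
      nr <- nri(scores[[set]][[pr[1]]], scores[[set]][[pr[2]]],
                labels[[set]])
      data.frame(set = set, comparison = paste(pr[1], "vs", pr[2]),
                 delta_auc = dl$delta, delta_lo = dl$ci_lo,
                 delta_hi = dl$ci_hi, delong_z = dl$z,
                 delong_p = dl$p_value, nri = nr$nri, nri_z = nr$z,
                 nri_p = nr$p_value)
    }))
  }))

  report <- structure(list(
    baseline = baseline, association = assoc,
    quartiles = list(training = quart_train, validation = quart_valid),
    models = models, evaluation = ev, comparison = cmp,
    split_sizes = c(training = nrow(train), validation = nrow(valid)),
    seed = seed, log = log_lines
  ), class = "run_report")

  if (!is.null(outdir)) write_reports(report, outdir)
  report
}

#' Write pipeline stage reports to disk
#'
#' One file per stage: baseline characteristics, per-SNP association,
#' wGRS quartile association, fitted model JSONs, evaluation and
#' comparison tables, plus a run log.
#'
#' @param report a \code{run_report} from \code{\link{run_pipeline}}.
#' @param outdir output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(report$baseline, "baseline.tsv")
  wt(report$association, "association.tsv")
  qa <- do.call(rbind, lapply(names(report$quartiles), function(set) {
    cbind(set = set, report$quartiles[[set]]$table,
          p_trend = report$quartiles[[set]]$p_trend)
  }))
  wt(qa, "wgrs_quartiles.tsv")
  for (m in names(report$models)) {
    p <- file.path(outdir, paste0("model_", m, ".json"))
    write_model_json(report$models[[m]], p)
    paths <- c(paths, p)
  }
  wt(report$evaluation, "evaluation.tsv")
  if (nrow(report$comparison)) {
    wt(report$comparison, "comparison.tsv")
  }
  lp <- file.path(outdir, "run.log")
  writeLines(c(sprintf("seed: %d", report$seed), report$log), lp)
  paths <- c(paths, lp)
  invisible(paths)
}
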