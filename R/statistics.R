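## Cohort-level statistics: per-gene prevalence, VAF correlations,
## two-group comparisons, and disease-free survival stratification
## (Kaplan-Meier, log-rank, univariate and forward-LR multivariate Cox).
## No multiple-testing correction is applied anywhere; p-values are
## reported as computed, which callers should keep in mind when scanning
## many genes or covariates.

#' Per-gene mutation prevalence of a cohort component
#'
#' Counts, per gene, the patients carrying at least one retained mutation
#' in that gene, as a percentage of `denominator` (conventionally: all
#' patients for the neoplastic component, mutation-positive patients for
#' the stroma).
#'
#' @param calls Retained mutation calls of one component across the cohort
#'   (data.frame with `patient_id` and `gene`).
#' @param denominator Number of patients forming 100%.
#' @return data.frame sorted by descending count: `gene`, `n_patients`,
#'   `percent`.
#' @export
prevalence_table <- function(calls, denominator) {
  stopifnot(denominator >= 1)
  if (nrow(calls) == 0) {
    return(data.frame(gene = character(0), n_patients = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- unique(calls[, c("patient_id", "gene")])
  counts <- sort(table(tab$gene), decreasing = TRUE)
  data.frame(
    gene = names(counts),
    n_patients = as.integer(counts),
    percent = 100 * as.integer(counts) / denominator,
    stringsAsFactors = FALSE
  )
}

#' Spearman correlation of co-occurring VAF pairs
#'
#' Used for the KRAS-vs-TP53 VAF consistency analysis within a component:
#' each co-mutant specimen contributes one `(x, y)` pair.
#'
#' @param x,y Paired VAF vectors.
#' @return list with `rho`, `rho_squared`, `p` (two-sided), `n`.
#' @export
vaf_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, rho_squared = rho^2, p = ct$p.value, n = length(x))
}

#' Two-group comparison: Mann-Whitney or chi-square
#'
#' Continuous values (TCF, mutation burden) are compared with the
#' Mann-Whitney U-test (normal approximation with tie correction);
#' 2x2 counts with Pearson's chi-square without continuity correction.
#'
#' @param test `"mann_whitney"` or `"chi_square"`.
#' @param x,g For `mann_whitney`: values and a two-level grouping vector.
#' @param counts For `chi_square`: a 2x2 matrix of counts.
#' @return list with `statistic`, `p`, and the underlying htest object.
#' @export
#' @examples
#' group_compare("chi_square", counts = matrix(c(99, 15, 72, 62), nrow = 2))
group_compare <- function(test = c("mann_whitney", "chi_square"),
                          x = NULL, g = NULL, counts = NULL) {
  test <- match.arg(test)
  if (test == "mann_whitney") {
    stopifnot(!is.null(x), !is.null(g))
    g <- factor(g)
    if (nlevels(g) != 2) stop("mann_whitney needs exactly two groups")
    if (any(table(g) == 0)) stop("both groups must be nonempty")
    ht <- suppressWarnings(stats::wilcox.test(x ~ g, exact = FALSE,
                                              correct = TRUE))
  } else {
    stopifnot(!is.null(counts), all(dim(counts) == c(2, 2)))
    ht <- stats::chisq.test(counts, correct = FALSE)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, htest = ht)
}

#' Disease-free survival stratified by a genomic grouping
#'
#' Product-limit Kaplan-Meier curves with per-group median DFS (reported as
#' `NA` = unreached when the curve never drops below 0.5), the log-rank
#' test, a univariate Cox model for the grouping (Efron ties, Wald CI),
#' and - when `covariates` are supplied - a multivariate Cox model built by
#' forward likelihood-ratio selection (entry p = 0.05) over the grouping
#' and the covariates.
#'
#' @param records Clinical data.frame with `dfs_months` and `event`.
#' @param grouping Name of the logical/two-level column to stratify by
#'   (e.g. `"neoplasm_like"`, `"stromal_kras"`).
#' @param covariates Optional character vector of additional covariate
#'   column names for the multivariate model.
#' @param min_followup Drop patients with `dfs_months` below this value
#'   (the DFS analysis set may be restricted to patients followed up for
#'   at least a year); default 0 keeps everyone.
#' @return Object of class `survival_result`: group labels and sizes,
#'   per-group median DFS, `logrank_p`, `hazard_ratio` with `ci_lower`,
#'   `ci_upper` and `cox_p`, the fitted univariate model, and (if selected)
#'   the multivariate fit with the chosen terms.
#' @export
survival_analysis <- function(records, grouping = "neoplasm_like",
                              covariates = NULL, min_followup = 0) {
  stopifnot(grouping %in% names(records),
            all(c("dfs_months", "event") %in% names(records)))
  records <- records[records$dfs_months >= min_followup, , drop = FALSE]
  g <- factor(records[[grouping]])
  if (nlevels(g) < 2) stop("grouping has a single level after filtering")
  if (sum(records$event) == 0) stop("no relapse events in the analysis set")
  if (any(table(g) < 2)) stop("need at least 2 patients per group")

  surv <- survival::Surv(records$dfs_months, records$event)
  km <- survival::survfit(surv ~ g)
  med <- summary(km)$table[, "median"]   # NA where the curve stays > 0.5
  lr <- survival::survdiff(surv ~ g)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)

  cox <- survival::coxph(surv ~ g, ties = "efron")
  sm <- summary(cox)
  hr <- unname(sm$conf.int[1, "exp(coef)"])
  ci <- unname(sm$conf.int[1, c("lower .95", "upper .95")])
  cox_p <- unname(sm$coefficients[1, "Pr(>|z|)"])

  multivariate <- NULL
  if (!is.null(covariates)) {
    multivariate <- forward_lr_cox(records, grouping, covariates)
  }

  structure(list(
    grouping = grouping,
    groups = levels(g),
    n = as.integer(table(g)),
    events = as.integer(tapply(records$event, g, sum)),
    median_dfs = unname(med),
    logrank_p = logrank_p,
    hazard_ratio = hr,
    ci_lower = ci[1],
    ci_upper = ci[2],
    cox_p = cox_p,
    km = km,
    cox = cox,
    multivariate = multivariate
  ), class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  med <- ifelse(is.na(x$median_dfs), "unreached",
                sprintf("%.1f mo", x$median_dfs))
  cat(sprintf("<survival_result> DFS by %s\n", x$grouping))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  %s = %s: n = %d, events = %d, median DFS %s\n",
                x$grouping, x$groups[i], x$n[i], x$events[i], med[i]))
  }
  cat(sprintf("  log-rank p = %.4g; HR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$logrank_p, x$hazard_ratio, x$ci_lower, x$ci_upper, x$cox_p))
  if (!is.null(x$multivariate)) {
    cat("  multivariate (forward LR) retained: ",
        paste(x$multivariate$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Forward likelihood-ratio covariate selection for a Cox model:
# at each step the candidate with the smallest add-one LRT p-value enters
# if p < `entry_p`; stops otherwise.
forward_lr_cox <- function(records, grouping, covariates, entry_p = 0.05) {
  surv <- survival::Surv(records$dfs_months, records$event)
  candidates <- unique(c(grouping, covariates))
  selected <- character(0)
  fit_formula <- function(terms) {
    if (length(terms) == 0) {
      survival::coxph(surv ~ 1, data = records, ties = "efron")
    } else {
      survival::coxph(stats::reformulate(terms, response = "surv"),
                      data = records, ties = "efron")
    }
  }
  current <- fit_formula(selected)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    pvals <- vapply(remaining, function(term) {
      fit <- tryCatch(fit_formula(c(selected, term)), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      lrt <- 2 * (fit$loglik[2] - current$loglik[length(current$loglik)])
      stats::pchisq(lrt, df = length(stats::coef(fit)) -
                      length(stats::coef(current)), lower.tail = FALSE)
    }, numeric(1))
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= entry_p) break
    enter <- remaining[which.min(pvals)]
    selected <- c(selected, enter)
    current <- fit_formula(selected)
  }
  list(selected = selected, fit = if (length(selected) > 0) current else NULL)
}
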