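# Group comparisons, correlations, frequency summaries and survival
# stratification over the patient-level feature matrix.
#
# Small-sample Wilcoxon tests use full enumeration with midranks so that
# exact two-sided p-values remain correct in the presence of ties (the
# asymptotic path applies the usual tie and continuity corrections). Both
# null distributions are symmetric about their mean under sign-flip /
# label-exchange symmetry, which the two-sided rule below exploits.

test_result <- function(statistic, p_value, n, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 q_value = NA_real_, n = n, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g, p=%.4g, n=%d\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; tied absolute differences receive average
#' ranks. For n <= `exact_limit` non-zero pairs the two-sided p-value is
#' exact, from full enumeration of the 2^n sign assignments (the statistic
#' is symmetric about n(n+1)/4, so the two-sided p is the probability of a
#' statistic at least as far from that center). Larger n uses the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y equal-length paired numeric vectors (pairs with missing
#'   values are dropped).
#' @param exact_limit largest n for the enumeration path.
#' @return `test_result` with statistic W (sum of positive-difference
#'   ranks).
#' @export
paired_wilcoxon <- function(x, y, exact_limit = 12) {
  if (length(x) != length(y)) stopf("paired vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  d <- (x - y)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all differences are zero: signed-rank test undefined")
  if (n < 3) stopf("need at least 3 non-zero differences (have %d)", n)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_limit) {
    # enumerate all sign assignments over the midranks
    stats <- vapply(0:(2^n - 1), function(mask) {
      sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0])
    }, numeric(1))
    p <- mean(abs(stats - mu) >= abs(w - mu) - 1e-12)
    method <- "wilcoxon_signed_rank_exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "wilcoxon_signed_rank_normal"
  }
  test_result(w, min(1, p), n, method)
}

#' Mann-Whitney U test for two independent samples
#'
#' Midranks on the pooled sample; U = R_a - n_a(n_a+1)/2 with R_a the rank
#' sum of the first group. For n_a + n_b <= `exact_limit` the two-sided
#' p-value is exact by enumeration of all group assignments (U is symmetric
#' about n_a n_b / 2); otherwise the tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param a,b numeric vectors (missing values dropped), each of length >= 2.
#' @param exact_limit largest pooled size for the enumeration path.
#' @return `test_result` with statistic U.
#' @export
mann_whitney <- function(a, b, exact_limit = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("each group needs at least 2 observations")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  if (n <= exact_limit) {
    splits <- utils::combn(n, na)
    stats <- apply(splits, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
    p <- mean(abs(stats - mu) >= abs(u - mu) - 1e-12)
    method <- "mann_whitney_exact"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "mann_whitney_normal"
  }
  test_result(u, min(1, p), n, method)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t-approximation with n - 2 degrees of freedom. Pairs with a missing
#' value are dropped.
#'
#' @param x,y numeric vectors of equal length; n >= 4 after deletion.
#' @return `test_result` with statistic rho; rho is `NA` with a warning if
#'   either vector is constant.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stopf("Spearman correlation needs at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant input: Spearman correlation undefined")
    return(test_result(NA_real_, NA_real_, n, "spearman"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  test_result(rho, max(p, .Machine$double.xmin), n, "spearman")
}

#' Frequency table of categorical clinical variables
#'
#' Per variable: category counts and percent = 100 * count / total, rounded
#' to one decimal. Categories are listed in order of first appearance;
#' missing values form an explicit "unknown" category when present.
#'
#' @param records data.frame of clinical records.
#' @param variables character vector of column names to summarize; defaults
#'   to all non-numeric columns except `patient_id`.
#' @return data.frame (variable, category, count, percent).
#' @export
frequency_table <- function(records, variables = NULL) {
  if (nrow(records) == 0) stopf("no records to summarize")
  if (is.null(variables)) {
    variables <- setdiff(names(records)[!vapply(records, is.numeric, logical(1))],
                         "patient_id")
  }
  total <- nrow(records)
  rows <- list()
  for (v in variables) {
    vals <- as.character(records[[v]])
    vals[is.na(vals)] <- "unknown"
    cats <- unique(vals)
    cnt <- vapply(cats, function(cc) sum(vals == cc), integer(1))
    rows[[v]] <- data.frame(variable = v, category = cats, count = cnt,
                            percent = round(100 * cnt / total, 1),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Chi-square or Fisher's exact test for a contingency table
#'
#' Uses Fisher's exact test (two-sided by the point-probability rule) when
#' any expected cell count is 5 or less, and Pearson's chi-square without
#' continuity correction otherwise.
#'
#' @param tab matrix of non-negative integer counts (r x c).
#' @return `test_result`; statistic is the chi-square value (NA for the
#'   Fisher branch).
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("contingency table must hold non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("contingency table has a zero margin: test undefined")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected <= 5)) {
    p <- stats::fisher.test(tab)$p.value
    test_result(NA_real_, min(1, p), n, "fisher_exact")
  } else {
    fit <- stats::chisq.test(tab, correct = FALSE)
    test_result(unname(fit$statistic), unname(fit$p.value), n, "chi_square")
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values (BH step-up), same order as input.
#' @export
adjust_bh <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Kaplan-Meier curves and log-rank test for a median-split feature
#'
#' Dichotomizes the cohort at the median of `feature` (values equal to the
#' median go to the "low" group), fits per-group Kaplan-Meier product-limit
#' curves for the chosen endpoint, and compares the groups with the
#' two-group log-rank test. With no events the log-rank p is `NA` but both
#' curves are still returned.
#'
#' @param cohort data.frame with the feature column and
#'   `<endpoint>_months` / `<endpoint>_event` columns.
#' @param feature name of a numeric column to stratify on.
#' @param endpoint `"PFS"`, `"RFS"` or `"OS"`.
#' @param cutpoint `"median"` or a numeric threshold (values <= threshold
#'   are "low").
#' @return list with `low` and `high` survival curves (each: times,
#'   survival, at_risk, n_events, group_label), `test` (`test_result`,
#'   log-rank chi-square) and the cut value used.
#' @export
km_logrank <- function(cohort, feature, endpoint = c("PFS", "RFS", "OS"),
                       cutpoint = "median") {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(tolower(endpoint), "_months")
  ecol <- paste0(tolower(endpoint), "_event")
  for (col in c(feature, tcol, ecol))
    if (!col %in% names(cohort)) stopf("cohort lacks column '%s'", col)
  ok <- stats::complete.cases(cohort[, c(feature, tcol, ecol)])
  d <- cohort[ok, , drop = FALSE]
  if (nrow(d) < 4) stopf("too few complete observations for survival analysis")
  cut <- if (identical(cutpoint, "median")) stats::median(d[[feature]])
         else as.numeric(cutpoint)
  group <- factor(ifelse(d[[feature]] <= cut, "low", "high"),
                  levels = c("low", "high"))
  if (any(tabulate(group, 2) == 0))
    stopf("degenerate split: one group is empty at cut %.4g", cut)
  surv <- survival::Surv(d[[tcol]], d[[ecol]])
  fit <- survival::survfit(surv ~ group)
  curves <- extract_km_curves(fit, levels(group))
  n_events <- sum(d[[ecol]])
  if (n_events >= 1 && nlevels(droplevels(group)) == 2) {
    lr <- survival::survdiff(surv ~ group)
    p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
    test <- test_result(unname(lr$chisq), p, nrow(d), "logrank")
  } else {
    test <- test_result(NA_real_, NA_real_, nrow(d), "logrank")
  }
  list(low = curves[["low"]], high = curves[["high"]], test = test,
       cut = cut, endpoint = endpoint, feature = feature)
}

extract_km_curves <- function(fit, group_levels) {
  strata <- if (is.null(fit$strata)) setNames(length(fit$time), group_levels[1])
            else fit$strata
  idx_end <- cumsum(strata)
  idx_start <- c(1, utils::head(idx_end, -1) + 1)
  labels <- sub("^group=", "", names(strata))
  out <- list()
  for (i in seq_along(strata)) {
    sel <- idx_start[i]:idx_end[i]
    out[[labels[i]]] <- list(times = fit$time[sel], survival = fit$surv[sel],
                             at_risk = fit$n.risk[sel],
                             n_events = fit$n.event[sel],
                             group_label = labels[i])
  }
  out
}

#' Assemble a patient-level cohort table from feature and clinical tables
#'
#' Pivots the long feature table (from [diversity_features()],
#' [shm_features()] or MHSI results) to one wide row per patient with
#' columns named `<chain>_<isotype>_<tissue>_<level>_<metric>`, then joins
#' the clinical table (and optional covariates) on `patient_id`.
#'
#' @param features long data.frame (patient_id, tissue, chain,
#'   isotype_view, level, metric, value).
#' @param clinical clinical data.frame with `patient_id`.
#' @param covariates optional data.frame with `patient_id` and numeric
#'   columns.
#' @return wide data.frame, one row per patient.
#' @export
cohort_table <- function(features, clinical, covariates = NULL) {
  if (nrow(features)) {
    key <- paste(features$chain, features$isotype_view, features$tissue,
                 features$level, features$metric, sep = "_")
    wide <- stats::reshape(
      data.frame(patient_id = features$patient_id, key = key,
                 value = features$value, stringsAsFactors = FALSE),
      idvar = "patient_id", timevar = "key", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
  } else {
    wide <- data.frame(patient_id = unique(clinical$patient_id),
                       stringsAsFactors = FALSE)
  }
  out <- merge(clinical, wide, by = "patient_id", all.x = TRUE, sort = TRUE)
  if (!is.null(covariates))
    out <- merge(out, covariates, by = "patient_id", all.x = TRUE, sort = TRUE)
  out
}
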