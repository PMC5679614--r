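#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, mapped
#' back to the input order. Adjusted values below the chosen alpha (0.05 by
#' convention here) are declared significant.
#'
#' @param p Numeric vector of raw p-values in \eqn{[0, 1]}; \code{NA}s are
#'   propagated and excluded from the family size \code{m}.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_fdr(c(0.005, 0.03, 0.04))
bh_fdr <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  out <- rep(NA_real_, length(p))
  if (m == 0) return(out)
  ord <- order(pv)
  scaled <- pmin(1, pv[ord] * m / seq_len(m))
  # running minimum from the largest rank down enforces monotonicity
  q <- rev(cummin(rev(scaled)))
  adj <- numeric(m)
  adj[ord] <- q
  out[ok] <- adj
  out
}

residualize <- function(y, covariates) {
  X <- cbind(`(Intercept)` = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, y)
}

#' Partial Pearson correlation
#'
#' Correlation between \code{x} and \code{y} after removing the linear
#' effect of the covariates from both: each is residualized on
#' \code{[intercept, covariates]} by least squares and the residuals are
#' correlated. The test statistic is \eqn{t = r\sqrt{df/(1-r^2)}} with
#' \eqn{df = n - k - 2} (k covariate columns), two-sided p from the t
#' distribution.
#'
#' @param x,y Numeric vectors without missing values (drop incomplete cases
#'   first).
#' @param covariates Numeric matrix or data.frame of covariate columns, or
#'   \code{NULL} for the plain Pearson correlation.
#' @return List with \code{r}, \code{statistic}, \code{df}, \code{p},
#'   \code{n}.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values; drop incomplete cases first")
  n <- length(x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (anyNA(covariates)) stop("missing values in covariates")
    stopifnot(nrow(covariates) == n)
    k <- ncol(covariates)
  } else k <- 0L
  if (n <= k + 2) stop("need n > k + 2 observations (n = ", n, ", k = ", k, ")")
  if (k > 0) {
    rx <- residualize(x, covariates)
    ry <- residualize(y, covariates)
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  r <- sum(rx * ry) / sqrt(sum(rx * rx) * sum(ry * ry))
  df <- n - k - 2
  r_cl <- max(-1, min(1, r))
  tstat <- if (abs(r_cl) >= 1) Inf * sign(r_cl)
           else r_cl * sqrt(df / (1 - r_cl^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, statistic = tstat, df = df, p = p, n = n)
}

#' Partial Spearman correlation
#'
#' Rank-transforms \code{x} and \code{y} (average ranks for ties) and
#' applies \code{\link{partial_pearson}} on the ranks; appropriate for
#' monotone but non-linear associations and skewed scores.
#'
#' @inheritParams partial_pearson
#' @return List with \code{rho}, \code{statistic}, \code{df}, \code{p},
#'   \code{n}.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  res <- partial_pearson(rank(x, ties.method = "average"),
                         rank(y, ties.method = "average"),
                         covariates)
  list(rho = res$r, statistic = res$statistic, df = res$df, p = res$p,
       n = res$n)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Least-squares linear model \code{value ~ group + covariates} with an
#' omnibus group F-test (extra sum of squares against the covariate-only
#' model) and pairwise group contrasts as t-tests on differences of group
#' coefficients (using the full coefficient covariance, so contrasts
#' between two non-reference groups are exact).
#'
#' @param values Numeric response (e.g. regional median R2t* or NV).
#' @param group Factor of group labels; the first level (or \code{ref}) is
#'   the reference. Every group needs at least 3 subjects.
#' @param covariates data.frame or matrix of numeric covariates (e.g. age
#'   and a gender dummy), or \code{NULL} for an unadjusted comparison.
#' @param ref Reference level for pairwise contrasts; defaults to the first
#'   factor level.
#' @return List with \code{omnibus} (one-row data.frame: F, df1, df2, p)
#'   and \code{contrasts} (data.frame with one row per group pair:
#'   \code{contrast}, \code{estimate}, \code{statistic}, \code{df},
#'   \code{p_raw}, \code{n}).
#' @export
ancova_compare <- function(values, group, covariates = NULL, ref = NULL) {
  group <- droplevels(as.factor(group))
  stopifnot(length(values) == length(group))
  counts <- table(group)
  if (any(counts < 3))
    stop("every group needs >= 3 subjects; too small: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  if (!is.null(ref)) group <- stats::relevel(group, ref = ref)
  n <- length(values)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    stopifnot(nrow(C) == n)
    dat <- data.frame(.value = values, .group = group, C)
    covnames <- colnames(C)
    full <- stats::lm(stats::as.formula(
      paste(".value ~ .group +", paste(covnames, collapse = " + "))), data = dat)
    null <- stats::lm(stats::as.formula(
      paste(".value ~", paste(covnames, collapse = " + "))), data = dat)
  } else {
    dat <- data.frame(.value = values, .group = group)
    full <- stats::lm(.value ~ .group, data = dat)
    null <- stats::lm(.value ~ 1, data = dat)
  }
  an <- stats::anova(null, full)
  omnibus <- data.frame(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                        p = an$`Pr(>F)`[2])
  # pairwise contrasts via the coefficient covariance
  lv <- levels(group)
  cf <- stats::coef(full)
  V <- stats::vcov(full)
  coef_of <- function(g) if (g == lv[1]) NULL else paste0(".group", g)
  df_res <- full$df.residual
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    w <- stats::setNames(numeric(length(cf)), names(cf))
    c1 <- coef_of(g1); c2 <- coef_of(g2)
    if (!is.null(c1)) w[c1] <- -1   # estimate = mean(g2) - mean(g1), adjusted
    if (!is.null(c2)) w[c2] <- w[c2] + 1
    est <- sum(w * cf)
    se <- sqrt(drop(t(w) %*% V %*% w))
    tstat <- est / se
    data.frame(contrast = paste(g2, "vs", g1), estimate = est,
               statistic = tstat, df = df_res,
               p_raw = 2 * stats::pt(-abs(tstat), df_res),
               n = sum(group %in% c(g1, g2)), stringsAsFactors = FALSE)
  })
  list(omnibus = omnibus, contrasts = do.call(rbind, rows))
}

battery_tests <- function() {
  data.frame(
    score = c("PASAT3", "PASAT2", "SDMT", "EDSS", "T25FW", "NHPT"),
    method = c("pearson", "pearson", "pearson",
               "spearman", "spearman", "spearman"),
    family_part = c("cognitive", "cognitive", "cognitive",
                    "physical", "physical", "physical"),
    stringsAsFactors = FALSE)
}

#' Region-by-score correlation battery
#'
#' For every (region, hemisphere, measure) x clinical score pair, computes
#' the covariate-adjusted correlation between the regional MRI measure and
#' the score across MS subjects: partial Pearson for the cognitive scores
#' (PASAT 3s/2s, SDMT), partial Spearman for the skewed physical scores
#' (EDSS, timed 25-foot walk, nine-hole peg test). Covariates are age, a
#' gender dummy, lesion load and treatment status. The nine-hole peg test
#' follows the lateralized rule: only right-handed subjects enter, and the
#' dominant-hand score is paired with left-hemisphere measures, the
#' non-dominant-hand score with right-hemisphere measures. Benjamini-
#' Hochberg FDR is applied exactly once per family; families follow the
#' study's presentation units: per measure, one family for the cognitive
#' correlations in the deep structures (hippocampus, amygdala), one for
#' the cognitive correlations across the cortical limbic regions, and one
#' for the physical-score correlations (which are only examined in the
#' deep structures).
#'
#' @param summaries Region-summary data.frame as returned by
#'   \code{\link{summarize_subject}} (rows for all subjects).
#' @param cohort Cohort data.frame with columns \code{subject_id},
#'   \code{group}, \code{age}, \code{gender}, \code{lesion_load},
#'   \code{treatment}, \code{handedness} and score columns \code{PASAT3},
#'   \code{PASAT2}, \code{SDMT}, \code{EDSS}, \code{T25FW},
#'   \code{NHPT_dom}, \code{NHPT_nondom}.
#' @param measures MRI measures to test; subset of
#'   \code{c("R2t*", "NV")} mapping to \code{median_r2t_star} and
#'   \code{normalized_volume}.
#' @param region_set Regions to include; defaults to those present in
#'   \code{summaries}.
#' @param physical_regions The deep-structure region set: the only regions
#'   tested against the physical scores (EDSS, timed walk, peg test), and
#'   the split point between the deep and cortical cognitive FDR families.
#'   Defaults to hippocampus and amygdala; cognitive scores span the full
#'   region set.
#' @param scores Optional subset of score names to test.
#' @param covariates Covariate column names used for adjustment.
#' @param ms_only Restrict to MS subjects (all groups except "HC");
#'   default \code{TRUE}.
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @return data.frame of test results: one row per cell with
#'   \code{region_name}, \code{hemisphere}, \code{measure}, \code{score},
#'   \code{method}, \code{family}, \code{estimate}, \code{statistic},
#'   \code{df}, \code{p_raw}, \code{p_fdr}, \code{significant}, \code{n},
#'   \code{covariates}.
#' @export
run_correlation_battery <- function(summaries, cohort,
                                    measures = c("R2t*", "NV"),
                                    region_set = NULL, scores = NULL,
                                    physical_regions = c("hippocampus",
                                                         "amygdala"),
                                    covariates = c("age", "gender",
                                                   "lesion_load", "treatment"),
                                    ms_only = TRUE, alpha = 0.05) {
  tests <- battery_tests()
  if (!is.null(scores)) tests <- tests[tests$score %in% scores, ]
  need_scores <- unique(unlist(lapply(tests$score, function(s)
    if (s == "NHPT") c("NHPT_dom", "NHPT_nondom") else s)))
  miss <- setdiff(c("subject_id", "group", covariates, need_scores,
                    if ("NHPT" %in% tests$score) "handedness"),
                  names(cohort))
  if (length(miss) > 0)
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (ms_only) cohort <- cohort[cohort$group != "HC", , drop = FALSE]
  if (is.null(region_set)) region_set <- unique(summaries$region_name)
  measure_col <- c(`R2t*` = "median_r2t_star", NV = "normalized_volume")
  stopifnot(all(measures %in% names(measure_col)))

  cov_numeric <- function(df) {
    out <- lapply(covariates, function(cn) {
      v <- df[[cn]]
      if (is.character(v) || is.factor(v)) as.numeric(as.factor(v)) - 1
      else as.numeric(v)
    })
    m <- do.call(cbind, out)
    colnames(m) <- covariates
    m
  }

  rows <- list()
  for (measure in measures) {
    mcol <- measure_col[[measure]]
    for (ti in seq_len(nrow(tests))) {
      score <- tests$score[ti]
      method <- tests$method[ti]
      regions_here <- if (tests$family_part[ti] == "physical")
        intersect(region_set, physical_regions) else region_set
      for (region in regions_here) {
        fam <- if (tests$family_part[ti] == "physical")
          paste0(measure, ":physical")
        else paste0(measure, ":cognitive-",
                    if (region %in% physical_regions) "deep" else "cortex")
        for (hemi in c("left", "right")) {
          sub <- summaries[summaries$region_name == region &
                           summaries$hemisphere == hemi, ]
          merged <- merge(sub, cohort, by = "subject_id")
          if (score == "NHPT") {
            merged <- merged[!is.na(merged$handedness) &
                             merged$handedness == "right", , drop = FALSE]
            score_col <- if (hemi == "left") "NHPT_dom" else "NHPT_nondom"
          } else score_col <- score
          keep <- stats::complete.cases(merged[, c(mcol, score_col, covariates)])
          merged <- merged[keep, , drop = FALSE]
          k <- length(covariates)
          if (nrow(merged) <= k + 2) {
            res <- list(r = NA_real_, statistic = NA_real_, df = NA_real_,
                        p = NA_real_, n = nrow(merged))
          } else {
            C <- cov_numeric(merged)
            res <- if (method == "pearson")
              partial_pearson(merged[[mcol]], merged[[score_col]], C)
            else {
              sp <- partial_spearman(merged[[mcol]], merged[[score_col]], C)
              list(r = sp$rho, statistic = sp$statistic, df = sp$df,
                   p = sp$p, n = sp$n)
            }
          }
          rows[[length(rows) + 1]] <- data.frame(
            region_name = region, hemisphere = hemi, measure = measure,
            score = score, method = method, family = fam,
            estimate = res$r, statistic = res$statistic, df = res$df,
            p_raw = res$p, n = res$n,
            covariates = paste(covariates, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  # FDR once per family
  out$p_fdr <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_fdr[sel] <- bh_fdr(out$p_raw[sel])
  }
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}

#' Covariate-adjusted group comparisons for a set of regions
#'
#' Runs \code{\link{ancova_compare}} (age and gender adjusted) for each
#' (region, hemisphere, measure) cell, with BH-FDR applied per measure x
#' hemisphere family over contrast p-values.
#'
#' @param summaries Region-summary rows for all subjects.
#' @param cohort Cohort table (must include \code{subject_id},
#'   \code{group}, \code{age}, \code{gender}).
#' @param measures,region_set As in \code{\link{run_correlation_battery}}.
#' @param ref Reference group for contrasts (default "HC").
#' @param alpha Significance level on adjusted p-values.
#' @return data.frame of contrast rows with \code{p_fdr} and
#'   \code{significant} columns, plus omnibus rows (\code{contrast = "omnibus"}).
#' @export
run_group_comparisons <- function(summaries, cohort,
                                  measures = c("R2t*", "NV"),
                                  region_set = c("hippocampus", "amygdala"),
                                  ref = "HC", alpha = 0.05) {
  measure_col <- c(`R2t*` = "median_r2t_star", NV = "normalized_volume")
  rows <- list()
  for (measure in measures) {
    mcol <- measure_col[[measure]]
    for (region in region_set) {
      for (hemi in c("left", "right")) {
        sub <- summaries[summaries$region_name == region &
                         summaries$hemisphere == hemi, ]
        merged <- merge(sub, cohort, by = "subject_id")
        merged <- merged[stats::complete.cases(
          merged[, c(mcol, "group", "age", "gender")]), , drop = FALSE]
        C <- cbind(age = merged$age,
                   gender = as.numeric(as.factor(merged$gender)) - 1)
        res <- ancova_compare(merged[[mcol]], merged$group, C, ref = ref)
        con <- res$contrasts
        con <- rbind(con,
                     data.frame(contrast = "omnibus", estimate = NA_real_,
                                statistic = res$omnibus$F,
                                df = res$omnibus$df2,
                                p_raw = res$omnibus$p, n = nrow(merged),
                                stringsAsFactors = FALSE))
        con$region_name <- region
        con$hemisphere <- hemi
        con$measure <- measure
        rows[[length(rows) + 1]] <- con
      }
    }
  }
  out <- do.call(rbind, rows)
  out$family <- paste0(out$measure, ":", out$hemisphere)
  out$p_fdr <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam & out$contrast != "omnibus"
    out$p_fdr[sel] <- bh_fdr(out$p_raw[sel])
  }
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}
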