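#' Spearman rank correlation with pairwise deletion
#'
#' Mid-ranks for ties, p-value from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom, and
#' the number of complete pairs reported alongside the estimate (cohort
#' tables are analysed with per-statistic pairwise deletion, so each
#' correlation carries its own n).
#'
#' @param x,y Paired numeric vectors; NAs are removed pairwise.
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1 - 1e-15) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Nonparametric group comparison
#'
#' Two groups: Wilcoxon rank-sum test. Three or more groups: tie-corrected
#' Kruskal-Wallis with a chi-square p-value, followed by Dunn's pairwise
#' z-tests with Bonferroni multiplication.
#'
#' @param groups List of numeric vectors (NAs dropped); all groups must be
#'   non-empty after NA removal.
#' @return List with `test` ("wilcoxon" or "kruskal-wallis"), `statistic`,
#'   `p.value`, and for >2 groups a `posthoc` tibble
#'   (`group1`, `group2`, `z`, `p_adj`).
#' @export
rank_tests <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0))
    stop("group with 0 observations", call. = FALSE)
  if (length(groups) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
    return(list(test = "wilcoxon", statistic = unname(wt$statistic),
                p.value = wt$p.value, posthoc = NULL))
  }
  kw <- stats::kruskal.test(groups)
  k <- length(groups)
  pooled <- unlist(groups)
  N <- length(pooled)
  rk <- rank(pooled)
  gidx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(rk, gidx, mean)
  ns <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  m <- k * (k - 1) / 2
  ph <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[i] + 1 / ns[j]))
    z <- (rbar[i] - rbar[j]) / se
    p_adj <- min(1, 2 * stats::pnorm(-abs(z)) * m)
    ph <- rbind(ph, tibble::tibble(group1 = i, group2 = j,
                                   z = unname(z), p_adj = p_adj))
  }
  list(test = "kruskal-wallis", statistic = unname(kw$statistic),
       p.value = kw$p.value, posthoc = ph)
}

# DeLong structural components: rows = cases, cols = controls
delong_components <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  if (length(x) == 0 || length(y) == 0)
    stop("both classes must be present", call. = FALSE)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(x), n = length(y))
}

#' ROC analysis with DeLong variance
#'
#' The AUC is the tie-aware Mann-Whitney concordance (ties count one half);
#' its variance comes from DeLong's structural components
#' (`S10/m + S01/n`), giving a 95% Wald confidence interval clipped to
#' \[0, 1\]. The threshold curve reports sensitivity and specificity at every
#' distinct score cutoff (predicting positive when `score >= cutoff`).
#'
#' @param scores Numeric marker values (higher = more disease-like).
#' @param labels Logical (or 0/1) outcome; `TRUE` = diseased.
#' @return A `roc_result`: list with `auc`, `delong_variance`, `ci95`,
#'   `curve` (tibble of score, sensitivity, specificity), `n_pos`, `n_neg`.
#' @export
roc_delong <- function(scores, labels) {
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  dc <- delong_components(scores, labels)
  s10 <- if (dc$m > 1) stats::var(dc$v10) else 0
  s01 <- if (dc$n > 1) stats::var(dc$v01) else 0
  v <- s10 / dc$m + s01 / dc$n
  half <- stats::qnorm(0.975) * sqrt(v)
  cuts <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble::tibble(
    score = cuts,
    sensitivity = vapply(cuts, function(c) mean(scores[labels] >= c), numeric(1)),
    specificity = vapply(cuts, function(c) mean(scores[!labels] < c), numeric(1)))
  structure(list(auc = dc$auc, delong_variance = v,
                 ci95 = c(max(0, dc$auc - half), min(1, dc$auc + half)),
                 curve = curve, n_pos = dc$m, n_neg = dc$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_delong
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_delong
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, delong_variance = x$delong_variance,
                 ci_low = x$ci95[1], ci_high = x$ci95[2],
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_delong
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC %.2f (95%% CI %.2f-%.2f)",
                                     object$auc, object$ci95[1],
                                     object$ci95[2])) +
    ggplot2::theme_minimal()
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both markers are scored on the same patients; the test statistic uses the
#' covariance of the DeLong structural components. Identical (or
#' rank-identical) scores give a zero AUC difference with `p = 1` by
#' convention.
#'
#' @param scores_a,scores_b Paired marker values.
#' @param labels Logical outcome, shared by both markers.
#' @return One-row tibble: `auc_a`, `auc_b`, `delta_auc`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  ok <- stats::complete.cases(scores_a, scores_b, labels)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]
  labels <- as.logical(labels[ok])
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  delta <- da$auc - db$auc
  v10 <- cbind(da$v10, db$v10)
  v01 <- cbind(da$v01, db$v01)
  s10 <- if (da$m > 1) stats::cov(v10) else matrix(0, 2, 2)
  s01 <- if (da$n > 1) stats::cov(v01) else matrix(0, 2, 2)
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  if (vd <= 1e-15) {
    z <- 0
    p <- if (abs(delta) < 1e-15) 1 else 0
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = da$auc, auc_b = db$auc, delta_auc = delta,
                 z = z, p = p)
}

#' Combine markers into a logistic risk score
#'
#' Linear combination framework for diagnostic markers: a logistic
#' regression of the binary outcome on the marker columns yields a linear
#' risk score whose ROC performance is then evaluated; because the ROC is
#' rank-invariant, the linear predictor itself is used as the combined
#' score. Complete-case rows are used. Perfect separation triggers a
#' ridge-penalized fallback (small L2 penalty), flagged in the output.
#'
#' @param table Cohort tibble.
#' @param columns Character vector (>= 2) of marker columns.
#' @param outcome Name of the logical outcome column (default `ph_status`).
#' @return A `combined_marker`: list with `columns`, `coefficients`,
#'   `score` (per complete-case row), `row_index`, `roc` ([roc_delong()] of
#'   the score), `penalized`.
#' @export
combine_markers <- function(table, columns, outcome = "ph_status") {
  stopifnot(length(columns) >= 2)
  dat <- table[, c(columns, outcome)]
  cc <- stats::complete.cases(dat)
  if (sum(cc) < 10) stop("need at least 10 complete-case rows", call. = FALSE)
  dat <- dat[cc, ]
  y <- as.numeric(dat[[outcome]])
  X <- as.matrix(dat[, columns])
  penalized <- FALSE
  coefs <- NULL
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ X, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_warn || !fit$converged || any(abs(stats::coef(fit)[-1]) > 50,
                                        na.rm = TRUE)) {
    penalized <- TRUE
    gfit <- suppressWarnings(
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = 0.01, standardize = TRUE))
    coefs <- c(as.numeric(gfit$a0), as.numeric(gfit$beta))
  } else {
    coefs <- unname(stats::coef(fit))
    coefs[is.na(coefs)] <- 0
  }
  names(coefs) <- c("(Intercept)", columns)
  score <- as.numeric(cbind(1, X) %*% coefs)
  structure(list(columns = columns, coefficients = coefs, score = score,
                 row_index = which(cc),
                 roc = roc_delong(score, dat[[outcome]]),
                 penalized = penalized),
            class = "combined_marker")
}

#' @rdname combine_markers
#' @param x A `combined_marker`.
#' @param ... Unused.
#' @export
tidy.combined_marker <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname combine_markers
#' @export
glance.combined_marker <- function(x, ...) {
  dplyr::mutate(glance(x$roc), penalized = x$penalized,
                n = length(x$score))
}

#' Apply the labeling-accuracy exclusion rule
#'
#' Scans whose artery/vein labeling accuracy is strictly below
#' `min_accuracy` (default 0.80) are excluded from the artery/vein
#' subcohort; an accuracy of exactly the threshold is retained. Rows with
#' missing accuracy (not assessed) stay in the full cohort but are excluded
#' from the A/V subcohort.
#'
#' @param table Cohort tibble with an `av_accuracy` column (fraction 0-1).
#' @param min_accuracy Strict lower bound for retention.
#' @return List: `table` (unchanged full cohort), `av_subcohort` (retained
#'   rows), `log` (tibble with `row`, `av_accuracy`, `reason` per excluded
#'   row).
#' @export
apply_exclusions <- function(table, min_accuracy = 0.80) {
  if (!"av_accuracy" %in% names(table))
    stop("av_accuracy column required", call. = FALSE)
  acc <- table$av_accuracy
  low <- !is.na(acc) & acc < min_accuracy
  not_assessed <- is.na(acc)
  keep <- !low & !not_assessed
  log <- tibble::tibble(
    row = which(!keep),
    av_accuracy = acc[!keep],
    reason = ifelse(is.na(acc[!keep]), "accuracy not assessed",
                    sprintf("labeling accuracy %.3f below %.2f",
                            acc[!keep], min_accuracy)))
  list(table = table, av_subcohort = table[keep, ], log = log)
}
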