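#' Confusion-matrix screening metrics
#'
#' Standard screening-test metrics from counts. The likelihood ratios follow
#' the usual infinity convention: PLR is infinite when specificity is 1 and
#' sensitivity is positive; ratios with undefined 0/0 denominators are
#' returned as `NA`.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return named list with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `plr`, `nlr`.
#' @export
screening_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be >= 0")
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) { if (num == 0) NA_real_ else Inf } else num / den
  }
  list(sensitivity = sens,
       specificity = spec,
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       accuracy = (tp + tn) / total,
       plr = ratio(sens, 1 - spec),
       nlr = ratio(1 - sens, spec))
}

auc_discrimination_grade <- function(auc) {
  if (auc >= 0.9) "outstanding discrimination"
  else if (auc >= 0.8) "excellent discrimination"
  else if (auc >= 0.7) "acceptable discrimination"
  else if (auc > 0.5) "below acceptable discrimination"
  else "no discrimination"
}

#' ROC analysis with the Youden-index cut-off
#'
#' Labels are `cobb > cobb_threshold`; a subject screens positive when the
#' asymmetry index is at or above the cut-off (larger index, more asymmetric
#' back). The ROC is evaluated at midpoints between sorted distinct scores,
#' AUC by the trapezoidal rule, and the reported cut-off maximizes the
#' Youden index (sensitivity + specificity - 1), ties breaking toward the
#' lower cut-off so a screening tool keeps sensitivity. The AUC confidence
#' interval is DeLong's by default, or a seeded percentile bootstrap.
#'
#' @param data a `screening_dataset` (columns `i_asym`, `cobb`).
#' @param cobb_threshold Cobb-angle threshold in degrees defining disease.
#' @param conf_level CI level (default 0.95).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n,boot_seed bootstrap replicates and seed.
#' @return an object of class `roc_result`: `auc`, `auc_ci_95`, `cutoff`,
#'   the Table-style metrics at the cut-off, `discrimination_category`, the
#'   full `curve` (data frame of cut-offs, sensitivity, specificity), and
#'   counts.
#' @export
roc_with_youden <- function(data, cobb_threshold, conf_level = 0.95,
                            ci_method = c("delong", "bootstrap"),
                            boot_n = 2000, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  scores <- data$i_asym
  labels <- data$cobb > cobb_threshold
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be non-empty after thresholding cobb")

  s <- sort(unique(scores))
  cutoffs <- c(min(s) - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
               max(s) + 1)
  sens <- vapply(cutoffs, function(ct) mean(scores[labels] >= ct), numeric(1))
  spec <- vapply(cutoffs, function(ct) mean(scores[!labels] < ct), numeric(1))

  # trapezoidal AUC over the ROC polyline (FPR ascending)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)

  youden <- sens + spec - 1
  best <- which(youden == max(youden))[1]   # cutoffs ascending: lowest wins
  cutoff <- cutoffs[best]
  tp <- sum(labels & scores >= cutoff)
  fp <- sum(!labels & scores >= cutoff)
  tn <- sum(!labels & scores < cutoff)
  fn <- sum(labels & scores < cutoff)
  met <- screening_metrics(tp, fp, tn, fn)

  ci <- if (ci_method == "delong")
    auc_ci_delong(scores, labels, conf_level)
  else auc_ci_bootstrap(scores, labels, conf_level, boot_n, boot_seed)

  structure(c(list(auc = auc, auc_ci_95 = ci, cutoff = cutoff,
                   cobb_threshold = cobb_threshold,
                   discrimination_category = auc_discrimination_grade(auc),
                   n_pos = n_pos, n_neg = n_neg,
                   confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                   curve = data.frame(cutoff = cutoffs, sensitivity = sens,
                                      specificity = spec)),
              met),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f (%.3f, %.3f), cut-off %.3g mm, sens %.2f, spec %.2f — %s>\n",
              x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$cutoff,
              x$sensitivity, x$specificity, x$discrimination_category))
  invisible(x)
}

# DeLong variance of the AUC (the AUC equals the Mann-Whitney U statistic
# scaled by n_pos * n_neg; the placement-value decomposition gives its SE).
auc_ci_delong <- function(scores, labels, conf_level = 0.95) {
  xs <- scores[labels]
  ys <- scores[!labels]
  m <- length(xs); n <- length(ys)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(xs, function(a) mean(psi(a, ys)), numeric(1))
  v01 <- vapply(ys, function(b) mean(psi(xs, b)), numeric(1))
  auc <- mean(v10)
  s2 <- if (m > 1) stats::var(v10) / m else 0
  s2 <- s2 + if (n > 1) stats::var(v01) / n else 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(s2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

auc_ci_bootstrap <- function(scores, labels, conf_level, boot_n, boot_seed) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(boot_seed)
  ip <- which(labels); ineg <- which(!labels)
  aucs <- replicate(boot_n, {
    i <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    auc_mann_whitney(scores[i], labels[i])
  })
  stats::quantile(aucs, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                  names = FALSE)
}

#' AUC via the Mann-Whitney U statistic
#'
#' `U / (n_pos * n_neg)` with the half-tie convention; equals the
#' trapezoidal ROC area. Kept as an exported primitive because it is the
#' cross-check for the ROC construction.
#'
#' @param scores numeric scores.
#' @param labels logical disease labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  xs <- scores[labels]
  ys <- scores[!labels]
  if (length(xs) == 0 || length(ys) == 0) stop("both classes must be non-empty")
  u <- sum(vapply(xs, function(a) sum(a > ys) + 0.5 * sum(a == ys),
                  numeric(1)))
  u / (length(xs) * length(ys))
}

cv_grade <- function(cv) {
  if (cv < 10) "very good"
  else if (cv <= 20) "good"
  else if (cv <= 30) "fair/moderate"
  else "poor"
}

#' Coefficient of variation with repeatability grading
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation, graded on the
#' standard repeatability bands (very good below 10%, good to 20%,
#' fair/moderate to 30%, poor above).
#'
#' @param values repeated measurements (mm); needs `n >= 2` and positive
#'   mean.
#' @return list with `cv_percent` and `grade`.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  cv <- 100 * stats::sd(values) / m
  list(cv_percent = cv, grade = cv_grade(cv))
}

#' Coefficient of variation from a reported mean and SD
#'
#' Worked-example form for published summary cells (mean +- SD).
#'
#' @param mean_value,sd_value summary statistics (same units).
#' @return list with `cv_percent` and `grade`.
#' @export
cv_from_summary <- function(mean_value, sd_value) {
  if (mean_value <= 0) stop("mean must be positive")
  if (sd_value < 0) stop("sd must be >= 0")
  cv <- 100 * sd_value / mean_value
  list(cv_percent = cv, grade = cv_grade(cv))
}

icc_grade <- function(icc) {
  if (icc > 0.9) "excellent"
  else if (icc > 0.75) "good"
  else if (icc >= 0.5) "moderate"
  else "poor"
}

#' Two-way mixed, absolute-agreement, single-measure ICC
#'
#' ICC(A,1) from the two-way mean-squares decomposition (subjects x
#' repeats), with the standard F-based confidence interval. Grading follows
#' the usual reliability bands (excellent above 0.90, good above 0.75,
#' moderate from 0.5, poor below). The model choice matters: other ICC
#' forms give different values on the same data.
#'
#' @param measurements numeric matrix, n subjects x k repeats, no missing
#'   cells.
#' @param conf_level CI level (default 0.95).
#' @return list with `icc`, `icc_ci_95`, `grade`, the mean squares, and a
#'   `degenerate` flag (TRUE when the between-subject variance vanishes).
#' @export
icc_two_way <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (any(is.na(m))) stop("no missing cells allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 repeats")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  degenerate <- denom <= 0 || (msr <= mse && msc <= mse && mse == 0)
  icc <- if (denom > 0) (msr - mse) / denom else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (!is.na(icc) && mse > 0) {
    # McGraw & Wong (1996) interval for ICC(A,1)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    alpha <- 1 - conf_level
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  list(icc = icc, icc_ci_95 = ci,
       grade = if (is.na(icc)) NA_character_ else icc_grade(icc),
       msr = msr, msc = msc, mse = mse, degenerate = degenerate)
}

#' Pearson correlations with a Fisher r-to-z comparison
#'
#' Pearson r in each group and the two-sided test of equality through the
#' Fisher transformation:
#' `z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param x1,y1 paired values of group 1 (n >= 4).
#' @param x2,y2 paired values of group 2 (n >= 4).
#' @return list with `r1`, `r2`, `z`, `p`, group sizes, and a `boundary`
#'   flag set when either correlation is exactly +-1 (atanh diverges; `z`
#'   and `p` are `NA` then).
#' @export
pearson_with_fisher_comparison <- function(x1, y1, x2, y2) {
  if (length(x1) != length(y1) || length(x2) != length(y2))
    stop("groups must be paired")
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 4 || n2 < 4) stop("each group needs n >= 4")
  if (stats::sd(x1) == 0 || stats::sd(y1) == 0 ||
      stats::sd(x2) == 0 || stats::sd(y2) == 0)
    stop("zero variance in a group")
  r1 <- stats::cor(x1, y1)
  r2 <- stats::cor(x2, y2)
  fisher_r_to_z_test(r1, n1, r2, n2)
}

#' @rdname pearson_with_fisher_comparison
#' @param r1,r2 correlation coefficients.
#' @param n1,n2 group sizes.
#' @export
fisher_r_to_z_test <- function(r1, n1, r2, n2) {
  boundary <- abs(r1) >= 1 || abs(r2) >= 1
  if (boundary) {
    z <- NA_real_; p <- NA_real_
  } else {
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z = z, p = p,
       boundary = boundary)
}

#' Table-style screening report over thresholds and strata
#'
#' One [roc_with_youden()] row per Cobb threshold and per curve-type
#' stratum (plus the pooled cohort). Strata where only one class remains
#' are reported with an `error` note instead of metrics.
#'
#' @param data a `screening_dataset`.
#' @param cobb_thresholds thresholds in degrees (default 15, 20, 25).
#' @param by_curve_type also stratify by `curve_type` when present.
#' @return data frame report.
#' @export
screening_report <- function(data, cobb_thresholds = c(15, 20, 25),
                             by_curve_type = TRUE) {
  strata <- list(total = data)
  if (by_curve_type && "curve_type" %in% names(data))
    for (ct in sort(unique(data$curve_type)))
      strata[[ct]] <- data[data$curve_type == ct, , drop = FALSE]
  rows <- list()
  for (sname in names(strata)) {
    for (th in cobb_thresholds) {
      res <- tryCatch(roc_with_youden(strata[[sname]], th),
                      error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
        data.frame(stratum = sname, cobb_threshold = th, cutoff = NA,
                   auc = NA, auc_lo = NA, auc_hi = NA, sensitivity = NA,
                   specificity = NA, ppv = NA, npv = NA, accuracy = NA,
                   plr = NA, nlr = NA, error = conditionMessage(res))
      } else {
        data.frame(stratum = sname, cobb_threshold = th, cutoff = res$cutoff,
                   auc = res$auc, auc_lo = res$auc_ci_95[1],
                   auc_hi = res$auc_ci_95[2], sensitivity = res$sensitivity,
                   specificity = res$specificity, ppv = res$ppv,
                   npv = res$npv, accuracy = res$accuracy, plr = res$plr,
                   nlr = res$nlr, error = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}
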