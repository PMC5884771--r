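#' Tie-aware Spearman correlation
#'
#' The coefficient is the Pearson correlation of midranks (average ranks for
#' ties). The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' a Monte-Carlo permutation p-value is available for small, tie-heavy
#' samples.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm number of permutations for `p_method = "permutation"`.
#' @return an object of class `htest` with `estimate` (rho), `statistic`
#'   and `p.value`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 10000L) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "t") {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    stat <- c(t = tstat)
  } else {
    perm <- replicate(n_perm, stats::cor(rx, sample(ry)))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    stat <- c(permutations = n_perm)
  }
  structure(
    list(estimate = c(rho = rho), statistic = stat, p.value = min(1, p),
         alternative = "two.sided",
         method = sprintf("Spearman rank correlation (%s p-value)",
                          if (p_method == "t") "t-approximation" else "permutation"),
         data.name = "x and y"),
    class = "htest")
}

#' Exact Mann-Whitney test by complete enumeration
#'
#' The U statistic is computed from midranks of the pooled sample. The
#' p-value enumerates all `choose(n1 + n2, n1)` assignments of the observed
#' pooled values to the two groups, which handles ties exactly. The
#' two-sided p-value is `2 * min(P(U <= u), P(U >= u))`, capped at 1.
#' Enumeration is refused above `max_n` total observations rather than
#' silently approximated.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (`a` tends
#'   larger) or `"less"`.
#' @param max_n total-size cap for enumeration.
#' @return an `htest` with the U `statistic` for group `a` and exact
#'   `p.value`.
#' @export
mann_whitney_exact <- function(a, b,
                               alternative = c("two.sided", "greater", "less"),
                               max_n = 20L) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  if (n1 + n2 > max_n)
    stop("total n = ", n1 + n2, " exceeds the enumeration cap (", max_n,
         "); exact mode refused")
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[assignments], nrow = n1)) - n1 * (n1 + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge,
              less = p_le)
  structure(
    list(statistic = c(U = u_obs), p.value = p, alternative = alternative,
         method = "Exact Mann-Whitney test (complete enumeration)",
         data.name = sprintf("a (n=%d) and b (n=%d)", n1, n2)),
    class = "htest")
}

#' Fisher's exact test for a 2x2 table
#'
#' With all margins fixed, the table probability is hypergeometric. The
#' one-sided p-value is the tail of tables as or more extreme in the
#' observed direction; the two-sided p-value sums the probabilities of all
#' tables no more probable than the observed one (the standard convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"one.sided"` (observed direction) or `"two.sided"`.
#' @return an `htest` with the `[1,1]` count as `statistic` and the exact
#'   `p.value`.
#' @export
fisher_exact <- function(table, alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integers")
  m <- sum(table[1, ])           # row-1 margin
  n <- sum(table[2, ])
  k <- sum(table[, 1])           # column-1 margin
  if (m == 0 || n == 0 || k == 0 || sum(table[, 2]) == 0)
    stop("undefined test: empty margin")
  x <- table[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  expected <- k * m / (m + n)
  p_one <- if (x >= expected)
    sum(probs[support >= x]) else sum(probs[support <= x])
  p_obs <- stats::dhyper(x, m, n, k)
  p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- if (alternative == "one.sided") p_one else min(1, p_two)
  structure(
    list(statistic = c(x = x), p.value = p, alternative = alternative,
         method = "Fisher's exact test (hypergeometric)",
         data.name = "2x2 contingency table"),
    class = "htest")
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; `|differences|` are midranked. For `n`
#' non-zero differences up to `max_exact` the null distribution of the
#' positive-rank sum V is enumerated over all `2^n` sign assignments
#' (exact under ties); the two-sided p-value is `2 * min(tails)`, capped
#' at 1. Larger samples use the normal approximation with tie correction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param max_exact largest `n` for enumeration.
#' @return an `htest` with `statistic` V and `p.value`.
#' @export
wilcoxon_paired <- function(x, y,
                            alternative = c("two.sided", "greater", "less"),
                            max_exact = 15L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- (x - y)[is.finite(x) & is.finite(y)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= max_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p_le <- mean(v_all <= v_obs + 1e-9)
    p_ge <- mean(v_all >= v_obs - 1e-9)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "Exact Wilcoxon signed-rank test (sign enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v_obs - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(-z), less = stats::pnorm(z))
    method <- "Wilcoxon signed-rank test (normal approximation, tie-corrected)"
  }
  structure(
    list(statistic = c(V = v_obs), p.value = min(1, p),
         alternative = alternative, method = method,
         data.name = sprintf("paired differences (n=%d non-zero)", n)),
    class = "htest")
}

.icc_bands <- c(poor = 0, moderate = 0.50, good = 0.75, excellent = 0.90)

icc_band_label <- function(ci_low) {
  if (ci_low > 0.90) "excellent"
  else if (ci_low >= 0.75) "good"
  else if (ci_low >= 0.50) "moderate"
  else "poor"
}

#' Intraclass correlation with CI-based agreement band
#'
#' Inter-observer agreement uses the two-way, absolute-agreement,
#' single-measures ICC (ICC(A,1)); intra-observer (test-retest) agreement
#' uses the one-way random single-measures ICC (ICC(1)). Mean squares come
#' from the corresponding ANOVA and the 95% confidence interval from the
#' standard F-based formulas. The qualitative band is determined solely by
#' the lower CI bound: poor (< 0.50), moderate (0.50-0.75), good
#' (0.75-0.90; also reported as "substantial" in some nomenclatures),
#' excellent (> 0.90); the 0.50 and 0.75 bounds are inclusive and
#' "excellent" requires a lower bound strictly above 0.90.
#'
#' @param ratings numeric matrix, subjects x raters (or repeats), no
#'   missing cells.
#' @param model `"inter"` (two-way absolute agreement) or `"intra"`
#'   (one-way random).
#' @param conf_level confidence level for the interval.
#' @return an `af_icc` list: `icc`, `ci_low`, `ci_high`, `band`, `model`.
#' @export
icc_agreement <- function(ratings, model = c("inter", "intra"),
                          conf_level = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must have no missing cells")
  ns <- nrow(ratings); nr <- ncol(ratings)
  if (ns < 5) stop("need at least 5 subjects")
  if (nr < 2) stop("need at least 2 raters/repeats")
  alpha <- 1 - conf_level

  df <- data.frame(score = as.vector(ratings),
                   subject = factor(rep(seq_len(ns), nr)),
                   rater = factor(rep(seq_len(nr), each = ns)))
  if (model == "inter") {
    ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    if (msr <= mse + 1e-12 && stats::var(rowMeans(ratings)) < 1e-12)
      stop("undefined ICC: no between-subject variance")
    icc <- (msr - mse) / (msr + (nr - 1) * mse + nr * (msc - mse) / ns)
    if (icc > 1 - 1e-12) {   # perfect agreement: degenerate F interval
      out <- list(icc = 1, ci_low = 1, ci_high = 1)
      return(structure(
        c(out, list(band = icc_band_label(1), model = model,
                    conf_level = conf_level, n_subjects = ns, n_raters = nr)),
        class = "af_icc"))
    }
    a <- (nr * icc) / (ns * (1 - icc))
    b <- 1 + (nr * icc * (ns - 1)) / (ns * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (nr - 1) + (b * mse)^2 / ((ns - 1) * (nr - 1)))
    f_l <- stats::qf(1 - alpha / 2, ns - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, ns - 1)
    ci_low <- ns * (msr - f_l * mse) /
      (f_l * (nr * msc + (nr * ns - nr - ns) * mse) + ns * msr)
    ci_high <- ns * (f_u * msr - mse) /
      (nr * msc + (nr * ns - nr - ns) * mse + ns * f_u * msr)
  } else {
    ms <- summary(stats::aov(score ~ subject, data = df))[[1]][, "Mean Sq"]
    msb <- ms[1]; msw <- ms[2]
    if (msb <= msw + 1e-12 && stats::var(rowMeans(ratings)) < 1e-12)
      stop("undefined ICC: no between-subject variance")
    icc <- (msb - msw) / (msb + (nr - 1) * msw)
    if (icc > 1 - 1e-12) {
      out <- list(icc = 1, ci_low = 1, ci_high = 1)
      return(structure(
        c(out, list(band = icc_band_label(1), model = model,
                    conf_level = conf_level, n_subjects = ns, n_raters = nr)),
        class = "af_icc"))
    }
    f_obs <- msb / msw
    f_l <- f_obs / stats::qf(1 - alpha / 2, ns - 1, ns * (nr - 1))
    f_u <- f_obs * stats::qf(1 - alpha / 2, ns * (nr - 1), ns - 1)
    ci_low <- (f_l - 1) / (f_l + nr - 1)
    ci_high <- (f_u - 1) / (f_u + nr - 1)
  }
  structure(
    list(icc = unname(icc), ci_low = unname(min(ci_low, icc)),
         ci_high = unname(max(ci_high, icc)),
         band = icc_band_label(unname(min(ci_low, icc))),
         model = model, conf_level = conf_level,
         n_subjects = ns, n_raters = nr),
    class = "af_icc")
}

#' @export
print.af_icc <- function(x, ...) {
  cat(sprintf(
    "ICC (%s, single measures): %.3f [%.0f%% CI %.3f-%.3f] -> %s agreement\n",
    if (x$model == "inter") "two-way absolute agreement" else "one-way random",
    x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$band))
  invisible(x)
}

# Variables entering the cohort correlation matrix, in display order.
.cormat_vars <- c("age", "bcva_logmar", "oct_stage", "ise_width_deg",
                  "ring_diameter_deg", "hypo_diameter_deg")

#' Spearman correlation matrix over cohort variables
#'
#' Pairwise Spearman correlations (with t-approximation p-values, no
#' multiple-testing correction) between age, study-eye BCVA in LogMAR, OCT
#' stage, ISe defect width and the two lesion diameters. Missing values are
#' pairwise-deleted; cells with fewer than 4 complete pairs, and constant
#' columns, are skipped with a warning.
#'
#' @param cohort an [as_cohort()] table.
#' @return an `af_cormat` list with symmetric matrices `rho`, `p`, `n`.
#' @export
correlation_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "af_cohort"))
  bcva <- ifelse(cohort$study_eye == "OD", cohort$bcva_od, cohort$bcva_os)
  dat <- data.frame(
    age = cohort$age,
    bcva_logmar = snellen_to_logmar(bcva),
    oct_stage = as.numeric(cohort$oct_stage),
    ise_width_deg = cohort$ise_width_deg,
    ring_diameter_deg = if ("ring_diameter_deg" %in% names(cohort))
      cohort$ring_diameter_deg else NA_real_,
    hypo_diameter_deg = if ("hypo_diameter_deg" %in% names(cohort))
      cohort$hypo_diameter_deg else NA_real_)
  vars <- .cormat_vars
  usable <- vapply(vars, function(v) {
    ok <- sum(is.finite(dat[[v]])) >= 4 &&
      stats::sd(dat[[v]], na.rm = TRUE) > 0
    if (!ok) warning("column '", v, "' skipped (all-missing or constant)",
                     call. = FALSE)
    ok
  }, TRUE)
  vars <- vars[usable]
  k <- length(vars)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  diag(n) <- vapply(vars, function(v) sum(is.finite(dat[[v]])), 1.0)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      xi <- dat[[vars[i]]]; xj <- dat[[vars[j]]]
      keep <- is.finite(xi) & is.finite(xj)
      n[i, j] <- n[j, i] <- sum(keep)
      if (sum(keep) < 4 || stats::sd(xi[keep]) == 0 || stats::sd(xj[keep]) == 0)
        next
      res <- spearman_cor(xi[keep], xj[keep])
      rho[i, j] <- rho[j, i] <- unname(res$estimate)
      p[i, j] <- p[j, i] <- res$p.value
    }
  }
  structure(list(rho = rho, p = p, n = n), class = "af_cormat")
}

#' @export
print.af_cormat <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (upper triangle: rho; lower: p)\n")
  k <- ncol(x$rho)
  disp <- matrix("", k, k, dimnames = dimnames(x$rho))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) disp[i, j] <- ifelse(is.na(x$rho[i, j]), ".",
                                    formatC(x$rho[i, j], digits = digits, format = "f"))
    if (j < i) disp[i, j] <- ifelse(is.na(x$p[i, j]), ".",
                                    formatC(x$p[i, j], digits = 3, format = "f"))
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Group comparison by NIR-AF central hypoautofluorescence
#'
#' Splits the cohort into patients with a present versus absent NIR-AF
#' central hypoautofluorescent area (borderline cases are excluded from
#' both groups), compares ages with the exact two-sided Mann-Whitney test,
#' and cross-tabulates advanced outer-retinal alteration on OCT (stage 3
#' or 4) against group membership with Fisher's exact test (one-sided by
#' default, i.e. testing whether advanced stages are over-represented in
#' the hypoautofluorescent group).
#'
#' @param cohort an [as_cohort()] table with >= 2 present and >= 2 absent
#'   records.
#' @param fisher_alternative `"one.sided"` (default) or `"two.sided"`.
#' @return an `af_nir_groups` list: per-group age mean/SD and n, the
#'   Mann-Whitney `htest`, the 2x2 stage table and the Fisher `htest`.
#' @export
nir_group_analysis <- function(cohort,
                               fisher_alternative = c("one.sided", "two.sided")) {
  stopifnot(inherits(cohort, "af_cohort"))
  fisher_alternative <- match.arg(fisher_alternative)
  present <- cohort[cohort$niraf_hypo == "present", ]
  absent <- cohort[cohort$niraf_hypo == "absent", ]
  if (nrow(present) < 2 || nrow(absent) < 2)
    stop("need at least 2 patients in each NIR-AF group")
  mw <- mann_whitney_exact(present$age, absent$age)
  advanced <- function(d) sum(d$oct_stage >= 3)
  tab <- matrix(c(advanced(present), nrow(present) - advanced(present),
                  advanced(absent), nrow(absent) - advanced(absent)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("NIR hypoAF present", "NIR hypoAF absent"),
                                c("stage 3-4", "stage 1-2")))
  fis <- fisher_exact(tab, alternative = fisher_alternative)
  structure(
    list(age_present = c(n = nrow(present), mean = mean(present$age),
                         sd = stats::sd(present$age)),
         age_absent = c(n = nrow(absent), mean = mean(absent$age),
                        sd = stats::sd(absent$age)),
         mann_whitney = mw, stage_table = tab, fisher = fis,
         n_borderline = sum(cohort$niraf_hypo == "borderline")),
    class = "af_nir_groups")
}

#' @export
print.af_nir_groups <- function(x, ...) {
  cat("NIR-AF central hypoautofluorescence group comparison\n")
  cat(sprintf("  age, present group: %.1f +/- %.1f years (n=%d)\n",
              x$age_present["mean"], x$age_present["sd"], x$age_present["n"]))
  cat(sprintf("  age, normal group:  %.1f +/- %.1f years (n=%d)\n",
              x$age_absent["mean"], x$age_absent["sd"], x$age_absent["n"]))
  cat(sprintf("  exact Mann-Whitney two-sided p = %.3f\n",
              x$mann_whitney$p.value))
  print(x$stage_table)
  cat(sprintf("  Fisher %s p = %.3f (%d borderline case(s) excluded)\n",
              x$fisher$alternative, x$fisher$p.value, x$n_borderline))
  invisible(x)
}
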