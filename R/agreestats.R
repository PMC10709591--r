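#' Intraclass correlation for two-observer agreement
#'
#' ICC(2,1) in the Shrout-Fleiss numbering (ICC(A,1) in McGraw-Wong):
#' two-way random effects, absolute agreement, single measures -- the
#' standard choice when two raters measure the same cases and the absolute
#' value of the measurement matters, so that a constant offset between
#' raters is penalised. Confidence interval by the McGraw-Wong F method;
#' the P value tests ICC > 0 via F = MSR/MSE.
#'
#' @param x,y paired measurements (equal length >= 3, finite).
#' @param conf_level confidence level for the interval.
#' @return List with `icc`, `ci` (length 2), `p`, and the mean squares.
#' @export
icc_agreement <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired measurements")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("measurements must be finite")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
  if (abs(denom) < 1e-300) {
    warning("no variance in either direction; ICC undefined, returning 0")
    return(list(icc = 0, ci = c(NA_real_, NA_real_), p = NA_real_,
                ms = c(MSR = MSR, MSC = MSC, MSE = MSE)))
  }
  icc <- (MSR - MSE) / denom
  alpha <- 1 - conf_level
  if (MSE <= 1e-300 && MSC <= 1e-300) {          # perfect agreement
    ci <- c(1, 1); p <- 0
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - n - k) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - n - k) * MSE + n * FU * MSR)
    p <- pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci, p = p, ms = c(MSR = MSR, MSC = MSC, MSE = MSE))
}

#' Compare two dependent correlations sharing a variable
#'
#' Hotelling-Williams test for overlapping dependent correlations: given
#' r(a,b) and r(c,b) computed on the same n cases (b is the shared
#' reference, here the real thin-section measurement) and the
#' cross-correlation r(a,c), tests whether the two correlations with b
#' differ. Two-sided P from a t distribution with n - 3 degrees of freedom.
#' As r(a,c) tends to 0 the statistic approaches the independent Fisher
#' z-test, which is also exposed via `method = "fisher"` (note that Fisher's
#' independent test is generally inappropriate for overlapping correlations
#' measured on the same subjects).
#'
#' @param r_ab,r_cb the two correlations with the shared variable, |r| < 1.
#' @param r_ac correlation between the two non-shared variables, |r| < 1.
#' @param n number of cases (>= 4).
#' @param method "williams" (default) or "fisher" (ignores r_ac).
#' @return List with `statistic` and `p`.
#' @export
compare_dependent_r <- function(r_ab, r_cb, r_ac, n, method = c("williams", "fisher")) {
  method <- match.arg(method)
  if (any(abs(c(r_ab, r_cb, r_ac)) >= 1)) stop("correlations must satisfy |r| < 1")
  if (n < 4) stop("need n >= 4")
  if (method == "fisher") {
    z <- (atanh(r_ab) - atanh(r_cb)) / sqrt(2 / (n - 3))
    return(list(statistic = z, p = 2 * pnorm(-abs(z))))
  }
  detR <- 1 - r_ab^2 - r_cb^2 - r_ac^2 + 2 * r_ab * r_cb * r_ac
  if (detR < 0)
    stop("correlations do not form a valid (positive semi-definite) matrix")
  rbar <- (r_ab + r_cb) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_ac)^3
  tstat <- (r_ab - r_cb) * sqrt((n - 1) * (1 + r_ac) / denom)
  list(statistic = tstat, p = 2 * pt(-abs(tstat), df = n - 3))
}

#' Cohen's kappa with confidence interval
#'
#' Unweighted kappa from the K x K contingency table of two label vectors
#' over a shared category set (categories are treated nominally; a
#' linear-weighted variant is available via `weighted = TRUE`). The 95\%
#' confidence interval uses the Fleiss-Cohen-Everitt large-sample standard
#' error; the P value tests kappa > 0 with the null-hypothesis standard
#' error.
#'
#' @param labels_a,labels_b equal-length label vectors (factors or
#'   coercible); factor levels define the shared category set.
#' @param categories optional explicit category levels.
#' @param conf_level confidence level.
#' @param weighted if `TRUE`, linear weights on the ordered categories.
#' @return List with `kappa`, `ci`, `p`, `po`, `pe`, `table`.
#' @export
cohen_kappa <- function(labels_a, labels_b, categories = NULL,
                        conf_level = 0.95, weighted = FALSE) {
  if (length(labels_a) == 0L) stop("empty input")
  if (length(labels_a) != length(labels_b)) stop("label vectors must match in length")
  if (is.null(categories))
    categories <- union(levels(factor(labels_a)), levels(factor(labels_b)))
  fa <- factor(labels_a, levels = categories)
  fb <- factor(labels_b, levels = categories)
  if (any(is.na(fa)) || any(is.na(fb))) stop("labels outside the category set")
  n <- length(fa)
  tab <- table(fa, fb)
  p <- tab / n
  K <- length(categories)
  w <- if (weighted) 1 - abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
       else diag(K)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj_))
  if (1 - pe < 1e-12) {
    warning("kappa undefined: chance agreement is 1 (single category present)")
    return(list(kappa = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                po = po, pe = pe, table = tab))
  }
  kap <- (po - pe) / (1 - pe)
  # large-sample variance (Fleiss, Cohen & Everitt 1969), unweighted form;
  # for the weighted variant the analogous weighted expressions are used
  wi_ <- as.vector(w %*% pj_)   # row-weighted expected
  wj_ <- as.vector(t(w) %*% pi_)
  A <- sum(p * (w - outer(wi_, rep(1, K)) * (1 - kap) -
                  outer(rep(1, K), wj_) * (1 - kap))^2)
  var_k <- (A - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(kap - zq * se, kap + zq * se)
  # null SE for testing kappa > 0
  var0 <- (pe + pe^2 - sum(outer(pi_, pj_) * w *
                             (outer(wi_, rep(1, K)) + outer(rep(1, K), wj_)))) /
    (n * (1 - pe)^2)
  se0 <- sqrt(max(var0, 1e-300))
  pval <- pnorm(kap / se0, lower.tail = FALSE)
  list(kappa = kap, ci = ci, p = pval, po = po, pe = pe, table = tab)
}

#' Interpretation band for a kappa value
#'
#' Standard qualitative bands: below 0.20 poor, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 good, 0.81-1.00 almost perfect (upper bounds
#' inclusive).
#'
#' @param k kappa value(s) in [-1, 1].
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(k) {
  if (any(!is.finite(k)) || any(k < -1) || any(k > 1))
    stop("kappa must lie in [-1, 1]")
  cut_labels <- c("poor", "fair", "moderate", "good", "almost perfect")
  idx <- findInterval(k, c(-1, 0.20, 0.40, 0.60, 0.80), left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[k <= 0.20] <- 1L
  cut_labels[pmax(idx, 1L)]
}

#' ANCOVA comparing modalities and observers against a reference size
#'
#' Linear model of the measured solid size on observer and modality with the
#' reference (real thin-section) size as covariate:
#' `size ~ observer + modality + real_size`, with type-II F tests per term
#' (each term tested by dropping it from the full model). The model
#' structure is isolated here so alternatives are one-line swaps.
#'
#' @param data long-format data.frame with columns `size` (measured),
#'   `observer`, `modality` (factors or coercible) and `real_size` (the
#'   covariate).
#' @return List with per-term `(F, p)` entries (`observer`, `modality`,
#'   `real_size`) and the fitted `model`.
#' @export
ancova_modality_observer <- function(data) {
  need <- c("size", "observer", "modality", "real_size")
  if (!all(need %in% names(data)))
    stop("data must have columns size, observer, modality, real_size")
  data$observer <- factor(data$observer)
  data$modality <- factor(data$modality)
  full <- stats::lm(size ~ observer + modality + real_size, data = data)
  if (any(is.na(coef(full))))
    stop("rank-deficient ANCOVA design: check factor levels and balance")
  drop_term <- function(term) {
    red <- stats::update(full, paste(". ~ . -", term))
    an <- stats::anova(red, full)
    # computed by hand: anova() reports NA when a term's sum of squares
    # is numerically zero (a term that contributes nothing has F = 0)
    ss <- max(an$`Sum of Sq`[2], 0)
    df1 <- an$Df[2]
    mse <- an$RSS[2] / an$Res.Df[2]
    Fv <- if (mse > 0) (ss / df1) / mse else 0
    c(F = Fv, p = stats::pf(Fv, df1, an$Res.Df[2], lower.tail = FALSE))
  }
  list(observer = drop_term("observer"),
       modality = drop_term("modality"),
       real_size = drop_term("real_size"),
       model = full)
}
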