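# Negative binomial differential expression:
#   variance prefilter -> median-of-ratios size factors -> per-feature
#   dispersion (method-of-moments start, profile-likelihood refinement) ->
#   NB GLM (log link, IRLS, size factors as offsets) -> Wald test ->
#   Benjamini-Hochberg -> UP/DOWN classification.
# This deliberately covers the two components the referenced workflow names
# (median-of-ratios normalisation, NB dispersion modelling) plus a standard
# Wald test; it does not attempt empirical-Bayes dispersion shrinkage,
# outlier handling or independent filtering.

ALPHA_MIN <- 1e-8
ALPHA_MAX <- 10
LFC_CAP <- 30

#' Variance prefilter
#'
#' Removes features whose sample variance across all columns is strictly
#' below the given percentile of the per-feature variance distribution
#' (linear-interpolation percentile, i.e. `quantile(type = 7)`).
#'
#' @param matrix counts matrix (features x samples), >= 2 samples.
#' @param percentile percentile of the variance distribution (default 1, the
#'   first percentile).
#' @return the filtered matrix, with removed feature names in the
#'   `"removed"` attribute.
#' @export
variance_filter <- function(matrix, percentile = 1) {
  if (ncol(matrix) < 2L) stop("variance filter needs >= 2 samples")
  v <- apply(matrix, 1L, stats::var)
  cut <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
  drop <- v < cut
  out <- matrix[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(matrix)[drop]
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with a positive geometric mean across samples) of the ratio of
#' the feature's count to its geometric mean. Identical columns give factors
#' of exactly 1; scaling a column scales its factor by the same constant.
#'
#' @param matrix counts matrix (features x samples).
#' @return named numeric vector of positive size factors.
#' @export
size_factors_median_of_ratios <- function(matrix) {
  loggm <- rowMeans(log(matrix))
  use <- is.finite(loggm)
  if (!any(use)) stop("no feature with positive counts in all samples")
  sf <- apply(matrix, 2L, function(col) exp(stats::median(log(col[use]) - loggm[use])))
  stopifnot(all(sf > 0))
  sf
}

# NB log-likelihood of one feature at fixed dispersion, means from the fit
.nb_loglik <- function(y, mu, alpha) {
  if (alpha < ALPHA_MIN) alpha <- ALPHA_MIN
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# IRLS fit of an NB GLM with log link and offsets, fixed dispersion.
# Returns natural-log-scale coefficients, their covariance (inverse Fisher
# information) and fitted means.
.nb_irls <- function(y, X, offset, alpha, max_iter = 100L, tol = 1e-8) {
  # start from a regularised log-linear fit
  z0 <- log(y + 0.5) - offset
  beta <- tryCatch(stats::lm.fit(X, z0)$coefficients, error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -50), 50)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    ll <- .nb_loglik(y, exp(pmin(pmax(drop(X %*% beta_new) + offset, -50), 50)), alpha)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
    ll_old <- ll
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -50), 50)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X, X * w)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, cov = cov, mu = mu, loglik = .nb_loglik(y, mu, alpha),
       converged = converged)
}

#' Per-feature negative binomial dispersion estimate
#'
#' Method-of-moments start `max(alpha_min, (s^2 - mean)/mean^2)` on
#' normalised counts, refined by maximising the Cox-Reid adjusted profile
#' log-likelihood (group means re-fitted at each candidate; the adjustment
#' corrects the small-sample downward bias of plain profile ML) over
#' `log(alpha)` on `[log(1e-8), log(10)]` with one-dimensional bounded
#' optimisation.
#' Underdispersed features (e.g. constant counts) land exactly on the
#' `1e-8` floor. All-zero features are skipped (NA) and reported.
#'
#' @param matrix counts matrix (features x samples).
#' @param design design matrix (samples x coefficients), e.g. from
#'   [stats::model.matrix()]; defaults to an intercept-only design.
#' @param factors size factors (default from
#'   [size_factors_median_of_ratios()]).
#' @return named numeric vector of dispersions (NA for skipped features),
#'   with skipped feature names in the `"skipped"` attribute.
#' @export
estimate_dispersion <- function(matrix, design = NULL, factors = NULL) {
  if (is.null(factors)) factors <- size_factors_median_of_ratios(matrix)
  if (is.null(design)) design <- matrix(1, ncol(matrix), 1L)
  offset <- log(factors)
  out <- setNames(rep(NA_real_, nrow(matrix)), rownames(matrix))
  for (i in seq_len(nrow(matrix)))
    out[i] <- .dispersion_one(matrix[i, ], design, offset)
  attr(out, "skipped") <- rownames(matrix)[is.na(out)]
  out
}

.dispersion_one <- function(y, X, offset) {
  if (all(y == 0)) return(NA_real_)
  norm <- y / exp(offset)
  mbar <- mean(norm)
  a0 <- max(ALPHA_MIN, (stats::var(norm) - mbar) / mbar^2)
  # Cox-Reid adjusted profile log-likelihood: the -0.5 log det(X'WX) term
  # corrects the downward bias of plain profile ML when the mean parameters
  # are estimated from the same few samples
  prof <- function(la) {
    a <- exp(la)
    f <- .nb_irls(y, X, offset, a)
    w <- f$mu / (1 + a * f$mu)
    f$loglik - 0.5 * as.numeric(determinant(crossprod(X, X * w))$modulus)
  }
  opt <- stats::optimize(prof, interval = log(c(ALPHA_MIN, ALPHA_MAX)), maximum = TRUE)
  cand <- c(exp(opt$maximum), min(max(a0, ALPHA_MIN), ALPHA_MAX), ALPHA_MIN)
  ll <- vapply(log(cand), prof, numeric(1))
  a <- cand[which.max(ll)]
  # optimize() stops a hair inside the boundary; estimates this close to the
  # floor are indistinguishable from it
  if (log(a) - log(ALPHA_MIN) < 0.05) a <- ALPHA_MIN
  a
}

#' Fit a negative binomial GLM for one feature
#'
#' Log-link IRLS with `log(size factors)` as offsets, run to convergence
#' (relative log-likelihood change below 1e-8, at most 100 iterations).
#' Coefficients and standard errors (inverse Fisher information) are reported
#' in log2 units. Complete separation (an all-zero group driving the
#' coefficient off scale) is capped at +/-30 log2 units and flagged.
#'
#' @param y counts for one feature (length = samples).
#' @param design design matrix (samples x coefficients).
#' @param factors size factors.
#' @param alpha NB dispersion for this feature.
#' @param coef which coefficient to report (column index or name; default the
#'   last column).
#' @return list: `log2fc`, `se` (log2 scale), `base_mean` (mean normalised
#'   count), `converged`, `capped`.
#' @export
fit_nb_glm <- function(y, design, factors, alpha, coef = ncol(design)) {
  stopifnot(length(y) == nrow(design), length(factors) == length(y))
  if (is.character(coef)) coef <- match(coef, colnames(design))
  fit <- .nb_irls(y, design, log(factors), max(alpha, ALPHA_MIN))
  b2 <- fit$beta[coef] / log(2)
  se2 <- sqrt(fit$cov[coef, coef]) / log(2)
  capped <- FALSE
  if (!is.finite(b2) || abs(b2) > LFC_CAP) {
    b2 <- sign(b2) * LFC_CAP
    capped <- TRUE
  }
  list(log2fc = unname(b2), se = unname(se2),
       base_mean = mean(y / factors), converged = fit$converged, capped = capped)
}

#' Wald test of a fitted coefficient
#'
#' `stat = log2fc / se`, two-sided p-value from the standard normal tail.
#' A zero or non-finite standard error yields an NA p-value and a flag.
#'
#' @param log2fc,se coefficient and standard error (same scale).
#' @return list: `stat`, `p`.
#' @export
wald_test <- function(log2fc, se) {
  if (!is.finite(se) || se <= 0) return(list(stat = NA_real_, p = NA_real_))
  stat <- log2fc / se
  list(stat = stat, p = 2 * stats::pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{j>=i} p_(j) * m / j`, clipped at 1),
#' returned in input order. Delegates to [stats::p.adjust()] after validating
#' the input range.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' UP/DOWN classification of fold changes
#'
#' `up` iff `log2fc > lfc_threshold` and `p < p_threshold`; `down` iff
#' `log2fc < -lfc_threshold` and `p < p_threshold`; `no` otherwise. The
#' defaults are the |log2FC| > 0.6, p < 0.05 rule; `p` is the unadjusted
#' p-value by default (see [mirna_de()]'s `classify_on`).
#'
#' @param log2fc,p numeric vectors.
#' @param lfc_threshold,p_threshold classification thresholds.
#' @return character vector in {"up", "down", "no"}.
#' @export
#' @examples
#' classify_change(c(1.1, -3.046, 0.054), c(0.007, 0.036, 0.896))
classify_change <- function(log2fc, p, lfc_threshold = 0.6, p_threshold = 0.05) {
  out <- rep("no", length(log2fc))
  sig <- !is.na(p) & p < p_threshold
  out[sig & log2fc > lfc_threshold] <- "up"
  out[sig & log2fc < -lfc_threshold] <- "down"
  out
}

#' Negative binomial differential expression
#'
#' The package's model-fitting front end. Applies the variance prefilter,
#' estimates median-of-ratios size factors and per-feature NB dispersions,
#' fits a log-link NB GLM per feature with the size factors as offsets, Wald
#' tests the requested coefficient, adjusts p-values across all tested
#' features with Benjamini-Hochberg and classifies each feature as
#' up/down/no.
#'
#' @param counts features x samples matrix of non-negative counts with
#'   dimnames.
#' @param coldata data.frame of per-sample covariates (rows in column order
#'   of `counts`); must contain every variable in `design`. Character columns
#'   are converted to factors, so list the reference level first or pass
#'   factors with explicit levels.
#' @param design model formula over `coldata` columns, e.g. `~ condition` or
#'   `~ subject + condition` for a paired design.
#' @param coef coefficient to test (name or index in the model matrix;
#'   default the last column, i.e. the treatment-vs-reference contrast for
#'   `~ condition`).
#' @param lfc_threshold,p_threshold classification thresholds (defaults 0.6
#'   and 0.05).
#' @param variance_percentile variance prefilter percentile (default 1).
#' @param classify_on `"p_unadj"` (default) or `"p_adj"`: which p-value feeds
#'   the classification rule.
#' @return object of class `mirna_de`: a list with `results` (data.frame:
#'   `mirna`, `base_mean`, `log2fc`, `se`, `wald_stat`, `p_unadj`, `p_adj`,
#'   `change`, `converged`, `capped`), `size_factors`, `dispersions`,
#'   `removed` (variance-filtered names), `design`, `coef`, and the
#'   thresholds used.
#' @seealso [volcano_table()], [power_two_sample_t()]
#' @export
mirna_de <- function(counts, coldata, design = ~condition, coef = NULL,
                     lfc_threshold = 0.6, p_threshold = 0.05,
                     variance_percentile = 1, classify_on = c("p_unadj", "p_adj")) {
  classify_on <- match.arg(classify_on)
  stopifnot(is.matrix(counts), nrow(coldata) == ncol(counts))
  if (any(counts < 0)) stop("negative counts")
  coldata <- as.data.frame(coldata)
  for (v in all.vars(design))
    if (is.character(coldata[[v]])) coldata[[v]] <- factor(coldata[[v]])
  X <- stats::model.matrix(design, coldata)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  if (is.null(coef)) coef <- ncol(X)
  if (is.character(coef)) {
    coef <- match(coef, colnames(X))
    if (is.na(coef)) stop("coef not found in model matrix columns")
  }

  filtered <- variance_filter(counts, variance_percentile)
  removed <- attr(filtered, "removed")
  sf <- size_factors_median_of_ratios(filtered)
  disp <- estimate_dispersion(filtered, X, sf)

  feats <- rownames(filtered)
  res <- data.frame(mirna = feats, base_mean = NA_real_, log2fc = NA_real_,
                    se = NA_real_, wald_stat = NA_real_, p_unadj = NA_real_,
                    p_adj = NA_real_, change = "no", converged = NA,
                    capped = NA, stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    if (is.na(disp[i])) next  # all-zero feature: skipped, reported via dispersions
    f <- fit_nb_glm(filtered[i, ], X, sf, disp[i], coef)
    w <- wald_test(f$log2fc, f$se)
    res$base_mean[i] <- f$base_mean; res$log2fc[i] <- f$log2fc; res$se[i] <- f$se
    res$wald_stat[i] <- w$stat; res$p_unadj[i] <- w$p
    res$converged[i] <- f$converged; res$capped[i] <- f$capped
  }
  res$p_adj <- bh_adjust(res$p_unadj)
  p_class <- if (classify_on == "p_unadj") res$p_unadj else res$p_adj
  res$change <- classify_change(res$log2fc, p_class, lfc_threshold, p_threshold)
  rownames(res) <- NULL
  structure(list(results = res, size_factors = sf, dispersions = disp,
                 removed = removed, design = design, coef = colnames(X)[coef],
                 lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 classify_on = classify_on,
                 notes = c("no empirical-Bayes dispersion shrinkage",
                           "no outlier handling", "no independent filtering")),
            class = "mirna_de")
}

#' @export
print.mirna_de <- function(x, ...) {
  r <- x$results
  cat("Negative binomial differential expression (Wald test)\n")
  cat("  design: ", deparse(x$design), "   coefficient: ", x$coef, "\n", sep = "")
  cat("  features tested: ", nrow(r), " (", length(x$removed),
      " removed by variance filter)\n", sep = "")
  cat("  classified: ", sum(r$change == "up"), " up, ", sum(r$change == "down"),
      " down (|log2FC| > ", x$lfc_threshold, ", ", x$classify_on, " < ",
      x$p_threshold, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.mirna_de <- function(object, n = 10L, ...) {
  print(object)
  r <- object$results[order(object$results$p_unadj), ]
  cat("\nTop features by unadjusted p-value:\n")
  print(utils::head(r[, c("mirna", "base_mean", "log2fc", "p_unadj", "p_adj", "change")], n),
        digits = 3, row.names = FALSE)
  invisible(object)
}

#' @export
coef.mirna_de <- function(object, ...) {
  setNames(object$results$log2fc, object$results$mirna)
}

#' @export
as.data.frame.mirna_de <- function(x, ...) x$results

#' Volcano plot / plot-ready volcano table
#'
#' `volcano_table()` returns the columns a volcano plot needs (`log2fc`,
#' `neg_log10_p` from the unadjusted p-value, `change`); the `plot` method
#' draws it with base graphics.
#'
#' @param fit a [mirna_de()] object.
#' @return data.frame with `mirna`, `log2fc`, `neg_log10_p`, `change`.
#' @export
volcano_table <- function(fit) {
  stopifnot(inherits(fit, "mirna_de"))
  r <- fit$results
  data.frame(mirna = r$mirna, log2fc = r$log2fc,
             neg_log10_p = -log10(r$p_unadj), change = r$change,
             stringsAsFactors = FALSE)
}

#' @export
plot.mirna_de <- function(x, ...) {
  v <- volcano_table(x)
  col <- c(no = "grey60", up = "firebrick", down = "steelblue")[v$change]
  graphics::plot(v$log2fc, v$neg_log10_p, col = col, pch = 16,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ italic(p)), ...)
  graphics::abline(v = c(-x$lfc_threshold, x$lfc_threshold), lty = 2, col = "grey40")
  graphics::abline(h = -log10(x$p_threshold), lty = 2, col = "grey40")
  invisible(v)
}

#' Post-hoc power of a two-sided independent-samples t-test
#'
#' Power for detecting a standardised effect size `d` with group sizes `n1`
#' and `n2` at two-sided level `alpha`, via the noncentral t distribution:
#' `df = n1 + n2 - 2`, noncentrality `d * sqrt(n1 n2 / (n1 + n2))`, power
#' `P(T' > t*) + P(T' < -t*)` with `t*` the upper `alpha/2` central-t
#' quantile.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d Cohen's d effect size (>= 0).
#' @param alpha two-sided significance level.
#' @return the power (scalar in `[0, 1]`).
#' @export
#' @examples
#' power_two_sample_t(6, 9, 0.8)  # ~0.29
power_two_sample_t <- function(n1, n2, d, alpha = 0.05) {
  .chk_num(n1, "n1", 2); .chk_num(n2, "n2", 2)
  .chk_num(d, "d", 0); .chk_num(alpha, "alpha", 1e-12, 1 - 1e-12)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp = ncp)
}
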