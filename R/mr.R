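#' Select MR instruments from summary statistics
#'
#' Filters variants at `p < p_thresh` and thins them to one per region by the
#' same greedy strongest-first distance merge used for locus definition, with
#' a wide window (default 5 Mb) standing in for LD-based clumping.
#'
#' @param summary Lead-SNP style `data.frame` with `chr`, `bp`, `p`.
#' @param p_thresh Inclusion threshold; default 1e-6.
#' @param window_kb Clumping radius in kb; default 5000.
#' @return The selected instrument rows (locus leads).
#' @export
select_instruments <- function(summary, p_thresh = 1e-6, window_kb = 5000) {
  summary <- validate_lead_snps(summary)
  if (is.null(summary$p)) stop("p-values are required for instrument selection")
  kept <- summary[summary$p < p_thresh, , drop = FALSE]
  if (nrow(kept) == 0)
    stop("no instruments: no variant passes p < ", format(p_thresh))
  merge_loci(kept, window_kb = window_kb)$leads
}

is_palindromic <- function(ea, oa) {
  flip <- c(A = "T", T = "A", C = "G", G = "C")
  toupper(ea) %in% names(flip) & toupper(oa) == flip[toupper(ea)]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants between the two tables (by `rsid`, falling back on
#' `chr:bp`), removes palindromic (A/T, C/G) variants whose strand cannot be
#' resolved, flips the outcome effect (and its alleles) when the outcome's
#' allele labels are swapped relative to the exposure, and drops variants
#' whose allele pairs cannot be reconciled (with a warning).
#'
#' @param exposure,outcome Lead-SNP style `data.frame`s with `ea`, `oa`,
#'   `beta`, `se` columns.
#' @return An object of class `mr_instruments`: a `data.frame` with one row
#'   per harmonized variant (`beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `ea`, `oa`, ...).
#' @export
harmonize <- function(exposure, outcome) {
  key <- function(t) {
    k <- t$rsid
    if (is.null(k)) k <- rep(NA_character_, nrow(t))
    miss <- is.na(k)
    k[miss] <- paste0(t$chr[miss], ":", t$bp[miss])
    k
  }
  ke <- key(exposure); ko <- key(outcome)
  m <- match(ke, ko)
  keep <- !is.na(m)
  if (!any(keep)) stop("no overlapping variants between exposure and outcome")
  e <- exposure[keep, , drop = FALSE]
  o <- outcome[m[keep], , drop = FALSE]

  pal <- is_palindromic(e$ea, e$oa)
  e <- e[!pal, , drop = FALSE]; o <- o[!pal, , drop = FALSE]
  if (nrow(e) == 0) stop("all overlapping variants are palindromic")

  same <- toupper(o$ea) == toupper(e$ea) & toupper(o$oa) == toupper(e$oa)
  swapped <- toupper(o$ea) == toupper(e$oa) & toupper(o$oa) == toupper(e$ea)
  bad <- !(same | swapped)
  if (any(bad))
    warning(sum(bad), " variant(s) dropped: allele pairs cannot be reconciled")
  e <- e[!bad, , drop = FALSE]
  o <- o[!bad, , drop = FALSE]
  swapped <- swapped[!bad]
  beta_out <- ifelse(swapped, -o$beta, o$beta)
  eaf_out <- if (!is.null(o$eaf)) ifelse(swapped, 1 - o$eaf, o$eaf) else NA
  out <- data.frame(
    rsid = if (!is.null(e$rsid)) e$rsid else paste0(e$chr, ":", e$bp),
    chr = e$chr, bp = e$bp, ea = e$ea, oa = e$oa,
    eaf_exposure = if (!is.null(e$eaf)) e$eaf else NA,
    eaf_outcome = eaf_out,
    beta_exposure = e$beta, se_exposure = e$se,
    beta_outcome = beta_out, se_outcome = o$se,
    stringsAsFactors = FALSE)
  if (any(out$se_exposure <= 0) || any(out$se_outcome <= 0))
    stop("standard errors must be positive")
  class(out) <- c("mr_instruments", "data.frame")
  out
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat("<mr_instruments>", nrow(x), "harmonized variants\n")
  print.data.frame(utils::head(x, 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

mr_result <- function(method, estimate, se, p, n, intercept = NULL,
                      intercept_se = NULL, intercept_p = NULL,
                      Q = NULL, Q_p = NULL) {
  z <- stats::qnorm(0.975)
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = estimate - z * se, ci_high = estimate + z * se,
                 p_value = p, n_instruments = n,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_p = intercept_p, Q = Q, Q_p = Q_p),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (SE %.4f, 95%% CI %.4f to %.4f), p = %.3g, k = %d\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high,
              x$p_value, x$n_instruments))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  if (!is.null(x$Q))
    cat(sprintf("  Cochran Q = %.3f (df %d), p = %.3g\n",
                x$Q, x$n_instruments - 1, x$Q_p))
  invisible(x)
}

check_instruments <- function(set, min_k, caller) {
  stopifnot(inherits(set, "mr_instruments") || is.data.frame(set))
  k <- nrow(set)
  if (k < min_k)
    stop(caller, " requires at least ", min_k, " instruments (got ", k, ")",
         if (min_k == 2) "; use a Wald ratio for a single instrument")
  invisible(k)
}

#' Inverse-variance weighted MR estimate
#'
#' The IVW estimate `sum(bx by / sy^2) / sum(bx^2 / sy^2)`, equivalent to the
#' weighted regression of outcome on exposure effects through the origin. By
#' default the standard error uses multiplicative random effects: the
#' fixed-effect SE is scaled by `max(1, sqrt(Q / (k - 1)))`.
#'
#' @param set An [harmonize()]d `mr_instruments` set (k >= 2).
#' @param random_effects Use multiplicative random-effects scaling (default).
#' @return An `mr_result` with the estimate, Cochran Q and normal-theory CI/p.
#' @export
mr_ivw <- function(set, random_effects = TRUE) {
  k <- check_instruments(set, 2, "mr_ivw")
  bx <- set$beta_exposure; by <- set$beta_outcome; sy <- set$se_outcome
  w <- bx^2 / sy^2
  est <- sum(bx * by / sy^2) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  ratio <- by / bx
  Q <- sum(w * (ratio - est)^2)
  phi <- if (random_effects) max(1, Q / (k - 1)) else 1
  se <- se_fixed * sqrt(phi)
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_result(if (random_effects) "IVW (multiplicative random effects)"
            else "IVW (fixed effects)",
            est, se, p, k,
            Q = Q, Q_p = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' an intercept (weights `1 / se_outcome^2`), after orienting every
#' instrument so its exposure effect is non-negative. The slope is the causal
#' estimate; the intercept estimates directional pleiotropy. Residual
#' overdispersion is floored at 1 (multiplicative random effects). With
#' `n_boot > 0`, standard errors come from resampling instruments.
#'
#' @param set An `mr_instruments` set (k >= 3).
#' @param n_boot Bootstrap draws (0 = analytic SEs).
#' @param seed Seed for the bootstrap.
#' @return An `mr_result` including intercept fields.
#' @export
mr_egger <- function(set, n_boot = 0, seed = NULL) {
  k <- check_instruments(set, 3, "mr_egger")
  s <- ifelse(set$beta_exposure < 0, -1, 1)
  bx <- s * set$beta_exposure; by <- s * set$beta_outcome
  sy <- set$se_outcome
  fit <- egger_wls(bx, by, sy)
  if (n_boot > 0) {
    boots <- withr::with_seed(if (is.null(seed)) 1L else as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(k, k, replace = TRUE)
        if (length(unique(bx[idx])) < 2) return(c(NA_real_, NA_real_))
        f <- egger_wls(bx[idx], by[idx], sy[idx])
        c(f$slope, f$intercept)
      }, numeric(2))
    })
    se_slope <- stats::sd(boots[1, ], na.rm = TRUE)
    se_int <- stats::sd(boots[2, ], na.rm = TRUE)
    method <- "MR-Egger (bootstrap)"
  } else {
    se_slope <- fit$se_slope
    se_int <- fit$se_intercept
    method <- "MR-Egger"
  }
  mr_result(method, fit$slope, se_slope,
            2 * stats::pnorm(-abs(fit$slope / se_slope)), k,
            intercept = fit$intercept, intercept_se = se_int,
            intercept_p = 2 * stats::pnorm(-abs(fit$intercept / se_int)))
}

# weighted least squares with intercept; dispersion floored at 1
egger_wls <- function(bx, by, sy) {
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * by)
  beta <- solve(XtWX, XtWy)
  res <- by - X %*% beta
  k <- length(bx)
  sigma2 <- max(1, sum(w * res^2) / (k - 2))
  covb <- sigma2 * solve(XtWX)
  list(intercept = beta[1], slope = beta[2],
       se_intercept = sqrt(covb[1, 1]), se_slope = sqrt(covb[2, 2]))
}

# weighted median of x with weights w (Bowden 2016 interpolation)
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  pk <- (cumsum(w) - w / 2) / sum(w)
  if (pk[1] >= 0.5) return(x[1])
  if (pk[length(pk)] <= 0.5) return(x[length(x)])
  below <- max(which(pk < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - pk[below]) / (pk[below + 1] - pk[below])
}

#' Median-based MR estimates
#'
#' Per-variant Wald ratios `beta_outcome / beta_exposure`; the simple median
#' or the weighted median with inverse-variance weights of the ratio
#' (first-order: `var = se_outcome^2 / beta_exposure^2`). Standard errors are
#' obtained by nonparametric bootstrap over instruments.
#'
#' @param set An `mr_instruments` set (k >= 3 after dropping zero exposure
#'   effects, which are removed with a warning).
#' @param weighted Weighted (default) or simple median.
#' @param n_boot Bootstrap draws; default 1000.
#' @param seed Seed for the bootstrap.
#' @return An `mr_result`.
#' @export
mr_median <- function(set, weighted = TRUE, n_boot = 1000, seed = NULL) {
  check_instruments(set, 3, "mr_median")
  zero <- set$beta_exposure == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure effect dropped")
    set <- set[!zero, , drop = FALSE]
  }
  k <- check_instruments(set, 3, "mr_median")
  ratio <- set$beta_outcome / set$beta_exposure
  w <- if (weighted) set$beta_exposure^2 / set$se_outcome^2 else rep(1, k)
  est <- weighted_median(ratio, w)
  boots <- withr::with_seed(if (is.null(seed)) 1L else as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      weighted_median(ratio[idx], w[idx])
    }, numeric(1))
  })
  se <- stats::sd(boots)
  p <- if (se == 0) as.numeric(est == 0) else 2 * stats::pnorm(-abs(est / se))
  if (se == 0 && est != 0) p <- .Machine$double.xmin
  mr_result(if (weighted) "Weighted median" else "Simple median",
            est, se, p, k)
}

#' Cochran Q heterogeneity statistic
#'
#' `Q = sum(w_i (ratio_i - estimate)^2)` over per-variant Wald ratios with
#' first-order inverse-variance weights `w_i = beta_exposure^2 /
#' se_outcome^2`; p from the chi-square distribution with k - 1 df.
#'
#' @param set An `mr_instruments` set (k >= 2).
#' @param estimate Causal estimate to measure heterogeneity around (defaults
#'   to the IVW estimate).
#' @return List with `Q` and `p`.
#' @export
cochran_q <- function(set, estimate = NULL) {
  k <- check_instruments(set, 2, "cochran_q")
  if (is.null(estimate)) estimate <- mr_ivw(set)$estimate
  w <- set$beta_exposure^2 / set$se_outcome^2
  ratio <- set$beta_outcome / set$beta_exposure
  Q <- sum(w * (ratio - estimate)^2)
  list(Q = Q, p = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

#' Run the standard set of MR estimators
#'
#' @param set An `mr_instruments` set.
#' @param n_boot Bootstrap draws for the median estimators.
#' @param seed Seed for bootstraps.
#' @return `data.frame` with one row per method (`method, n_snps, estimate,
#'   se, ci_low, ci_high, p, intercept, intercept_p, Q, Q_p`).
#' @export
mr_report <- function(set, n_boot = 1000, seed = 1) {
  fits <- list(mr_ivw(set),
               mr_egger(set),
               mr_median(set, weighted = FALSE, n_boot = n_boot, seed = seed),
               mr_median(set, weighted = TRUE, n_boot = n_boot, seed = seed))
  do.call(rbind, lapply(fits, function(f) data.frame(
    method = f$method, n_snps = f$n_instruments, estimate = f$estimate,
    se = f$se, ci_low = f$ci_low, ci_high = f$ci_high, p = f$p_value,
    intercept = if (is.null(f$intercept)) NA else f$intercept,
    intercept_p = if (is.null(f$intercept_p)) NA else f$intercept_p,
    Q = if (is.null(f$Q)) NA else f$Q,
    Q_p = if (is.null(f$Q_p)) NA else f$Q_p,
    stringsAsFactors = FALSE)))
}

#' Instrument pleiotropy screen against measured risk factors
#'
#' Regresses each risk factor on each instrument's genotype dosage (plus
#' covariates) by ordinary least squares and flags instruments with any
#' association below the Bonferroni threshold `alpha / (k_snps * n_factors)`,
#' marking them for a leave-out sensitivity rerun.
#'
#' @param dosages n x k matrix of per-variant genotype dosages (0..2).
#' @param risk_factors n x m matrix or data.frame of risk-factor values.
#' @param covariates Optional n x c numeric matrix of covariates.
#' @param alpha Family-wise level; default 0.05.
#' @return List with `p_values` (k x m matrix), `threshold`, and `flagged`
#'   (logical per instrument).
#' @export
pleiotropy_screen <- function(dosages, risk_factors, covariates = NULL,
                              alpha = 0.05) {
  dosages <- as.matrix(dosages)
  risk_factors <- as.matrix(risk_factors)
  stopifnot(nrow(dosages) == nrow(risk_factors))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(dosages))
  }
  k <- ncol(dosages); m <- ncol(risk_factors)
  pv <- matrix(NA_real_, k, m,
               dimnames = list(colnames(dosages), colnames(risk_factors)))
  for (s in seq_len(k)) {
    X <- cbind(dosage = dosages[, s], covariates)
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1)
      stop("rank-deficient design for instrument ", s,
           ": collinear column(s) ",
           paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1],
                 collapse = ", "))
    for (f in seq_len(m)) {
      fit <- stats::lm.fit(cbind(1, X), risk_factors[, f])
      res <- fit$residuals
      df <- length(res) - fit$rank
      sigma2 <- sum(res^2) / df
      R <- qr.R(fit$qr)
      covb <- chol2inv(R) * sigma2
      tstat <- fit$coefficients[2] / sqrt(covb[2, 2])
      pv[s, f] <- 2 * stats::pt(-abs(tstat), df)
    }
  }
  threshold <- alpha / (k * m)
  list(p_values = pv, threshold = threshold,
       flagged = apply(pv < threshold, 1, any))
}
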