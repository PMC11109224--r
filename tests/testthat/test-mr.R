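test_that("select_instruments filters by p and thins by distance", {
  tab <- data.frame(trait = "E", chr = "1", bp = c(1e6, 2e6, 3e6),
                    p = c(1e-9, 1e-8, 1e-7))
  expect_equal(nrow(select_instruments(tab)), 1)
  tab2 <- rbind(tab, data.frame(trait = "E", chr = "2", bp = 1e6, p = 1e-5))
  sel <- select_instruments(tab2)
  expect_false(any(sel$chr == "2"))

  sim <- make_leadsnp_table(n_clusters = 25, snps_per_cluster = 3,
                            intra_span_kb = 50, inter_gap_kb = 11000, seed = 4)
  expect_equal(nrow(select_instruments(sim, p_thresh = 1e-6,
                                       window_kb = 5000)), 25)
  expect_error(select_instruments(transform(tab, p = 0.5)), "no instruments")
})

test_that("harmonize drops palindromes and resolves swapped alleles", {
  exp_tab <- data.frame(trait = "E", chr = "1", bp = c(1, 2, 3, 4) * 1e6,
                        rsid = paste0("rs", 1:4),
                        ea = c("G", "A", "C", "A"), oa = c("A", "T", "T", "G"),
                        eaf = 0.3, beta = c(0.1, 0.2, 0.3, 0.4), se = 0.01,
                        p = 1e-8)
  out_tab <- exp_tab
  out_tab$beta <- c(0.05, 0.1, 0.15, 0.2)
  # rs1: swapped alleles; rs2: palindromic (A/T); rs3: same; rs4: mismatched
  out_tab$ea <- c("A", "A", "C", "A"); out_tab$oa <- c("G", "T", "T", "C")
  expect_warning(h <- harmonize(exp_tab, out_tab), "reconciled")
  expect_equal(h$rsid, c("rs1", "rs3"))
  expect_equal(h$beta_outcome, c(-0.05, 0.15))
  expect_equal(h$beta_exposure, c(0.1, 0.3))

  expect_error(harmonize(exp_tab, transform(out_tab, rsid = paste0("xx", 1:4))),
               "no overlapping")
  all_pal <- transform(exp_tab, ea = "A", oa = "T")
  expect_error(harmonize(all_pal, all_pal), "palindromic")
})

test_that("IVW equals the weighted through-origin regression oracle", {
  mk_set <- function(bx, by, sy) {
    structure(data.frame(beta_exposure = bx, se_exposure = 0.01,
                         beta_outcome = by, se_outcome = sy),
              class = c("mr_instruments", "data.frame"))
  }
  s3 <- mk_set(c(0.10, 0.20, 0.15), c(0.05, 0.11, 0.07),
               c(0.01, 0.02, 0.015))
  oracle <- unname(coef(lm(s3$beta_outcome ~ 0 + s3$beta_exposure,
                           weights = 1 / s3$se_outcome^2)))
  expect_equal(mr_ivw(s3)$estimate, oracle, tolerance = 1e-12)

  # exact on random sets up to 10 instruments
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    s <- mk_set(rnorm(k, 0.1, 0.05), rnorm(k, 0.05, 0.03),
                runif(k, 0.005, 0.05))
    oracle <- unname(coef(lm(s$beta_outcome ~ 0 + s$beta_exposure,
                             weights = 1 / s$se_outcome^2)))
    expect_equal(mr_ivw(s)$estimate, oracle, tolerance = 1e-12)
  }

  # perfectly linear instruments: estimate theta, Q = 0
  lin <- mk_set(c(0.1, 0.2, 0.3), 0.7 * c(0.1, 0.2, 0.3), 0.01)
  fit <- mr_ivw(lin)
  expect_equal(fit$estimate, 0.7, tolerance = 1e-12)
  expect_equal(fit$Q, 0, tolerance = 1e-18)
  expect_error(mr_ivw(lin[1, , drop = FALSE]), "at least 2")

  # sign equivariance
  neg <- mk_set(-lin$beta_exposure, lin$beta_outcome, lin$se_outcome)
  expect_equal(mr_ivw(neg)$estimate, -0.7, tolerance = 1e-12)

  # simulated recovery at theta = log(1.77)
  theta <- log(1.77)
  ests <- vapply(1:300, function(s) {
    d <- make_mr_dataset(k = 50, theta = theta, seed = s)
    mr_ivw(harmonize(d$exposure, d$outcome))$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - theta), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("MR-Egger recovers slope and planted directional pleiotropy", {
  d0 <- make_mr_dataset(k = 80, theta = 0.4, seed = 11)
  set0 <- harmonize(d0$exposure, d0$outcome)
  e0 <- mr_egger(set0)
  expect_lt(abs(e0$intercept), 3 * e0$intercept_se)
  expect_lt(abs(e0$estimate - mr_ivw(set0)$estimate), 3 * e0$se)

  # directional pleiotropy c: the oriented intercept is centred at c while
  # the slope stays at theta
  ints <- slopes <- numeric(60)
  for (s in 1:60) {
    d <- make_mr_dataset(k = 60, theta = 0.4, pleiotropy = "directional",
                         pleio_c = 0.05, seed = 100 + s)
    f <- mr_egger(harmonize(d$exposure, d$outcome))
    ints[s] <- f$intercept; slopes[s] <- f$estimate
  }
  expect_lt(abs(mean(ints) - 0.05), 0.005)
  expect_lt(abs(mean(slopes) - 0.4), 0.05)

  # balanced pleiotropy: intercept centred at zero
  bints <- vapply(1:40, function(s) {
    d <- make_mr_dataset(k = 60, theta = 0.4, pleiotropy = "balanced",
                         pleio_c = 0.05, seed = 300 + s)
    mr_egger(harmonize(d$exposure, d$outcome))$intercept
  }, numeric(1))
  expect_lt(abs(mean(bints)), 3 * sd(bints) / sqrt(length(bints)) + 0.005)

  expect_error(mr_egger(set0[1:2, ]), "at least 3")

  # bootstrap SEs in the same ballpark as analytic ones
  eb <- mr_egger(set0, n_boot = 200, seed = 3)
  expect_equal(eb$estimate, e0$estimate)
  expect_lt(abs(log(eb$se / e0$se)), log(2.5))
})

test_that("median estimators are robust and match the weighted-median oracle", {
  mk_set <- function(bx, by, sy) {
    structure(data.frame(beta_exposure = bx, se_exposure = 0.01,
                         beta_outcome = by, se_outcome = sy),
              class = c("mr_instruments", "data.frame"))
  }
  # all ratios identical: estimate theta with zero bootstrap spread
  same <- mk_set(c(0.1, 0.2, 0.4), 0.9 * c(0.1, 0.2, 0.4), 0.01)
  f <- mr_median(same, weighted = FALSE, n_boot = 50, seed = 1)
  expect_equal(f$estimate, 0.9, tolerance = 1e-12)
  expect_equal(f$se, 0)

  # outlier robustness: ratios (1,1,1,1,9) -> median 1
  out5 <- mk_set(rep(0.1, 5), c(0.1, 0.1, 0.1, 0.1, 0.9), 0.01)
  expect_equal(mr_median(out5, weighted = FALSE, n_boot = 10, seed = 1)$estimate, 1)

  # dominant-weight instrument pins the (interpolated) weighted median
  dom <- mk_set(c(1, 0.02, 0.02), c(2, 0.001, 0.0006), c(0.01, 0.01, 0.01))
  w <- dom$beta_exposure^2 / dom$se_outcome^2
  expect_gt(w[1] / sum(w), 0.5)
  expect_equal(mr_median(dom, weighted = TRUE, n_boot = 10, seed = 1)$estimate,
               2, tolerance = 0.01)

  # brute-force oracle for the weighted median on random sets
  oracle_wmedian <- function(x, w) {
    ord <- order(x); x <- x[ord]; w <- w[ord]
    pk <- (cumsum(w) - w / 2) / sum(w)
    if (any(pk == 0.5)) return(x[which(pk == 0.5)])
    lo2 <- suppressWarnings(max(x[pk < 0.5]))
    hi2 <- min(x[pk > 0.5])
    if (!is.finite(lo2)) return(x[1])
    plo <- pk[x == lo2][1]; phi <- pk[x == hi2][1]
    lo2 + (hi2 - lo2) * (0.5 - plo) / (phi - plo)
  }
  set.seed(77)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    x <- rnorm(k); w <- runif(k, 0.1, 2)
    s <- mk_set(rep(1, k), x, sqrt(1 / w))
    expect_equal(mr_median(s, weighted = TRUE, n_boot = 5, seed = 1)$estimate,
                 oracle_wmedian(x, w), tolerance = 1e-10)
  }

  zero <- mk_set(c(0, 0.1, 0.2, 0.3), c(0, 0.05, 0.1, 0.15), 0.01)
  expect_warning(fz <- mr_median(zero, n_boot = 10, seed = 1), "zero exposure")
  expect_equal(fz$n_instruments, 3)
})

test_that("Cochran Q is zero for homogeneous ratios and matches hand computation", {
  mk_set <- function(bx, by, sy) {
    structure(data.frame(beta_exposure = bx, se_exposure = 0.01,
                         beta_outcome = by, se_outcome = sy),
              class = c("mr_instruments", "data.frame"))
  }
  hom <- mk_set(c(0.1, 0.2), c(0.05, 0.10), 0.01)
  q <- cochran_q(hom)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)

  # k = 2 closed form: with w_i = bx_i^2/sy_i^2, ratios r_i
  s2 <- mk_set(c(0.1, 0.2), c(0.08, 0.1), c(0.01, 0.02))
  w <- c(0.1, 0.2)^2 / c(0.01, 0.02)^2
  r <- c(0.8, 0.5)
  est <- sum(w * r) / sum(w)
  expect_equal(cochran_q(s2)$Q, sum(w * (r - est)^2), tolerance = 1e-12)

  # homogeneous simulation: E[Q/(k-1)] ~ 1
  qs <- vapply(1:200, function(s) {
    d <- make_mr_dataset(k = 20, theta = 0.3, seed = 400 + s)
    st <- harmonize(d$exposure, d$outcome)
    cochran_q(st)$Q / (nrow(st) - 1)
  }, numeric(1))
  expect_equal(mean(qs), 1, tolerance = 0.1)
})

test_that("pleiotropy screen applies the Bonferroni rule and finds planted signals", {
  set.seed(13)
  n <- 400; k <- 19
  dos <- matrix(rbinom(n * k, 2, 0.3), n, k)
  fac <- matrix(rnorm(n * 7), n, 7)
  scr <- pleiotropy_screen(dos, fac)
  expect_equal(signif(scr$threshold, 2), 3.8e-4)
  expect_equal(dim(scr$p_values), c(19, 7))

  # planted signal is flagged
  fac2 <- fac
  fac2[, 3] <- 10 * dos[, 5] + rnorm(n)
  scr2 <- pleiotropy_screen(dos, fac2)
  expect_true(scr2$flagged[5])
  expect_lt(scr2$p_values[5, 3], scr2$threshold)

  # null flag rate is at the family-wise level, roughly
  flags <- vapply(1:60, function(s) {
    set.seed(2000 + s)
    d <- matrix(rbinom(150 * 5, 2, 0.4), 150, 5)
    f <- matrix(rnorm(150 * 7), 150, 7)
    any(pleiotropy_screen(d, f)$flagged)
  }, logical(1))
  expect_lt(mean(flags), 0.25)

  # covariates and collinearity
  cov1 <- cbind(age = rnorm(n))
  expect_silent(pleiotropy_screen(dos, fac, covariates = cov1))
  bad <- cbind(a = dos[, 1], b = 2 * dos[, 1])
  expect_error(pleiotropy_screen(dos, fac, covariates = bad),
               "rank-deficient")
})
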