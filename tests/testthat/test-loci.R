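test_that("merge_loci reproduces the published per-trait locus counts", {
  tab <- la_lead_snps()
  expect_equal(nrow(tab), 42)
  expect_length(merge_loci(tab[tab$trait == "LAmax", ]), 5)
  expect_length(merge_loci(tab[tab$trait == "LAmin", ]), 8)
  expect_length(merge_loci(tab[tab$trait == "LAEF", ]), 4)
  expect_length(merge_loci(tab[tab$trait == "LASV", ]), 2)

  two <- data.frame(trait = "T", chr = "1", bp = c(1e6, 1.1e6),
                    p = c(1e-9, 1e-8))
  ls2 <- merge_loci(two)
  expect_length(ls2, 1)
  expect_equal(ls2$leads$p, 1e-9)

  expect_error(merge_loci(data.frame(trait = "T", chr = "1", bp = 1e6)),
               "p-values")
  no_p <- merge_loci(data.frame(trait = "T", chr = "1", bp = c(1e6, 5e6)),
                     require_p = FALSE)
  expect_length(no_p, 2)
})

test_that("merge_loci is order-invariant and partitions the input", {
  tab <- la_lead_snps()
  ref <- merge_loci(tab)
  key <- function(ls) paste(ls$leads$chr, ls$leads$bp, sep = ":")
  set.seed(42)
  for (i in 1:100) {
    sh <- merge_loci(tab[sample(nrow(tab)), ])
    expect_identical(sort(key(sh)), sort(key(ref)))
  }
  # every SNP in exactly one locus; lead p is the member minimum
  n_assigned <- sum(vapply(ref$members, nrow, 1L))
  expect_equal(n_assigned, nrow(tab))
  for (i in seq_along(ref$members))
    expect_equal(min(ref$members[[i]]$p), ref$leads$p[i])
})

test_that("distinct_loci_across_traits pools and deduplicates", {
  tab <- la_lead_snps()
  pooled <- distinct_loci_across_traits(split(tab, tab$trait))
  expect_length(pooled, 20)
  one <- distinct_loci_across_traits(tab[tab$trait == "LAmax", ])
  expect_length(one, 5)
  dup <- distinct_loci_across_traits(list(tab[tab$trait == "LAEF", ],
                                          tab[tab$trait == "LAEF", ]))
  expect_length(dup, 4)
})

test_that("shared_loci matches the published shared and indexed-only counts", {
  tab <- la_lead_snps()
  lamax <- merge_loci(tab[tab$trait == "LAmax", ])
  lamin <- merge_loci(tab[tab$trait == "LAmin", ])
  expect_equal(nrow(shared_loci(lamax, lamin)), 4)

  # disjoint chromosomes share nothing
  a <- merge_loci(data.frame(trait = "A", chr = "1", bp = 1e6, p = 1e-9))
  b <- merge_loci(data.frame(trait = "B", chr = "2", bp = 1e6, p = 1e-9))
  expect_equal(nrow(shared_loci(a, b)), 0)

  # indexed LAmax/LAmin shared loci away from every unindexed locus: 3
  imax <- merge_loci(tab[tab$trait == "LAmax_indexed", ])
  imin <- merge_loci(tab[tab$trait == "LAmin_indexed", ])
  sh <- shared_loci(imax, imin)
  unidx <- merge_loci(tab[tab$trait %in% c("LAmax", "LAmin", "LAEF", "LASV"), ])
  away <- vapply(seq_len(nrow(sh)), function(i) {
    !any(unidx$leads$chr == sh$chr[i] &
           abs(unidx$leads$bp - sh$bp_a[i]) <= 5e5)
  }, logical(1))
  expect_equal(sum(away), 3)
})

test_that("overlap_count honours the inclusive window", {
  ls <- merge_loci(data.frame(trait = "T", chr = c("1", "2"),
                              bp = c(1e6, 2e6), p = c(1e-9, 1e-9)))
  expect_equal(overlap_count(ls, data.frame(chr = character(0),
                                            bp = numeric(0))), 0L)
  expect_equal(overlap_count(ls, data.frame(chr = "1", bp = 1e6 + 5e5)), 1L)
  expect_equal(overlap_count(ls, data.frame(chr = "1", bp = 1e6 + 5e5 + 1)), 0L)

  sim <- make_leadsnp_table(n_clusters = 10, seed = 2)
  lsim <- merge_loci(sim)
  planted <- lsim$leads[1:3, c("chr", "bp")]
  planted$bp <- planted$bp + 1000
  expect_equal(overlap_count(lsim, planted), 3L)
  expect_lte(overlap_count(lsim, planted), length(lsim))
})

test_that("permutation_test uses the add-one rule and detects enrichment", {
  sim <- make_leadsnp_table(n_clusters = 12, seed = 5)
  ls <- merge_loci(sim)
  reference <- ls$leads[, c("chr", "bp")]
  # identity provider: every null set equals the observed leads -> p = 1
  ident <- function(i) ls$leads[, c("chr", "bp")]
  res <- permutation_test(ls, reference, ident, n_sets = 50)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed_overlap, 12L)

  # observed zero -> p = 1
  farref <- data.frame(chr = "21", bp = 2.3e8)
  res0 <- permutation_test(ls, farref, ident, n_sets = 20)
  expect_equal(res0$observed_overlap,
               overlap_count(ls, farref))
  expect_equal(res0$p_value, 1)

  # provider returning the wrong size errors
  expect_error(permutation_test(ls, reference, function(i) ls$leads[1:3, ],
                                n_sets = 5), "size")
})

test_that("permutation p-values follow the exchangeable null distribution", {
  # panel SNPs; the observed set is itself a uniform draw, so its overlap is
  # exchangeable with the null overlaps and p follows the rank distribution
  # of one draw among n_sets + 1 iid overlap counts (here hypergeometric,
  # since sets are sampled without replacement from the panel)
  panel <- data.frame(chr = as.character(rep(1:22, each = 40)),
                      bp = rep(seq(1e6, by = 4e6, length.out = 40), 22))
  ref_rows <- seq(1, nrow(panel), by = 5)
  reference <- panel[ref_rows, ]
  reference$bp <- reference$bp + 100
  n_runs <- 150; n_sets <- 39; size <- 15
  pvals <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    prov <- uniform_null_provider(panel, size = size, seed = 1000 + r)
    leads <- prov(0)
    ls <- merge_loci(transform(leads, trait = "T", p = 1e-9), window_kb = 1)
    pvals[r] <- permutation_test(ls, reference, prov, n_sets = n_sets)$p_value
  }
  # independent oracle for the null p distribution: rank of one
  # Hypergeometric(panel, reference, size) count among n_sets iid others
  set.seed(99)
  m <- length(ref_rows); nn <- nrow(panel) - m
  oracle <- vapply(seq_len(4000), function(i) {
    counts <- stats::rhyper(n_sets + 1, m, nn, size)
    (1 + sum(counts[-1] >= counts[1])) / (1 + n_sets)
  }, numeric(1))
  expect_lt(abs(mean(pvals) - mean(oracle)), 4 * sd(oracle) / sqrt(n_runs))
  expect_gt(suppressWarnings(ks.test(pvals, oracle)$p.value), 0.001)
})

test_that("hwe_exact_p agrees with full enumeration and flags extremes", {
  expect_equal(hwe_exact_p(57, 0, 0), 1)
  expect_equal(hwe_exact_p(1, 3, 1), oracle_hwe(1, 3, 1), tolerance = 1e-12)
  expect_lt(hwe_exact_p(0, 100, 0), 1e-6)
  expect_error(hwe_exact_p(-1, 2, 3), ">= 0")

  set.seed(9)
  for (i in 1:40) {
    n <- sample(3:66, 1)
    a <- sample(0:n, 1); rest <- n - a
    h <- sample(0:rest, 1); b <- rest - h
    expect_equal(hwe_exact_p(a, h, b), oracle_hwe(a, h, b),
                 tolerance = 1e-12,
                 info = paste(a, h, b))
  }
})
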