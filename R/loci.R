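#' Read a GWAS lead-SNP table
#'
#' Expected tab-separated columns: `trait, chr, bp, rsid, ea, oa, eaf, beta,
#' se, p` (extra columns are kept; `rsid`, `eaf`, `beta`, `se` may be NA).
#'
#' @param path Path to a TSV file.
#' @return A validated `data.frame` of lead SNPs.
#' @export
read_lead_snps <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validate_lead_snps(tab)
}

validate_lead_snps <- function(tab) {
  need <- c("trait", "chr", "bp")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("lead-SNP table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) stop("lead-SNP table is empty")
  tab$chr <- as.character(tab$chr)
  tab$bp <- as.numeric(tab$bp)
  if (any(tab$bp <= 0)) stop("bp positions must be positive")
  if (!is.null(tab$eaf) && any(!is.na(tab$eaf) & (tab$eaf <= 0 | tab$eaf >= 1)))
    stop("eaf must lie strictly between 0 and 1")
  if (!is.null(tab$se) && any(!is.na(tab$se) & tab$se <= 0))
    stop("se must be positive")
  tab
}

#' Lead SNPs for the left atrial traits (packaged fixture)
#'
#' The GWAS lead-SNP table for the seven LA traits (LAmax, LAmin, LAEF, LASV
#' and the BSA-indexed volumes), 42 rows, GRCh37 positions.
#'
#' @return A `data.frame` with columns `trait, chr, bp, rsid, ea, oa, eaf,
#'   beta, se, p, nearest_gene`.
#' @export
la_lead_snps <- function() {
  read_lead_snps(system.file("extdata", "la_lead_snps.tsv",
                             package = "atriumkit", mustWork = TRUE))
}

#' Define distinct genomic loci by greedy strongest-first merging
#'
#' Starting with the SNP with the smallest P value, all other SNPs within
#' `window_kb` on the same chromosome are assigned to its locus; the
#' procedure iterates over the remaining SNPs until none are left. "Within"
#' is inclusive: `|delta bp| <= window_kb * 1000`. Ties in P are broken by
#' (chr, bp) so the result is deterministic and independent of row order.
#'
#' @param snps Lead-SNP `data.frame` (needs `chr`, `bp` and, unless
#'   `require_p = FALSE`, `p`).
#' @param window_kb Merging window in kb; default 500.
#' @param require_p If FALSE and `p` is missing, input order is used instead.
#' @return An object of class `locus_set`: `leads` (one row per locus, in
#'   selection order), `members` (list of member-row data.frames) and
#'   `window_kb`.
#' @export
merge_loci <- function(snps, window_kb = 500, require_p = TRUE) {
  snps <- validate_lead_snps(snps)
  if (is.null(snps$p) || anyNA(snps$p)) {
    if (require_p) stop("p-values are required (set require_p = FALSE to order by input)")
    snps$p <- seq_len(nrow(snps))
  }
  window_bp <- window_kb * 1000
  ord <- order(snps$p, snps$chr, snps$bp)
  remaining <- rep(TRUE, nrow(snps))
  lead_rows <- integer(0)
  members <- list()
  for (i in ord) {
    if (!remaining[i]) next
    in_window <- remaining & snps$chr == snps$chr[i] &
      abs(snps$bp - snps$bp[i]) <= window_bp
    lead_rows <- c(lead_rows, i)
    members[[length(members) + 1]] <- snps[which(in_window), , drop = FALSE]
    remaining[in_window] <- FALSE
  }
  structure(list(leads = snps[lead_rows, , drop = FALSE],
                 members = members, window_kb = window_kb),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("<locus_set>", nrow(x$leads), "loci (window",
      x$window_kb, "kb)\n")
  lab <- paste0("chr", x$leads$chr, ":", format(x$leads$bp, big.mark = ","))
  n_mem <- vapply(x$members, nrow, integer(1))
  for (i in seq_along(lab))
    cat(sprintf("  %s  lead p=%.2g  members=%d\n",
                lab[i], x$leads$p[i], n_mem[i]))
  invisible(x)
}

#' Number of loci in a locus set
#' @param x A `locus_set`.
#' @param ... Unused.
#' @export
length.locus_set <- function(x) nrow(x$leads)

#' Distinct loci across several trait tables
#'
#' Pools the rows of all tables and applies [merge_loci()] to the pooled set,
#' so a locus reached by several traits is counted once.
#'
#' @param tables List of lead-SNP `data.frame`s (or a single one).
#' @param window_kb Merging window in kb.
#' @return A `locus_set`.
#' @export
distinct_loci_across_traits <- function(tables, window_kb = 500) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  common <- Reduce(intersect, lapply(tables, names))
  pooled <- do.call(rbind, lapply(tables, function(t) t[common]))
  merge_loci(pooled, window_kb = window_kb)
}

#' Loci shared between two locus sets
#'
#' Pairs of loci whose lead SNPs are within `window_kb` on the same
#' chromosome; each lead is used at most once, pairs taken greedily by
#' increasing distance.
#'
#' @param a,b `locus_set` objects on the same genome build.
#' @param window_kb Matching window in kb.
#' @return `data.frame` of pairs with columns `chr`, `bp_a`, `bp_b`,
#'   `dist_bp` (zero rows when nothing is shared).
#' @export
shared_loci <- function(a, b, window_kb = 500) {
  stopifnot(inherits(a, "locus_set"), inherits(b, "locus_set"))
  window_bp <- window_kb * 1000
  cand <- NULL
  for (i in seq_len(nrow(a$leads))) {
    same <- which(b$leads$chr == a$leads$chr[i] &
                  abs(b$leads$bp - a$leads$bp[i]) <= window_bp)
    if (length(same) > 0)
      cand <- rbind(cand, data.frame(
        i = i, j = same, chr = a$leads$chr[i],
        bp_a = a$leads$bp[i], bp_b = b$leads$bp[same],
        dist_bp = abs(b$leads$bp[same] - a$leads$bp[i])))
  }
  empty <- data.frame(chr = character(0), bp_a = numeric(0),
                      bp_b = numeric(0), dist_bp = numeric(0))
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$dist_bp), , drop = FALSE]
  used_i <- logical(nrow(a$leads)); used_j <- logical(nrow(b$leads))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_i[cand$i[k]] && !used_j[cand$j[k]]) {
      keep[k] <- TRUE
      used_i[cand$i[k]] <- TRUE
      used_j[cand$j[k]] <- TRUE
    }
  }
  out <- cand[keep, c("chr", "bp_a", "bp_b", "dist_bp"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# count of leads (data.frame with chr, bp) having >= 1 reference SNP in window
count_leads_overlapping <- function(leads, reference, window_bp) {
  vapply(seq_len(nrow(leads)), function(i) {
    any(reference$chr == leads$chr[i] &
        abs(reference$bp - leads$bp[i]) <= window_bp)
  }, logical(1))
}

#' Count loci overlapping a reference lead-SNP list
#'
#' A locus counts once when at least one reference lead SNP lies within
#' `window_kb` (inclusive) of its lead SNP on the same chromosome.
#'
#' @param la A `locus_set`.
#' @param reference_leads Reference lead-SNP `data.frame` (`chr`, `bp`).
#' @param window_kb Window in kb; default 500.
#' @return Integer overlap count (<= number of loci).
#' @export
overlap_count <- function(la, reference_leads, window_kb = 500) {
  stopifnot(inherits(la, "locus_set"))
  if (nrow(reference_leads) == 0) return(0L)
  reference_leads$chr <- as.character(reference_leads$chr)
  sum(count_leads_overlapping(la$leads, reference_leads, window_kb * 1000))
}

#' Uniform null-set provider over a SNP panel
#'
#' Returns a provider function for [permutation_test()]: call `i` yields the
#' `i`-th null set, a uniform without-replacement sample of `size` SNPs from
#' the panel, deterministically seeded from `seed` and `i`.
#'
#' @param panel `data.frame` with `chr`, `bp` columns to sample from.
#' @param size Number of SNPs per null set.
#' @param seed Integer seed.
#' @return Function `f(i)` returning a `data.frame` of `size` rows.
#' @export
uniform_null_provider <- function(panel, size, seed = 1) {
  panel$chr <- as.character(panel$chr)
  if (nrow(panel) < size) stop("panel smaller than requested set size")
  force(seed)
  function(i) {
    rows <- withr::with_seed(as.integer((seed + 104729 * i) %% .Machine$integer.max),
                             sample.int(nrow(panel), size))
    panel[rows, , drop = FALSE]
  }
}

#' Permutation enrichment test of locus overlap
#'
#' The observed overlap of the LA loci with the reference lead list is
#' compared to the overlaps of `n_sets` matched null SNP sets (each the size
#' of the LA lead list) drawn from the provider. The one-tailed p-value uses
#' the add-one rule `p = (1 + #\{null >= observed\}) / (1 + n_sets)`, whose
#' attainable minimum with 10,000 sets is ~1E-04.
#'
#' @param la A `locus_set`.
#' @param reference_leads Reference lead-SNP `data.frame`.
#' @param null_set_provider Function `f(i)` returning the `i`-th null lead
#'   set as a `data.frame` with `chr`, `bp` and exactly as many rows as `la`
#'   has loci (see [uniform_null_provider()]).
#' @param n_sets Number of null sets; default 10000.
#' @param window_kb Window in kb; default 500.
#' @return An object of class `permutation_result` with fields
#'   `observed_overlap`, `null_counts` and `p_value`.
#' @export
permutation_test <- function(la, reference_leads, null_set_provider,
                             n_sets = 10000, window_kb = 500) {
  stopifnot(inherits(la, "locus_set"), is.function(null_set_provider))
  observed <- overlap_count(la, reference_leads, window_kb)
  window_bp <- window_kb * 1000
  n_leads <- nrow(la$leads)
  reference_leads$chr <- as.character(reference_leads$chr)
  null_counts <- integer(n_sets)
  for (i in seq_len(n_sets)) {
    nulls <- null_set_provider(i)
    if (is.null(nulls) || nrow(nulls) != n_leads)
      stop("null provider returned a set of size ",
           if (is.null(nulls)) 0 else nrow(nulls),
           " at draw ", i, " (expected ", n_leads, ")")
    nulls$chr <- as.character(nulls$chr)
    null_counts[i] <- sum(count_leads_overlapping(nulls, reference_leads,
                                                  window_bp))
  }
  p <- (1 + sum(null_counts >= observed)) / (1 + n_sets)
  structure(list(observed_overlap = observed, null_counts = null_counts,
                 p_value = p, n_sets = n_sets),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation overlap test: observed %d, null mean %.2f, p = %.3g (%d sets)\n",
              x$observed_overlap, mean(x$null_counts), x$p_value, x$n_sets))
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the exact distribution of the
#' heterozygote count is enumerated (probabilities computed by the stable
#' recurrence); the two-sided p-value sums the probabilities of all
#' heterozygote counts no more likely than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (>= 0, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be >= 0")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("total genotype count must be positive")
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalised log-probabilities by recurrence from the smallest het count
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k]
    # P(h) / P(h-2) = 4 * hom_rare(h-2) * hom_common(h-2) / (h * (h-1)),
    # with hom_rare = (rare - h)/2 and hom_common = n - h - hom_rare
    hom_r_prev <- (rare - (h - 2)) / 2
    hom_c_prev <- n - (h - 2) - hom_r_prev
    logp[k] <- logp[k - 1] + log(4 * hom_r_prev * hom_c_prev) -
      log(h) - log(h - 1)
  }
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- which(hets == n_het)
  if (length(obs) == 0)
    stop("observed heterozygote count has the wrong parity for the allele counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}
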