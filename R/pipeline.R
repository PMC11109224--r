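#' Validate a run configuration
#'
#' Fills defaults for the reconstruction and genetics parameters and checks
#' referenced paths. All randomness in a run flows through the named seeds
#' recorded in the output manifest.
#'
#' @param input_paths Character vector of paths that must exist (may be empty).
#' @param grid_res,smoothing_sigma,padding Reconstruction parameters.
#' @param window_kb Locus window (kb).
#' @param n_sets Permutation null sets.
#' @param expected_frames Expected cine frame count for QC; default 50.
#' @param seed Integer master seed.
#' @param out_dir Optional output directory (created on demand).
#' @return A validated `run_config` list.
#' @export
run_config <- function(input_paths = character(0), grid_res = 96,
                       smoothing_sigma = 1.5, padding = 0.25,
                       window_kb = 500, n_sets = 10000,
                       expected_frames = 50, seed = 1,
                       out_dir = NULL) {
  missing_paths <- input_paths[!file.exists(input_paths)]
  if (length(missing_paths) > 0)
    stop("input path(s) do not exist: ", paste(missing_paths, collapse = ", "))
  stopifnot(grid_res >= 16, smoothing_sigma >= 0, padding >= 0,
            window_kb > 0, n_sets >= 1, expected_frames >= 1)
  structure(list(input_paths = input_paths, grid_res = grid_res,
                 smoothing_sigma = smoothing_sigma, padding = padding,
                 window_kb = window_kb, n_sets = n_sets,
                 expected_frames = expected_frames,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_manifest <- function(config, extra, path) {
  jsonlite::write_json(c(list(
    package = "atriumkit",
    version = as.character(utils::packageVersion("atriumkit")),
    seed = config$seed,
    parameters = config[c("grid_res", "smoothing_sigma", "padding",
                          "window_kb", "n_sets")]), extra),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the imaging arm on a set of studies
#'
#' Per study: cohort QC (population frame-delta statistics computed over the
#' batch), then reconstruction and phenotype extraction for studies passing
#' QC. QC-flagged studies are reported with phenotypes withheld, never
#' silently dropped; studies whose input errors are recorded and the run
#' continues.
#'
#' @param studies Named list; each element a list of [cine_segmentation()]
#'   views for one study.
#' @param config A [run_config()].
#' @param bsa_m2 Optional named numeric vector of body surface areas.
#' @param write_meshes Write per-frame PLY meshes when `out_dir` is set.
#' @return List with `phenotypes` (data.frame), `qc` (data.frame), `traces`,
#'   and `manifest`.
#' @export
run_imaging_study <- function(studies, config = run_config(), bsa_m2 = NULL,
                              write_meshes = FALSE) {
  stopifnot(inherits(config, "run_config"), length(studies) >= 1)
  ids <- names(studies)
  if (is.null(ids)) ids <- sprintf("study_%03d", seq_along(studies))

  # QC on the first view of each study, cohort population stats in one batch
  first_views <- lapply(studies, function(s) s[[1]])
  qc <- if (length(studies) >= 2)
    qc_cohort(first_views, expected_frames = config$expected_frames)
  else
    list(reports = lapply(first_views, qc_flags, pop = NULL,
                          expected_frames = config$expected_frames),
         pop = NULL)
  qc_df <- do.call(rbind, lapply(seq_along(ids), function(i) {
    r <- qc$reports[[i]]
    data.frame(id = ids[i],
               flag_multi_component = r$flag_multi_component,
               flag_frame_jump = r$flag_frame_jump,
               flag_empty_frame = r$flag_empty_frame,
               flag_bad_frame_count = r$flag_bad_frame_count,
               max_frame_delta_px = r$max_frame_delta_px,
               stringsAsFactors = FALSE)
  }))
  flagged <- apply(qc_df[, 2:5], 1, function(x) any(x, na.rm = TRUE))

  traces <- vector("list", length(ids)); names(traces) <- ids
  pheno_rows <- list(); errors <- list()
  for (i in seq_along(ids)) {
    if (flagged[i]) next
    res <- tryCatch({
      tr <- reconstruct_trace(studies[[i]], grid_res = config$grid_res,
                              smoothing_sigma = config$smoothing_sigma,
                              padding = config$padding)
      traces[[i]] <- tr
      bsa <- if (!is.null(bsa_m2)) unname(bsa_m2[ids[i]]) else NULL
      ph <- la_phenotypes(tr, bsa_m2 = bsa)
      data.frame(id = ids[i], la_max_ml = ph$la_max_ml,
                 la_min_ml = ph$la_min_ml, la_sv_ml = ph$la_sv_ml,
                 la_ef = ph$la_ef_frac,
                 bsa_m2 = if (is.null(bsa)) NA else bsa,
                 la_max_i = if (is.null(bsa)) NA else ph$la_max_i,
                 la_min_i = if (is.null(bsa)) NA else ph$la_min_i,
                 la_sv_i = if (is.null(bsa)) NA else ph$la_sv_i,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[ids[i]]] <- conditionMessage(res)
    } else {
      pheno_rows[[ids[i]]] <- res
    }
  }
  phenotypes <- if (length(pheno_rows) > 0) do.call(rbind, pheno_rows) else
    data.frame()

  manifest <- list(n_studies = length(ids), qc_flagged = ids[flagged],
                   errors = errors)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(phenotypes, file.path(config$out_dir, "phenotypes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(qc_df, file.path(config$out_dir, "qc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (id in ids[!flagged])
      if (!is.null(traces[[id]]))
        write_volume_trace_csv(traces[[id]],
                               file.path(config$out_dir,
                                         paste0(id, "_trace.csv")))
    write_manifest(config, manifest,
                   file.path(config$out_dir, "manifest.json"))
  }
  list(phenotypes = phenotypes, qc = qc_df, traces = traces,
       manifest = manifest)
}

#' Run the genetics arm
#'
#' Per-trait locus definition, pooled distinct loci, and optionally the
#' overlap permutation test and the two-sample MR estimators.
#'
#' @param lead_snps Lead-SNP `data.frame` (with a `trait` column) or a path
#'   to a TSV.
#' @param config A [run_config()].
#' @param reference_leads Optional reference lead list for the overlap test.
#' @param null_panel Optional SNP panel for the default uniform null provider
#'   (required when `reference_leads` is given).
#' @param mr_exposure,mr_outcome Optional summary-stat tables for MR.
#' @return List with `per_trait_loci`, `pooled_loci`, `locus_counts`,
#'   optional `overlap` and `mr`, plus `manifest`.
#' @export
run_genetics_study <- function(lead_snps, config = run_config(),
                               reference_leads = NULL, null_panel = NULL,
                               mr_exposure = NULL, mr_outcome = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(lead_snps)) lead_snps <- read_lead_snps(lead_snps)
  lead_snps <- validate_lead_snps(lead_snps)

  traits <- unique(lead_snps$trait)
  per_trait <- lapply(traits, function(tr)
    merge_loci(lead_snps[lead_snps$trait == tr, , drop = FALSE],
               window_kb = config$window_kb))
  names(per_trait) <- traits
  pooled <- distinct_loci_across_traits(
    lapply(traits, function(tr) lead_snps[lead_snps$trait == tr, , drop = FALSE]),
    window_kb = config$window_kb)
  counts <- data.frame(trait = c(traits, "pooled"),
                       n_loci = c(vapply(per_trait, length.locus_set, 1L),
                                  length.locus_set(pooled)),
                       stringsAsFactors = FALSE)

  overlap <- NULL
  if (!is.null(reference_leads)) {
    if (is.null(null_panel))
      stop("null_panel is required when reference_leads is given")
    provider <- uniform_null_provider(null_panel,
                                      size = nrow(pooled$leads),
                                      seed = config$seed)
    overlap <- permutation_test(pooled, reference_leads, provider,
                                n_sets = config$n_sets,
                                window_kb = config$window_kb)
  }

  mr <- NULL
  if (!is.null(mr_exposure) && !is.null(mr_outcome)) {
    inst <- select_instruments(mr_exposure)
    set <- harmonize(inst, mr_outcome)
    mr <- mr_report(set, seed = config$seed)
  }

  manifest <- list(n_snps = nrow(lead_snps), traits = traits,
                   overlap_requested = !is.null(reference_leads),
                   mr_requested = !is.null(mr))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(counts, file.path(config$out_dir, "locus_counts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(mr))
      utils::write.table(mr, file.path(config$out_dir, "mr_report.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(config, manifest,
                   file.path(config$out_dir, "manifest.json"))
  }
  list(per_trait_loci = per_trait, pooled_loci = pooled,
       locus_counts = counts, overlap = overlap, mr = mr,
       manifest = manifest)
}
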