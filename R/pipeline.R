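#' Run the full analysis pipeline on a synthetic or supplied study
#'
#' Chains every stage in order, per set: channel-sum scaling, missingness
#' filtering, log2 transform, GIS-anchored median-polish batch correction,
#' bootstrap covariate regression, and Student's t differential abundance;
#' then across sets: AT+ sample filtering, Fisher meta-analysis,
#' Z-transformation and biomarker-trait correlation; then projection of a
#' reference cohort onto modules (kME/bicor), module-trait association,
#' over-representation of AD-changed plasma proteins in modules, plasma/
#' reference overlap coverage; and finally ROC panel classification against
#' plasma pTau181. One TSV per result table plus a machine-readable JSON
#' summary (stage counts, thresholds, config hash, seed) are written when
#' `out_dir` is given. The run is a pure function of `(config, data)`:
#' equal configurations and seeds give byte-identical output bundles.
#'
#' @param config A [default_config()] list.
#' @param design Optional [synthetic_design()]; when supplied (the default
#'   uses `config$seed`), data are simulated.
#' @param data Optional list with `matrix`, `metadata` (and optionally
#'   `reference`, `network`, `ref_metadata`) to analyze instead of
#'   simulating.
#' @param out_dir Output directory for the result bundle, or `NULL` to
#'   return results only.
#' @return Invisibly, a list with every stage's result tables and the
#'   `summary` list.
#' @export
run_pipeline <- function(config = default_config(), design = NULL,
                         data = NULL, out_dir = NULL) {
  if (is.null(data)) {
    if (is.null(design)) design <- synthetic_design(seed = config$seed)
    sim <- simulate_dataset(design)
    ref <- simulate_reference_brain(design)
    data <- list(matrix = sim$matrix, metadata = sim$metadata,
                 truth = sim$truth, reference = ref$matrix,
                 network = ref$network, ref_metadata = ref$ref_metadata)
  }
  meta_all <- data$metadata
  sets <- unique(meta_all$set)
  summary <- list(config = unclass(config), config_hash = config_hash(config),
                  seed = config$seed, stages = list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  per_set <- list()
  for (s in sets) {
    sm <- meta_all[meta_all$set == s, , drop = FALSE]
    mat <- am_subset(data$matrix, samples = sm$sample_id)
    scaled <- stage("normalize", channel_sum_scale(mat))
    filt <- stage("filter", filter_missingness(scaled$matrix,
                                               config$max_missing_frac))
    lg <- stage("log2", log2_transform(filt$matrix))
    tc <- stage("batch-correct",
                tampor_correct(lg, sm, use_gis = config$use_gis,
                               tol = config$polish_tol,
                               max_iter = config$polish_max_iter))
    br <- stage("regress",
                bootstrap_regress(tc$matrix, sm,
                                  covariates = config$covariates,
                                  protected = config$protected,
                                  B = config$bootstrap_B,
                                  seed = derive_seed(config$seed,
                                                     match(s, sets))))
    per_set[[s]] <- list(metadata = sm, corrected = br$matrix,
                         scaling = scaled$report, dropped = filt$dropped,
                         polish = tc$state, regression = br$report)
    summary$stages[[s]] <- list(
      n_samples = nrow(sm), n_proteins_in = nrow(mat$values),
      n_proteins_retained = nrow(filt$matrix$values),
      n_dropped_missingness = length(filt$dropped),
      polish_iterations = tc$state$iterations)
  }

  # AT+ filtering before the two-set comparison
  atf <- stage("at-filter",
               at_filter(meta_all, ratio_cut = config$at_ratio_cut,
                         moca_ad = config$at_moca_ad,
                         moca_ctl = config$at_moca_ctl))
  summary$stages$at_filter <- list(n_retained = length(atf$retained),
                                   n_excluded = nrow(atf$excluded))

  stats_by_set <- list()
  for (s in sets) {
    sm <- per_set[[s]]$metadata
    keep <- sm$sample_id[sm$is_gis | sm$sample_id %in% atf$retained]
    m <- am_subset(per_set[[s]]$corrected, samples = keep)
    stats_by_set[[s]] <- stage("differential",
                               ttest_by_group(m, sm[sm$sample_id %in% keep, ]))
    summary$stages[[paste0("differential_", s)]] <- list(
      n_tested = sum(stats_by_set[[s]]$tested),
      n_q_lt_volcano = sum(stats_by_set[[s]]$q < config$fdr_volcano,
                           na.rm = TRUE),
      n_q_lt_heatmap = sum(stats_by_set[[s]]$q < config$fdr_heatmap,
                           na.rm = TRUE))
  }

  meta_tab <- if (length(sets) >= 2) {
    stage("meta", combine_sets(stats_by_set[[1]], stats_by_set[[2]]))
  } else {
    st <- stats_by_set[[1]]
    data.frame(protein_id = st$protein_id, gene_symbol = st$gene_symbol,
               p_set1 = st$p, log2fc_set1 = st$log2fc,
               p_set2 = NA_real_, log2fc_set2 = NA_real_,
               meta_p = st$p, meta_q = st$q, mean_log2fc = st$log2fc,
               n_sets = 1L, concordant = NA, stringsAsFactors = FALSE)
  }
  summary$stages$meta <- list(
    n_proteins = nrow(meta_tab),
    n_meta_p_lt_0.05 = sum(meta_tab$meta_p < 0.05, na.rm = TRUE),
    n_meta_p_lt_roc = sum(meta_tab$meta_p < config$meta_p_max, na.rm = TRUE))

  # combined corrected matrix over retained biological samples of both sets
  combined <- stage("combine", {
    ids <- sort(unique(unlist(lapply(per_set, function(x)
      rownames(x$corrected$values)))))
    cols <- unlist(lapply(per_set, function(x) {
      sm <- x$metadata
      intersect(colnames(x$corrected$values),
                sm$sample_id[!sm$is_gis & sm$sample_id %in% atf$retained])
    }))
    vv <- matrix(NA_real_, length(ids), length(cols),
                 dimnames = list(ids, cols))
    syms <- stats::setNames(rep(NA_character_, length(ids)), ids)
    for (x in per_set) {
      v <- x$corrected$values
      cc <- intersect(colnames(v), cols)
      vv[rownames(v), cc] <- v[, cc]
      syms[rownames(v)] <- x$corrected$gene_symbols[rownames(v)]
    }
    abundance_matrix(vv, syms, scale = "corrected")
  })

  zmat <- stage("z-transform", suppressWarnings(z_transform(combined)))
  traits_tab <- stage("traits", correlate_traits(zmat, meta_all))
  summary$stages$traits <- list(
    n_cells = nrow(traits_tab),
    n_p_lt_0.05 = sum(traits_tab$p < 0.05, na.rm = TRUE))

  # module projection and enrichment on the reference cohort
  assignment <- mt_corr <- enrich_up <- enrich_down <- coverage <- NULL
  if (!is.null(data$network)) {
    assignment <- stage("map-modules",
                        assign_modules(data$reference, data$network,
                                       kme_min = config$kme_min))
    if (!is.null(data$ref_metadata))
      mt_corr <- stage("module-traits",
                       module_trait_correlation(data$network,
                                                data$ref_metadata))
    brain_ids <- rownames(data$reference$values)
    mod_members <- split(assignment$protein_id, assignment$module)
    mod_members <- mod_members[names(mod_members) != "grey"]
    up <- meta_tab$protein_id[!is.na(meta_tab$meta_p) &
                                meta_tab$meta_p < 0.05 &
                                meta_tab$mean_log2fc > 0]
    down <- meta_tab$protein_id[!is.na(meta_tab$meta_p) &
                                  meta_tab$meta_p < 0.05 &
                                  meta_tab$mean_log2fc < 0]
    enrich_up <- stage("enrich", fet_enrichment(
      intersect(up, brain_ids), mod_members, brain_ids,
      min_genes = config$min_genes))
    enrich_down <- stage("enrich", fet_enrichment(
      intersect(down, brain_ids), mod_members, brain_ids,
      min_genes = config$min_genes))
    coverage <- stage("overlap", overlap_summary(
      rownames(combined$values), brain_ids, data$network))
    summary$stages$modules <- list(
      n_assigned = sum(assignment$assigned),
      n_grey = sum(!assignment$assigned),
      plasma_brain_overlap = coverage$n_overlap)
  }

  # ROC on eligible proteins, benchmarked against plasma pTau181
  roc_res <- NULL
  elig <- stage("roc-eligibility",
                eligible_proteins(meta_tab, zmat, meta_all,
                                  meta_p_max = config$meta_p_max))
  summary$stages$roc <- list(n_eligible = length(elig$proteins),
                             n_samples = length(elig$samples))
  if (length(elig$proteins) >= 1) {
    sm <- meta_all[match(elig$samples, meta_all$sample_id), ]
    ok <- !is.na(sm$diagnosis) & !is.na(sm$plasma_pTau181)
    sm <- sm[ok, , drop = FALSE]
    feat <- zmat$values[elig$proteins, sm$sample_id, drop = FALSE]
    roc_res <- stage("roc", rank_and_panel(feat, sm$diagnosis,
                                           covariate = sm$plasma_pTau181,
                                           k = config$panel_size))
    summary$stages$roc$panel_auc <- roc_res$panel_roc$auc
    summary$stages$roc$covariate_auc <- roc_res$covariate_roc$auc
    summary$stages$roc$combined_auc <- roc_res$combined_roc$auc
    summary$stages$roc$delong_p <- roc_res$comparison$p
  }

  result <- list(per_set = per_set, stats_by_set = stats_by_set,
                 at_filter = atf, meta = meta_tab, z = zmat,
                 traits = traits_tab, assignment = assignment,
                 module_traits = mt_corr, enrichment_up = enrich_up,
                 enrichment_down = enrich_down, coverage = coverage,
                 roc = roc_res, summary = summary, truth = data$truth)

  if (!is.null(out_dir)) write_bundle(result, out_dir, config)
  invisible(result)
}

# write one TSV per result table plus summary.json; deterministic bytes
write_bundle <- function(result, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(config)
  stamp <- function(df) { df$config_hash <- h; df }
  for (s in names(result$stats_by_set))
    write_tsv(stamp(result$stats_by_set[[s]]),
              file.path(out_dir, paste0("differential_", s, ".tsv")))
  write_tsv(stamp(result$meta), file.path(out_dir, "meta.tsv"))
  write_tsv(stamp(result$traits), file.path(out_dir, "trait_correlations.tsv"))
  write_tsv(stamp(result$at_filter$excluded),
            file.path(out_dir, "at_filter_exclusions.tsv"))
  if (!is.null(result$assignment))
    write_tsv(stamp(result$assignment),
              file.path(out_dir, "module_assignment.tsv"))
  if (!is.null(result$module_traits))
    write_tsv(stamp(result$module_traits),
              file.path(out_dir, "module_trait_correlations.tsv"))
  if (!is.null(result$enrichment_up))
    write_tsv(stamp(result$enrichment_up),
              file.path(out_dir, "enrichment_up.tsv"))
  if (!is.null(result$enrichment_down))
    write_tsv(stamp(result$enrichment_down),
              file.path(out_dir, "enrichment_down.tsv"))
  if (!is.null(result$roc)) {
    write_tsv(stamp(result$roc$ranking),
              file.path(out_dir, "roc_ranking.tsv"))
    write_tsv(stamp(result$roc$panel_roc$thresholds),
              file.path(out_dir, "roc_panel_thresholds.tsv"))
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
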