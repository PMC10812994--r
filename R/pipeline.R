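# End-to-end orchestration: simulate -> ALFF -> group GLM (ALFF branch
# with GRF correction, GMV branch with Monte-Carlo extent threshold) ->
# expression preprocessing -> spatial association + crossover ->
# enrichment -> clinical correlations, with one config, per-stage file
# outputs and recovery scoring against the synthetic ground truth.

#' Default pipeline configuration
#'
#' Desk-scale study conditions: 24x28x24 grid at 3 mm, 31 subjects per
#' arm, 200 time points at TR 2 s, band 0.01-0.08 Hz, voxel p 0.001 /
#' cluster p 0.05, 2000 genes (50 true, coupling r 0.5), 300 samples,
#' 3 donors, 2 probes per gene.
#'
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @param ... Named overrides of any default entry.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    grid_shape = c(24L, 28L, 24L),
    voxel_size = c(3, 3, 3),
    n_case = 31L, n_control = 31L,
    tr = 2, n_timepoints = 200L,
    band = c(0.01, 0.08),
    amplitude_effect = 0.5, gmv_effect = 0.15,
    cluster_radius_mm = 7.5,
    gmv_smoothing_fwhm = 8,
    one_sample_alpha = 0.05,
    voxel_p = 0.001, cluster_p = 0.05,
    mc_iterations = 1000L,
    connectivity = 26L,
    n_genes = 2000L, n_true_genes = 50L, coupling_r = 0.5,
    n_samples = 300L, n_donors = 3L, probes_per_gene = 2L,
    alpha_gene = 0.01, r_min = 0.2,
    stability_threshold = 0.2,
    enrichment_q_max = 0.05, min_overlap = 3L,
    modality = "both",
    version = as.character(utils::packageVersion("neurotx")))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown option(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file of flat keys matching [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$version <- NULL
  do.call(pipeline_config, c(list(seed = vals$seed %||% 1L),
                             vals[setdiff(names(vals), "seed")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

child_seed <- function(seed, k) (abs(as.integer(seed)) %% 20000000L) *
  100L + as.integer(k)

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in order on synthetic data with known ground
#' truth, writes each stage's artifacts under `outdir`, and scores
#' recovery. All randomness derives from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results, including
#'   `recovery` (the [score_recovery()] output) and `outdir`.
#' @export
run_all <- function(config = pipeline_config(), outdir = tempfile("ntx")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))

  # --- simulate -----------------------------------------------------------
  mask <- make_mask(cfg$grid_shape, cfg$voxel_size,
                    seed = child_seed(cfg$seed, 1))
  effect <- default_effect_spec(mask,
                                cluster_radius_mm = cfg$cluster_radius_mm,
                                amplitude_effect = cfg$amplitude_effect,
                                gmv_effect = cfg$gmv_effect)
  design <- generate_design(cfg$n_case, cfg$n_control,
                            seed = child_seed(cfg$seed, 2))
  write_design_table(design, file.path(outdir, "design.tsv"))
  write_volume(structure(list(grid = mask$grid,
                              values = array(as.numeric(mask$inside),
                                             dim = dim(mask$inside))),
                         class = "volume3d"),
               file.path(outdir, "mask.nii.gz"))
  stage_log("simulate", "mask %d voxels, %d subjects", mask_size(mask),
            nrow(design))

  # --- alff (streaming over generated subjects) ---------------------------
  alff_maps <- generate_group_fmri(
    design, mask, effect, tr = cfg$tr, n_timepoints = cfg$n_timepoints,
    seed = child_seed(cfg$seed, 3), band = cfg$band,
    apply_fn = function(ts) compute_alff(ts, NULL, cfg$band[1],
                                         cfg$band[2]))
  gmv_maps <- generate_group_gmv(design, mask, effect,
                                 smoothing_fwhm = cfg$gmv_smoothing_fwhm,
                                 seed = child_seed(cfg$seed, 4))

  # --- groupdiff: ALFF branch (GRF) ---------------------------------------
  osm <- one_sample_mask(alff_maps, design$group, mask,
                         null_value = 1, alpha = cfg$one_sample_alpha)
  dm <- build_design_matrix(design)
  fit_a <- fit_two_sample_glm(alff_maps, dm, osm)
  sm_a <- estimate_smoothness(fit_a$residuals, fit_a$mask, fit_a$tmap$dof)
  rec_a <- grf_cluster_correction(fit_a$tmap, sm_a, cfg$voxel_p,
                                  cfg$cluster_p,
                                  connectivity = cfg$connectivity)
  write_volume(fit_a$tmap, file.path(outdir, "tmap_alff.nii.gz"))
  make_cluster_table(rec_a, file.path(outdir, "clusters_alff.tsv"))
  jsonlite::write_json(list(fwhm_mm = sm_a$fwhm_mm, resels = sm_a$resels,
                            dof = sm_a$dof),
                       file.path(outdir, "smoothness_alff.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- groupdiff: GMV branch (Monte-Carlo) --------------------------------
  fit_g <- fit_two_sample_glm(gmv_maps, dm, mask)
  sm_g <- estimate_smoothness(fit_g$residuals, fit_g$mask, fit_g$tmap$dof)
  kmin <- monte_carlo_cluster_threshold(fit_g$mask, sm_g, cfg$voxel_p,
                                        cfg$cluster_p,
                                        n_iter = cfg$mc_iterations,
                                        seed = child_seed(cfg$seed, 5),
                                        connectivity = cfg$connectivity)
  rec_g <- mc_cluster_records(fit_g$tmap, kmin, cfg$voxel_p,
                              connectivity = cfg$connectivity)
  write_volume(fit_g$tmap, file.path(outdir, "tmap_gmv.nii.gz"))
  make_cluster_table(rec_g, file.path(outdir, "clusters_gmv.tsv"))
  jsonlite::write_json(list(fwhm_mm = sm_g$fwhm_mm, resels = sm_g$resels,
                            dof = sm_g$dof, extent_threshold = kmin),
                       file.path(outdir, "smoothness_gmv.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- expression ---------------------------------------------------------
  # true genes track the shared disease pattern: the average of the two
  # z-scored t-maps, so they correlate with both modalities
  shared <- shared_effect_map(fit_a$tmap, fit_g$tmap, mask)
  truth <- expression_truth(cfg$n_genes, cfg$n_true_genes, cfg$coupling_r,
                            n_donors = cfg$n_donors,
                            probes_per_gene = cfg$probes_per_gene)
  eset <- generate_expression_samples(mask, truth, shared,
                                      n_samples = cfg$n_samples,
                                      seed = child_seed(cfg$seed, 6))
  prep <- prep_expression(eset, mask,
                          stability_threshold = cfg$stability_threshold)
  expr_out <- data.frame(gene = rownames(prep$matrix$matrix),
                         prep$matrix$matrix, check.names = FALSE)
  write_tsv(expr_out, file.path(outdir, "expression_matrix.tsv"))

  # --- associate ----------------------------------------------------------
  assoc <- list()
  sel_lists <- list()
  for (mod in c("alff", "gmv")) {
    if (!(cfg$modality %in% c("both", mod))) next
    tmap <- if (mod == "alff") fit_a$tmap else fit_g$tmap
    feats <- prep$matrix$features
    ok <- !is.na(tmap$values[feats$voxel])
    tv <- tmap$values[feats$voxel][ok]
    a <- mass_correlation(prep$matrix$matrix[, ok, drop = FALSE], tv)
    a <- dual_threshold(a, cfg$alpha_gene, cfg$r_min)
    assoc[[mod]] <- a
    sel_lists[[mod]] <- selected_genes(a)
    write_tsv(a, file.path(outdir, sprintf("associations_%s.tsv", mod)))
    writeLines(sel_lists[[mod]],
               file.path(outdir, sprintf("selected_genes_%s.txt", mod)))
  }
  crossover <- if (length(sel_lists) == 2L)
    intersect_gene_lists(sel_lists$alff, sel_lists$gmv) else
      sel_lists[[1]]
  writeLines(crossover, file.path(outdir, "crossover_genes.txt"))

  # --- enrich -------------------------------------------------------------
  collections <- generate_gene_sets(truth,
                                    seed = child_seed(cfg$seed, 7))
  universe <- rownames(prep$matrix$matrix)
  enr <- run_enrichment(crossover, collections, universe,
                        q_max = 1, min_overlap = cfg$min_overlap)
  write_tsv(enr, file.path(outdir, "enrichment.tsv"))

  # --- clinical -----------------------------------------------------------
  clin_rows <- NULL
  if (nrow(rec_a) > 0) {
    summ <- cluster_subject_summaries(alff_maps, rec_a, fit_a$mask)
    clin <- generate_clinical_table(design, imaging_score = summ[, 1],
                                    seed = child_seed(cfg$seed, 8))
    write_tsv(clin, file.path(outdir, "clinical.tsv"))
    case_rows <- design$group == "case"
    clin_rows <- spearman_with_fdr(
      as.data.frame(summ)[case_rows, , drop = FALSE],
      clin[case_rows, c("ahi", "ess", "moca", "stroop_word")])
    write_tsv(clin_rows, file.path(outdir, "clinical_correlations.tsv"))
  }

  # --- score --------------------------------------------------------------
  outputs <- list(config = cfg, mask = mask, effect = effect,
                  design = design, alff_maps = alff_maps,
                  fit_alff = fit_a, smoothness_alff = sm_a,
                  clusters_alff = rec_a,
                  fit_gmv = fit_g, smoothness_gmv = sm_g,
                  clusters_gmv = rec_g, mc_extent_threshold = kmin,
                  prep = prep, associations = assoc,
                  selected = sel_lists, crossover = crossover,
                  enrichment = enr, clinical = clin_rows,
                  truth = truth, outdir = outdir)
  recovery <- score_recovery(outputs, truth)
  outputs$recovery <- recovery
  jsonlite::write_json(recovery, file.path(outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = cfg$seed,
         config_md5 = unname(tools::md5sum(file.path(outdir,
                                                     "config.yaml"))),
         n_subjects = nrow(design),
         n_features = nrow(prep$matrix$features),
         n_genes_retained = nrow(prep$matrix$matrix),
         true_genes = truth$true_gene_ids,
         cluster_centers = effect$cluster_centers,
         cluster_signs = effect$signs),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(outputs)
}

# average of z-scored in-mask t-values of two maps, as a stat_map-like
# volume for the expression generator
shared_effect_map <- function(tmap_a, tmap_b, mask) {
  v <- array(0, dim = dim(mask$inside))
  za <- zb <- array(0, dim = dim(mask$inside))
  ia <- !is.na(tmap_a$values)
  ib <- !is.na(tmap_b$values)
  za[ia] <- as.numeric(scale(tmap_a$values[ia]))
  zb[ib] <- as.numeric(scale(tmap_b$values[ib]))
  v <- (za + zb) / 2
  structure(list(grid = mask$grid, values = v, mask = mask),
            class = "volume3d")
}

#' Generate fixture gene-set collections with one planted set
#'
#' The planted set contains `planted_fraction` of the true genes topped up
#' with null genes; the remaining sets are random draws from all genes.
#' Used as the enrichment fixture in place of a live ontology database.
#'
#' @param truth An [expression_truth()].
#' @param n_sets Sets per category (default 20).
#' @param set_size Genes per set (default 60).
#' @param planted_fraction Fraction of true genes in the planted set
#'   (default 0.8).
#' @param categories Category labels (default `c("MF", "CC", "BP")`; the
#'   planted set goes in the first).
#' @param seed Integer seed.
#' @return Named list of categories, each a named list of gene sets; the
#'   planted set is called `PLANTED_TRUE_SET`.
#' @export
generate_gene_sets <- function(truth, n_sets = 20L, set_size = 60L,
                               planted_fraction = 0.8,
                               categories = c("MF", "CC", "BP"),
                               seed = 1L) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  genes <- truth$gene_ids
  n_true_in <- round(planted_fraction * length(truth$true_gene_ids))
  planted <- c(sample(truth$true_gene_ids, n_true_in),
               sample(setdiff(genes, truth$true_gene_ids),
                      max(0, set_size - n_true_in)))
  out <- list()
  for (ci in seq_along(categories)) {
    sets <- list()
    if (ci == 1L) sets$PLANTED_TRUE_SET <- sort(planted)
    while (length(sets) < n_sets) {
      nm <- sprintf("%s_SET%02d", categories[ci], length(sets) + 1L)
      sets[[nm]] <- sort(sample(genes, set_size))
    }
    out[[categories[ci]]] <- sets
  }
  out
}

#' Score pipeline outputs against the synthetic ground truth
#'
#' A surviving cluster counts as recovered if it overlaps a seeded cluster
#' by at least one voxel; gene metrics are set comparisons against the
#' true gene ids; the enrichment rank is the position of the planted set.
#'
#' @param outputs Result list of [run_all()] (or a compatible subset with
#'   `mask`, `effect`, `clusters_*`, `selected`, `crossover`,
#'   `enrichment`).
#' @param truth An [expression_truth()].
#' @return List of recovery metrics, all in `[0, 1]` except the rank.
#' @export
score_recovery <- function(outputs, truth) {
  mask <- outputs$mask
  ind <- effect_indicator(mask, outputs$effect)
  seeded_vox <- which(ind != 0)
  cluster_score <- function(records) {
    vox_list <- attr(records, "voxels")
    if (is.null(vox_list) || !length(vox_list))
      return(list(sensitivity = 0, precision = NA_real_))
    hit_seeded <- vapply(vox_list, function(v)
      length(intersect(v, seeded_vox)) >= 1L, TRUE)
    # a seeded cluster is recovered if any surviving cluster touches it
    centers <- outputs$effect$cluster_centers
    rec <- vapply(seq_len(nrow(centers)), function(k) {
      one <- effect_spec(centers[k, , drop = FALSE],
                         outputs$effect$cluster_radius_mm,
                         signs = outputs$effect$signs[k])
      vk <- which(effect_indicator(mask, one) != 0)
      any(vapply(vox_list, function(v)
        length(intersect(v, vk)) >= 1L, TRUE))
    }, TRUE)
    list(sensitivity = mean(rec), precision = mean(hit_seeded))
  }
  ca <- cluster_score(outputs$clusters_alff)
  cg <- cluster_score(outputs$clusters_gmv)
  gene_score <- function(sel) {
    if (!length(sel)) return(list(sensitivity = 0, precision = NA_real_))
    tp <- length(intersect(sel, truth$true_gene_ids))
    list(sensitivity = tp / length(truth$true_gene_ids),
         precision = tp / length(sel))
  }
  ga <- gene_score(outputs$selected$alff %||% character(0))
  gg <- gene_score(outputs$selected$gmv %||% character(0))
  gx <- gene_score(outputs$crossover)
  enr <- outputs$enrichment
  rank_planted <- if (!is.null(enr) && nrow(enr) &&
                      "PLANTED_TRUE_SET" %in% enr$set)
    which(enr$set == "PLANTED_TRUE_SET")[1] else NA_integer_
  list(cluster_sensitivity_alff = ca$sensitivity,
       cluster_precision_alff = ca$precision,
       cluster_sensitivity_gmv = cg$sensitivity,
       cluster_precision_gmv = cg$precision,
       gene_sensitivity_alff = ga$sensitivity,
       gene_precision_alff = ga$precision,
       gene_sensitivity_gmv = gg$sensitivity,
       gene_precision_gmv = gg$precision,
       gene_sensitivity_crossover = gx$sensitivity,
       gene_precision_crossover = gx$precision,
       enrichment_rank_planted = rank_planted)
}
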