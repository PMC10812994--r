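# AHBA-style expression preprocessing: nine steps from probe-level donor
# samples to a clean genes-by-features matrix. Step order is fixed:
# (1) reannotate probes, (2) intensity filter, (3) probe selection,
# (4) sample-to-voxel matching, (5) missing data, (6) sample
# normalization, (7) gene normalization, (8) aggregation, (9) stable-gene
# filter. Every step records retained (probes, genes, samples) counts.

#' Revise probe-to-gene annotations
#'
#' Replaces stale gene symbols with the current ones and drops probes
#' absent from the current annotation map.
#'
#' @param annotation Data.frame with `probe_id`, `gene_symbol` (possibly
#'   stale).
#' @param current_map Data.frame with `probe_id`, `gene_symbol` (current).
#' @return Data.frame `probe_id`, `gene_symbol`, `is_current` (TRUE where
#'   the symbol was already current), with attribute `n_dropped`.
#' @export
reannotate_probes <- function(annotation, current_map) {
  stopifnot(!anyDuplicated(annotation$probe_id))
  idx <- match(annotation$probe_id, current_map$probe_id)
  keep <- !is.na(idx)
  n_dropped <- sum(!keep)
  out <- data.frame(
    probe_id = annotation$probe_id[keep],
    gene_symbol = current_map$gene_symbol[idx[keep]],
    is_current = annotation$gene_symbol[keep] ==
      current_map$gene_symbol[idx[keep]],
    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("reannotate_probes: no probes left after revision")
  stage_log("reannotate_probes", "%d probes kept, %d dropped, %d revised",
            nrow(out), n_dropped, sum(!out$is_current))
  structure(out, n_dropped = n_dropped)
}

#' Intensity-based probe filter
#'
#' Keeps probes whose intensity exceeds their background level in at least
#' `min_fraction` of samples.
#'
#' @param eset An `expression_sample_set` (fields `intensity`,
#'   `background`).
#' @param min_fraction Minimum fraction of above-background samples
#'   (default 0.5).
#' @return The sample set with sub-threshold probes removed.
#' @export
intensity_filter <- function(eset, min_fraction = 0.5) {
  frac <- rowMeans(eset$intensity >
                     matrix(eset$background, nrow(eset$intensity),
                            ncol(eset$intensity)))
  keep <- frac >= min_fraction
  if (!any(keep)) stop("intensity_filter: all probes filtered out")
  stage_log("intensity_filter", "%d / %d probes kept", sum(keep),
            length(keep))
  eset$intensity <- eset$intensity[keep, , drop = FALSE]
  eset$background <- eset$background[keep]
  eset
}

# row-wise Pearson correlation of two matrices with matching dims
row_cors <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# mean expression per (row x structure) within one donor
donor_structure_means <- function(mat, structures) {
  f <- factor(structures)
  groups <- levels(f)
  out <- matrix(NA_real_, nrow(mat), length(groups),
                dimnames = list(rownames(mat), groups))
  for (g in seq_along(groups)) {
    cols <- which(f == groups[g])
    out[, g] <- if (length(cols) == 1L) mat[, cols] else
      rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

# differential stability of each row: mean over donor pairs of the spatial
# correlation of donor-wise structure profiles
differential_stability <- function(mat, donors, structures) {
  ud <- unique(donors)
  if (length(ud) < 2L) return(rep(NA_real_, nrow(mat)))
  prof <- lapply(ud, function(d) {
    cols <- donors == d
    donor_structure_means(mat[, cols, drop = FALSE], structures[cols])
  })
  acc <- rep(0, nrow(mat))
  npair <- 0L
  for (a in seq_along(ud)[-length(ud)]) for (b in (a + 1):length(ud)) {
    common <- intersect(colnames(prof[[a]]), colnames(prof[[b]]))
    if (length(common) < 3L) next
    r <- row_cors(prof[[a]][, common, drop = FALSE],
                  prof[[b]][, common, drop = FALSE])
    r[is.na(r)] <- 0
    acc <- acc + r
    npair <- npair + 1L
  }
  if (npair == 0L) return(rep(NA_real_, nrow(mat)))
  acc / npair
}

#' Select one probe per gene
#'
#' With at least two donors the probe with the highest differential
#' stability (mean inter-donor spatial correlation of its structure-level
#' profile) wins; with a single donor the probe with the highest mean
#' intensity wins. Exact ties break to the lexicographically smaller
#' probe id.
#'
#' @param eset An `expression_sample_set` (after [intensity_filter()]).
#' @param annotation Reannotated probe table (from [reannotate_probes()]).
#' @param method `"differential_stability"` (default) or
#'   `"mean_intensity"`.
#' @return List: `eset` with one probe per gene (rows renamed to gene
#'   symbols), `selection` data.frame (gene_symbol, probe_id, score).
#' @export
select_probes <- function(eset, annotation,
                          method = c("differential_stability",
                                     "mean_intensity")) {
  method <- match.arg(method)
  probes <- intersect(rownames(eset$intensity), annotation$probe_id)
  if (!length(probes)) stop("select_probes: no annotated probes")
  mat <- eset$intensity[probes, , drop = FALSE]
  genes <- annotation$gene_symbol[match(probes, annotation$probe_id)]
  n_donors <- length(unique(eset$samples$donor))
  score <- if (method == "differential_stability" && n_donors >= 2L) {
    differential_stability(mat, eset$samples$donor,
                           eset$samples$structure)
  } else {
    rowMeans(mat)
  }
  score[is.na(score)] <- -Inf
  ord <- order(genes, -score, probes)
  first <- !duplicated(genes[ord])
  chosen <- ord[first]
  sel <- data.frame(gene_symbol = genes[chosen],
                    probe_id = probes[chosen],
                    score = score[chosen], stringsAsFactors = FALSE)
  out <- eset
  out$intensity <- mat[chosen, , drop = FALSE]
  rownames(out$intensity) <- sel$gene_symbol
  out$background <- eset$background[sel$probe_id]
  stage_log("select_probes", "%d genes from %d probes (%s)", nrow(sel),
            length(probes), method)
  list(eset = out, selection = sel)
}

#' Match expression samples to mask voxels
#'
#' Each sample is assigned to the nearest in-mask voxel centre within
#' `max_distance_mm`; unassigned samples are dropped. An optional
#' left-hemisphere filter (world x < 0) mirrors analyses restricted to the
#' left hemisphere.
#'
#' @param samples Data.frame with `sample_id`, `x`, `y`, `z` (world mm).
#' @param mask A [binary_mask()] in the same world frame.
#' @param max_distance_mm Assignment tolerance (default 2).
#' @param left_only Keep only samples with world x < 0 (default `FALSE`).
#' @return Data.frame `sample_id`, `voxel` (linear array index),
#'   `distance_mm`, with attribute `n_dropped`.
#' @export
match_samples_to_mask <- function(samples, mask, max_distance_mm = 2,
                                  left_only = FALSE) {
  s <- samples
  if (left_only) s <- s[s$x < 0, , drop = FALSE]
  vox <- mask_voxels(mask)
  centers <- voxel_to_world(mask$grid, vox)
  lin <- which(mask$inside)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  # fractional voxel position, then search the surrounding 2x2x2 block
  assigned <- integer(nrow(s))
  dist <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    d2 <- colSums((t(centers) - xyz[i, ])^2)
    j <- which.min(d2)
    assigned[i] <- lin[j]
    dist[i] <- sqrt(d2[j])
  }
  keep <- dist <= max_distance_mm
  n_dropped <- sum(!keep) + (nrow(samples) - nrow(s))
  out <- data.frame(sample_id = s$sample_id[keep],
                    voxel = assigned[keep], distance_mm = dist[keep],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("match_samples_to_mask: no samples assigned")
  stage_log("match_samples_to_mask", "%d samples assigned, %d dropped",
            nrow(out), n_dropped)
  structure(out, n_dropped = n_dropped)
}

#' Drop / impute missing expression values
#'
#' Genes missing in more than `threshold` of samples are dropped; the
#' remaining missing values are imputed by the gene's median within the
#' sample's donor.
#'
#' @param mat Genes x samples matrix (may contain `NA`).
#' @param donors Donor id per column.
#' @param threshold Maximum tolerated missing fraction per gene
#'   (default 0.5).
#' @return Matrix with no missing values.
#' @export
handle_missing <- function(mat, donors, threshold = 0.5) {
  frac <- rowMeans(is.na(mat))
  keep <- frac <= threshold
  mat <- mat[keep, , drop = FALSE]
  if (anyNA(mat)) {
    for (d in unique(donors)) {
      cols <- donors == d
      sub <- mat[, cols, drop = FALSE]
      med <- apply(sub, 1, stats::median, na.rm = TRUE)
      na_idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(na_idx)) {
        sub[na_idx] <- med[na_idx[, 1]]
        mat[, cols] <- sub
      }
    }
  }
  if (anyNA(mat)) {
    # a gene entirely missing within one donor: fall back to global median
    med <- apply(mat, 1, stats::median, na.rm = TRUE)
    na_idx <- which(is.na(mat), arr.ind = TRUE)
    mat[na_idx] <- med[na_idx[, 1]]
  }
  stage_log("handle_missing", "%d genes kept", nrow(mat))
  mat
}

# scaled robust sigmoid of a vector, then min-max rescale to [0,1];
# zero-spread input maps to 0.5
srs_unit <- function(x) {
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  if (iqr == 0) return(rep(0.5, length(x)))
  y <- 1 / (1 + exp(-(x - med) / (iqr / 1.349)))
  rng <- range(y)
  if (rng[2] == rng[1]) return(rep(0.5, length(x)))
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Normalize expression within donors (scaled robust sigmoid)
#'
#' Two passes: (i) sample normalization, each sample's values across genes
#' pushed through a scaled robust sigmoid `1 / (1 + exp(-(x - median) /
#' (IQR / 1.349)))` and min-max rescaled to `[0, 1]`, removing per-sample
#' and per-donor intensity distortions; (ii) gene normalization, the same
#' transform applied per gene across each donor's samples. Constant genes
#' are set to 0.5.
#'
#' @param mat Genes x samples matrix (no missing values).
#' @param donors Donor id per column.
#' @param sample_norm,gene_norm Toggle either pass (defaults `TRUE`).
#' @return Normalized matrix, bounded in `[0, 1]`.
#' @export
normalize_expression <- function(mat, donors, sample_norm = TRUE,
                                 gene_norm = TRUE) {
  stopifnot(!anyNA(mat))
  if (sample_norm) {
    for (j in seq_len(ncol(mat))) mat[, j] <- srs_unit(mat[, j])
  }
  if (gene_norm) {
    for (d in unique(donors)) {
      cols <- which(donors == d)
      if (length(cols) < 2L) next
      sub <- mat[, cols, drop = FALSE]
      mat[, cols] <- t(apply(sub, 1, srs_unit))
    }
  }
  mat
}

#' Aggregate samples by voxel and filter unstable genes
#'
#' Samples assigned to the same voxel are averaged into one feature;
#' differential stability (mean inter-donor correlation of donor-wise
#' structure profiles) is computed per gene on the pre-aggregation matrix
#' and genes below `stability_threshold` are dropped.
#'
#' @param mat Normalized genes x samples matrix.
#' @param samples Sample table (`sample_id`, `donor`, `structure`).
#' @param assignment Sample-to-voxel assignment from
#'   [match_samples_to_mask()].
#' @param stability_threshold Minimum differential stability (default
#'   0.2); use `-Inf` with fewer than two donors.
#' @return List of class `gene_by_sample_matrix`: `matrix` (genes x
#'   features), `features` (data.frame voxel, n_samples), `stability`
#'   (per retained gene), `n_unstable`.
#' @export
aggregate_and_stabilize <- function(mat, samples, assignment,
                                    stability_threshold = 0.2) {
  keep_cols <- match(assignment$sample_id, samples$sample_id)
  stopifnot(!anyNA(keep_cols))
  mat <- mat[, keep_cols, drop = FALSE]
  samples <- samples[keep_cols, , drop = FALSE]
  ds <- differential_stability(mat, samples$donor, samples$structure)
  if (all(is.na(ds))) ds <- rep(Inf, nrow(mat))  # single donor: keep all
  stable <- ds >= stability_threshold
  n_unstable <- sum(!stable)
  mat <- mat[stable, , drop = FALSE]
  ds <- ds[stable]
  vox <- assignment$voxel
  f <- factor(vox, levels = sort(unique(vox)))
  agg <- matrix(NA_real_, nrow(mat), nlevels(f),
                dimnames = list(rownames(mat), levels(f)))
  for (g in seq_len(nlevels(f))) {
    cols <- which(as.integer(f) == g)
    agg[, g] <- if (length(cols) == 1L) mat[, cols] else
      rowMeans(mat[, cols, drop = FALSE])
  }
  stage_log("aggregate_and_stabilize",
            "%d stable genes x %d features (%d unstable dropped)",
            nrow(agg), ncol(agg), n_unstable)
  structure(list(matrix = agg,
                 features = data.frame(voxel = as.integer(levels(f)),
                                       n_samples = as.integer(table(f))),
                 stability = ds, n_unstable = n_unstable),
            class = "gene_by_sample_matrix")
}

#' Run the full nine-step expression preprocessing
#'
#' @param eset An `expression_sample_set` (see
#'   [generate_expression_samples()] or the TSV readers).
#' @param mask A [binary_mask()].
#' @param min_fraction Intensity-filter fraction (default 0.5).
#' @param max_distance_mm Sample matching tolerance (default 2).
#' @param stability_threshold Stable-gene threshold (default 0.2).
#' @param left_only Restrict to left-hemisphere samples (default `FALSE`).
#' @param missing_threshold Missing-data threshold (default 0.5).
#' @return List of class `expression_prep`: `matrix`
#'   (a `gene_by_sample_matrix`), `assignment`, `selection`, `provenance`
#'   (per-step probe/gene/sample counts).
#' @export
prep_expression <- function(eset, mask, min_fraction = 0.5,
                            max_distance_mm = 2,
                            stability_threshold = 0.2, left_only = FALSE,
                            missing_threshold = 0.5) {
  prov <- list()
  note <- function(step, probes, genes, samples)
    prov[[step]] <<- c(probes = probes, genes = genes, samples = samples)
  note("input", nrow(eset$intensity), NA, nrow(eset$samples))
  ann <- reannotate_probes(eset$annotation, eset$current_map)       # 1
  eset$intensity <- eset$intensity[
    rownames(eset$intensity) %in% ann$probe_id, , drop = FALSE]
  eset$background <- eset$background[rownames(eset$intensity)]
  note("reannotate", nrow(eset$intensity),
       length(unique(ann$gene_symbol)), nrow(eset$samples))
  eset <- intensity_filter(eset, min_fraction)                      # 2
  note("intensity_filter", nrow(eset$intensity),
       length(unique(ann$gene_symbol[ann$probe_id %in%
                                       rownames(eset$intensity)])),
       nrow(eset$samples))
  sel <- select_probes(eset, ann)                                   # 3
  eset <- sel$eset
  note("select_probes", nrow(eset$intensity), nrow(eset$intensity),
       nrow(eset$samples))
  assignment <- match_samples_to_mask(eset$samples, mask,             # 4
                                      max_distance_mm, left_only)
  keep <- eset$samples$sample_id %in% assignment$sample_id
  eset$samples <- eset$samples[keep, , drop = FALSE]
  eset$intensity <- eset$intensity[, keep, drop = FALSE]
  note("match_samples", nrow(eset$intensity), nrow(eset$intensity),
       nrow(eset$samples))
  donors <- eset$samples$donor
  mat <- handle_missing(eset$intensity, donors, missing_threshold)  # 5
  note("handle_missing", nrow(mat), nrow(mat), ncol(mat))
  mat <- normalize_expression(mat, donors)                          # 6+7
  note("normalize", nrow(mat), nrow(mat), ncol(mat))
  gbs <- aggregate_and_stabilize(mat, eset$samples, assignment,     # 8+9
                                 stability_threshold)
  note("stabilize", nrow(gbs$matrix), nrow(gbs$matrix),
       ncol(gbs$matrix))
  structure(list(matrix = gbs, assignment = assignment,
                 selection = sel$selection, provenance = prov),
            class = "expression_prep")
}
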