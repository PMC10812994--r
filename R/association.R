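#' Extract t-values at matched sample features
#'
#' Returns the t-map value at each feature's assigned voxel, in feature
#' (column) order of the expression matrix, forming the t-value vector
#' the gene profiles are correlated against.
#'
#' @param tmap A [stat_map()].
#' @param features Feature table from [aggregate_and_stabilize()] (column
#'   `voxel` of linear array indices), or an assignment data.frame with a
#'   `voxel` column.
#' @return Numeric vector of t-values (length = number of features), with
#'   the voxel indices as names.
#' @export
extract_t_at_samples <- function(tmap, features) {
  stopifnot(inherits(tmap, "stat_map"))
  vox <- features$voxel
  stopifnot(all(vox >= 1), all(vox <= length(tmap$values)))
  tv <- tmap$values[vox]
  if (anyNA(tv))
    stop("extract_t_at_samples: feature voxel outside the statistic mask")
  stats::setNames(tv, vox)
}

#' Mass Pearson correlation of gene profiles against a t-vector
#'
#' Per gene: Pearson r and the two-sided p-value from the t-distribution
#' with n - 2 degrees of freedom. Constant genes are flagged undefined and
#' excluded from testing.
#'
#' @param mat Genes x features matrix (a `gene_by_sample_matrix` is
#'   accepted).
#' @param tvec Numeric t-value vector, one entry per feature column.
#' @return Data.frame `gene`, `r`, `p`, `direction` (+1/-1), `tested`;
#'   untested (constant) genes carry `NA` r/p.
#' @export
mass_correlation <- function(mat, tvec) {
  if (inherits(mat, "gene_by_sample_matrix")) mat <- mat$matrix
  n <- ncol(mat)
  stopifnot(length(tvec) == n)
  if (n < 3L) stop("mass_correlation: need at least 3 features")
  tc <- tvec - mean(tvec)
  st <- sqrt(sum(tc^2))
  M <- mat - rowMeans(mat)
  sg <- sqrt(rowSums(M^2))
  tested <- sg > 0 & st > 0
  r <- rep(NA_real_, nrow(mat))
  r[tested] <- (M[tested, , drop = FALSE] %*% tc) / (sg[tested] * st)
  r <- pmin(1, pmax(-1, r))
  p <- rep(NA_real_, nrow(mat))
  tt <- r[tested] * sqrt((n - 2) / pmax(1 - r[tested]^2,
                                        .Machine$double.eps))
  p[tested] <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  n_const <- sum(!tested)
  if (n_const) stage_log("mass_correlation",
                         "%d constant gene(s) excluded", n_const)
  data.frame(gene = rownames(mat), r = r, p = p,
             direction = sign(r), tested = tested,
             stringsAsFactors = FALSE)
}

#' Dual-criterion gene selection
#'
#' A gene is selected iff its Bonferroni-corrected p-value passes
#' (`p < alpha / n_tests`) and its absolute correlation exceeds `r_min` —
#' the conjunction rule used for imaging-transcriptomics screens.
#'
#' @param associations Data.frame from [mass_correlation()].
#' @param alpha Family-wise alpha before correction (default 0.01).
#' @param r_min Minimum absolute Pearson r (default 0.2).
#' @param n_tests Bonferroni denominator; defaults to the number of genes
#'   actually tested.
#' @return The associations data.frame with a logical `passes` column and
#'   attribute `p_threshold` (the per-test threshold).
#' @export
dual_threshold <- function(associations, alpha = 0.01, r_min = 0.2,
                           n_tests = NULL) {
  if (is.null(n_tests)) n_tests <- sum(associations$tested)
  thr <- alpha / n_tests
  passes <- !is.na(associations$p) & associations$p < thr &
    abs(associations$r) > r_min
  associations$passes <- passes
  structure(associations, p_threshold = thr)
}

#' Top positively and negatively correlated genes
#'
#' @param associations Data.frame from [dual_threshold()] (only rows with
#'   `passes` are ranked).
#' @param top_k Genes per direction (default 5).
#' @return List with `positive` and `negative` character vectors, sorted
#'   by r descending / ascending; ties break lexicographically.
#' @export
rank_genes <- function(associations, top_k = 5L) {
  sel <- associations[associations$passes %in% TRUE, , drop = FALSE]
  pos <- sel[sel$r > 0, , drop = FALSE]
  neg <- sel[sel$r < 0, , drop = FALSE]
  pos <- pos[order(-pos$r, pos$gene), , drop = FALSE]
  neg <- neg[order(neg$r, neg$gene), , drop = FALSE]
  list(positive = utils::head(pos$gene, top_k),
       negative = utils::head(neg$gene, top_k))
}

#' Intersect two selected-gene lists
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @return Sorted character vector of the intersection (the "crossover"
#'   genes shared by both modalities).
#' @export
intersect_gene_lists <- function(list_a, list_b) {
  sort(intersect(unique(list_a), unique(list_b)))
}

#' Selected genes of an association table
#' @param associations Data.frame from [dual_threshold()].
#' @return Character vector of genes with `passes == TRUE`.
#' @export
selected_genes <- function(associations) {
  associations$gene[associations$passes %in% TRUE]
}
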