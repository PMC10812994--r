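make_eset <- function(n_genes = 40, n_true = 5, n_samples = 60,
                      seed = 21, ...) {
  mask <- small_mask()
  truth <- expression_truth(n_genes = n_genes, n_true = n_true, ...)
  set.seed(seed + 1)
  eff <- as_volume3d(neurotx:::smooth_3d_plain(
    array(rnorm(prod(mask$grid$shape)), mask$grid$shape), c(3, 3, 3), 9),
    mask)
  list(mask = mask, truth = truth,
       eset = generate_expression_samples(mask, truth, eff, n_samples,
                                          seed = seed))
}

test_that("probe reannotation revises stale symbols and drops unmapped", {
  ann <- data.frame(probe_id = c("P1", "P2", "P3"),
                    gene_symbol = c("A_OLD", "B", "C"),
                    stringsAsFactors = FALSE)
  cur <- data.frame(probe_id = c("P1", "P2"),
                    gene_symbol = c("A", "B"), stringsAsFactors = FALSE)
  out <- reannotate_probes(ann, cur)
  expect_equal(out$gene_symbol, c("A", "B"))
  expect_equal(out$is_current, c(FALSE, TRUE))
  expect_equal(attr(out, "n_dropped"), 1L)
  # identity map leaves everything unchanged
  idm <- data.frame(probe_id = ann$probe_id,
                    gene_symbol = ann$gene_symbol,
                    stringsAsFactors = FALSE)
  out2 <- reannotate_probes(ann, idm)
  expect_equal(out2$gene_symbol, ann$gene_symbol)
  expect_true(all(out2$is_current))
  expect_error(reannotate_probes(ann, cur[0, ]), "no probes")
})

test_that("intensity filter implements the min-fraction threshold", {
  fx <- make_eset()
  planted <- fx$eset$planted_low
  filt <- intensity_filter(fx$eset, 0.5)
  expect_true(all(!planted %in% rownames(filt$intensity)))
  expect_true(all(setdiff(rownames(fx$eset$intensity), planted) %in%
                    rownames(filt$intensity)))
  # 40% above background at threshold 0.5 -> dropped; 50% kept
  es <- fx$eset
  es$intensity <- matrix(c(rep(100, 4), rep(10, 6),
                           rep(100, 5), rep(10, 5)),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("p40", "p50"), NULL))
  es$background <- c(p40 = 40, p50 = 40)
  keep <- intensity_filter(es, 0.5)
  expect_identical(rownames(keep$intensity), "p50")
  es$background <- c(p40 = 1e9, p50 = 1e9)
  expect_error(intensity_filter(es), "all probes")
})

test_that("probe selection prefers the stable probe and breaks ties
           lexicographically", {
  mask <- small_mask()
  set.seed(9)
  n_samples <- 90
  lin <- which(mask$inside)
  pick <- sort(sample(lin, n_samples))
  xyz <- voxel_to_world(mask$grid, arrayInd(pick, dim(mask$inside)) - 1L)
  donors <- sprintf("donor%d", ((seq_len(n_samples) - 1L) %% 3L) + 1L)
  structure_tag <- neurotx:::structure_labels(mask)[pick]
  samples <- data.frame(sample_id = sprintf("S%03d", 1:n_samples),
                        donor = donors, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], structure = structure_tag,
                        voxel = pick, stringsAsFactors = FALSE)
  pattern <- neurotx:::smooth_3d_plain(
    array(rnorm(prod(mask$grid$shape)), mask$grid$shape),
    c(3, 3, 3), 15)[pick]
  wins <- 0
  nrep <- 20
  for (r in seq_len(nrep)) {
    set.seed(100 + r)
    sig <- 100 + 10 * pattern + 0.5 * rnorm(n_samples)
    noise <- 100 + 10 * rnorm(n_samples)
    eset <- structure(list(
      samples = samples,
      intensity = rbind(PA_noise = noise, PB_signal = sig),
      background = c(PA_noise = 0, PB_signal = 0)),
      class = "expression_sample_set")
    ann <- data.frame(probe_id = c("PA_noise", "PB_signal"),
                      gene_symbol = c("G1", "G1"),
                      stringsAsFactors = FALSE)
    sel <- select_probes(eset, ann)
    if (sel$selection$probe_id == "PB_signal") wins <- wins + 1
  }
  expect_gte(wins / nrep, 0.95)
  # exact tie -> lexicographically smaller probe id
  eset <- structure(list(
    samples = samples,
    intensity = rbind(PB = rep(1:3, 30), PA = rep(1:3, 30)),
    background = c(PB = 0, PA = 0)), class = "expression_sample_set")
  ann <- data.frame(probe_id = c("PB", "PA"),
                    gene_symbol = c("G1", "G1"), stringsAsFactors = FALSE)
  sel <- select_probes(eset, ann)
  expect_equal(sel$selection$probe_id, "PA")
  # single-probe gene keeps its probe
  ann1 <- data.frame(probe_id = "PB", gene_symbol = "G9",
                     stringsAsFactors = FALSE)
  expect_equal(select_probes(eset, ann1)$selection$probe_id, "PB")
})

test_that("sample matching assigns nearest in-mask voxel within
           tolerance", {
  mask <- small_mask()
  vox <- mask_voxels(mask)
  ctr <- voxel_to_world(mask$grid, vox[10, , drop = FALSE])
  samples <- data.frame(
    sample_id = c("exact", "far"),
    x = c(ctr[1], 100), y = c(ctr[2], 100), z = c(ctr[3], 100),
    stringsAsFactors = FALSE)
  asn <- match_samples_to_mask(samples, mask, max_distance_mm = 2)
  expect_equal(asn$sample_id, "exact")
  expect_equal(asn$distance_mm, 0, tolerance = 1e-10)
  expect_equal(asn$voxel, which(mask$inside)[10])
  expect_equal(attr(asn, "n_dropped"), 1L)
  # hemisphere filter keeps exactly the x < 0 half of a symmetric set
  xs <- c(-9, -3, 3, 9)
  sym <- data.frame(sample_id = paste0("s", 1:4), x = xs, y = 0, z = 0,
                    stringsAsFactors = FALSE)
  left <- match_samples_to_mask(sym, mask, max_distance_mm = 3,
                                left_only = TRUE)
  expect_equal(left$sample_id, c("s1", "s2"))
  expect_error(match_samples_to_mask(samples[2, ], mask, 2),
               "no samples")
})

test_that("missing-data handling drops and imputes per contract", {
  m <- matrix(1:12, 3, 4,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  donors <- c("d1", "d1", "d2", "d2")
  expect_equal(handle_missing(m, donors), m)
  m2 <- m * 1.0
  m2[1, 2] <- NA                      # one missing -> donor median
  out <- handle_missing(m2, donors)
  expect_equal(unname(out[1, 2]), unname(m2[1, 1]))
  m3 <- m * 1.0
  m3[2, 1:3] <- NA                    # 75% missing at threshold 0.5
  out3 <- handle_missing(m3, donors)
  expect_false("g2" %in% rownames(out3))
})

test_that("scaled-robust-sigmoid normalization is bounded, monotone and
           invariant to per-donor affine rescaling", {
  set.seed(10)
  m <- matrix(rnorm(30 * 20, 100, 15), 30,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  donors <- rep(c("d1", "d2"), each = 10)
  nm <- normalize_expression(m, donors)
  expect_true(all(nm >= 0 & nm <= 1))
  # gene-wise ranking within donor preserved by the gene pass
  gn <- normalize_expression(m, donors, sample_norm = FALSE)
  for (g in c(1, 15)) {
    expect_equal(order(gn[g, donors == "d1"]),
                 order(m[g, donors == "d1"]))
  }
  # affine rescaling of one donor's raw intensities changes nothing
  m2 <- m
  m2[, donors == "d2"] <- 3.7 * m2[, donors == "d2"] + 55
  expect_equal(normalize_expression(m2, donors),
               normalize_expression(m, donors), tolerance = 1e-12)
  # direct recomputation oracle on one column
  sm <- normalize_expression(m, donors, gene_norm = FALSE)
  expect_equal(unname(sm[, 4]), unname(oracle_srs(m[, 4])),
               tolerance = 1e-12)
  # constant gene flagged to 0.5
  m3 <- rbind(m, constant = rep(5, 20))
  nm3 <- normalize_expression(m3, donors)
  expect_true(all(nm3["constant", ] == 0.5))
})

test_that("aggregation averages co-located samples and drops unstable
           genes", {
  fx <- make_eset(n_genes = 60, n_true = 10, n_samples = 90)
  prep <- prep_expression(fx$eset, fx$mask)
  # provenance counts are recorded for every step, non-increasing probes
  pv <- prep$provenance
  expect_true(all(c("reannotate", "intensity_filter", "select_probes",
                    "match_samples", "handle_missing", "normalize",
                    "stabilize") %in% names(pv)))
  probes <- sapply(pv, `[[`, "probes")
  expect_true(all(diff(probes[c("input", "reannotate",
                                "intensity_filter",
                                "select_probes")]) <= 0))
  expect_false(anyNA(prep$matrix$matrix))
  expect_false(any(duplicated(rownames(prep$matrix$matrix))))

  # two co-located samples average into one feature
  mat <- matrix(c(1, 3, 10), 1, dimnames = list("g1", NULL))
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        donor = "d1", structure = "B111",
                        stringsAsFactors = FALSE)
  asn <- data.frame(sample_id = c("a", "b", "c"),
                    voxel = c(5L, 5L, 9L), distance_mm = 0,
                    stringsAsFactors = FALSE)
  agg <- aggregate_and_stabilize(mat, samples, asn,
                                 stability_threshold = -Inf)
  expect_equal(unname(agg$matrix[1, ]), c(2, 10))

  # planted perfectly stable gene: same pattern in all donors -> DS ~ 1
  set.seed(11)
  ns <- 180
  donors <- rep(c("d1", "d2", "d3"), 60)
  structs <- rep(sprintf("st%d", 1:20), each = 9)
  pat <- rnorm(20)[match(structs, sprintf("st%d", 1:20))]
  stable_g <- pat + rnorm(ns, sd = 0.01)
  noise_g <- rnorm(ns)
  mat2 <- rbind(stable = stable_g, pure_noise = noise_g)
  samples2 <- data.frame(sample_id = sprintf("s%02d", 1:ns),
                         donor = donors, structure = structs,
                         stringsAsFactors = FALSE)
  asn2 <- data.frame(sample_id = samples2$sample_id,
                     voxel = seq_len(ns), distance_mm = 0,
                     stringsAsFactors = FALSE)
  agg2 <- aggregate_and_stabilize(mat2, samples2, asn2,
                                  stability_threshold = 0.2)
  expect_true("stable" %in% rownames(agg2$matrix))
  expect_gte(agg2$stability["stable"], 0.9)
  expect_false("pure_noise" %in% rownames(agg2$matrix))
})

test_that("planted-truth end-to-end: true genes survive preprocessing", {
  mask <- make_mask()
  effmap <- as_volume3d(reference_tmap_values(mask), mask)
  truth <- expression_truth(n_genes = 400, n_true = 40)
  eset <- generate_expression_samples(mask, truth, effmap, 300,
                                      seed = 77)
  prep <- prep_expression(eset, mask)
  surv <- mean(truth$true_gene_ids %in% rownames(prep$matrix$matrix))
  expect_gte(surv, 0.9)
})
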