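#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzipped) into the package's spatial
#' containers. 3D files become a plain volume (grid + array); 4D files
#' become a [time_series_image()] with the repetition time taken from the
#' header. World coordinates follow the file's sform/qform affine, adjusted
#' to the package's 0-based voxel convention.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param mask Optional [binary_mask()] to attach; defaults to an all-inside
#'   mask. A validation warning is raised if the data contain non-finite
#'   values inside the mask.
#' @return For 4D input a [time_series_image()]; for 3D input a list with
#'   fields `grid` and `values` (class `volume3d`).
#' @export
read_volume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (!(length(dims) %in% c(3L, 4L)))
    stop("read_volume: expected a 3D or 4D NIfTI volume, got ",
         length(dims), "D")
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  # RNifti's xform maps R's 1-based indices shifted: its convention is
  # 0-based voxel -> world, matching ours.
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- volume_grid(dims[1:3], vs, affine = aff)
  if (is.null(mask)) {
    mask <- binary_mask(grid, array(TRUE, dims[1:3]))
  }
  arr <- array(as.numeric(img), dim = dims)
  if (length(dims) == 4L) {
    tr <- as.numeric(img$pixdim[5])
    if (!is.finite(tr) || tr <= 0) tr <- 1
    flat <- matrix(arr, ncol = dims[4])
    if (!all(is.finite(flat[as.vector(mask$inside), ])))
      warning("read_volume: non-finite voxels inside mask")
    time_series_image(grid, arr, tr, mask)
  } else {
    if (!all(is.finite(arr[mask$inside])))
      warning("read_volume: non-finite voxels inside mask")
    structure(list(grid = grid, values = arr, mask = mask),
              class = "volume3d")
  }
}

#' Write a volume to NIfTI
#'
#' @param x A [time_series_image()], [stat_map()], `volume3d`, or a plain
#'   3D/4D array (then `grid` must be given).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid A [volume_grid()]; required when `x` is a bare array.
#' @param tr_seconds Repetition time stored in the header for 4D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL, tr_seconds = NULL) {
  if (inherits(x, "time_series_image")) {
    grid <- x$grid; tr_seconds <- x$tr_seconds; arr <- x$data
  } else if (inherits(x, c("stat_map", "volume3d"))) {
    grid <- x$grid; arr <- x$values
  } else {
    stopifnot(!is.null(grid))
    arr <- x
  }
  img <- RNifti::asNifti(arr)
  # sform alone carries the full affine; setting the qform as well makes
  # the writer re-derive spacings from the (unit) pixdim and lose them
  img <- RNifti::`sform<-`(img, value = structure(grid$affine,
                                                  code = 2L))
  if (length(dim(arr)) == 4L && !is.null(tr_seconds))
    img$pixdim[5] <- tr_seconds
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a subject design table
#'
#' Expects a tab-separated file with header columns `subject_id`, `group`
#' (`case` / `control`), `age`, `sex` (`male` / `female`), `education`,
#' `bmi`. One record per subject; subject ids must be unique.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per subject and validated columns.
#' @export
read_design_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "education", "bmi")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("read_design_table: missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df[, required])
  if (anyDuplicated(df$subject_id))
    stop("read_design_table: duplicated subject_id")
  if (!all(df$group %in% c("case", "control")))
    stop("read_design_table: group must be 'case' or 'control'")
  if (!all(df$sex %in% c("male", "female")))
    stop("read_design_table: sex must be 'male' or 'female'")
  for (col in c("age", "education", "bmi")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.finite(v)))
      stop("read_design_table: non-numeric value in column ", col)
    df[[col]] <- v
  }
  df[, required]
}

#' Write a design table
#' @param design Data.frame as returned by [read_design_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  write_tsv(design, path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated. Members are uppercased and deduplicated; empty sets and
#' duplicated set names are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene symbols; the
#'   `description` attribute carries the per-set description strings.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), description = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("read_gene_sets: line(s) with no members: ",
         paste(which(bad), collapse = ", "))
  names_ <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop("read_gene_sets: duplicate set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- names_
  structure(sets, description = stats::setNames(desc, names_))
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description strings.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

# Fixed-format TSV writer: 6 significant digits for doubles, no quoting.
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- signif(df[[col]], 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Per-stage structured logging; verbosity toggled by option neurotx.verbose.
stage_log <- function(stage, ...) {
  if (isTRUE(getOption("neurotx.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  invisible(NULL)
}

#' Write an expression sample set as TSV files
#'
#' Emits `samples.tsv`, `intensity.tsv` (probe x sample), `background.tsv`,
#' `annotation.tsv` and `current_annotation.tsv` under `dir`.
#'
#' @param eset An `expression_sample_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_sample_set <- function(eset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(eset$samples, file.path(dir, "samples.tsv"))
  intens <- data.frame(probe_id = rownames(eset$intensity),
                       eset$intensity, check.names = FALSE)
  write_tsv(intens, file.path(dir, "intensity.tsv"))
  write_tsv(data.frame(probe_id = names(eset$background),
                       background = unname(eset$background)),
            file.path(dir, "background.tsv"))
  write_tsv(eset$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(eset$current_map, file.path(dir, "current_annotation.tsv"))
  invisible(dir)
}

#' Read an expression sample set from TSV files
#'
#' Counterpart of [write_expression_sample_set()].
#'
#' @param dir Directory containing the five TSV files.
#' @return An `expression_sample_set` (without generator ground truth).
#' @export
read_expression_sample_set <- function(dir) {
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  intens <- read_tsv(file.path(dir, "intensity.tsv"))
  probe_id <- intens$probe_id
  mat <- as.matrix(intens[, -1, drop = FALSE])
  rownames(mat) <- probe_id
  colnames(mat) <- samples$sample_id
  bg <- read_tsv(file.path(dir, "background.tsv"))
  structure(list(samples = samples, intensity = mat,
                 background = stats::setNames(bg$background, bg$probe_id),
                 annotation = read_tsv(file.path(dir, "annotation.tsv")),
                 current_map = read_tsv(file.path(dir,
                                                  "current_annotation.tsv"))),
            class = "expression_sample_set")
}
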