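# Reading/writing image datasets and assembling the snapshot, transition
# and control matrices used by the eigenmode decompositions.

#' Write an aerosol image dataset to a directory
#'
#' Writes one greyscale PNG per image plus `manifest.csv` (columns:
#' filename, class_label, flow_rate_L_min, particle_size_um, replicate,
#' seed). If the dataset carries ground truth it is serialized alongside
#' as a single archive `ground_truth.rds`.
#'
#' PNG files are 8-bit, so pixel values are quantized to the 256-level
#' grid on writing (values are clamped to \[0, 1\]). A write/read
#' round-trip is exact for images already on that grid; fresh
#' double-precision images are reproduced to within 1/255. Numeric
#' invariants of the planted dynamics are defined on the in-memory
#' generator output, which is lossless.
#'
#' @param dataset an `aerosol_dataset` (see [generate_dataset()]).
#' @param directory output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  abort_if(!inherits(dataset, "aerosol_dataset"),
           "dataset must be an aerosol_dataset")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- dim(dataset$images)[3]
  for (i in seq_len(n)) {
    img <- pmin(pmax(dataset$images[, , i], 0), 1)
    png::writePNG(img, file.path(directory, dataset$manifest$filename[i]))
  }
  utils::write.csv(dataset$manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$ground_truth)) {
    saveRDS(dataset$ground_truth, file.path(directory, "ground_truth.rds"))
  }
  invisible(dataset$manifest)
}

#' Read an aerosol image dataset from a directory
#'
#' Reads `manifest.csv` and the PNG images it references; restores the
#' ground-truth archive if present. Pixel values and metadata round-trip
#' exactly for datasets written by [write_dataset()] whose images lie on
#' the 8-bit grid.
#'
#' @param directory dataset directory containing `manifest.csv`.
#' @return an `aerosol_dataset`.
#' @export
read_dataset <- function(directory) {
  manifest_path <- file.path(directory, "manifest.csv")
  abort_if(!file.exists(manifest_path), "no manifest found at %s",
           manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("filename", "class_label", "flow_rate_L_min",
                "particle_size_um", "replicate", "seed")
  missing_cols <- setdiff(required, names(manifest))
  abort_if(length(missing_cols) > 0, "manifest lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(manifest$class_label), CLASS_LABELS)
  abort_if(length(bad) > 0, "unknown class label(s): %s",
           paste(bad, collapse = ", "))
  key <- with(manifest, paste(class_label, flow_rate_L_min,
                              particle_size_um, replicate))
  abort_if(anyDuplicated(key) > 0,
           "duplicate (class, condition) key(s): %s",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  paths <- file.path(directory, manifest$filename)
  absent <- !file.exists(paths)
  abort_if(any(absent), "missing image file(s): %s",
           paste(manifest$filename[absent], collapse = ", "))

  first <- png::readPNG(paths[1])
  if (length(dim(first)) == 3L) first <- first[, , 1]
  h <- nrow(first)
  w <- ncol(first)
  images <- array(0, dim = c(h, w, nrow(manifest)))
  images[, , 1] <- first
  for (i in seq_len(nrow(manifest))[-1]) {
    img <- png::readPNG(paths[i])
    if (length(dim(img)) == 3L) img <- img[, , 1]
    abort_if(nrow(img) != h || ncol(img) != w,
             "image %s has size %dx%d, expected %dx%d",
             manifest$filename[i], nrow(img), ncol(img), h, w)
    images[, , i] <- img
  }
  gt_path <- file.path(directory, "ground_truth.rds")
  ground_truth <- if (file.exists(gt_path)) readRDS(gt_path) else NULL
  structure(list(images = images, manifest = manifest,
                 ground_truth = ground_truth, height = h, width = w),
            class = "aerosol_dataset")
}

#' Assemble the disease-progression snapshot matrix
#'
#' Flattens every image row-major into one column and orders columns in
#' the standard arrangement: groups (one per flow rate, particle size and
#' replicate triple) sorted by flow rate, then particle size, then
#' replicate ascending, and the five images of each group stacked in the
#' disease-progression sequence A0 to A4. Input order is irrelevant — the
#' assembly canonicalizes it. Incomplete groups are rejected.
#'
#' @param dataset an `aerosol_dataset`.
#' @return An object of class `snapshot_matrix`: list with `values`
#'   (`n_pixels x n_snapshots` matrix), `columns` (per-column metadata:
#'   group, stage 0-4, class_label, flow_rate, particle_size, replicate),
#'   `height`, `width`.
#' @export
assemble_snapshots <- function(dataset) {
  abort_if(!inherits(dataset, "aerosol_dataset"),
           "dataset must be an aerosol_dataset")
  m <- dataset$manifest
  stage <- match(m$class_label, CLASS_LABELS) - 1L
  abort_if(anyNA(stage), "unknown class label(s): %s",
           paste(unique(m$class_label[is.na(stage)]), collapse = ", "))
  ord <- order(m$flow_rate_L_min, m$particle_size_um, m$replicate, stage)
  m <- m[ord, , drop = FALSE]
  stage <- stage[ord]
  gkey <- paste(m$flow_rate_L_min, m$particle_size_um, m$replicate)
  group <- match(gkey, unique(gkey))

  # every group must contain exactly the five stages
  for (g in unique(group)) {
    got <- sort(stage[group == g])
    if (!identical(got, 0:4)) {
      missing_stages <- setdiff(0:4, got)
      cond <- m[group == g, ][1, ]
      stop(sprintf(
        "incomplete group (flow %s L/min, size %s um, replicate %s): missing class %s",
        cond$flow_rate_L_min, cond$particle_size_um, cond$replicate,
        paste(CLASS_LABELS[missing_stages + 1L], collapse = ", ")),
        call. = FALSE)
    }
  }

  npix <- dataset$height * dataset$width
  values <- matrix(0, npix, nrow(m))
  for (j in seq_len(nrow(m))) {
    values[, j] <- as.vector(t(dataset$images[, , ord[j]]))
  }
  columns <- data.frame(group = group, stage = stage,
                        class_label = m$class_label,
                        flow_rate = m$flow_rate_L_min,
                        particle_size = m$particle_size_um,
                        replicate = m$replicate,
                        stringsAsFactors = FALSE)
  structure(list(values = values, columns = columns,
                 height = dataset$height, width = dataset$width),
            class = "snapshot_matrix")
}

#' @export
print.snapshot_matrix <- function(x, ...) {
  cat(sprintf("snapshot_matrix: %d pixels x %d snapshots (%d groups)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$columns$group))))
  invisible(x)
}

#' Extract the numeric matrix from a snapshot matrix or pass one through
#' @noRd
snapshot_values <- function(x) {
  if (inherits(x, "snapshot_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a snapshot_matrix or a numeric matrix", call. = FALSE)
}

#' Mean image of a snapshot matrix
#'
#' The arithmetic mean across columns — the "averaged image" of the whole
#' database that carries its shared background structure.
#'
#' @param x a `snapshot_matrix` or numeric matrix with one image per
#'   column.
#' @return numeric vector of length `n_pixels`.
#' @export
mean_image <- function(x) {
  v <- snapshot_values(x)
  abort_if(ncol(v) == 0, "snapshot matrix has no columns")
  rowMeans(v)
}

#' Center a snapshot matrix by its mean image
#'
#' Subtracts [mean_image()] from every column, producing the
#' variance-from-mean matrix that principal component analysis operates
#' on. Row means of the result are zero.
#'
#' @param x a `snapshot_matrix` (metadata is preserved) or numeric matrix.
#' @return same type as the input, centered.
#' @export
center_snapshots <- function(x) {
  v <- snapshot_values(x)
  abort_if(ncol(v) == 0, "snapshot matrix has no columns")
  centered <- v - rowMeans(v)
  if (inherits(x, "snapshot_matrix")) {
    x$values <- centered
    x
  } else {
    centered
  }
}

#' Split a snapshot matrix into before/after transition matrices
#'
#' Within each disease-progression group, the "before" matrix takes
#' stages A0-A3 and the "after" matrix stages A1-A4, so column `k` of the
#' after matrix is the same snapshot group one stage later than column
#' `k` of the before matrix. Columns remain group-contiguous; both
#' matrices have `4 * n_groups` columns. The columns are exact views of
#' the input columns (no recomputation).
#'
#' @param x a `snapshot_matrix` with complete groups of 5 stages.
#' @return list of class `transition_pair` with elements `x_prime`
#'   (stages 0-3) and `x_dprime` (stages 1-4), both `snapshot_matrix`
#'   objects.
#' @export
split_transitions <- function(x) {
  abort_if(!inherits(x, "snapshot_matrix"),
           "x must be a snapshot_matrix (column metadata is required)")
  cols <- x$columns
  sizes <- table(cols$group)
  bad <- names(sizes)[sizes != N_STAGES]
  abort_if(length(bad) > 0,
           "group(s) %s do not have exactly %d stages",
           paste(bad, collapse = ", "), N_STAGES)
  # columns are stage-ordered within contiguous groups after assembly
  ord <- order(cols$group, cols$stage)
  abort_if(!identical(ord, seq_len(nrow(cols))),
           "snapshot columns are not in canonical group/stage order; use assemble_snapshots()")
  take <- function(keep) {
    structure(list(values = x$values[, keep, drop = FALSE],
                   columns = cols[keep, , drop = FALSE],
                   height = x$height, width = x$width),
              class = "snapshot_matrix")
  }
  structure(list(x_prime = take(cols$stage <= 3L),
                 x_dprime = take(cols$stage >= 1L)),
            class = "transition_pair")
}

#' Build the control matrix aligned with a transition split
#'
#' For the transition into stage `s+1` of group `g`, the control column
#' is `(particle_size(g), flow_rate(g), severity(s+1))` — the input that
#' produced the new state. Severity is the dimensionless constriction
#' fraction of the target class (see [airway_disease_specs()]). With
#' `standardize = TRUE` (default) each row is scaled to mean 0, sd 1;
#' the three controls differ by orders of magnitude (0.2 um particle
#' sizes vs 33 L/min flow rates), so unstandardized controls would let
#' one input dominate the regression. Constant rows are centered and
#' left at zero (no division), with a message.
#'
#' @param split a `transition_pair` from [split_transitions()].
#' @param standardize standardize rows? Default `TRUE`.
#' @return An object of class `control_matrix`: list with `values`
#'   (`3 x n_transitions`), `center`, `scale`, `standardized`.
#' @export
build_control_matrix <- function(split, standardize = TRUE) {
  abort_if(!inherits(split, "transition_pair"),
           "split must come from split_transitions()")
  meta <- split$x_dprime$columns
  abort_if(anyNA(meta$particle_size) || anyNA(meta$flow_rate) ||
             anyNA(meta$class_label),
           "transition metadata is incomplete")
  specs <- airway_disease_specs()
  sev <- specs$severity[match(meta$class_label, specs$label)]
  raw <- rbind(particle_size = meta$particle_size,
               flow_rate = meta$flow_rate,
               severity = sev)
  if (standardize) {
    std <- standardize_rows(raw)
    structure(list(values = std$values, center = std$center,
                   scale = std$scale, standardized = TRUE),
              class = "control_matrix")
  } else {
    structure(list(values = raw, center = rep(0, 3), scale = rep(1, 3),
                   standardized = FALSE),
              class = "control_matrix")
  }
}

#' @noRd
control_values <- function(y) {
  if (inherits(y, "control_matrix")) y$values
  else if (is.matrix(y)) y
  else stop("expected a control_matrix or a numeric matrix", call. = FALSE)
}
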