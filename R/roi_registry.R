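#' ROI registries
#'
#' An ROI registry is a tibble with one row per region of interest and the
#' columns `name`, `network` (one of `"MVN"`, `"DMN"`, `"control"`), sphere
#' definition (`x`, `y`, `z` center in MNI mm and `radius_mm`) or a
#' `mask_path` pointing at a binary NIfTI volume, a free-text `note`, and a
#' logical `synthetic` flag marking sphere centers that are simulation
#' stand-ins rather than literature coordinates. The target voxel grid is
#' attached as the `grid` attribute.
#'
#' The packaged default registry holds the 16 regions used for resting-state
#' network analysis: 8 in the motor/visuospatial network (MVN: bilateral M1,
#' SMA, IPS, FEF), 4 in the default mode network (DMN: bilateral LP, PCC,
#' MPF), and 4 control regions (bilateral V1 and A1). IPS, FEF, LP, PCC and
#' MPF carry their published sphere centers; M1, SMA, V1 and A1 are
#' anatomically defined regions (Brodmann areas) for which the registry ships
#' synthetic sphere centers so that simulations can voxelize them — for real
#' data, supply Brodmann masks via `mask_path` instead.
#'
#' @param rois a data frame with the columns described above (missing
#'   optional columns are filled).
#' @param grid target [vol_grid()].
#' @return A `cf_registry` tibble.
#' @seealso [load_roi_registry()], [voxelize_roi()], [partition_network_pairs()]
#' @export
roi_registry <- function(rois, grid = default_grid()) {
  rois <- tibble::as_tibble(rois)
  stopifnot(all(c("name", "network") %in% names(rois)))
  for (col in c("x", "y", "z", "radius_mm")) {
    if (!col %in% names(rois)) rois[[col]] <- NA_real_
  }
  if (!"mask_path" %in% names(rois)) rois$mask_path <- NA_character_
  if (!"note" %in% names(rois)) rois$note <- NA_character_
  if (!"synthetic" %in% names(rois)) rois$synthetic <- FALSE
  rois$mask_path <- as.character(rois$mask_path)
  rois$note <- as.character(rois$note)
  rois$synthetic <- as.logical(rois$synthetic)
  rois <- rois[, c("name", "network", "x", "y", "z", "radius_mm",
                   "mask_path", "note", "synthetic")]

  if (anyDuplicated(rois$name)) {
    dup <- unique(rois$name[duplicated(rois$name)])
    stop("duplicate ROI name(s): ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(rois$network), c("MVN", "DMN", "control"))
  if (length(bad) > 0) {
    stop("unknown network label(s): ", paste(bad, collapse = ", "),
         " (expected MVN, DMN or control)")
  }
  sphere <- !is.na(rois$x)
  if (any(sphere & (!is.finite(rois$x) | !is.finite(rois$y) | !is.finite(rois$z)))) {
    stop("malformed sphere center coordinates")
  }
  if (any(sphere & !(rois$radius_mm > 0))) {
    stop("sphere-defined ROIs need radius_mm > 0")
  }
  if (any(!sphere & is.na(rois$mask_path))) {
    stop("each ROI needs either a sphere center (x, y, z) or a mask_path")
  }
  structure(rois, grid = grid, class = c("cf_registry", class(rois)))
}

#' @export
print.cf_registry <- function(x, ...) {
  cat(sprintf("<cf_registry> %d ROIs (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$network)), table(x$network)),
                    collapse = ", ")))
  NextMethod()
}

registry_grid <- function(registry) {
  g <- attr(registry, "grid")
  if (is.null(g)) default_grid() else g
}

# The 16-ROI table: published sphere centers where available; synthetic
# stand-in centers for the Brodmann-defined regions (flagged).
default_roi_table <- function(radius_mm = 7.5) {
  tibble::tribble(
    ~name, ~network, ~x,  ~y,   ~z,  ~note,                          ~synthetic,
    "lM1",  "MVN",   -38, -22,  54,  "Left primary motor cortex (Area 4)",      TRUE,
    "rM1",  "MVN",    38, -22,  54,  "Right primary motor cortex (Area 4)",     TRUE,
    "lSMA", "MVN",    -6,  -8,  58,  "Left supplementary motor area (Area 6)",  TRUE,
    "rSMA", "MVN",     6,  -8,  58,  "Right supplementary motor area (Area 6)", TRUE,
    "lIPS", "MVN",   -25, -57,  46,  "Left intra-parietal sulcus",              FALSE,
    "rIPS", "MVN",    25, -57,  46,  "Right intra-parietal sulcus",             FALSE,
    "lFEF", "MVN",   -25, -13,  50,  "Left frontal eye field",                  FALSE,
    "rFEF", "MVN",    25, -13,  50,  "Right frontal eye field",                 FALSE,
    "lLP",  "DMN",   -45, -67,  36,  "Left lateral parietal region",            FALSE,
    "rLP",  "DMN",    45, -67,  36,  "Right lateral parietal region",           FALSE,
    "PCC",  "DMN",    -5, -49,  40,  "Posterior cingulate cortex",              FALSE,
    "MPF",  "DMN",    -1,  47,  -4,  "Medial prefrontal cortex",                FALSE,
    "lV1",  "control", -8, -88,  2,  "Left primary visual cortex (Area 17)",    TRUE,
    "rV1",  "control",  8, -88,  2,  "Right primary visual cortex (Area 17)",   TRUE,
    "lA1",  "control", -47, -22, 10, "Left auditory cortex (Areas 41/42)",      TRUE,
    "rA1",  "control",  47, -22, 10, "Right auditory cortex (Areas 41/42)",     TRUE
  ) |>
    dplyr::mutate(radius_mm = radius_mm, mask_path = NA_character_)
}

#' Load an ROI registry
#'
#' `source = "default"` returns the packaged 16-ROI registry (8 MVN, 4 DMN,
#' 4 control). Otherwise `source` is a path to a TSV with columns `name`,
#' `network`, `x`, `y`, `z`, `radius_mm` and optionally `mask_path`, `note`,
#' `synthetic`.
#'
#' The sphere radius is only published for the left lateral parietal region
#' (7.5 mm); the same radius is used for every sphere ROI by default and can
#' be changed via `radius_mm`.
#'
#' @param source `"default"` or a file path.
#' @param grid target [vol_grid()].
#' @param radius_mm sphere radius (mm) for the default registry.
#' @return A `cf_registry`.
#' @examples
#' reg <- load_roi_registry("default")
#' dplyr::count(reg, network)
#' @export
load_roi_registry <- function(source = "default", grid = default_grid(),
                              radius_mm = 7.5) {
  if (identical(source, "default")) {
    return(roi_registry(default_roi_table(radius_mm), grid))
  }
  if (!file.exists(source)) stop("registry file not found: ", source)
  df <- readr::read_tsv(source, show_col_types = FALSE)
  roi_registry(df, grid)
}

#' Write an ROI registry to TSV
#'
#' @param registry a `cf_registry`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_registry <- function(registry, path) {
  readr::write_tsv(tibble::as_tibble(registry), path)
  invisible(path)
}

#' Voxelize one ROI onto a grid
#'
#' Sphere ROIs contain every voxel whose *center* lies within `radius_mm`
#' (Euclidean distance in mm) of the MNI center; mask ROIs contain the
#' nonzero voxels of the mask volume, whose grid must match `grid`.
#'
#' @param roi a single ROI: one row of a `cf_registry` (or a list with the
#'   same fields).
#' @param grid target [vol_grid()].
#' @return Integer matrix (n x 3) of 0-based voxel indices, with the 1-based
#'   linear index into an array of the grid's shape as attribute `linear`.
#' @examples
#' g <- vol_grid(c(20, 20, 12), c(3, 3, 3.5), c(-30, -30, -21))
#' vox <- voxelize_roi(list(name = "demo", x = 0, y = 0, z = 0, radius_mm = 7.5), g)
#' nrow(vox)
#' @export
voxelize_roi <- function(roi, grid) {
  if (is.data.frame(roi)) {
    stopifnot(nrow(roi) == 1)
    roi <- as.list(roi)
  }
  if (!is.null(roi$mask_path) && !is.na(roi$mask_path)) {
    mask <- RNifti::readNifti(roi$mask_path)
    if (!all(dim(mask)[1:3] == grid$shape)) {
      stop("mask grid ", paste(dim(mask)[1:3], collapse = "x"),
           " does not match target grid ", paste(grid$shape, collapse = "x"),
           " for ROI ", roi$name)
    }
    ijk <- which(array(mask != 0, dim = grid$shape), arr.ind = TRUE) - 1L
  } else {
    center <- c(roi$x, roi$y, roi$z)
    r <- roi$radius_mm
    stopifnot(is.finite(r), r > 0)
    cv <- drop(mni_to_vox(center, grid))
    if (any(cv < -0.5) || any(cv > grid$shape - 0.5)) {
      stop("sphere center (", paste(center, collapse = ", "),
           ") maps outside the grid for ROI ", roi$name)
    }
    # candidate box around the center, then exact distance test
    lo <- pmax(0L, floor(cv - r / grid$vox_mm))
    hi <- pmin(grid$shape - 1L, ceiling(cv + r / grid$vox_mm))
    ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
    mm <- vox_to_mni(ijk, grid)
    d2 <- (mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 + (mm[, 3] - center[3])^2
    ijk <- ijk[d2 <= r^2, , drop = FALSE]
  }
  if (nrow(ijk) == 0) stop("ROI ", roi$name, " contains no voxels on this grid")
  storage.mode(ijk) <- "integer"
  dimnames(ijk) <- list(NULL, c("i", "j", "k"))
  attr(ijk, "linear") <- vox_linear_index(ijk, grid)
  ijk
}

#' Voxelize every ROI of a registry
#'
#' @param registry a `cf_registry`.
#' @param grid target grid; defaults to the registry's own.
#' @return A tibble with one row per (ROI, voxel): `name`, `network`, 0-based
#'   `i`, `j`, `k` and the 1-based `linear` array index.
#' @export
voxelize_registry <- function(registry, grid = registry_grid(registry)) {
  purrr::map_dfr(seq_len(nrow(registry)), function(r) {
    vox <- voxelize_roi(registry[r, ], grid)
    tibble::tibble(name = registry$name[r], network = registry$network[r],
                   i = vox[, 1], j = vox[, 2], k = vox[, 3],
                   linear = attr(vox, "linear"))
  })
}

network_pair_label <- function(net_a, net_b) {
  rank <- c(MVN = 1L, DMN = 2L, control = 3L)
  a <- pmin(rank[net_a], rank[net_b])
  b <- pmax(rank[net_a], rank[net_b])
  lv <- names(rank)
  paste(lv[a], lv[b], sep = "-")
}

#' The six network-pair types
#'
#' Canonical ordering of the unordered network-pair labels used to partition
#' an ROI correlation matrix.
#'
#' @return Character vector of length 6.
#' @export
network_pair_types <- function() {
  c("MVN-MVN", "MVN-DMN", "DMN-DMN", "MVN-control", "DMN-control",
    "control-control")
}

#' Partition ROI pairs into network-pair types
#'
#' Every unordered off-diagonal ROI pair is assigned to exactly one of the six
#' network-pair types (MVN-MVN, MVN-DMN, DMN-DMN, MVN-control, DMN-control,
#' control-control); types absent from the registry yield no rows. For the
#' default 16-ROI registry the type sizes are 28, 32, 6, 32, 16 and 6,
#' summing to 16*15/2 = 120.
#'
#' @param registry a `cf_registry` (any data frame with `name` and `network`
#'   columns works).
#' @return A tibble with columns `roi_a`, `roi_b`, `network_a`, `network_b`,
#'   `pair_type` (factor over [network_pair_types()]), one row per unordered
#'   pair, ordered as the upper triangle of the registry's ROI order.
#' @examples
#' pairs <- partition_network_pairs(load_roi_registry("default"))
#' dplyr::count(pairs, pair_type, .drop = FALSE)
#' @export
partition_network_pairs <- function(registry) {
  n <- nrow(registry)
  if (n < 2) {
    return(tibble::tibble(roi_a = character(), roi_b = character(),
                          network_a = character(), network_b = character(),
                          pair_type = factor(character(),
                                             levels = network_pair_types())))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- idx[, "row"]; b <- idx[, "col"]
  tibble::tibble(
    roi_a = registry$name[a], roi_b = registry$name[b],
    network_a = registry$network[a], network_b = registry$network[b],
    pair_type = factor(network_pair_label(registry$network[a],
                                          registry$network[b]),
                       levels = network_pair_types())
  )
}
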