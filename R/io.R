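#' A 4D BOLD run
#'
#' Container for a 4D voxel time series with its repetition time, grid
#' geometry, optional sidecar confound table and provenance metadata.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param tr_s repetition time (s).
#' @param grid a [vol_grid()] matching the first three dimensions.
#' @param confounds optional per-volume confound table.
#' @param ground_truth optional generator ground truth (simulated runs).
#' @param meta named list (subject, group, session, seed, ...).
#' @return A `cf_bold` object.
#' @export
bold_run <- function(data, tr_s, grid, confounds = NULL, ground_truth = NULL,
                     meta = list()) {
  stopifnot(length(dim(data)) == 4, tr_s > 0,
            all(dim(data)[1:3] == grid$shape))
  structure(list(data = data, tr_s = tr_s, grid = grid,
                 n_volumes = dim(data)[4], confounds = confounds,
                 ground_truth = ground_truth, meta = meta),
            class = "cf_bold")
}

#' @export
print.cf_bold <- function(x, ...) {
  cat(sprintf("<cf_bold> %s voxels x %d volumes, TR %g s\n",
              paste(x$grid$shape, collapse = " x "), x$n_volumes, x$tr_s))
  invisible(x)
}

#' Read a 4D BOLD run from NIfTI-1
#'
#' @param path NIfTI file (optionally gzipped).
#' @param tr_s optional TR override (s); otherwise taken from the header's
#'   pixdim, and an error is raised if the header carries none.
#' @return A [bold_run()]. The grid is taken from the header voxel sizes and
#'   the sform/qform translation (axis-aligned part; oblique orientations
#'   are not interpreted).
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D NIfTI, got ", length(d), "D")
  pd <- RNifti::pixdim(img)
  if (is.null(tr_s)) {
    tr_s <- if (length(pd) >= 4) pd[4] else 0
    if (!is.finite(tr_s) || tr_s <= 0) {
      stop("no repetition time in header; supply tr_s")
    }
  }
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  grid <- vol_grid(d[1:3], abs(pd[1:3]), origin)
  bold_run(array(as.numeric(img), d), tr_s = tr_s, grid = grid,
           meta = list(path = path))
}

#' Write a 4D BOLD run to NIfTI-1
#'
#' @param bold a [bold_run()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path) {
  stopifnot(inherits(bold, "cf_bold"))
  g <- bold$grid
  aff <- diag(c(g$vox_mm, 1))
  aff[1:3, 4] <- g$origin_mm
  img <- RNifti::asNifti(bold$data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`pixdim<-`(img, c(g$vox_mm, bold$tr_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a per-volume confound table (TSV)
#'
#' @param path TSV file with one row per volume (6 motion parameters and 3
#'   tissue means by convention).
#' @return A tibble.
#' @export
read_confounds <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_confounds
#' @param confounds confound table.
#' @export
write_confounds <- function(confounds, path) {
  readr::write_tsv(tibble::as_tibble(confounds), path)
  invisible(path)
}

#' Write / read run provenance (JSON)
#'
#' Provenance records the seed, generator parameters and labels needed to
#' regenerate an artifact bit-identically.
#'
#' @param prov named list.
#' @param path JSON file.
#' @export
write_provenance <- function(prov, path) {
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a labeled ROI matrix to TSV (ROI names as header and first column)
#'
#' @param m named ROI x ROI matrix (or `cf_zmat`, whose z matrix is used).
#' @param path TSV file.
#' @export
write_roi_matrix <- function(m, path) {
  if (inherits(m, "cf_zmat")) m <- m$z
  df <- tibble::as_tibble(m, rownames = "roi")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_roi_matrix
#' @export
read_roi_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$roi
  m
}
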