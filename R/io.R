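# Volumes travel as NIfTI-1 (mm units) with a JSON sidecar carrying
# provenance; tables as UTF-8 comma-separated CSV with fixed precision.

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a volume as NIfTI-1 with a JSON sidecar
#'
#' @param volume 3-D array, `recon_volume`, or `spect_phantom` field.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel Voxel size in mm (taken from the object when available).
#' @param sidecar Optional list serialized to `<path>.json` (provenance:
#'   specs, configs, seeds).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, voxel = NULL, sidecar = NULL) {
  if (inherits(volume, "recon_volume")) {
    if (is.null(sidecar)) {
      sidecar <- list(recon_config = unclass(volume$config),
                      voxel_mm = volume$voxel)
      sidecar$recon_config$corrections <-
        as.list(volume$config$corrections)
    }
    voxel <- volume$voxel
    volume <- volume$values
  }
  if (length(dim(volume)) != 3) abort("expected a 3-D volume")
  if (is.null(voxel)) abort("voxel size required")
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path A `.nii` / `.nii.gz` file holding a 3-D volume.
#' @return List with `values` (3-D array), `voxel` (mm), and `sidecar`
#'   (parsed JSON provenance, or `NULL` when absent).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf(
                    "malformed NIfTI file %s: %s", path, conditionMessage(e))))
  if (length(dim(img)) != 3) {
    abort(sprintf("expected a 3-D volume, got %d dimensions",
                  length(dim(img))))
  }
  voxel <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(voxel)) || any(voxel <= 0)) {
    abort("invalid voxel sizes in NIfTI header")
  }
  sc <- sidecar_path(path)
  sidecar <- if (file.exists(sc)) jsonlite::read_json(sc,
                                                      simplifyVector = TRUE)
  list(values = array(as.numeric(img), dim(img)), voxel = as.numeric(voxel),
       sidecar = sidecar)
}

#' Write a projection set (two NIfTI arrays + JSON sidecar)
#'
#' @param ps A `projection_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_projection_set <- function(ps, dir) {
  stopifnot(inherits(ps, "projection_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bs <- ps$phantom_spec$voxel[c(1, 3)]
  write_volume(ps$photopeak, file.path(dir, "photopeak.nii.gz"),
               voxel = c(bs[1], bs[2], 1))
  write_volume(ps$scatterwin, file.path(dir, "scatterwin.nii.gz"),
               voxel = c(bs[1], bs[2], 1))
  cfg <- unclass(ps$config)
  cfg$window <- unclass(cfg$window)
  jsonlite::write_json(
    list(view_angles = ps$view_angles, config = cfg, noise = ps$noise),
    file.path(dir, "projections.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Write records as CSV with fixed precision
#'
#' Deterministic column order (as given), UTF-8, comma separator, LF
#' endings. RC / contrast / COV style columns default to 2 decimals and
#' p-values to 3, matching the printed-table conventions; list columns are
#' dropped.
#'
#' @param records A data frame; zero rows give a header-only file.
#' @param path Output path.
#' @param precision Named vector of decimal counts overriding the defaults
#'   per column.
#' @return Invisibly, `path`.
#' @export
write_tables <- function(records, path, precision = NULL) {
  stopifnot(is.data.frame(records))
  records <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  digits_for <- function(nm) {
    if (!is.null(precision) && nm %in% names(precision)) {
      return(precision[[nm]])
    }
    if (grepl("p_value", nm)) return(3)
    if (nm %in% c("rc", "contrast", "cov", "mean", "sd") ||
        grepl("^sphere_", nm)) return(2)
    NA_integer_
  }
  for (nm in names(records)) {
    d <- digits_for(nm)
    if (!is.na(d) && is.numeric(records[[nm]])) {
      records[[nm]] <- formatC(records[[nm]], format = "f", digits = d)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(records, con, row.names = FALSE, quote = FALSE, eol = "\n",
            fileEncoding = "UTF-8")
  invisible(path)
}
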