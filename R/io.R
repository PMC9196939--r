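# Both JSON schemas store numeric values as decimal strings with 17
# significant digits (JSON text at 15 digits is not bit-exact for doubles);
# the readers convert any fully numeric-parsing array back.
.num_to_str <- function(x)
  rapply(x, function(v) if (is.numeric(v)) sprintf("%.17g", v) else v,
         how = "replace")
.str_to_num <- function(x)
  rapply(x, function(v) {
    if (is.character(v) && length(v)) {
      w <- suppressWarnings(as.numeric(v))
      if (!anyNA(w)) {
        dim(w) <- dim(v)
        return(w)
      }
    }
    v
  }, how = "replace")

#' Write / read an image stack as NIfTI-1 plus JSON sidecar
#'
#' The voxel data go to `<prefix>.nii.gz`; the acquisition axis, per-volume
#' settings, and acquisition parameters go to `<prefix>.json`. The round
#' trip is bit-exact for doubles (NIfTI datatype `DT_FLOAT64`; sidecar
#' numbers serialized at full precision).
#'
#' @param stack an `image_stack`.
#' @param prefix output path without extension.
#' @return `prefix`, invisibly.
#' @export
write_image_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  vox <- if (!is.null(stack$geometry)) stack$geometry$voxel_mm else c(1, 1, 1)
  img <- RNifti::asNifti(stack$data,
                         list(pixdim = c(-1, vox, 1, 0, 0, 0)),
                         datatype = "double")
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  acq <- if (!is.null(stack$acq)) unclass(stack$acq)
  if (!is.null(acq$b_matrices))  # row-major 3x3 lists, s/mm^2
    acq$b_matrices <- lapply(acq$b_matrices, function(b) as.vector(t(b)))
  side <- .num_to_str(list(schema = "qmridmi-image-1",
                           axis = stack$axis,
                           axis_values = stack$axis_values,
                           acq = acq, geometry = stack$geometry))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (is.null(side$schema) || !identical(side$schema, "qmridmi-image-1"))
    stop("unknown image sidecar dialect; expected schema qmridmi-image-1")
  side <- .str_to_num(side)
  dat <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  attributes(dat) <- list(dim = dim(dat))
  acq <- side$acq
  if (!is.null(acq)) {
    if (!is.null(acq$b_matrices)) {
      bm <- acq$b_matrices
      if (is.matrix(bm)) bm <- split(bm, row(bm))
      acq$b_matrices <- lapply(bm, function(b)
        matrix(unlist(b), 3, 3, byrow = TRUE))
      names(acq$b_matrices) <- NULL
    }
    class(acq) <- "acq_spec"
  }
  av <- side$axis_values
  if (is.numeric(av)) storage.mode(av) <- "double"
  image_stack(dat, axis = side$axis, axis_values = av,
              acq = acq, geometry = side$geometry)
}

#' Write / read a 2H FID series as a documented JSON container
#'
#' Complex samples are stored as full-precision real/imaginary matrices
#' `[point, block]` alongside dwell time, reference frequency, and block
#' start times (schema `qmridmi-fid-1`). JSON keeps the container
#' text-based and the round trip bit-exact.
#'
#' @param fids a `fid_series`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_fid_series <- function(fids, path) {
  stopifnot(inherits(fids, "fid_series"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  obj <- .num_to_str(list(
    schema = "qmridmi-fid-1",
    n_points = nrow(fids$fid), n_blocks = ncol(fids$fid),
    dwell_s = fids$dwell, ref_mhz = fids$ref_mhz,
    block_start_min = fids$block_start_min,
    block_min = fids$block_min,
    re = as.vector(Re(fids$fid)), im = as.vector(Im(fids$fid))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fid_series
#' @export
read_fid_series <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, "qmridmi-fid-1"))
    stop("unknown FID container dialect; expected schema qmridmi-fid-1")
  obj <- .str_to_num(obj)
  re <- matrix(obj$re, obj$n_points, obj$n_blocks)
  im <- matrix(obj$im, obj$n_points, obj$n_blocks)
  structure(list(fid = matrix(complex(real = re, imaginary = im),
                              obj$n_points, obj$n_blocks),
                 dwell = obj$dwell_s, ref_mhz = obj$ref_mhz,
                 block_start_min = obj$block_start_min,
                 block_min = obj$block_min, acq = NULL, truth = NULL),
            class = "fid_series")
}

#' Write the phantom ground truth sidecar
#'
#' Per-label masks as an integer NIfTI volume plus a CSV of preset
#' parameters (the simulator truth / recovery targets).
#'
#' @param phantom a [build_label_map()] phantom.
#' @param prefix output path without extension.
#' @return `prefix`, invisibly.
#' @export
write_ground_truth <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "phantom_spec"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(phantom$label_map + 0L,
                         list(pixdim = c(-1, phantom$geometry$voxel_mm, 1,
                                         0, 0, 0)),
                         datatype = "int16")
  RNifti::writeNifti(img, paste0(prefix, "_labels.nii.gz"))
  truth <- do.call(rbind, lapply(phantom$presets, function(p)
    data.frame(tissue = p$name, r1 = p$r1, r2 = p$r2,
               adc = mean(diag(p$adc)), mtr = p$mtr, s0 = p$s0,
               dce_auc = if (!is.null(p$dce$auc)) p$dce$auc else NA)))
  utils::write.csv(truth, paste0(prefix, "_truth.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a cohort manifest CSV
#'
#' Accepts UTF-8 BOM and CRLF line endings and normalizes both; trims
#' whitespace from headers.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xef, 0xbb, 0xbf))))
    raw <- raw[-(1:3)]
  txt <- gsub("\r\n", "\n", rawToChar(raw), fixed = TRUE)
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE,
                        strip.white = TRUE)
  names(df) <- trimws(names(df))
  df
}

# provenance sidecar: parameters actually used plus md5s of the inputs
.write_provenance <- function(path, stage, params, inputs = character()) {
  rec <- list(tool = "qmridmi",
              version = as.character(utils::packageVersion("qmridmi")),
              stage = stage, params = params,
              input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
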