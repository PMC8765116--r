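## Input/output: 2D slices as NIfTI (pixel size in the header) or delimited
## text, dataset directories with a JSON manifest, estimator checkpoints as
## JSON, and evaluation reports as JSON.

#' Load a 2D image slice
#'
#' Supported formats: NIfTI (\code{.nii}, \code{.nii.gz}; pixel size read
#' from the header) and comma-separated text (\code{.csv};
#' \code{pixelSizeMm} must then be supplied).  A 3D NIfTI volume requires
#' an explicit \code{slice} index.
#'
#' @param path file path.
#' @param slice optional slice index for 3D NIfTI volumes.
#' @param pixelSizeMm pixel size for formats that do not carry one.
#' @return A list: \code{values} (matrix) and \code{pixelSizeMm}.
#' @export
loadImage <- function(path, slice = NULL, pixelSizeMm = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    px <- RNifti::pixdim(img)[1]
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] == 1L) arr <- arr[, , 1L]
      else if (is.null(slice)) stop("3D volume: supply a slice index")
      else arr <- arr[, , slice]
    }
    if (length(dim(arr)) != 2L) stop("expected a 2D slice")
    list(values = unclass(arr), pixelSizeMm = px)
  } else if (grepl("\\.csv$", path)) {
    if (is.null(pixelSizeMm)) stop("pixelSizeMm required for csv input")
    list(values = as.matrix(utils::read.csv(path, header = FALSE)),
         pixelSizeMm = pixelSizeMm)
  } else stop("unsupported image format: ", path)
}

#' Save a 2D image slice
#'
#' @param values matrix, or a \code{\linkS4class{ReconImage}} /
#'   \code{\linkS4class{TFAMap}}.
#' @param path output path (\code{.nii}, \code{.nii.gz} or \code{.csv}).
#' @param pixelSizeMm pixel size stored in the NIfTI header; derived from
#'   the object when possible.
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(values, path, pixelSizeMm = NULL) {
  if (is(values, "ReconImage")) {
    if (is.null(pixelSizeMm)) pixelSizeMm <- values@pixelSizeMm
    values <- values@values
  } else if (is(values, "TFAMap")) {
    if (is.null(pixelSizeMm)) pixelSizeMm <- sqrt(values@pixelAreaCm2) * 10
    values <- values@values
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (is.null(pixelSizeMm)) stop("pixelSizeMm required for NIfTI output")
    img <- RNifti::asNifti(values)
    RNifti::pixdim(img) <- c(pixelSizeMm, pixelSizeMm)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.csv$", path)) {
    utils::write.table(values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Reconstructed slices and TFA maps are stored as NIfTI pairs plus a JSON
#' manifest recording the seed and per-slice areas.
#'
#' @param dataset a list as returned by \code{\link{simulateSlices}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  for (i in seq_len(n)) {
    saveImage(dataset$images[[i]],
              file.path(dir, sprintf("recon_%04d.nii.gz", i)))
    saveImage(dataset$tfa[[i]],
              file.path(dir, sprintf("tfa_%04d.nii.gz", i)))
  }
  manifest <- list(n = n, seed = dataset$seed, areasCm2 = dataset$areasCm2,
                   pixelSizeMm = dataset$images[[1]]@pixelSizeMm)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by \code{\link{writeDataset}}
#'
#' @param dir dataset directory.
#' @return A list shaped like the output of \code{\link{simulateSlices}}.
#' @export
readDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  images <- vector("list", manifest$n); tfa <- vector("list", manifest$n)
  for (i in seq_len(manifest$n)) {
    ri <- loadImage(file.path(dir, sprintf("recon_%04d.nii.gz", i)))
    images[[i]] <- reconImage(pmax(ri$values, 0), ri$pixelSizeMm)
    ti <- loadImage(file.path(dir, sprintf("tfa_%04d.nii.gz", i)))
    tfa[[i]] <- tfaMap(pmin(pmax(ti$values, 0), 1), (ti$pixelSizeMm / 10)^2)
  }
  list(images = images, tfa = tfa, areasCm2 = manifest$areasCm2,
       seed = manifest$seed)
}

#' Save / load an estimator checkpoint (JSON)
#'
#' Weights, architecture and training history in a single JSON file.
#'
#' @param estimator a \code{\linkS4class{TrainedEstimator}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveEstimator <- function(estimator, path) {
  cfg <- estimator@config
  obj <- list(inputDim = cfg@inputDim, depth = cfg@depth,
              baseChannels = cfg@baseChannels,
              normalization = estimator@meta$normalization,
              seed = estimator@meta$seed, history = estimator@history,
              weights = lapply(estimator@weights, function(x)
                list(dim = if (is.matrix(x)) dim(x) else length(x),
                     data = as.numeric(x))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveEstimator
#' @param path checkpoint path.
#' @export
loadEstimator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- networkConfig(obj$inputDim, depth = obj$depth,
                       baseChannels = obj$baseChannels)
  w <- lapply(obj$weights, function(x) {
    d <- unlist(x$dim)
    v <- as.numeric(unlist(x$data))
    if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  })
  new("TrainedEstimator", weights = w, config = cfg,
      history = as.numeric(unlist(obj$history)),
      meta = list(normalization = obj$normalization, seed = obj$seed))
}

#' Write an evaluation report as JSON
#'
#' @param report an \code{\linkS4class{EvalReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  obj <- list(pixelwiseEmse = report@pixelwiseEmse,
              normalizedAreaEmse = report@normalizedAreaEmse,
              dsc = list(mean = report@dscMeanCi[1],
                         ciLow = report@dscMeanCi[2],
                         ciHigh = report@dscMeanCi[3]),
              jsc = list(mean = report@jscMeanCi[1],
                         ciLow = report@jscMeanCi[2],
                         ciHigh = report@jscMeanCi[3]),
              biasRange = range(report@biasMap),
              nTumors = report@nTumors,
              nRealizations = report@nRealizations,
              perBin = report@perBin)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
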