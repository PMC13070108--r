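#' Read a NIfTI-1 volume
#'
#' 4-D files become \linkS4class{BoldRun}s with voxel size and repetition
#' interval taken from the header; 3-D files are returned as plain arrays
#' (integer labels preserved) with a \code{"grid"} attribute. No resampling
#' or reorientation is applied; the affine is honoured only for voxel size.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param dt repetition interval override in seconds; required when a 4-D
#'   header carries a zero/absent repetition time.
#' @param paradigm,session,subjectID labels attached to a returned
#'   \linkS4class{BoldRun}.
#' @return a \linkS4class{BoldRun} (4-D) or an array with a "grid" attribute (3-D).
#' @export
readVolume <- function(path, dt = NULL, paradigm = "CO2", session = "test",
                       subjectID = "sub-01") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")"))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # plain array, drop image class
  pd <- RNifti::pixdim(img)
  nd <- length(dim(a))
  if (!nd %in% c(3L, 4L)) stop("expected a 3-D or 4-D volume, got ", nd, "-D")
  grid <- VoxelGrid(dim(a)[1:3], voxelSize = pd[1:3])
  if (nd == 3L) {
    out <- a
    attributes(out) <- list(dim = dim(a), grid = grid)
    return(out)
  }
  tr <- if (length(pd) >= 4) pd[4] else 0
  if (is.null(dt)) {
    if (!is.finite(tr) || tr <= 0)
      stop("4-D file has zero/absent repetition time; pass an explicit dt")
    dt <- tr
  }
  BoldRun(a, grid = grid, dt = dt, paradigm = paradigm, session = session,
          subjectID = subjectID)
}

#' Write a volume as NIfTI-1
#'
#' @param x a \linkS4class{BoldRun}, or a 3-D/4-D array (optionally carrying a
#'   "grid" attribute from \code{\link{readVolume}}).
#' @param path output path (.nii or .nii.gz).
#' @param grid optional \linkS4class{VoxelGrid} for plain arrays.
#' @param dt repetition interval stored in the header for 4-D arrays.
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, grid = NULL, dt = NULL) {
  if (is(x, "BoldRun")) {
    a <- x@data; grid <- x@grid; dt <- x@dt
  } else {
    a <- x
    if (is.null(grid)) grid <- attr(x, "grid", exact = TRUE)
    if (is.null(grid)) grid <- VoxelGrid(dim(a)[1:3])
    attr(a, "grid") <- NULL
  }
  img <- RNifti::asNifti(a)
  pd <- grid@voxelSize
  if (length(dim(a)) == 4L) pd <- c(pd, if (is.null(dt)) 1 else dt)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path,
                     datatype = if (is.integer(a)) "int32" else "double")
  invisible(path)
}

#' Read a tab-separated timeseries table
#'
#' One column per series, header row required, UTF-8, missing cells marked
#' \code{"n/a"}. Every column becomes a \linkS4class{SampledSeries} at the
#' sampling interval supplied by the caller (tables carry no timing metadata).
#'
#' @param path path to a .tsv file.
#' @param dt sampling interval in seconds for all columns.
#' @param t0 time of the first row in seconds.
#' @param missing token marking missing cells (default "n/a").
#' @return named list of \linkS4class{SampledSeries}.
#' @export
readTimeseriesTable <- function(path, dt, t0 = 0, missing = "n/a") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": field counts ",
         paste(unique(nf), collapse = ", "))
  df <- utils::read.delim(path, sep = "\t", na.strings = missing,
                          check.names = FALSE, colClasses = "character")
  out <- lapply(names(df), function(nm) {
    col <- df[[nm]]
    suppressWarnings(v <- as.numeric(col))
    badRows <- which(is.na(v) & !is.na(col))
    if (length(badRows))
      stop(sprintf("non-numeric cell in column '%s', row %d: '%s'",
                   nm, badRows[1], col[badRows[1]]))
    SampledSeries(v, dt = dt, t0 = t0, label = nm)
  })
  setNames(out, names(df))
}

#' Write series to a tab-separated table
#'
#' @param series named list of \linkS4class{SampledSeries} of equal length,
#'   or a data.frame/matrix.
#' @param path output path.
#' @param missing token written for NA cells.
#' @return the path, invisibly.
#' @export
writeTimeseriesTable <- function(series, path, missing = "n/a") {
  if (is.list(series) && all(vapply(series, is, TRUE, "SampledSeries"))) {
    n <- vapply(series, function(s) length(s@values), 1L)
    if (length(unique(n)) != 1L) stop("all series must have equal length")
    df <- as.data.frame(lapply(series, seriesValues), check.names = FALSE)
    if (is.null(names(series)) || any(!nzchar(names(series))))
      names(df) <- vapply(series, function(s) s@label, "")
  } else df <- as.data.frame(series)
  df[] <- lapply(df, function(col) {
    out <- format(col, digits = 12, trim = TRUE, scientific = FALSE)
    out[is.na(col)] <- missing
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.log <- function(runID, ...) {
  message(sprintf("[%s] %s", runID, paste0(...)))
}
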