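## Serialization of datasets/observers and the external-ROI loader.
## Containers are R-native RDS files with a version tag; the layout is a
## plain list with named arrays (`absent`, `present`, `angles`) and full
## parameter/seed records, so round trips are bit-identical.

CONTAINER_VERSION <- "taskobs-1"

#' Save a paired dataset
#'
#' @param dataset A `paired_images` object.
#' @param path Output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_paired_images <- function(dataset, path) {
  stopifnot(inherits(dataset, "paired_images"))
  obj <- unclass(dataset)
  obj$container_version <- CONTAINER_VERSION
  saveRDS(obj, path)
  invisible(path)
}

#' Load a paired dataset
#'
#' @param path File written by [write_paired_images()].
#' @return A `paired_images` object.
#' @export
read_paired_images <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container_version, CONTAINER_VERSION))
    stop("not a taskobs paired-image container: ", path)
  obj$container_version <- NULL
  structure(obj, class = "paired_images")
}

#' Save an observer (with method metadata)
#'
#' @param observer A `linear_observer` or `channelized_observer`.
#' @param path Output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_observer <- function(observer, path) {
  stopifnot(inherits(observer, "linear_observer") ||
              inherits(observer, "channelized_observer"))
  saveRDS(list(container_version = CONTAINER_VERSION, observer = observer),
          path)
  invisible(path)
}

#' Load an observer
#' @param path File written by [write_observer()].
#' @return The stored observer.
#' @export
read_observer <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container_version, CONTAINER_VERSION))
    stop("not a taskobs observer container: ", path)
  obj$observer
}

as_image_rows <- function(x, what) {
  if (is.matrix(x)) return(list(images = x, grid = NULL))
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    imgs <- t(apply(x, 3, as.vector))
    return(list(images = matrix(imgs, d[3], d[1] * d[2]),
                grid = d[1:2]))
  }
  stop(what, " must be an n x N matrix or a rows x cols x n array")
}

#' Load externally supplied region-of-interest stacks
#'
#' Normalizes user-supplied signal-absent and signal-present image stacks
#' (for example VICTRE-style digital-mammography ROIs, 109 x 109
#' spiculated-mass or 65 x 65 microcalcification patches, with binary
#' labels implied by the stack) into the `paired_images` container.  The
#' mean signal is then estimated from the designated split via the usual
#' class-mean difference.
#'
#' @param absent,present Image stacks: `n x N` matrices of flattened
#'   images, `rows x cols x n` arrays, or paths to `.rds` files holding
#'   either.
#' @param grid Grid as `c(rows, cols)`; inferred from 3-D arrays.
#' @return A `paired_images` object.
#' @export
load_external_rois <- function(absent, present, grid = NULL) {
  if (is.character(absent)) absent <- readRDS(absent)
  if (is.character(present)) present <- readRDS(present)
  a <- as_image_rows(absent, "absent")
  p <- as_image_rows(present, "present")
  if (is.null(grid)) grid <- if (!is.null(a$grid)) a$grid else p$grid
  if (is.null(grid)) stop("grid must be given for flattened-matrix input")
  stopifnot(ncol(a$images) == prod(grid), ncol(p$images) == prod(grid))
  if (nrow(a$images) != nrow(p$images))
    stop("signal-absent and signal-present stacks must have equal counts")
  if (nrow(a$images) < 1) stop("empty image stack")
  if (!all(is.finite(a$images)) || !all(is.finite(p$images)))
    stop("non-finite pixel values in ROI stack")
  structure(list(absent = a$images, present = p$images,
                 grid = as.integer(grid),
                 angles = rep(NA_real_, nrow(a$images)),
                 params = list(source = "external_roi"),
                 seed = NULL, source = NULL,
                 noiseless_backgrounds = NULL),
            class = "paired_images")
}

#' Write study results as CSV and JSON rows
#'
#' @param results A results data frame (from [run_size_sweep()] or
#'   [run_domain_shift()]).
#' @param path Output path without extension; `.csv` is always written,
#'   `.json` when the jsonlite package is available.
#' @return The CSV path, invisibly.
#' @export
write_results <- function(results, path) {
  csv <- paste0(path, ".csv")
  utils::write.csv(results, csv, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(results, paste0(path, ".json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(csv)
}
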