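# Regions of interest: polygons in pixel coordinates and the boolean masks
# derived from them. Conventions: 0-based coordinates, row-major, a polygon
# vertex is (x = column, y = row), and a pixel belongs to the ROI iff its
# centre lies inside the polygon (even-odd rule).

#' Region of interest
#'
#' Constructs an ROI from a polygon (rasterised by the pixel-centre
#' even-odd test) or directly from a boolean mask.
#'
#' @param label ROI label: `"atrium"`, `"ventricle"`, `"yolk"` or `"other"`.
#' @param polygon Optional two-column matrix of `(x, y)` vertices in 0-based
#'   pixel coordinates.
#' @param mask Optional logical matrix (height x width). Exactly one of
#'   `polygon`/`mask` must be given; when a polygon is given, `image_shape`
#'   is required.
#' @param image_shape Integer `(height, width)` used to rasterise a polygon.
#' @return An object of class `roi` with fields `label`, `polygon` (may be
#'   `NULL`) and `mask`.
#' @export
roi <- function(label = c("atrium", "ventricle", "yolk", "other"),
                polygon = NULL, mask = NULL, image_shape = NULL) {
  label <- match.arg(label)
  if (is.null(mask)) {
    if (is.null(polygon) || is.null(image_shape)) {
      stop("provide either a mask, or a polygon plus image_shape",
           call. = FALSE)
    }
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
      stop("polygon must be a matrix of at least 3 (x, y) vertices",
           call. = FALSE)
    }
    mask <- polygon_mask(polygon, image_shape)
  }
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  structure(list(label = label, polygon = polygon, mask = mask),
            class = "roi")
}

# Even-odd ray-casting containment test of pixel centres (x = col, y = row,
# 0-based) against a closed polygon.
polygon_mask <- function(polygon, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  px <- rep(0:(w - 1L), each = h)   # column-major grid, x = column
  py <- rep(0:(h - 1L), times = w)  # y = row
  n <- nrow(polygon)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = h, ncol = w)
}

#' Read ROIs from a JSON polygon file
#'
#' The file holds an array of objects with fields `label` and `polygon`
#' (array of `[x, y]` vertex pairs, 0-based pixel coordinates).
#'
#' @param path Path to the JSON file.
#' @param image_shape Integer `(height, width)` for rasterisation.
#' @return A named list of [roi()] objects.
#' @export
read_rois_json <- function(path, image_shape) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (item in spec) {
    poly <- do.call(rbind, lapply(item$polygon, function(v) {
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))
    }))
    r <- roi(label = as.character(item$label), polygon = poly,
             image_shape = image_shape)
    out[[r$label]] <- r
  }
  out
}

#' Write ROIs to a JSON polygon file
#'
#' @param rois A list of [roi()] objects with non-`NULL` polygons.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rois_json <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(label = r$label, polygon = unname(apply(r$polygon, 1, as.numeric,
                                                 simplify = FALSE)))
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
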