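#' Endocardial/epicardial contours for one short-axis slice
#'
#' Contours are simple polygons in 0-based pixel coordinates (x right,
#' y down, pixel centres at integers), matching the manual endo/epi tracing
#' workflow of semi-quantitative perfusion analysis; papillary muscles are
#' excluded via explicit polygons.
#'
#' @param level One of `"base"`, `"mid"`, `"apex"`.
#' @param endo,epi Two-column matrices of polygon vertices `(x, y)`; the
#'   closing edge back to the first vertex is implicit.
#' @param rv_insertion Length-2 RV-insertion landmark `(x, y)`; anchors the
#'   angular origin of the AHA segmentation.
#' @param papillary Optional list of polygons excluded from the myocardium.
#' @return An object of class `slice_contours`.
#' @export
slice_contours <- function(level, endo, epi, rv_insertion,
                           papillary = list()) {
  level <- match.arg(level, c("base", "mid", "apex"))
  endo <- .as_polygon(endo, "endo")
  epi <- .as_polygon(epi, "epi")
  papillary <- lapply(papillary, .as_polygon, what = "papillary")
  if (length(rv_insertion) != 2L)
    stop("slice_contours: 'rv_insertion' must be a length-2 point")
  structure(list(level = level, endo = endo, epi = epi,
                 rv_insertion = as.numeric(rv_insertion),
                 papillary = papillary),
            class = "slice_contours")
}

.as_polygon <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop(sprintf("'%s' polygon must be a matrix with >= 3 rows of (x, y)",
                 what))
  # drop an explicit closing vertex
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing (even-odd rule) containment test for a set of points.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Two-column vertex matrix (implicitly closed).
#' @return Logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the mask iff its centre (integer 0-based coordinates)
#' is inside the polygon under the even-odd rule.
#'
#' @param poly Two-column vertex matrix in pixel coordinates.
#' @param grid `c(nrow, ncol)` grid size; the mask is indexed `[x + 1, y + 1]`.
#' @return Logical matrix of dimension `grid`.
#' @export
rasterize_polygon <- function(poly, grid) {
  xs <- rep(seq_len(grid[1]) - 1L, times = grid[2])
  ys <- rep(seq_len(grid[2]) - 1L, each = grid[1])
  matrix(point_in_polygon(xs, ys, poly), nrow = grid[1], ncol = grid[2])
}

# binary morphology with a Euclidean disk; masks indexed [x+1, y+1]
.disk_offsets <- function(radius) {
  r <- floor(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off[off$dx^2 + off$dy^2 <= radius^2, , drop = FALSE]
}

.shift_mask <- function(mask, dx, dy, fill = FALSE) {
  out <- matrix(fill, nrow(mask), ncol(mask))
  src_x <- seq_len(nrow(mask)) - dx
  src_y <- seq_len(ncol(mask)) - dy
  ok_x <- src_x >= 1 & src_x <= nrow(mask)
  ok_y <- src_y >= 1 & src_y <= ncol(mask)
  out[ok_x, ok_y] <- mask[src_x[ok_x], src_y[ok_y]]
  out
}

.erode_disk <- function(mask, radius) {
  off <- .disk_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out & .shift_mask(mask, off$dx[k], off$dy[k], fill = FALSE)
  out
}

.dilate_disk <- function(mask, radius) {
  off <- .disk_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out | .shift_mask(mask, off$dx[k], off$dy[k], fill = FALSE)
  out
}

#' Rasterize the myocardial annulus of one slice
#'
#' A pixel is myocardium iff its centre is inside the epicardial contour,
#' outside the endocardial contour, and outside every papillary-exclusion
#' polygon (even-odd rule throughout).
#'
#' @param contours A [slice_contours()] object.
#' @param grid `c(nrow, ncol)` grid size.
#' @return Logical matrix: `TRUE` on myocardium.
#' @export
rasterize_annulus <- function(contours, grid) {
  stopifnot(inherits(contours, "slice_contours"))
  epi <- rasterize_polygon(contours$epi, grid)
  endo <- rasterize_polygon(contours$endo, grid)
  if (any(endo & !epi) || !any(epi & !endo))
    stop("rasterize_annulus: endocardial contour must lie strictly inside ",
         "the epicardial contour")
  ann <- epi & !endo
  for (pap in contours$papillary)
    ann <- ann & !rasterize_polygon(pap, grid)
  ann
}

# polygon area centroid (shoelace); falls back to vertex mean for
# degenerate (zero-area) input
.polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Shoelace area of a polygon
#'
#' @param poly Two-column vertex matrix.
#' @return Area in squared vertex units (always >= 0).
#' @export
polygon_area <- function(poly) {
  poly <- .as_polygon(poly, "poly")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' AHA 16-segment labelling of one short-axis slice
#'
#' Assigns every annulus pixel an AHA segment label by its angle about the
#' endocardial centroid. Angle zero is the ray toward the RV-insertion
#' landmark; sectors advance with increasing `atan2(dy, dx)` in the x-right /
#' y-down pixel frame. Basal slices carry labels 1-6 and mid slices 7-12 in
#' six 60-degree sectors; apical slices carry 13-16 in four 90-degree
#' sectors. A pixel exactly on a sector boundary goes to the lower-numbered
#' segment. The blood-pool ROI is the endocardial mask eroded by 2 pixels.
#'
#' @param contours A [slice_contours()] with the RV-insertion landmark set.
#' @param grid `c(nrow, ncol)` grid size.
#' @return An object of class `segment_mask`: list with `level`, `labels`
#'   (integer matrix, 0 = background) and `blood_pool` (logical matrix).
#' @export
segment_aha16 <- function(contours, grid) {
  stopifnot(inherits(contours, "slice_contours"))
  if (is.null(contours$rv_insertion) || anyNA(contours$rv_insertion))
    stop("segment_aha16: RV-insertion landmark is required")
  ann <- rasterize_annulus(contours, grid)
  ctr <- .polygon_centroid(contours$endo)
  n_sectors <- if (contours$level == "apex") 4L else 6L
  offset <- switch(contours$level, base = 0L, mid = 6L, apex = 12L)
  width <- 2 * pi / n_sectors

  idx <- which(ann)
  px <- (idx - 1L) %% grid[1]
  py <- (idx - 1L) %/% grid[1]
  ang_rv <- atan2(contours$rv_insertion[2] - ctr[2],
                  contours$rv_insertion[1] - ctr[1])
  rel <- (atan2(py - ctr[2], px - ctr[1]) - ang_rv) %% (2 * pi)
  r <- rel / width
  sector <- ifelse(r > 0 & r == floor(r), r, floor(r) + 1)  # ties -> lower
  sector[sector > n_sectors] <- n_sectors

  labels <- matrix(0L, grid[1], grid[2])
  labels[idx] <- as.integer(offset + sector)

  bp <- .erode_disk(rasterize_polygon(contours$endo, grid), 2)
  structure(list(level = contours$level, labels = labels, blood_pool = bp),
            class = "segment_mask")
}

#' Body surface area (Mosteller)
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @return BSA in square metres.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  if (height_cm <= 0 || weight_kg <= 0)
    stop("bsa_mosteller: height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Left-ventricular volumes by summation of discs
#'
#' Per phase, the cavity volume is the sum over slices of endocardial area
#' times the slice increment (thickness plus gap). End diastole / end systole
#' are taken as the phases with maximum / minimum volume. LVEF is
#' `100 * (LVEDV - LVESV) / LVEDV`; LVEDVi indexes LVEDV to Mosteller BSA.
#'
#' @param phases List over cardiac phases; each element is a list of
#'   endocardial polygons (pixel coordinates), one per slice.
#' @param thickness Slice thickness (mm).
#' @param gap Inter-slice gap (mm), default 0.
#' @param spacing In-plane pixel spacing (mm), scalar or `c(dx, dy)`.
#' @param height_cm,weight_kg Patient height and weight for BSA.
#' @return A list of class `volume_result` with `lvedv`, `lvesv` (mL),
#'   `lvef` (%), `bsa` (m^2), `lvedvi` (mL/m^2).
#' @export
lv_volumes <- function(phases, thickness, gap = 0, spacing = 1,
                       height_cm, weight_kg) {
  if (length(phases) < 1L) stop("lv_volumes: need at least one phase")
  if (thickness <= 0 || any(spacing <= 0))
    stop("lv_volumes: spacings must be positive")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2)
  vols <- vapply(phases, function(slices) {
    areas_mm2 <- vapply(slices, polygon_area, numeric(1)) *
      spacing[1] * spacing[2]
    sum(areas_mm2 * (thickness + gap)) / 1000  # mm^3 -> mL
  }, numeric(1))
  lvedv <- max(vols); lvesv <- min(vols)
  bsa <- bsa_mosteller(height_cm, weight_kg)
  structure(list(lvedv = lvedv, lvesv = lvesv,
                 lvef = 100 * (lvedv - lvesv) / lvedv,
                 bsa = bsa, lvedvi = lvedv / bsa),
            class = "volume_result")
}

#' Read / write slice contours as JSON
#'
#' Schema: `{"level":…, "endo":[[x,y]…], "epi":[[x,y]…],
#' "rv_insertion":[x,y], "papillary":[[[x,y]…]…]}`, all coordinates in the
#' 0-based pixel frame.
#'
#' @param contours A [slice_contours()] object.
#' @param path File path.
#' @return `write_contours_json` returns `path` invisibly;
#'   `read_contours_json` returns a [slice_contours()].
#' @export
write_contours_json <- function(contours, path) {
  stopifnot(inherits(contours, "slice_contours"))
  obj <- list(level = contours$level,
              endo = unname(contours$endo),
              epi = unname(contours$epi),
              rv_insertion = contours$rv_insertion,
              papillary = lapply(contours$papillary, unname))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  if (!file.exists(path))
    stop("read_contours_json: no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pap <- obj$papillary
  if (is.null(pap) || length(pap) == 0L) {
    pap <- list()
  } else if (is.array(pap) && length(dim(pap)) == 3L) {
    pap <- lapply(seq_len(dim(pap)[1]), function(i) pap[i, , ])
  }
  slice_contours(level = obj$level, endo = obj$endo, epi = obj$epi,
                 rv_insertion = obj$rv_insertion, papillary = pap)
}
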