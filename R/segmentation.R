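#' @title Five-threshold morphological segmentation protocol
#' @name segmentation
#' @description The published protocol isolates K-edge material with
#'   five named thresholds and binary mask arithmetic: A (above-edge
#'   volume >= 3.8 cm^-1, candidate dense material), B (above-edge
#'   >= 12, high-Z minerals), C (subtraction >= 3, K-edge signal),
#'   D (dilated negative subtraction voxels, shift/shrinkage
#'   artifacts), E (below-edge in [3, 4], optional extra exclusion
#'   band).  The chain is f = (A AND C) - D; g = dilate26(f);
#'   h = g AND C; i = h - (B AND C), with set minus meaning
#'   AND NOT.
NULL

#' Segmentation parameters (thresholds A--E)
#'
#' Defaults are the published protocol values.  All "no less than"
#' bounds are inclusive; threshold E is the closed interval \[3, 4\].
#'
#' @param threshold_A above-edge cut (cm^-1), default 3.8.
#' @param threshold_B above-edge high-Z mineral cut (cm^-1), default 12.
#' @param threshold_C subtraction cut (cm^-1), default 3.
#' @param threshold_D_cutoff subtraction values strictly below this are
#'   shift artifacts to dilate, default 0.
#' @param threshold_E closed interval on the below-edge volume,
#'   default `c(3, 4)`.
#' @param dilation_iterations iterations of 26-neighbour dilation for
#'   stage g, default 1.
#' @param h_rule `"table2"` keeps g AND C (canonical); `"text"` is the
#'   alternative reading g AND NOT C (documented contradiction in the
#'   source protocol; see the methods vignette).
#' @param use_threshold_E also exclude (E AND C) at the final stage.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_A = 3.8, threshold_B = 12,
                                threshold_C = 3, threshold_D_cutoff = 0,
                                threshold_E = c(3, 4),
                                dilation_iterations = 1,
                                h_rule = c("table2", "text"),
                                use_threshold_E = FALSE) {
  h_rule <- match.arg(h_rule)
  stopifnot(threshold_A > 0, threshold_B > 0, threshold_C > 0,
            threshold_B > threshold_A,
            length(threshold_E) == 2L, threshold_E[1] <= threshold_E[2],
            dilation_iterations >= 0)
  structure(list(threshold_A = threshold_A, threshold_B = threshold_B,
                 threshold_C = threshold_C,
                 threshold_D_cutoff = threshold_D_cutoff,
                 threshold_E = threshold_E,
                 dilation_iterations = as.integer(dilation_iterations),
                 h_rule = h_rule, use_threshold_E = use_threshold_E),
            class = "segmentation_params")
}

new_mask <- function(data, label = "") {
  storage.mode(data) <- "integer"
  structure(data, label = label, class = "binary_mask")
}

#' Threshold a volume into a binary mask
#'
#' Voxel = 1 iff `lower <= value` (and `value <= upper` when bounded);
#' both bounds inclusive ("no less than" / "between" semantics).
#'
#' @param volume numeric 3D array.
#' @param lower inclusive lower bound.
#' @param upper inclusive upper bound, default unbounded.
#' @param label semantic label stored on the mask (e.g. `"A"`).
#' @return integer 0/1 array of class `binary_mask`.
#' @export
threshold_mask <- function(volume, lower, upper = Inf, label = "") {
  stopifnot_volume(volume)
  if (lower > upper) stop("'lower' must not exceed 'upper'")
  new_mask(array((volume >= lower) & (volume <= upper), dim(volume)), label)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask%s> %s voxels on / %d (%.3g%%)\n",
              if (nzchar(attr(x, "label") %||% ""))
                paste0(" ", attr(x, "label")) else "",
              format(sum(x)), length(x), 100 * mean(x)))
  invisible(x)
}

mask_and <- function(a, b, label = "")
  new_mask(array(a > 0 & b > 0, dim(a)), label)
mask_minus <- function(a, b, label = "")
  new_mask(array(a > 0 & !(b > 0), dim(a)), label)

# zero-padded shift of a 3D array by integer offsets
shift_volume <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1L), dim = d)
  src <- function(n, o) {
    i <- seq_len(n) - o
    i[i < 1L | i > n] <- NA_integer_
    i
  }
  sz <- src(d[1], dz); sy <- src(d[2], dy); sx <- src(d[3], dx)
  oz <- which(!is.na(sz)); oy <- which(!is.na(sy)); ox <- which(!is.na(sx))
  out[oz, oy, ox] <- a[sz[oz], sy[oy], sx[ox]]
  out
}

#' 3D morphological dilation with the 26-neighbourhood
#'
#' Full 3x3x3 structuring element ("26 adjacent voxels"), applied
#' `iterations` times; 0 iterations is the identity.  The volume
#' boundary clips the neighbourhood.
#'
#' @param mask a binary mask (0/1 or logical 3D array).
#' @param iterations non-negative integer.
#' @return `binary_mask`.
#' @export
dilate26 <- function(mask, iterations = 1) {
  stopifnot(iterations >= 0)
  m <- mask > 0
  for (it in seq_len(iterations)) {
    acc <- m
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      acc <- acc | shift_volume(m, dz, dy, dx)
    }
    m <- acc
  }
  new_mask(array(m, dim(mask)), attr(mask, "label") %||% "")
}

#' Shift/shrinkage artifact mask (Threshold D)
#'
#' Sample motion between the two scans produces paired dark/bright
#' rims in the subtraction.  Voxels strictly below
#' `threshold_D_cutoff` (default 0, i.e. negative differences) are
#' selected and dilated once with the 26-neighbourhood so the mask
#' also covers the adjacent bright rim.
#'
#' @param sub subtraction volume (signed cm^-1).
#' @param params a [segmentation_params()].
#' @return `binary_mask` labelled `"D"`.
#' @export
shift_artifact_mask <- function(sub, params = segmentation_params()) {
  stopifnot_volume(sub)
  d <- new_mask(array(sub < params$threshold_D_cutoff, dim(sub)), "D")
  dilate26(d, 1)
}

#' Full segmentation chain for K-edge material
#'
#' Computes the five threshold masks and the published mask
#' arithmetic: `f = (A AND C) - D`, `g = dilate26(f)`, `h = g AND C`
#' (canonical rule), `i = h - (B AND C)` with an optional extra
#' exclusion `(E AND C)`.  Returns the final mask `i`; all stages are
#' attached when `return_stages = TRUE`.
#'
#' @param above,below registered above/below-edge volumes (cm^-1).
#' @param sub their subtraction volume (from [kes_subtract()]).
#' @param params a [segmentation_params()].
#' @param return_stages return `list(masks = ..., final = i)` instead
#'   of just the final mask.
#' @return `binary_mask` labelled `"i"`, or a list of all stages.
#' @export
segment_yttria <- function(above, below, sub,
                           params = segmentation_params(),
                           return_stages = FALSE) {
  stopifnot_volume(above); stopifnot_volume(below); stopifnot_volume(sub)
  same_shape(above, below); same_shape(above, sub)
  A <- threshold_mask(above, params$threshold_A, label = "A")
  B <- threshold_mask(above, params$threshold_B, label = "B")
  C <- threshold_mask(sub, params$threshold_C, label = "C")
  D <- shift_artifact_mask(sub, params)
  E <- threshold_mask(below, params$threshold_E[1], params$threshold_E[2],
                      label = "E")
  f <- mask_minus(mask_and(A, C), D, "f")
  g <- dilate26(f, params$dilation_iterations)
  attr(g, "label") <- "g"
  h <- if (params$h_rule == "table2") mask_and(g, C, "h")
       else mask_minus(g, C, "h")
  excl <- mask_and(B, C)
  if (params$use_threshold_E)
    excl <- new_mask(array(excl > 0 | (E > 0 & C > 0), dim(excl)))
  i <- mask_minus(h, excl, "i")
  if (!return_stages) return(i)
  list(masks = list(A = A, B = B, C = C, D = D, E = E,
                    f = f, g = g, h = h, i = i),
       final = i)
}

#' Label connected components (26-connectivity)
#'
#' Breadth-first component labelling over the 26-neighbourhood;
#' returns per-component voxel counts and bounding boxes.  The summed
#' component sizes always equal the mask voxel count.
#'
#' @param mask binary mask (0/1 or logical 3D array).
#' @return object of class `region_labels`: `labels` (integer array,
#'   0 = background) and `summary` (data.frame with `label`, `voxels`
#'   and bounding box columns `z0,z1,y0,y1,x0,x1`).
#' @export
label_regions <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  m <- array(as.integer(mask > 0), d)
  lab <- label3d_26(m, as.integer(d))
  labels <- array(lab, d)
  n <- max(lab)
  if (n == 0L) {
    summary <- data.frame(label = integer(0), voxels = integer(0),
                          z0 = integer(0), z1 = integer(0),
                          y0 = integer(0), y1 = integer(0),
                          x0 = integer(0), x1 = integer(0))
  } else {
    idx <- which(lab > 0L)
    li <- lab[idx]
    ai <- arrayInd(idx, d)
    summary <- data.frame(
      label = seq_len(n),
      voxels = as.integer(tabulate(li, n)),
      z0 = as.integer(tapply(ai[, 1], li, min)),
      z1 = as.integer(tapply(ai[, 1], li, max)),
      y0 = as.integer(tapply(ai[, 2], li, min)),
      y1 = as.integer(tapply(ai[, 2], li, max)),
      x0 = as.integer(tapply(ai[, 3], li, min)),
      x1 = as.integer(tapply(ai[, 3], li, max)))
  }
  structure(list(labels = labels, summary = summary),
            class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  cat("<region_labels>", nrow(x$summary), "components,",
      sum(x$summary$voxels), "voxels\n")
  invisible(x)
}
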