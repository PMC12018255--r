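#' Classified label raster at metric pixel size
#'
#' A plain pixel raster of integer class labels (0 = background) with a
#' square pixel edge in metres, as produced by a land-cover classifier at
#' native (e.g. 10 m) resolution. No geographic lattice is attached; patch
#' filtering and confusion metrics operate on pixels.
#'
#' @param values Integer matrix of nonnegative labels.
#' @param pixel_size Pixel edge, metres (default 10).
#' @return An object of class `label_grid`.
#' @export
label_grid <- function(values, pixel_size = 10) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) {
    stop("labels must be nonnegative", call. = FALSE)
  }
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  storage.mode(values) <- "integer"
  structure(list(values = values, pixel_size = pixel_size),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  cat(sprintf("<label_grid> %d x %d pixels at %g m; %d foreground\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              sum(x$values > 0, na.rm = TRUE)))
  invisible(x)
}

#' Label connected components of a binary matrix
#'
#' Two-pass union-find labelling with selectable 4- or 8-connectivity
#' (8-connectivity counts diagonal neighbours as adjacent).
#'
#' @param m Logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component ids (0 = background).
#' @export
label_components <- function(m, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  nr <- nrow(m)
  nc <- ncol(m)
  fg <- which(m > 0)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  parent <- seq_along(fg)
  idx_of <- integer(nr * nc)
  idx_of[fg] <- seq_along(fg)

  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  offsets <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8) {
    offsets <- c(offsets, list(c(-1L, -1L), c(-1L, 1L)))
  }
  for (k in seq_along(fg)) {
    r <- rows[k]
    cc <- cols[k]
    for (off in offsets) {
      r2 <- r + off[1]
      c2 <- cc + off[2]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
        j <- idx_of[(c2 - 1L) * nr + r2]
        if (j > 0L) union(k, j)
      }
    }
  }
  roots <- vapply(seq_along(fg), find, integer(1))
  lab[fg] <- as.integer(factor(roots))
  lab
}

#' Remove small patches from a binary classification
#'
#' Contiguity filtering of a classified raster: connected components of the
#' positive class smaller than `min_pixels` are set to background; larger
#' components are retained intact. With the source analysis's 50-pixel
#' threshold at 10 m pixels, the smallest retained patch is 0.5 ha, so the
#' filter restricts the map to commercial-scale plantations. The operation
#' is idempotent and never adds pixels.
#'
#' @param binary A binary (0/1) [label_grid()].
#' @param min_pixels Minimum component size retained (default 50).
#' @param connectivity 4 or 8 (default 8).
#' @return A filtered [label_grid()].
#' @export
patch_filter <- function(binary, min_pixels = 50, connectivity = 8) {
  stopifnot(inherits(binary, "label_grid"))
  if (min_pixels < 1) stop("`min_pixels` must be >= 1", call. = FALSE)
  v <- binary$values
  if (!all(v %in% c(0L, 1L))) {
    stop("`binary` must contain only labels 0 and 1", call. = FALSE)
  }
  lab <- label_components(v, connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab)
    drop <- which(sizes < min_pixels)
    v[lab %in% drop] <- 0L
  }
  label_grid(v, binary$pixel_size)
}

#' Minimum mapped patch area implied by a pixel threshold
#'
#' @param min_pixels Pixel-count threshold.
#' @param pixel_size Pixel edge, metres.
#' @return Area in hectares (`min_pixels * pixel_size^2 / 1e4`).
#' @export
min_patch_area_ha <- function(min_pixels = 50, pixel_size = 10) {
  min_pixels * pixel_size^2 / 1e4
}

#' Confusion counts for one target class
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d FP %d FN %d TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' The four standard one-vs-rest metrics:
#' accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2 precision recall / (precision + recall).
#' A metric whose denominator is zero is returned as `NaN` with a warning.
#'
#' @param counts A [confusion_counts()] object.
#' @return One-row tibble with `accuracy`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.nan(precision) || is.nan(recall)) {
    warning("f1 undefined", call. = FALSE)
    NaN
  } else if (precision + recall == 0) {
    0 # degenerate classifier: no true positives at all
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = precision,
    recall = recall,
    f1 = f1
  )
}

#' Tally a one-vs-rest confusion matrix from label grids
#'
#' @param predicted,truth [label_grid()]s of identical dimensions.
#' @param target_class The class treated as positive (default 1).
#' @return A [confusion_counts()] object.
#' @export
confusion_from_grids <- function(predicted, truth, target_class = 1L) {
  stopifnot(inherits(predicted, "label_grid"), inherits(truth, "label_grid"))
  if (!identical(dim(predicted$values), dim(truth$values))) {
    stop("label grids differ in shape", call. = FALSE)
  }
  p <- predicted$values == target_class
  t <- truth$values == target_class
  keep <- !is.na(p) & !is.na(t)
  confusion_counts(
    tp = sum(p & t & keep),
    fp = sum(p & !t & keep),
    fn = sum(!p & t & keep),
    tn = sum(!p & !t & keep)
  )
}
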