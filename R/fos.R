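#' @keywords internal
#' 8-connected component labeling by iterative label propagation: every
#' foreground pixel starts with its own index and repeatedly takes the
#' maximum over its 8-neighborhood until a fixed point; labels are then
#' renumbered 1..k in raster order of first occurrence. Convergence takes
#' O(component diameter) vectorized passes, cheap for cell-sized blobs.
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    nb <- lab
    for (d in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                   c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L)))
      nb <- pmax(nb, shift(lab, d[1], d[2]))
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  u <- unique(lab[lab > 0L])
  if (length(u)) {
    remap <- integer(max(u))
    remap[sort(u)] <- seq_along(u)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Threshold and particle-count one image channel
#'
#' Replicates the "analyze particles" quantitation: pixels strictly above a
#' global intensity threshold form the binary mask; connected components are
#' found with 8-connectivity; components with pixel area outside
#' `size_range` are discarded. Consistent fluorescence and size thresholds
#' should be used across all sections of a study.
#'
#' @param channel 2-D intensity matrix.
#' @param intensity_threshold global threshold; pixels `> threshold` are
#'   foreground. Use [auto_threshold()] for a background-driven default.
#' @param size_range `c(min_px, max_px)` inclusive area filter;
#'   `min_px >= 1`.
#' @return list with `count` and `labels` (integer label map, filtered
#'   components renumbered 1..count).
#' @export
threshold_count <- function(channel, intensity_threshold,
                            size_range = c(5, 10000)) {
  stopifnot(is.matrix(channel))
  if (length(channel) == 0L) stop("empty image")
  if (length(size_range) != 2L || size_range[1] > size_range[2])
    stop("inverted size_range")
  if (size_range[1] < 1) stop("min_px must be >= 1")
  mask <- channel > intensity_threshold
  lab <- label_components_8(mask)
  k <- max(lab)
  if (k == 0L) return(list(count = 0L, labels = lab))
  area <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(area >= size_range[1] & area <= size_range[2])
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  list(count = length(keep), labels = lab)
}

#' Automatic background-driven threshold
#'
#' `mean + 2 * SD` of the background, with the background estimated as the
#' pixels at or below the channel's 90th intensity percentile (the manual
#' threshold "adjusted to minimize nonspecific background fluorescence" has
#' no closed form; this is the logged automatic surrogate).
#'
#' @param channel 2-D intensity matrix.
#' @param k SD multiplier (default 2).
#' @param bg_quantile quantile bounding the background population.
#' @return scalar threshold.
#' @export
auto_threshold <- function(channel, k = 2, bg_quantile = 0.9) {
  bg <- channel[channel <= stats::quantile(channel, bg_quantile)]
  mean(bg) + k * stats::sd(bg)
}

#' @keywords internal centroids (row, col) of a label map, ordered by label
label_centroids <- function(labels) {
  k <- max(labels)
  if (k == 0L) return(data.frame(row = numeric(0), col = numeric(0)))
  idx <- which(labels > 0L)
  l <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  data.frame(row = as.numeric(tapply(rows, l, mean)),
             col = as.numeric(tapply(cols, l, mean)))
}

#' Colocalization counts from two label maps
#'
#' A green (reporter) object is colocalized when the centroid of some red
#' (Fos) object lies inside its mask (`mode = "centroid"`, the default); an
#' area-overlap rule (`mode = "overlap"`: at least `min_overlap` of the red
#' object's area inside one green mask, ties broken by nearest green
#' centroid) is also provided. Each red object matches at most one green
#' object; a green object containing several red centroids counts once.
#'
#' @param labels_green,labels_red integer label maps sharing shape (from
#'   [threshold_count()]).
#' @param mode `"centroid"` or `"overlap"`.
#' @param min_overlap minimum red-area fraction for `"overlap"` mode.
#' @return an object of class `cell_counts`: `n_green`, `n_red`, `n_coloc`,
#'   `pct_coloc` (`100 * n_coloc / n_green`, `NA` when `n_green` is 0),
#'   `labels_green`, `labels_red`, `coloc_green_labels`.
#' @export
colocalize <- function(labels_green, labels_red,
                       mode = c("centroid", "overlap"), min_overlap = 0.5) {
  mode <- match.arg(mode)
  if (!identical(dim(labels_green), dim(labels_red)))
    stop("label maps must share shape")
  n_green <- max(labels_green)
  n_red <- max(labels_red)
  hits <- integer(0)
  if (n_red > 0L && n_green > 0L) {
    if (mode == "centroid") {
      cent <- label_centroids(labels_red)
      ri <- pmin(pmax(round(cent$row), 1L), nrow(labels_green))
      ci <- pmin(pmax(round(cent$col), 1L), ncol(labels_green))
      hits <- labels_green[cbind(ri, ci)]
    } else {
      gcent <- label_centroids(labels_green)
      rcent <- label_centroids(labels_red)
      hits <- vapply(seq_len(n_red), function(r) {
        px <- labels_red == r
        under <- labels_green[px]
        under <- under[under > 0L]
        if (!length(under)) return(0L)
        tab <- table(under)
        frac <- as.numeric(tab) / sum(px)
        cand <- as.integer(names(tab))[frac >= min_overlap]
        if (!length(cand)) return(0L)
        if (length(cand) == 1L) return(cand)
        d2 <- (gcent$row[cand] - rcent$row[r])^2 +
          (gcent$col[cand] - rcent$col[r])^2
        cand[which.min(d2)]
      }, integer(1))
    }
    hits <- unique(hits[hits > 0L])
  }
  structure(list(
    n_green = n_green, n_red = n_red, n_coloc = length(hits),
    pct_coloc = if (n_green > 0L) 100 * length(hits) / n_green else NA_real_,
    labels_green = labels_green, labels_red = labels_red,
    coloc_green_labels = sort(hits)
  ), class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf(
    "<cell_counts> green %d, red %d, colocalized %d (%s%%)\n",
    x$n_green, x$n_red, x$n_coloc,
    if (is.na(x$pct_coloc)) "NA" else sprintf("%.1f", x$pct_coloc)))
  invisible(x)
}

#' Count one two-channel field
#'
#' Thresholds and counts both channels, then colocalizes.
#'
#' @param field an [image_field()].
#' @param threshold_green,threshold_red global intensity thresholds;
#'   `NULL` uses [auto_threshold()] per channel.
#' @param size_range inclusive component area filter (px).
#' @param ... passed to [colocalize()].
#' @return a `cell_counts` with a `section_index` element.
#' @export
count_field <- function(field, threshold_green = NULL, threshold_red = NULL,
                        size_range = c(5, 10000), ...) {
  stopifnot(inherits(field, "image_field"))
  if (is.null(threshold_green)) threshold_green <- auto_threshold(field$green)
  if (is.null(threshold_red)) threshold_red <- auto_threshold(field$red)
  g <- threshold_count(field$green, threshold_green, size_range)
  r <- threshold_count(field$red, threshold_red, size_range)
  out <- colocalize(g$labels, r$labels, ...)
  out$section_index <- field$section_index
  out
}

#' Totals and per-section profile over a section series
#'
#' Counts are summed across sections and the overall percent computed from
#' the summed counts (not averaged per-section percents); the per-section
#' profile is ordered rostro-caudally by `section_index`.
#'
#' @param counts list of `cell_counts`, each carrying a distinct
#'   `section_index`.
#' @return list with `totals` (`n_green`, `n_red`, `n_coloc`, `pct_coloc`)
#'   and `profile` (data.frame ordered by section).
#' @export
section_series_summary <- function(counts) {
  if (!length(counts)) stop("need at least one section")
  idx <- vapply(counts, function(x) as.integer(x$section_index %||% NA),
                integer(1))
  if (anyNA(idx)) stop("every cell_counts needs a section_index")
  if (anyDuplicated(idx)) stop("duplicate section_index")
  profile <- data.frame(
    section_index = idx,
    n_green = vapply(counts, function(x) as.numeric(x$n_green), numeric(1)),
    n_red = vapply(counts, function(x) as.numeric(x$n_red), numeric(1)),
    n_coloc = vapply(counts, function(x) as.numeric(x$n_coloc), numeric(1)),
    pct_coloc = vapply(counts, function(x) as.numeric(x$pct_coloc),
                       numeric(1)))
  profile <- profile[order(profile$section_index), ]
  rownames(profile) <- NULL
  tg <- sum(profile$n_green); tr <- sum(profile$n_red)
  tc <- sum(profile$n_coloc)
  list(totals = list(n_green = tg, n_red = tr, n_coloc = tc,
                     pct_coloc = if (tg > 0) 100 * tc / tg else NA_real_),
       profile = profile)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-channel field from TIFF files
#'
#' @param path_green,path_red single-channel TIFF paths.
#' @param pixel_size_um,section_index metadata for [image_field()].
#' @param scale multiply intensities read from TIFF (readTIFF returns
#'   values in `[0, 1]`; the default restores a 16-bit scale).
#' @return an [image_field()].
#' @export
read_image_field <- function(path_green, path_red, pixel_size_um = 1.0,
                             section_index = 1L, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to read TIFF fields")
  g <- tiff::readTIFF(path_green) * scale
  r <- tiff::readTIFF(path_red) * scale
  image_field(g, r, pixel_size_um, section_index)
}

#' Write a two-channel field to TIFF files
#'
#' @param field an [image_field()].
#' @param path_green,path_red output paths.
#' @param scale divisor mapping intensities to the `[0, 1]` range expected
#'   by writeTIFF (default 16-bit).
#' @return invisibly, the two paths.
#' @export
write_image_field <- function(field, path_green, path_red, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write TIFF fields")
  stopifnot(inherits(field, "image_field"))
  tiff::writeTIFF(pmin(field$green / scale, 1), path_green,
                  bits.per.sample = 16L)
  tiff::writeTIFF(pmin(field$red / scale, 1), path_red,
                  bits.per.sample = 16L)
  invisible(c(path_green, path_red))
}
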