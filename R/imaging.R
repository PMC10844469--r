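# Minimal imaging stage: render synthetic two-channel fields (nuclear stain
# + reporter) from cell records, and recover per-cell nuclear/cytoplasmic
# ratios from such images. Stands in for the interactive CellProfiler
# quantification with the simplest defensible operators: Otsu threshold,
# connected components, size filter, annulus cytoplasm.

.nuclear_stain_intensity <- 400 # expected counts inside a stained nucleus

#' Render a synthetic two-channel image pair
#'
#' Nuclei are drawn as bright disks (radius `nuc_radius_um`) in the nuclear
#' channel; the reporter channel draws each cell as a cytoplasm disk (radius
#' `cyt_radius_um`) at its cytoplasmic intensity with the nuclear region
#' overwritten at the nuclear intensity, so that by construction each cell's
#' nuclear/cytoplasmic reporter ratio equals its record's ratio. Poisson
#' shot noise is applied when `noise_level > 0` (1 = pure Poisson at the
#' drawn counts; larger values coarsen the photon scale). Deterministic
#' given `seed`.
#'
#' @param cells Per-cell table with `x_um`, `y_um`, `nuc_intensity`,
#'   `cyt_intensity`.
#' @param pixel_size Pixel size in um/px, within `[0.2, 2]` (default 0.65,
#'   10x objective class).
#' @param noise_level 0 for noiseless rendering, 1 for Poisson noise.
#' @param seed Integer seed.
#' @param field_width,field_height Optional field extent (um), centered on
#'   the origin; defaults to the cell bounding box plus a margin.
#' @param nuc_radius_um,cyt_radius_um Nucleus and cytoplasm disk radii (um).
#' @return An object of class `image_pair`: `nuclear` and `reporter`
#'   matrices (rows = y, columns = x), `pixel_size`, `origin` (um
#'   coordinates of the image's top-left corner).
#' @export
render_images <- function(cells, pixel_size = 0.65, noise_level = 1,
                          seed = 1L, field_width = NULL,
                          field_height = NULL,
                          nuc_radius_um = 5, cyt_radius_um = 9) {
  stopifnot(is.data.frame(cells), pixel_size >= 0.2, pixel_size <= 2,
            noise_level >= 0, nuc_radius_um < cyt_radius_um)
  margin <- cyt_radius_um + 6
  if (is.null(field_width)) {
    xr <- if (nrow(cells)) range(cells$x_um) else c(0, 0)
    yr <- if (nrow(cells)) range(cells$y_um) else c(0, 0)
    origin <- c(xr[1] - margin, yr[1] - margin)
    nx <- ceiling((diff(xr) + 2 * margin) / pixel_size)
    ny <- ceiling((diff(yr) + 2 * margin) / pixel_size)
  } else {
    stopifnot(field_height > 0, field_width > 0)
    origin <- c(-field_width / 2, -field_height / 2)
    nx <- ceiling(field_width / pixel_size)
    ny <- ceiling(field_height / pixel_size)
  }
  nuc_ch <- matrix(0, nrow = ny, ncol = nx)
  rep_ch <- matrix(0, nrow = ny, ncol = nx)

  disk_window <- function(cx, cy, rad) {
    cols <- max(1, floor((cx - origin[1] - rad) / pixel_size)):
      min(nx, ceiling((cx - origin[1] + rad) / pixel_size))
    rows <- max(1, floor((cy - origin[2] - rad) / pixel_size)):
      min(ny, ceiling((cy - origin[2] + rad) / pixel_size))
    xc <- origin[1] + (cols - 0.5) * pixel_size
    yc <- origin[2] + (rows - 0.5) * pixel_size
    inside <- outer(yc, xc, function(y, x) (x - cx)^2 + (y - cy)^2 <= rad^2)
    list(rows = rows, cols = cols, inside = inside)
  }

  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) { # cytoplasm first, overlaps keep max
      w <- disk_window(cells$x_um[i], cells$y_um[i], cyt_radius_um)
      patch <- rep_ch[w$rows, w$cols]
      patch[w$inside] <- pmax(patch[w$inside], cells$cyt_intensity[i])
      rep_ch[w$rows, w$cols] <- patch
    }
    for (i in seq_len(nrow(cells))) { # nuclei overwrite cytoplasm
      w <- disk_window(cells$x_um[i], cells$y_um[i], nuc_radius_um)
      np <- nuc_ch[w$rows, w$cols]
      np[w$inside] <- .nuclear_stain_intensity
      nuc_ch[w$rows, w$cols] <- np
      rp <- rep_ch[w$rows, w$cols]
      rp[w$inside] <- cells$nuc_intensity[i]
      rep_ch[w$rows, w$cols] <- rp
    }
    d <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
    diag(d) <- Inf
    overlap_frac <- mean(apply(d, 1, min) < 2 * nuc_radius_um)
    if (nrow(cells) > 1 && overlap_frac > 0.5) {
      warning(sprintf("%.0f%% of nuclei overlap a neighbor; quantification %s",
                      100 * overlap_frac, "will be unreliable"))
    }
  }
  if (noise_level > 0) {
    withr::with_seed(as.integer(seed), {
      nuc_ch[] <- stats::rpois(length(nuc_ch), nuc_ch / noise_level) *
        noise_level
      rep_ch[] <- stats::rpois(length(rep_ch), rep_ch / noise_level) *
        noise_level
    })
  }
  structure(list(nuclear = nuc_ch, reporter = rep_ch,
                 pixel_size = pixel_size, origin = origin),
            class = "image_pair")
}

#' Segment nuclei in a nuclear-stain channel
#'
#' Global Otsu threshold, connected-component labelling, and a size filter
#' keeping objects with area inside `area_range_um2` (default 25-400 um^2).
#' A blank image yields zero labels and an empty centroid table.
#'
#' @param nuclear_channel Intensity matrix (rows = y) or an `image_pair`.
#' @param pixel_size Pixel size in um/px (taken from an `image_pair`).
#' @param origin Image origin in um (taken from an `image_pair`).
#' @param area_range_um2 Admissible nucleus area interval (um^2).
#' @return List with `labels` (integer matrix, 0 = background) and
#'   `centroids` (`data.frame`: `label`, `x_um`, `y_um`, `area_um2`).
#' @export
segment_nuclei <- function(nuclear_channel, pixel_size = 0.65,
                           origin = c(0, 0), area_range_um2 = c(25, 400)) {
  if (inherits(nuclear_channel, "image_pair")) {
    pixel_size <- nuclear_channel$pixel_size
    origin <- nuclear_channel$origin
    nuclear_channel <- nuclear_channel$nuclear
  }
  stopifnot(is.matrix(nuclear_channel), length(nuclear_channel) > 0,
            pixel_size > 0)
  empty <- list(
    labels = matrix(0L, nrow(nuclear_channel), ncol(nuclear_channel)),
    centroids = data.frame(label = integer(0), x_um = numeric(0),
                           y_um = numeric(0), area_um2 = numeric(0))
  )
  rng <- range(nuclear_channel)
  if (rng[1] == rng[2]) return(empty)
  norm <- (nuclear_channel - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > th
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  px_area <- pixel_size^2
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes * px_area >= area_range_um2[1] &
                  sizes * px_area <= area_range_um2[2])
  if (length(keep) == 0) return(empty)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- relabel[labels[nz]]
  idx <- which(out > 0, arr.ind = TRUE)
  lab <- out[out > 0]
  cx <- tapply(origin[1] + (idx[, 2] - 0.5) * pixel_size, lab, mean)
  cy <- tapply(origin[2] + (idx[, 1] - 0.5) * pixel_size, lab, mean)
  area <- tapply(lab, lab, length) * px_area
  list(labels = out,
       centroids = data.frame(label = as.integer(names(cx)),
                              x_um = as.numeric(cx), y_um = as.numeric(cy),
                              area_um2 = as.numeric(area)))
}

#' Quantify nuclear/cytoplasmic reporter ratios from an image pair
#'
#' Nuclei are segmented in the nuclear channel; per nucleus the nuclear
#' reporter intensity is the mean reporter signal inside the nucleus mask,
#' and the cytoplasmic intensity is the mean in an annulus obtained by
#' dilating the nucleus by `dilate_um` and subtracting all nuclear pixels
#' (so an abutting neighbor's nucleus never leaks into the annulus). Cells
#' whose annulus is empty (overcrowding) are flagged `qc_excluded` and
#' their ratio set to `NA`.
#'
#' @param pair An `image_pair` from [render_images()] or
#'   [read_image_pair()].
#' @param dilate_um Annulus width in um (default 3).
#' @param area_range_um2 Nucleus size filter passed to [segment_nuclei()].
#' @return Per-cell table in the canonical schema (positions are nucleus
#'   centroids; `conc_nM`, `ground_truth`, `called`, `n_neighbors` unset)
#'   plus a `qc_excluded` column.
#' @export
quantify_images <- function(pair, dilate_um = 3,
                            area_range_um2 = c(25, 400)) {
  stopifnot(inherits(pair, "image_pair"))
  seg <- segment_nuclei(pair$nuclear, pair$pixel_size, pair$origin,
                        area_range_um2)
  n <- nrow(seg$centroids)
  if (n == 0) {
    out <- .empty_cells()
    out$qc_excluded <- logical(0)
    return(out)
  }
  brush_r <- max(1L, as.integer(round(dilate_um / pair$pixel_size)))
  kern <- EBImage::makeBrush(2L * brush_r + 1L, shape = "disc")
  dil <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(seg$labels), kern))
  lab_vec <- seg$labels[seg$labels > 0]
  nuc_mean <- tapply(pair$reporter[seg$labels > 0], lab_vec, mean)
  ann <- dil > 0 & seg$labels == 0
  cyt_mean <- rep(NA_real_, n)
  if (any(ann)) {
    cm <- tapply(pair$reporter[ann], dil[ann], mean)
    cyt_mean[as.integer(names(cm))] <- as.numeric(cm)
  }
  nuc_mean <- as.numeric(nuc_mean[as.character(seq_len(n))])
  excluded <- is.na(cyt_mean) | cyt_mean <= 0
  ratio <- ifelse(excluded, NA_real_, nuc_mean / cyt_mean)
  data.frame(
    cell_id = seq_len(n),
    x_um = seg$centroids$x_um, y_um = seg$centroids$y_um,
    nuc_intensity = nuc_mean, cyt_intensity = cyt_mean,
    nuc_cyt_ratio = ratio, conc_nM = NA_real_,
    ground_truth = NA, called = NA, n_neighbors = NA_integer_,
    experiment_id = NA_character_, qc_excluded = excluded,
    stringsAsFactors = FALSE
  )
}

.tiff_scale <- 65535

#' Write / read an image pair as a multi-page 16-bit TIFF
#'
#' Page 1 is the nuclear-stain channel, page 2 the reporter channel.
#' Intensities are stored as 16-bit counts; pixel size and origin are not
#' encoded in the file and must be re-supplied on read.
#'
#' @param pair An `image_pair`.
#' @param path TIFF file path.
#' @param pixel_size,origin Geometry to attach on read.
#' @return `write_image_pair` returns `path` invisibly; `read_image_pair`
#'   returns an `image_pair`.
#' @export
write_image_pair <- function(pair, path) {
  stopifnot(inherits(pair, "image_pair"))
  clip <- function(m) pmin(pmax(m, 0), .tiff_scale) / .tiff_scale
  tiff::writeTIFF(list(clip(pair$nuclear), clip(pair$reporter)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(path, pixel_size = 0.65, origin = c(0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2) stop("expected a 2-page TIFF (nuclear, reporter)")
  structure(list(nuclear = pages[[1]] * .tiff_scale,
                 reporter = pages[[2]] * .tiff_scale,
                 pixel_size = pixel_size, origin = origin),
            class = "image_pair")
}
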