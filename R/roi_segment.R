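#' Construct an ROI image object
#'
#' Bundles one segmented nodule region: the intensity grid, its binary
#' mask, and identifiers tying it to a patient and scan.
#'
#' @param pixels Numeric matrix of intensities (arbitrary CT-like units).
#' @param mask 0/1 matrix of the same shape (1 = nodule).
#' @param patient_id,scan_index,roi_id Identifiers.
#' @return Object of class `roi_image`.
#' @export
roi_image <- function(pixels, mask, patient_id = NA_character_,
                      scan_index = 0L, roi_id = NA_character_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  stopifnot(is.matrix(mask), all(dim(mask) == dim(pixels)))
  if (!all(mask %in% c(0, 1))) stop_invalid("mask must be binary (0/1)")
  structure(
    list(pixels = pixels, mask = mask, patient_id = patient_id,
         scan_index = as.integer(scan_index), roi_id = roi_id),
    class = "roi_image"
  )
}

#' Seeded region growing
#'
#' Grows a region from a seed pixel by repeatedly admitting frontier pixels
#' whose intensity differs from the running region mean by at most `tol`.
#' The frontier is processed first-in-first-out with neighbours enqueued in
#' row-major order (up, down, left, right for 4-connectivity), which makes
#' the result deterministic. This is the background-removal step applied to
#' each manually delineated nodule ROI before texture extraction.
#'
#' @param pixels Numeric intensity matrix.
#' @param seed_point Integer pair `c(row, col)`; defaults to the grid centre.
#' @param tol Non-negative intensity tolerance against the running mean.
#' @param connectivity 4 (default) or 8.
#' @return 0/1 mask matrix; the region is connected and contains the seed.
#' @export
region_grow <- function(pixels, seed_point = NULL, tol = 0,
                        connectivity = 4L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (is.null(seed_point)) seed_point <- c(ceiling(nr / 2), ceiling(nc / 2))
  sr <- as.integer(seed_point[1]); sc <- as.integer(seed_point[2])
  if (sr < 1L || sr > nr || sc < 1L || sc > nc) {
    stop_invalid("seed point (%d, %d) outside the %d x %d grid", sr, sc, nr, nc)
  }
  if (tol < 0) stop_invalid("tol must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop_invalid("connectivity must be 4 or 8")

  nbr <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  }

  in_region <- matrix(FALSE, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  queue <- integer(nr * nc)      # FIFO of linear indices
  head <- 1L; tail <- 0L
  push <- function(idx) { tail <<- tail + 1L; queue[tail] <<- idx }

  sidx <- (sc - 1L) * nr + sr
  visited[sidx] <- TRUE
  push(sidx)
  region_sum <- 0; region_n <- 0L

  while (head <= tail) {
    idx <- queue[head]; head <- head + 1L
    val <- pixels[idx]
    mean_now <- if (region_n == 0L) val else region_sum / region_n
    if (abs(val - mean_now) <= tol) {
      in_region[idx] <- TRUE
      region_sum <- region_sum + val
      region_n <- region_n + 1L
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      for (d in nbr) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          i2 <- (c2 - 1L) * nr + r2
          if (!visited[i2]) {
            visited[i2] <- TRUE
            push(i2)
          }
        }
      }
    }
  }
  mask <- matrix(0, nr, nc)
  mask[in_region] <- 1
  mask
}

#' Zero out background pixels of an ROI
#'
#' Sets every pixel outside the mask to exactly 0 and leaves foreground
#' pixels untouched. Idempotent.
#'
#' @param image A `roi_image`.
#' @return The `roi_image` with background zeroed.
#' @export
apply_mask <- function(image) {
  stopifnot(inherits(image, "roi_image"))
  if (sum(image$mask) == 0) {
    stop_invalid("degenerate ROI: mask has no foreground pixels")
  }
  image$pixels[image$mask == 0] <- 0
  image
}
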