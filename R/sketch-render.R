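# Binarization and sketch rendering.
#
# A sketch keeps the binary value of every pixel whose surrounding 3x3 patch
# belongs to the selected feature set and blanks everything else to the
# background. Pixels without a complete 3x3 neighborhood (the one-pixel
# border ring) are always background, matching the windows counted by
# patch_distribution().

#' Binarize a grayscale image
#'
#' Converts an 8-bit grayscale image to 1-bit black/white. With
#' `method = "median"` the threshold is the per-image median pixel value
#' (balancing black and white mass); with `method = "fixed"` a user
#' threshold is applied. A pixel becomes white (1) when its value is greater
#' than or equal to the threshold.
#'
#' @param img Matrix of pixel values in `[0, 255]`, or a `gray_image` as
#'   returned by [read_gray_image()].
#' @param method `"median"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"` (ignored otherwise).
#' @return A `binary_image`: list with `pixels` (`{0,1}` matrix) and
#'   `provenance` recording the method and the threshold actually used.
#' @export
binarize <- function(img, method = c("median", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  px <- if (inherits(img, "gray_image")) img$pixels else img
  if (!is.matrix(px) || length(px) == 0L) {
    stop_domain("img must be a non-empty pixel matrix")
  }
  if (any(is.na(px)) || any(px < 0) || any(px > 255)) {
    stop_domain("pixel values must lie in [0, 255]")
  }
  thr <- switch(method,
    median = median(px),
    fixed = {
      if (!is.numeric(threshold) || length(threshold) != 1L) {
        stop_domain("method = \"fixed\" requires a numeric threshold")
      }
      threshold
    }
  )
  out <- matrix(as.integer(px >= thr), nrow(px), ncol(px))
  structure(
    list(pixels = out,
         provenance = list(method = method, threshold = thr)),
    class = "binary_image"
  )
}

#' Render a sketch from a binary image and a feature set
#'
#' Every pixel with a complete 3x3 neighborhood keeps its binary value if
#' the pattern code of that neighborhood is in `features`; all other pixels
#' (including the border ring) become background, coded `NA`.
#'
#' @param img A `binary_image` or a `{0,1}` matrix, at least 3x3.
#' @param features A `feature_set` (possibly empty).
#' @return A `sketch`: list with `pixels` (matrix of 0 = black, 1 = white,
#'   `NA` = background) and `retained_count`.
#' @export
generate_sketch <- function(img, features) {
  stopifnot(inherits(features, "feature_set"))
  px <- if (inherits(img, "binary_image")) img$pixels else img
  codes <- patch_code_matrix(px) # validates size/binarity
  h <- nrow(px)
  w <- ncol(px)
  keep <- matrix(codes %in% features$codes, nrow(codes), ncol(codes))
  out <- matrix(NA_integer_, h, w)
  interior <- px[2:(h - 1L), 2:(w - 1L), drop = FALSE]
  interior[!keep] <- NA_integer_
  out[2:(h - 1L), 2:(w - 1L)] <- interior
  structure(
    list(pixels = out, retained_count = sum(keep)),
    class = "sketch"
  )
}

#' Fraction of valid patch centers retained by a sketch
#'
#' Diagnostic related to the bandwidth cap `W`: the achieved density equals
#' the summed probability, under the image's own patch statistics, of the
#' selected patterns.
#'
#' @param s A `sketch`.
#' @return Density in `[0, 1]`.
#' @export
sketch_density <- function(s) {
  stopifnot(inherits(s, "sketch"))
  h <- nrow(s$pixels)
  w <- ncol(s$pixels)
  n_centers <- (h - 2L) * (w - 2L)
  if (n_centers <= 0L) stop_domain("sketch has no valid patch centers")
  s$retained_count / n_centers
}

#' @export
print.sketch <- function(x, ...) {
  cat(sprintf("Sketch %dx%d: %d pixels retained (density %.4f)\n",
              nrow(x$pixels), ncol(x$pixels), x$retained_count,
              sketch_density(x)))
  invisible(x)
}

# ---- image file I/O --------------------------------------------------------

#' Read a grayscale image from PNG or PGM
#'
#' PNG files are read with the png package (color images are converted to
#' luminance by channel averaging); PGM supports the plain `P2` and binary
#' `P5` 8-bit variants.
#'
#' @param path File path ending in `.png`, `.pgm`.
#' @return A `gray_image`: list with `pixels` (matrix of values in
#'   `[0, 255]`), `width`, `height`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
      round(a * 255)
    },
    pgm = read_pgm(path),
    stop_domain("unsupported image format: ", ext)
  )
  structure(
    list(pixels = px, width = ncol(px), height = nrow(px)),
    class = "gray_image"
  )
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop_domain("not an 8-bit PGM file")
  tokens <- character(0)
  # header: width, height, maxval (comments starting with '#' skipped)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop_domain("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  dims <- as.integer(tokens)
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  if (maxval > 255) stop_domain("only 8-bit PGM supported")
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a sketch (or binary image) as an 8-bit grayscale PNG
#'
#' Sketch pixels map to the display convention: background 127, black 0,
#' white 255.
#'
#' @param x A `sketch` or `binary_image`.
#' @param path Output `.png` path.
#' @export
write_sketch_png <- function(x, path) {
  px <- if (inherits(x, "sketch")) {
    out <- x$pixels * 255L
    out[is.na(out)] <- 127L
    out
  } else if (inherits(x, "binary_image")) {
    x$pixels * 255L
  } else {
    stop_domain("x must be a sketch or binary_image")
  }
  png::writePNG(px / 255, path)
  invisible(path)
}
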