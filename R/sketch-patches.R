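# Patch alphabet: every 3x3 binary patch is encoded as an integer in
# [0, 511], reading the patch row-major with the top-left pixel as the most
# significant bit. The encoding is fixed so serialized feature sets are
# bit-exact across platforms.

PATCH_SIZE <- 3L
N_PATTERNS <- 512L

#' Encode a 3x3 binary patch as an integer pattern code
#'
#' Patterns are read row-major with the top-left pixel as the most
#' significant bit, giving a bijection between 3x3 binary grids and the
#' integers 0..511.
#'
#' @param patch A 3x3 matrix with entries in `{0, 1}`.
#' @return Integer scalar in `[0, 511]`.
#' @seealso [code_to_patch()] for the inverse.
#' @examples
#' patch_code(matrix(1, 3, 3)) # 511
#' patch_code(matrix(0, 3, 3)) # 0
#' @export
patch_code <- function(patch) {
  if (!is.matrix(patch) || !all(dim(patch) == PATCH_SIZE)) {
    stop_domain("patch must be a 3x3 matrix")
  }
  check_matrix_binary(patch)
  bits <- as.integer(t(patch)) # row-major order
  sum(bits * 2L^(8:0))
}

#' Decode an integer pattern code into its 3x3 binary patch
#'
#' @param code Integer scalar in `[0, 511]`.
#' @return A 3x3 matrix with entries in `{0, 1}`.
#' @export
code_to_patch <- function(code) {
  if (!is.numeric(code) || length(code) != 1L || is.na(code) ||
      code != round(code) || code < 0 || code > 511) {
    stop_domain("code must be a single integer in [0, 511]")
  }
  bits <- as.integer(intToBits(as.integer(code)))[9:1]
  matrix(bits, nrow = PATCH_SIZE, byrow = TRUE)
}

# Pattern codes at every valid center of a binary matrix: centers are pixels
# with a complete 3x3 neighborhood, so the result is an (h-2) x (w-2) matrix.
patch_code_matrix <- function(px) {
  check_matrix_binary(px)
  h <- nrow(px)
  w <- ncol(px)
  if (h < PATCH_SIZE || w < PATCH_SIZE) {
    stop_domain("image must be at least 3x3 for patch extraction")
  }
  codes <- matrix(0, h - 2L, w - 2L)
  k <- 0L
  for (dr in 0:2) {
    for (dc in 0:2) {
      codes <- codes + px[(1L + dr):(h - 2L + dr), (1L + dc):(w - 2L + dc),
                          drop = FALSE] * 2^(8L - k)
      k <- k + 1L
    }
  }
  storage.mode(codes) <- "integer"
  codes
}

#' Empirical distribution of 3x3 patch patterns over binary images
#'
#' Counts every 3x3 patch centered on every pixel with a complete
#' neighborhood (overlapping windows included), pooled over all supplied
#' images. This is the ensemble statistic that feature selection operates on.
#'
#' @param imgs A binary image (see [binarize()]) or a list of them; plain
#'   `{0,1}` matrices are accepted too. Every image must be at least 3x3.
#' @return An object of class `patch_distribution` with components `counts`
#'   (integer vector of length 512, indexed by pattern code + 1), `total`
#'   (number of windows counted) and `prob` (`counts / total`).
#' @examples
#' d <- patch_distribution(matrix(1, 5, 5))
#' d$counts[[512]] # the all-ones pattern occupies all 9 windows
#' @export
patch_distribution <- function(imgs) {
  if (is.matrix(imgs) || inherits(imgs, "binary_image")) imgs <- list(imgs)
  if (!is.list(imgs) || length(imgs) == 0L) {
    stop_domain("imgs must be one binary image or a non-empty list of them")
  }
  counts <- integer(N_PATTERNS)
  total <- 0L
  for (im in imgs) {
    px <- if (inherits(im, "binary_image")) im$pixels else im
    codes <- patch_code_matrix(px)
    counts <- counts + tabulate(as.vector(codes) + 1L, nbins = N_PATTERNS)
    total <- total + length(codes)
  }
  new_patch_distribution(counts, total)
}

# Constructor used both by the image path and by tests that specify
# probabilities directly.
new_patch_distribution <- function(counts, total) {
  stopifnot(length(counts) == N_PATTERNS, total > 0)
  structure(
    list(counts = as.integer(counts), total = as.integer(total),
         prob = counts / total),
    class = "patch_distribution"
  )
}

#' Build a patch distribution from explicit pattern probabilities
#'
#' Mainly for tests and worked examples where the alphabet is small and the
#' probabilities are chosen by hand. Probabilities must sum to 1.
#'
#' @param codes Integer pattern codes in `[0, 511]`, no duplicates.
#' @param probs Probabilities for each code, summing to 1.
#' @param total Pseudo-count total used to express the probabilities as
#'   integer counts (default `1e6`); probabilities are taken at face value.
#' @return A `patch_distribution`.
#' @export
patch_distribution_from_probs <- function(codes, probs, total = 1e6) {
  stopifnot(length(codes) == length(probs), !anyDuplicated(codes),
            all(codes >= 0), all(codes <= 511), all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-9) {
    stop_domain("probs must sum to 1")
  }
  counts <- numeric(N_PATTERNS)
  counts[codes + 1L] <- probs * total
  d <- structure(
    list(counts = counts, total = total, prob = counts / total),
    class = "patch_distribution"
  )
  d
}

#' @export
print.patch_distribution <- function(x, ...) {
  nz <- sum(x$prob > 0)
  cat("Patch distribution over 3x3 binary patterns\n")
  cat(sprintf("  windows counted: %s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  patterns observed: %d / 512\n", nz))
  cat(sprintf("  entropy of full distribution: %.3f bits\n",
              sum(entropy_contribution(x$prob[x$prob > 0]))))
  invisible(x)
}
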