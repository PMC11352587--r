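# Constrained maximum-entropy feature selection.
#
# A feature set S maximizes sum_{i in S} p_i * log2(1 / p_i) subject to
# |S| <= N (capacity: the system can store only N distinct features) and
# sum_{i in S} p_i <= W (bandwidth: the retained features may cover at most
# a fraction W of the input). Selection is deterministic: candidates are
# ranked by descending entropy contribution with ties broken by ascending
# pattern code.

BANDWIDTH_TOL <- 1e-12

#' Shannon entropy contribution of a single pattern
#'
#' Returns `p * log2(1/p)`, the term a pattern with occurrence probability
#' `p` adds to the output entropy of a system that transmits it. By the
#' usual limit convention the contribution is 0 at both `p = 0` and `p = 1`.
#'
#' @param p Probability (vectorized), each value in `[0, 1]`.
#' @return Entropy contribution(s) in bits.
#' @examples
#' entropy_contribution(0.5) # 0.5
#' entropy_contribution(c(0, 1)) # both 0
#' @export
entropy_contribution <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_domain("p must be numeric in [0, 1]")
  }
  out <- numeric(length(p))
  pos <- p > 0 & p < 1
  out[pos] <- p[pos] * log2(1 / p[pos])
  out
}

new_feature_set <- function(codes, probs, N, W) {
  structure(
    list(codes = as.integer(codes), probs = as.numeric(probs),
         N = as.integer(N), W = as.numeric(W),
         total_prob = sum(probs),
         entropy_bits = sum(entropy_contribution(probs))),
    class = "feature_set"
  )
}

check_nw <- function(N, W) {
  if (!is_count(N)) stop_domain("N must be a positive integer")
  if (!is.numeric(W) || length(W) != 1L || is.na(W) || W <= 0 || W > 1) {
    stop_domain("W must be in (0, 1]")
  }
}

#' Greedy constrained maximum-entropy feature selection
#'
#' The base procedure ranks all patterns with non-zero probability by
#' descending entropy contribution (ties: ascending pattern code) and scans
#' the ranking, admitting a pattern whenever doing so keeps the selected
#' total probability within the bandwidth `W`, until `N` features are
#' selected or candidates run out.
#'
#' Because the constrained problem is a knapsack, the plain scan can pack
#' the bandwidth poorly when a few high-probability patterns crowd out
#' combinations of lighter ones. With `refine = TRUE` (the default) the
#' scan is followed by a deterministic local refinement: the scan is
#' repeated with the candidate list truncated at every probability ceiling
#' (so "all patterns lighter than x" solutions are always considered), and
#' the best solution is improved by drop-and-refill moves — remove up to
#' `max_drop` selected patterns and greedily refill — until no move raises
#' the total entropy. The refinement depth adapts to the alphabet size so
#' runtime stays modest on full 512-pattern image distributions; `refine =
#' FALSE` gives the plain single-scan behaviour.
#'
#' @param dist A [patch_distribution].
#' @param N Capacity: maximum number of features (the reference stimuli use
#'   `N = 50`).
#' @param W Bandwidth: cap on the total probability of selected features
#'   (the reference stimuli use `W = 0.05`).
#' @param refine Apply the local refinement (default TRUE).
#' @return A `feature_set` with the selected pattern `codes` (ordered by
#'   descending entropy contribution), their `probs`, and the achieved
#'   `total_prob` and `entropy_bits`.
#' @seealso [select_features_exact()] for the exhaustive solver usable on
#'   small alphabets.
#' @export
select_features_greedy <- function(dist, N, W, refine = TRUE) {
  stopifnot(inherits(dist, "patch_distribution"))
  check_nw(N, W)
  p <- dist$prob
  cand <- which(p > 0) - 1L # pattern codes, ascending
  if (length(cand) == 0L) stop_domain("distribution has no observed patterns")
  pc <- p[cand + 1L]
  h <- entropy_contribution(pc)
  m <- length(cand)
  ord_h <- order(-h, cand)
  fill <- function(sel, ord, forbid = integer(0)) {
    tot <- sum(pc[sel])
    cnt <- sum(sel)
    for (i in ord) {
      if (cnt >= N) break
      if (!(i %in% forbid) && !sel[i] && h[i] > 0 &&
          tot + pc[i] <= W + BANDWIDTH_TOL) {
        sel[i] <- TRUE
        tot <- tot + pc[i]
        cnt <- cnt + 1L
      }
    }
    sel
  }
  val <- function(sel) sum(h[sel])
  best <- fill(rep(FALSE, m), ord_h)
  if (refine) {
    # candidate orders truncated at each probability ceiling
    ceilings <- unique(sort(pc, decreasing = TRUE))
    orders <- lapply(ceilings[-1], function(ce) {
      ord_h[pc[ord_h] <= ce + BANDWIDTH_TOL]
    })
    best_fill <- function(base, forbid = integer(0)) {
      out <- fill(base, ord_h, forbid)
      for (ord in orders) {
        alt <- fill(base, ord, forbid)
        if (val(alt) > val(out) + 1e-12) out <- alt
      }
      out
    }
    best <- best_fill(rep(FALSE, m))
    # drop-and-refill depth: exhaustive small-subset drops are affordable
    # only on small alphabets; large alphabets get single drops
    max_drop <- if (m <= 24) 3L else 1L
    deep_orders <- m <= 24
    repeat {
      improved <- FALSE
      sel_idx <- which(best)
      for (depth in seq_len(min(max_drop, length(sel_idx)))) {
        drops <- if (depth == 1L) {
          matrix(sel_idx, nrow = 1L)
        } else {
          utils::combn(sel_idx, depth)
        }
        for (q in seq_len(ncol(drops))) {
          ij <- drops[, q]
          base <- best
          base[ij] <- FALSE
          alt <- if (deep_orders) {
            best_fill(base, forbid = ij)
          } else {
            fill(base, ord_h, forbid = ij)
          }
          if (val(alt) > val(best) + 1e-12) {
            best <- alt
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
  }
  keep <- which(best)
  ord <- keep[order(-h[keep], cand[keep])]
  new_feature_set(cand[ord], pc[ord], N, W)
}

#' Exact constrained maximum-entropy feature selection (exhaustive)
#'
#' Enumerates every subset of the observed patterns and returns the one
#' maximizing total entropy subject to `|S| <= N` and `sum(p) <= W`. Ties
#' are broken in favour of the lexicographically smallest sorted code set.
#' Refuses alphabets larger than 20 patterns; intended as a gold standard
#' for validating the greedy solver on small problems.
#'
#' @inheritParams select_features_greedy
#' @return A `feature_set`.
#' @export
select_features_exact <- function(dist, N, W) {
  stopifnot(inherits(dist, "patch_distribution"))
  check_nw(N, W)
  p <- dist$prob
  cand <- which(p > 0) - 1L
  m <- length(cand)
  if (m == 0L) stop_domain("distribution has no observed patterns")
  if (m > 20L) {
    stop_domain("exact solver refuses alphabets larger than 20 patterns")
  }
  pc <- p[cand + 1L]
  h <- entropy_contribution(pc)
  masks <- 0:(2^m - 1)
  size <- integer(length(masks))
  sump <- numeric(length(masks))
  sumh <- numeric(length(masks))
  for (j in seq_len(m)) {
    on <- bitwAnd(masks, 2^(j - 1L)) > 0
    size <- size + on
    sump <- sump + on * pc[j]
    sumh <- sumh + on * h[j]
  }
  ok <- size <= N & sump <= W + BANDWIDTH_TOL
  best_h <- max(sumh[ok])
  tied <- masks[ok & abs(sumh - best_h) < 1e-12]
  best <- tied[[1L]]
  if (length(tied) > 1L) {
    best_codes <- sort(cand[bitwAnd(tied[[1L]], 2^(seq_len(m) - 1L)) > 0])
    for (mk in tied[-1L]) {
      codes_mk <- sort(cand[bitwAnd(mk, 2^(seq_len(m) - 1L)) > 0])
      if (codeset_less(codes_mk, best_codes)) {
        best <- mk
        best_codes <- codes_mk
      }
    }
  }
  keep <- bitwAnd(best, 2^(seq_len(m) - 1L)) > 0
  # report in the same deterministic order as the greedy solver
  ord <- order(-h[keep], cand[keep])
  new_feature_set(cand[keep][ord], pc[keep][ord], N, W)
}

# Lexicographic comparison of two sorted code vectors (shorter prefix wins).
codeset_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d patterns (N = %d, W = %.4g)\n",
              length(x$codes), x$N, x$W))
  cat(sprintf("  total probability: %.6f\n", x$total_prob))
  cat(sprintf("  entropy: %.4f bits\n", x$entropy_bits))
  invisible(x)
}

#' Serialize a feature set to JSON
#'
#' @param fs A `feature_set`.
#' @param path Output file path.
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  jsonlite::write_json(
    list(codes = fs$codes, probs = fs$probs, N = fs$N, W = fs$W,
         total_prob = fs$total_prob, entropy_bits = fs$entropy_bits),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_feature_set(x$codes, x$probs, x$N, x$W)
}
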