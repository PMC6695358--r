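# Numerical primitives shared across the package.

# Probability floor applied before any logarithm. Zeros in likelihood or
# transition arrays are replaced by this value and the column renormalised.
.P_FLOOR <- 1e-16

#' Softmax of a numeric vector
#'
#' Numerically stable softmax, the workhorse for every categorical
#' normalisation in the package. Operates column-wise when given a matrix.
#'
#' @param x Numeric vector or matrix (columns are treated independently).
#' @return Object of the same shape with non-negative entries summing to 1
#'   (per column).
#' @export
#' @examples
#' softmax(c(0, 0))
#' softmax(log(c(0.8, 0.2)) * 2)
softmax <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    cm <- x[cbind(max.col(t(x), ties.method = "first"), seq_len(ncol(x)))]
    e <- exp(x - rep(cm, each = n))
    return(e * rep(1 / colSums(e), each = n))
  }
  e <- exp(x - max(x))
  e / sum(e)
}

# Floor probabilities and renormalise columns of a matrix whose first
# dimension indexes the category.
.floor_cols <- function(m) {
  m[m < .P_FLOOR] <- .P_FLOOR
  sweep(m, 2, colSums(m), "/")
}

# log after flooring; for arrays of probabilities.
.ln <- function(p) log(pmax(p, .P_FLOOR))

# Normalise a vector of non-negative weights to a categorical distribution.
.norm_vec <- function(p) {
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) return(rep(1 / length(p), length(p)))
  p / s
}

.assert_dist <- function(p, tol = 1e-9, what = "distribution") {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(sprintf("invalid %s: entries must be >= 0 and sum to 1", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. All stochastic entry points route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-trial seed stream: the first n draws are identical for
# any larger n under the same master seed, so trial counts can grow without
# perturbing earlier trials.
trial_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Khatri-Rao style column-wise outer product of two probability matrices
# (rows x policies): result rows index (i, j) with i fastest, matching R's
# column-major flattening of array dims.
.kr2 <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  a[rep(seq_len(na), times = nb), , drop = FALSE] *
    b[rep(seq_len(nb), each = na), , drop = FALSE]
}

.kr_list <- function(mats) {
  out <- mats[[1]]
  if (length(mats) > 1) {
    for (k in 2:length(mats)) out <- .kr2(out, mats[[k]])
  }
  out
}
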