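#' Behaviour part names
#'
#' The three intensity classes of the 24-h movement composition, in the fixed
#' order used throughout the package: sedentary behaviour (SB), light physical
#' activity (LPA), and moderate-to-vigorous physical activity (MVPA).
#'
#' @return Character vector `c("sb", "lpa", "mvpa")`.
#' @export
behaviour_parts <- function() c("sb", "lpa", "mvpa")

# Coerce a composition argument to an n x 3 matrix with canonical column names.
as_comp_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(c(behaviour_parts(), colnames(x)), colnames(x)), drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop("a behaviour composition has exactly 3 parts (sb, lpa, mvpa); got ", ncol(x))
  if (!is.numeric(x)) stop("composition parts must be numeric")
  colnames(x) <- behaviour_parts()
  x
}

#' Close a composition to a fixed total
#'
#' Rescales strictly positive parts so that each row sums to `total`
#' (the closure operation of Aitchison geometry). The default total of
#' 600 minutes corresponds to a 10-h bounded day of classified behaviour.
#'
#' @param x Numeric vector of 3 parts (SB, LPA, MVPA) or an n x 3 matrix /
#'   data frame of compositions, in any positive units.
#' @param total Positive scalar the parts should sum to (600, 1440, or 1 for
#'   proportions).
#' @return Composition(s) of the same shape as `x`, rows summing to `total`.
#' @examples
#' close_composition(c(559.72, 6.57, 33.71), total = 1)
#' @export
close_composition <- function(x, total = 600) {
  vec <- is.null(dim(x))
  m <- as_comp_matrix(x)
  if (!is.numeric(total) || length(total) != 1L || total <= 0)
    stop("total must be a positive scalar")
  if (any(m <= 0))
    stop("all parts must be strictly positive; run zero_replace() first")
  out <- m * (total / rowSums(m))
  if (vec) out[1L, ] else out
}

#' Replace zero parts by a small positive amount
#'
#' Zeros are replaced by `epsilon` and the non-zero parts are shrunk
#' multiplicatively so each row's total is preserved. The default epsilon is
#' half of one 10-s epoch expressed in minutes (1/12 min).
#'
#' @param x Composition vector or matrix with non-negative parts.
#' @param epsilon Replacement value for zero parts, in the units of `x`.
#' @return Strictly positive composition(s) with row totals unchanged.
#' @export
zero_replace <- function(x, epsilon = 1 / 12) {
  vec <- is.null(dim(x))
  m <- as_comp_matrix(x)
  if (any(m < 0)) stop("parts must be non-negative")
  if (any(rowSums(m) <= 0)) stop("all-zero composition cannot be replaced")
  if (epsilon <= 0) stop("epsilon must be positive")
  out <- m
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (any(z)) {
      tot <- sum(m[i, ])
      need <- sum(z) * epsilon
      if (need >= tot) stop("epsilon too large for row total")
      out[i, z] <- epsilon
      out[i, !z] <- m[i, !z] * (tot - need) / tot
    }
  }
  if (vec) out[1L, ] else out
}

#' Geometric-mean composition of a sample
#'
#' The compositional centre: component-wise geometric mean across samples,
#' closed to `total`. This is the sample baseline used for isotemporal
#' substitution.
#'
#' @param x n x 3 matrix or data frame of strictly positive compositions.
#' @param total Closure total of the result (default 600 min).
#' @return Length-3 named composition summing to `total`.
#' @export
geometric_mean_composition <- function(x, total = 600) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 1L) stop("need at least one composition")
  if (any(m <= 0)) stop("all parts must be strictly positive")
  g <- exp(colMeans(log(m)))
  close_composition(g, total = total)
}

#' Pairwise log-ratio variation matrix
#'
#' Entry (i, j) is the sample variance (denominator n - 1) of
#' log(part_i / part_j) across samples. Values near zero indicate two
#' behaviours that are nearly proportional across the sample; the matrix is
#' symmetric with a zero diagonal and is invariant to per-sample closure.
#'
#' @param x n x 3 matrix or data frame of strictly positive compositions,
#'   n >= 2.
#' @return 3 x 3 symmetric matrix with dimnames `behaviour_parts()`.
#' @export
variation_matrix <- function(x) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 compositions for a variation matrix")
  if (any(m <= 0)) stop("all parts must be strictly positive")
  lm_ <- log(m)
  d <- ncol(m)
  v <- matrix(0, d, d, dimnames = list(behaviour_parts(), behaviour_parts()))
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    v[i, j] <- v[j, i] <- stats::var(lm_[, i] - lm_[, j])
  }
  v
}

#' Orthonormal ilr basis from a sequential binary partition
#'
#' Builds the 3 x 2 contrast matrix whose columns are orthonormal clr-plane
#' basis vectors for a sequential binary partition (SBP) of the three parts.
#' The default SBP is {SB | LPA, MVPA} then {LPA | MVPA}, giving
#' z1 = sqrt(2/3) log(SB / sqrt(LPA * MVPA)) and
#' z2 = sqrt(1/2) log(LPA / MVPA).
#'
#' @param sbp 2 x 3 sign matrix (+1 numerator group, -1 denominator group,
#'   0 absent), one row per balance.
#' @return 3 x 2 matrix `V` with `t(V) %*% V = I` and zero column sums.
#' @export
ilr_basis <- function(sbp = default_sbp()) {
  sbp <- as.matrix(sbp)
  if (!all(dim(sbp) == c(2L, 3L))) stop("sbp must be a 2 x 3 sign matrix")
  if (!all(sbp %in% c(-1, 0, 1))) stop("sbp entries must be -1, 0 or +1")
  V <- matrix(0, 3L, 2L, dimnames = list(behaviour_parts(), c("z1", "z2")))
  for (k in 1:2) {
    r <- sum(sbp[k, ] == 1)
    s <- sum(sbp[k, ] == -1)
    if (r == 0L || s == 0L) stop("each balance needs parts on both sides")
    a <- sqrt(s / (r * (r + s)))
    b <- -sqrt(r / (s * (r + s)))
    V[sbp[k, ] == 1, k] <- a
    V[sbp[k, ] == -1, k] <- b
  }
  g <- crossprod(V)
  if (max(abs(g - diag(2))) > 1e-10)
    stop("sbp does not define an orthonormal basis (balances must be nested)")
  V
}

#' @rdname ilr_basis
#' @export
default_sbp <- function() {
  matrix(c(1, -1, -1,
           0,  1, -1), nrow = 2, byrow = TRUE,
         dimnames = list(c("z1", "z2"), behaviour_parts()))
}

#' @rdname ilr_basis
#' @details `alternative_sbp()` gives the partition {MVPA | SB, LPA} then
#'   {SB | LPA}, useful for verifying that regression summaries do not
#'   depend on the basis choice.
#' @export
alternative_sbp <- function() {
  matrix(c(-1, -1, 1,
            1, -1, 0), nrow = 2, byrow = TRUE,
         dimnames = list(c("z1", "z2"), behaviour_parts()))
}

#' Isometric log-ratio transform
#'
#' Maps strictly positive 3-part compositions to 2 unconstrained coordinates
#' via an orthonormal log-ratio basis. The result is invariant to the
#' composition's total (closure).
#'
#' @param x Composition vector or n x 3 matrix / data frame, strictly
#'   positive.
#' @param basis 3 x 2 contrast matrix from [ilr_basis()].
#' @return Length-2 vector `(z1, z2)` or n x 2 matrix.
#' @export
ilr_transform <- function(x, basis = ilr_basis()) {
  vec <- is.null(dim(x))
  m <- as_comp_matrix(x)
  if (any(m <= 0)) stop("ilr requires strictly positive parts")
  z <- log(m) %*% basis
  colnames(z) <- c("z1", "z2")
  if (vec) z[1L, ] else z
}

#' Inverse ilr transform
#'
#' Recovers the unique strictly positive composition with the given ilr
#' coordinates and total.
#'
#' @param z Length-2 coordinate vector or n x 2 matrix.
#' @param total Closure total of the result (default 600 min).
#' @param basis 3 x 2 contrast matrix from [ilr_basis()].
#' @return Composition(s) with `ilr_transform(result, basis) == z`.
#' @export
ilr_inverse <- function(z, total = 600, basis = ilr_basis()) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1)
  z <- as.matrix(z)
  if (ncol(z) != 2L) stop("ilr coordinates have 2 components")
  if (!all(is.finite(z))) stop("ilr coordinates must be finite")
  clr <- z %*% t(basis)
  comp <- exp(clr)
  out <- close_composition(comp, total = total)
  if (vec) out[1L, ] else out
}

#' Aitchison distance between two compositions
#'
#' Equals the Euclidean distance between the ilr images; computed here
#' directly from the full set of pairwise log-ratios so it can serve as an
#' independent check of the isometry.
#'
#' @param x,y Length-3 strictly positive compositions.
#' @return Non-negative scalar distance.
#' @export
aitchison_distance <- function(x, y) {
  x <- as_comp_matrix(x)[1L, ]
  y <- as_comp_matrix(y)[1L, ]
  if (any(x <= 0) || any(y <= 0)) stop("parts must be strictly positive")
  d <- length(x)
  s <- 0
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    s <- s + (log(x[i] / x[j]) - log(y[i] / y[j]))^2
  }
  unname(sqrt(s / d))
}

#' Reallocate time between two behaviours
#'
#' Moves `delta` minutes from one part to another, leaving the third part and
#' the total unchanged (the raw-minutes construction of isotemporal
#' substitution). With `clamp = TRUE`, a donor part smaller than
#' `delta + epsilon` is floored at `epsilon` and only the available time is
#' moved, so the perturbed composition stays strictly inside the simplex;
#' otherwise an infeasible reallocation is an error.
#'
#' @param x Length-3 composition (minutes).
#' @param add,remove Part names from `behaviour_parts()`; must differ.
#' @param delta Non-negative minutes to move.
#' @param clamp Logical; floor the donor at `epsilon` instead of erroring.
#' @param epsilon Donor floor used when `clamp = TRUE` (default 1/12 min).
#' @return Length-3 composition with the same total as `x`.
#' @export
reallocate <- function(x, add, remove, delta, clamp = FALSE, epsilon = 1 / 12) {
  x <- as_comp_matrix(x)[1L, ]
  parts <- behaviour_parts()
  add <- match.arg(add, parts)
  remove <- match.arg(remove, parts)
  if (add == remove) stop("add and remove must be different behaviours")
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop("delta must be a non-negative scalar")
  moved <- delta
  if (x[remove] <= delta) {
    if (!clamp)
      stop(sprintf(
        "reallocation infeasible: removing %.3g min from %s leaves %.3g (deficit %.3g min)",
        delta, remove, x[remove] - delta, delta - x[remove]))
    moved <- max(x[remove] - epsilon, 0)
  }
  out <- x
  out[remove] <- x[remove] - moved
  out[add] <- x[add] + moved
  out
}

#' Convert a variation matrix to an ilr covariance
#'
#' Recovers the clr covariance implied by a pairwise log-ratio variation
#' matrix (using the zero-row-sum identifiability constraint) and projects it
#' onto an ilr basis. Used to turn published log-ratio variation summaries
#' into generator covariance defaults.
#'
#' @param v 3 x 3 symmetric variation matrix with zero diagonal.
#' @param basis 3 x 2 contrast matrix from [ilr_basis()].
#' @return 2 x 2 symmetric positive-definite ilr covariance matrix.
#' @export
ilr_covariance_from_variation <- function(v, basis = ilr_basis()) {
  v <- as.matrix(v)
  if (!all(dim(v) == c(3L, 3L)) || max(abs(v - t(v))) > 1e-10 || any(diag(v) != 0))
    stop("v must be a symmetric 3 x 3 matrix with zero diagonal")
  d <- 3L
  r <- rowMeans(v)
  tr <- sum(r) / 2
  gamma <- matrix(0, d, d)
  diag(gamma) <- r - tr / d
  for (i in 1:(d - 1L)) for (j in (i + 1L):d) {
    gamma[i, j] <- gamma[j, i] <- (gamma[i, i] + gamma[j, j] - v[i, j]) / 2
  }
  sig <- t(basis) %*% gamma %*% basis
  sig <- (sig + t(sig)) / 2
  if (any(eigen(sig, symmetric = TRUE, only.values = TRUE)$values <= 1e-12))
    stop("variation matrix does not imply a positive-definite ilr covariance")
  dimnames(sig) <- list(c("z1", "z2"), c("z1", "z2"))
  sig
}
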