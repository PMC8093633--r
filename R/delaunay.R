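# Bowyer-Watson incremental Delaunay triangulation in plain R. The vertex
# counts used for fiber fields (a few hundred points) make an O(n^2)
# insertion scheme entirely adequate.
#
# The bounding "super triangle" is treated symbolically as three vertices at
# infinity in fixed directions. Triangles touching them use the limit forms
# of the in-circle and orientation predicates (a half-plane test) instead of
# literal far-away coordinates; a finite super triangle is either too close
# (misses hull triangles whose circumcircles are huge) or too far (the
# determinant predicate loses precision).

# directions of the three vertices at infinity, counter-clockwise
.SUPER_U <- matrix(c(-sqrt(3) / 2, -0.5,
                      sqrt(3) / 2, -0.5,
                      0,            1), 3, 2, byrow = TRUE)

#' Delaunay triangulation of a 2D point set
#'
#' @param x,y coordinates of the points (no duplicates; not all collinear).
#' @return integer matrix with three columns; each row indexes the vertices
#'   of one triangle, rows sorted lexicographically so the triangle order is
#'   deterministic.
#' @export
#' @examples
#' p <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' delaunay(p[, 1], p[, 2]) # two triangles covering the unit square
delaunay <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3, all(is.finite(x)), all(is.finite(y)))
  if (anyDuplicated(cbind(x, y)) > 0) stop("duplicate vertices")
  span <- max(diff(range(x)), diff(range(y)))
  if (span <= 0) stop("degenerate (collinear) vertex set")
  areas2 <- abs((x - x[1]) * (y[2] - y[1]) - (x[2] - x[1]) * (y - y[1]))
  if (max(areas2) < 1e-12 * span^2) stop("degenerate (collinear) vertex set")

  px <- (x - min(x)) / span       # unit scale for conditioning
  py <- (y - min(y)) / span
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  ux <- function(v) .SUPER_U[v - n, 1]
  uy <- function(v) .SUPER_U[v - n, 2]

  # orientation with vertices possibly at infinity; a,b,c scalars
  orient3 <- function(a, b, c) {
    sup <- c(a, b, c) > n
    v <- c(a, b, c)
    ns <- sum(sup)
    if (ns == 0) {
      (px[b] - px[a]) * (py[c] - py[a]) - (py[b] - py[a]) * (px[c] - px[a])
    } else if (ns == 1) {
      k <- which(sup)                     # rotate the super vertex to last
      v <- c(v[-seq_len(k)], v[seq_len(k)])  # cyclic: (k+1.., 1..k)
      A <- v[1]; B <- v[2]; s <- v[3]
      (px[B] - px[A]) * uy(s) - (py[B] - py[A]) * ux(s)
    } else if (ns == 2) {
      k <- which(!sup)                    # rotate the real vertex to first
      v <- c(v[seq(k, 3)], v[seq_len(k - 1)])
      si <- v[2]; sj <- v[3]
      ux(si) * uy(sj) - uy(si) * ux(sj)
    } else {
      1 # (s1, s2, s3) is counter-clockwise by construction
    }
  }

  # counter-clockwise storage
  make_ccw <- function(a, b, c) {
    if (orient3(a, b, c) < 0) c(a, c, b) else c(a, b, c)
  }

  A <- s1; B <- s2; C <- s3
  nsup <- 3L                              # per-triangle super-vertex count

  for (i in seq_len(n)) {
    ntri <- length(A)
    bad <- logical(ntri)

    real <- which(nsup == 0L)
    if (length(real)) {                   # vectorised in-circle determinant
      a <- A[real]; b <- B[real]; cc <- C[real]
      adx <- px[a] - px[i]; ady <- py[a] - py[i]
      bdx <- px[b] - px[i]; bdy <- py[b] - py[i]
      cdx <- px[cc] - px[i]; cdy <- py[cc] - py[i]
      a2 <- adx^2 + ady^2; b2 <- bdx^2 + bdy^2; c2 <- cdx^2 + cdy^2
      det <- adx * (bdy * c2 - b2 * cdy) -
             ady * (bdx * c2 - b2 * cdx) +
             a2 * (bdx * cdy - bdy * cdx)
      bad[real] <- det > 0
    }
    for (t in which(nsup == 1L)) {        # half-plane limit of the circle
      v <- c(A[t], B[t], C[t])
      k <- which(v > n)
      v <- c(v[-seq_len(k)], v[seq_len(k)])
      Xa <- v[1]; Xb <- v[2]
      bad[t] <- (px[Xb] - px[Xa]) * (py[i] - py[Xa]) -
                (py[Xb] - py[Xa]) * (px[i] - px[Xa]) > 0
    }
    for (t in which(nsup == 2L)) {
      v <- c(A[t], B[t], C[t])
      k <- which(v <= n)
      v <- c(v[seq(k, 3)], v[seq_len(k - 1)])
      X <- v[1]; si <- v[2]; sj <- v[3]
      bad[t] <- (px[X] - px[i]) * (uy(si) - uy(sj)) -
                (py[X] - py[i]) * (ux(si) - ux(sj)) > 0
    }
    bad[nsup == 3L] <- TRUE

    bw <- which(bad)
    if (length(bw) == 0L)
      stop("Delaunay insertion failed (degenerate point configuration)")
    edges <- rbind(cbind(A[bw], B[bw]), cbind(B[bw], C[bw]),
                   cbind(C[bw], A[bw]))
    e1 <- pmin(edges[, 1], edges[, 2]); e2 <- pmax(edges[, 1], edges[, 2])
    key <- e1 * (n + 4) + e2
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    A <- A[-bw]; B <- B[-bw]; C <- C[-bw]; nsup <- nsup[-bw]
    for (e in which(once)) {
      tr <- make_ccw(i, edges[e, 1], edges[e, 2])
      A <- c(A, tr[1]); B <- c(B, tr[2]); C <- c(C, tr[3])
      nsup <- c(nsup, sum(tr > n))
    }
  }
  keep <- nsup == 0L
  real <- cbind(A[keep], B[keep], C[keep])
  real <- t(apply(real, 1, sort))
  real[order(real[, 1], real[, 2], real[, 3]), , drop = FALSE]
}
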