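# B-spline bases on the position and time domains, tensor-product
# coefficient surfaces, and quadrature for genotype-times-basis integrals.

#' Construct a univariate B-spline basis
#'
#' Builds an order-\code{order} B-spline basis with \code{n_basis} functions
#' on \code{[domain_lo, domain_hi]}, with equally spaced interior knots and
#' full-multiplicity boundary knots, so the basis forms a partition of unity
#' on the whole domain.
#'
#' @param domain_lo,domain_hi real endpoints of the domain,
#'   \code{domain_hi > domain_lo}.
#' @param n_basis number of basis functions; must be at least \code{order}.
#' @param order spline order (order = polynomial degree + 1; 4 = cubic).
#' @param knots optional full knot vector (including boundary multiplicity);
#'   derived from the arguments when \code{NULL}.
#' @return an object of class \code{"lfdat_basis"} with elements
#'   \code{domain_lo}, \code{domain_hi}, \code{order}, \code{n_basis},
#'   \code{knots}.
#' @examples
#' b <- make_bspline_basis(0, 9, 15, 4)
#' E <- eval_basis(b, seq(0, 9, length.out = 50))
#' range(rowSums(E))   # partition of unity
#' @export
make_bspline_basis <- function(domain_lo, domain_hi, n_basis, order = 4L,
                               knots = NULL) {
  if (!is.numeric(domain_lo) || !is.numeric(domain_hi) ||
      domain_hi <= domain_lo)
    stop("degenerate domain: require domain_hi > domain_lo")
  order <- as.integer(order)
  n_basis <- as.integer(n_basis)
  if (order < 1L) stop("order must be >= 1")
  if (n_basis < order)
    stop("n_basis (", n_basis, ") must be >= order (", order, ")")
  if (is.null(knots)) {
    n_interior <- n_basis - order
    interior <- if (n_interior > 0L)
      seq(domain_lo, domain_hi, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
    else numeric(0)
    knots <- c(rep(domain_lo, order), interior, rep(domain_hi, order))
  } else {
    if (is.unsorted(knots)) stop("knots must be nondecreasing")
    if (min(knots) != domain_lo || max(knots) != domain_hi)
      stop("knots must span exactly [domain_lo, domain_hi]")
    if (length(knots) != n_basis + order)
      stop("length(knots) must equal n_basis + order")
  }
  structure(list(domain_lo = domain_lo, domain_hi = domain_hi,
                 order = order, n_basis = n_basis, knots = knots),
            class = "lfdat_basis")
}

#' Evaluate a B-spline basis (or a derivative) at a set of points
#'
#' @param basis an \code{"lfdat_basis"} object.
#' @param x evaluation points, all inside the basis domain.
#' @param deriv derivative order (0 = the functions themselves).
#' @return matrix of dimension \code{length(x) x n_basis}.
#' @export
eval_basis <- function(basis, x, deriv = 0L) {
  stopifnot(inherits(basis, "lfdat_basis"))
  if (any(x < basis$domain_lo | x > basis$domain_hi))
    stop("evaluation points outside the basis domain [",
         basis$domain_lo, ", ", basis$domain_hi, "]")
  splines::splineDesign(basis$knots, x, ord = basis$order,
                        derivs = rep(as.integer(deriv), length(x)),
                        outer.ok = FALSE)
}

# Gauss-Legendre nodes/weights on [-1, 1]; order + 2 nodes is exact for
# products of two basis functions (degree 2*(order-1)) with margin.
.gl_rule <- function(order) pracma::gaussLegendre(order + 2L, -1, 1)

#' Gram matrix of a basis or of one of its derivatives
#'
#' Computes \eqn{\int \phi^{(d)}(x) \phi^{(d)}(x)^T dx} over the basis
#' domain by per-knot-span Gauss-Legendre quadrature (exact for the
#' piecewise-polynomial integrand).
#'
#' @param basis an \code{"lfdat_basis"} object.
#' @param deriv derivative order d (2 gives the curvature penalty matrix).
#' @return symmetric \code{n_basis x n_basis} matrix.
#' @export
basis_gram <- function(basis, deriv = 0L) {
  stopifnot(inherits(basis, "lfdat_basis"))
  if (deriv > 0L && basis$order < deriv + 1L)
    stop("order must be >= ", deriv + 1L, " for derivative ", deriv)
  rule <- .gl_rule(basis$order)
  breaks <- unique(basis$knots)
  M <- matrix(0, basis$n_basis, basis$n_basis)
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    h <- (b - a) / 2
    x <- a + (rule$x + 1) * h
    E <- eval_basis(basis, x, deriv)
    M <- M + crossprod(E, E * (rule$w * h))
  }
  (M + t(M)) / 2
}

#' Integrals of every basis function over a set of intervals
#'
#' Returns the matrix \code{I[i, j] = \int_{edges[i]}^{edges[i+1]} phi_j(s) ds},
#' computed exactly (per-polynomial-piece quadrature).  Used to turn a
#' step-function genotype profile into functional regression weights.
#'
#' @param basis an \code{"lfdat_basis"} object.
#' @param edges nondecreasing interval edges inside the domain
#'   (\code{length(edges) >= 2}).
#' @return matrix of dimension \code{(length(edges)-1) x n_basis}.
#' @export
basis_interval_integrals <- function(basis, edges) {
  stopifnot(inherits(basis, "lfdat_basis"), length(edges) >= 2L)
  if (is.unsorted(edges)) stop("edges must be nondecreasing")
  if (edges[1] < basis$domain_lo || edges[length(edges)] > basis$domain_hi)
    stop("edges outside the basis domain")
  rule <- .gl_rule(basis$order)
  cuts <- sort(unique(c(edges, unique(basis$knots))))
  cuts <- cuts[cuts >= edges[1] & cuts <= edges[length(edges)]]
  out <- matrix(0, length(edges) - 1L, basis$n_basis)
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    if (b <= a) next
    row <- findInterval((a + b) / 2, edges, rightmost.closed = TRUE)
    h <- (b - a) / 2
    x <- a + (rule$x + 1) * h
    out[row, ] <- out[row, ] + colSums(eval_basis(basis, x) * (rule$w * h))
  }
  out
}

#' Quadrature weights linking a genotype vector to the position basis
#'
#' Produces the \code{L x n_basis} matrix \code{W} with
#' \eqn{\int_0^M x_i(s) \phi_j(s) ds = \sum_l x_{il} W[l, j]} under the
#' chosen genotype-function convention:
#' \describe{
#'   \item{\code{"step"}}{\eqn{x_i(s)} is the step function taking the
#'     value \eqn{x_{il}} between the midpoints flanking SNP \eqn{l}
#'     (boundary intervals clipped to the domain); \code{W[l, j]} is the
#'     exact integral of \eqn{\phi_j} over that interval.}
#'   \item{\code{"point"}}{per-SNP point masses,
#'     \code{W[l, j] = phi_j(s_l) * (M / L)}.}
#' }
#'
#' @param positions strictly increasing SNP positions inside the basis
#'   domain.
#' @param s_basis position-domain \code{"lfdat_basis"}.
#' @param mode genotype-function convention, \code{"step"} (default) or
#'   \code{"point"}.
#' @return numeric matrix \code{length(positions) x n_basis}.
#' @export
genotype_functional_weights <- function(positions, s_basis,
                                        mode = c("step", "point")) {
  mode <- match.arg(mode)
  L <- length(positions)
  if (L < 1L) stop("empty region: no SNP positions")
  if (L > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(positions < s_basis$domain_lo | positions > s_basis$domain_hi))
    stop("positions outside the basis domain")
  if (mode == "point") {
    width <- (s_basis$domain_hi - s_basis$domain_lo) / L
    return(eval_basis(s_basis, positions) * width)
  }
  mids <- if (L > 1L) (positions[-L] + positions[-1L]) / 2 else numeric(0)
  edges <- c(s_basis$domain_lo, mids, s_basis$domain_hi)
  basis_interval_integrals(s_basis, edges)
}

#' Tensor-product coefficient surface
#'
#' Represents \eqn{\beta(s, t) = \sum_j \sum_k c_{jk} \phi_j(s) \phi_k(t)}
#' over the product of a position basis and a time basis.  The coefficient
#' matrix flattens row-major (position index major) into the length
#' \code{K = m_s * m_t} coefficient vector used by the regression engine.
#'
#' @param s_basis,t_basis marginal \code{"lfdat_basis"} objects.
#' @param coef coefficient matrix (\code{s_basis$n_basis} rows,
#'   \code{t_basis$n_basis} columns); defaults to all zeros.
#' @return an object of class \code{"lfdat_surface"}.
#' @export
beta_surface <- function(s_basis, t_basis, coef = NULL) {
  stopifnot(inherits(s_basis, "lfdat_basis"), inherits(t_basis, "lfdat_basis"))
  if (is.null(coef)) coef <- matrix(0, s_basis$n_basis, t_basis$n_basis)
  coef <- as.matrix(coef)
  if (nrow(coef) != s_basis$n_basis || ncol(coef) != t_basis$n_basis)
    stop("coef must be ", s_basis$n_basis, " x ", t_basis$n_basis)
  structure(list(s_basis = s_basis, t_basis = t_basis, coef = coef),
            class = "lfdat_surface")
}

#' @rdname beta_surface
#' @param surface an \code{"lfdat_surface"} object.
#' @export
surface_coef_vector <- function(surface) {
  stopifnot(inherits(surface, "lfdat_surface"))
  as.vector(t(surface$coef))
}

#' @rdname beta_surface
#' @param b coefficient vector of length \code{m_s * m_t}, row-major.
#' @export
surface_from_vector <- function(s_basis, t_basis, b) {
  if (length(b) != s_basis$n_basis * t_basis$n_basis)
    stop("coefficient vector has wrong length")
  beta_surface(s_basis, t_basis,
               matrix(b, s_basis$n_basis, t_basis$n_basis, byrow = TRUE))
}

#' Evaluate a coefficient surface on a grid
#'
#' @param surface an \code{"lfdat_surface"} object.
#' @param s_grid,t_grid evaluation points inside the respective domains.
#' @return matrix \code{[i, q] = beta(s_grid[i], t_grid[q])}.
#' @export
eval_surface <- function(surface, s_grid, t_grid) {
  stopifnot(inherits(surface, "lfdat_surface"))
  Es <- eval_basis(surface$s_basis, s_grid)
  Et <- eval_basis(surface$t_basis, t_grid)
  Es %*% surface$coef %*% t(Et)
}

#' Export a coefficient surface as a long-format grid
#'
#' @param surface an \code{"lfdat_surface"} object.
#' @param n_s,n_t grid resolution in each direction.
#' @return data.frame with columns \code{s}, \code{t}, \code{value},
#'   suitable for \code{write.csv}.
#' @export
surface_grid_df <- function(surface, n_s = 50L, n_t = 50L) {
  s <- seq(surface$s_basis$domain_lo, surface$s_basis$domain_hi,
           length.out = n_s)
  t <- seq(surface$t_basis$domain_lo, surface$t_basis$domain_hi,
           length.out = n_t)
  V <- eval_surface(surface, s, t)
  data.frame(s = rep(s, times = n_t), t = rep(t, each = n_s),
             value = as.vector(V))
}

#' @export
print.lfdat_basis <- function(x, ...) {
  cat("B-spline basis: order", x$order, ",", x$n_basis, "functions on [",
      x$domain_lo, ",", x$domain_hi, "]\n")
  invisible(x)
}

#' @export
print.lfdat_surface <- function(x, ...) {
  cat("Tensor-product coefficient surface:",
      x$s_basis$n_basis, "x", x$t_basis$n_basis, "coefficients\n")
  invisible(x)
}
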