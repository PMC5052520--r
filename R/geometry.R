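# Pure geometry: angles, least-squares ring planes, and the single-frame
# halogen-bond tests. All comparisons against criteria are strict, so
# boundary geometries are never bonds.

vnorm <- function(v) sqrt(sum(v * v))

#' Angle at a vertex
#'
#' The angle a-b-c at vertex `b`, in degrees, in `[0, 180]`.
#'
#' @param a,b,c Numeric 3-vectors (Angstroms).
#' @return Angle in degrees.
#' @export
#' @examples
#' vec_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate geometry: zero-length arm in angle computation")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Fit a ring plane
#'
#' Total-least-squares plane through a set of ring atom positions: the
#' centroid is the arithmetic mean and the normal the direction
#' minimizing the sum of squared point-plane distances (smallest
#' principal component of the centered coordinates). The normal's sign
#' is arbitrary; downstream angle definitions are sign-invariant.
#'
#' @param positions `n x 3` matrix, `n >= 3`, in Angstroms.
#' @return List with `centroid` (3-vector), `normal` (unit 3-vector) and
#'   `rmsd` (root-mean-square point-plane distance, Angstroms).
#' @export
ring_plane <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3L)
    stop("degenerate ring: need at least 3 atoms, got ", nrow(positions))
  centroid <- colMeans(positions)
  centered <- sweep(positions, 2, centroid)
  sv <- svd(centered)
  # collinear points span < 2 dimensions: second singular value ~ 0
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate ring: atoms are collinear")
  normal <- sv$v[, 3]
  normal <- normal / vnorm(normal)
  resid <- as.vector(centered %*% normal)
  list(centroid = centroid, normal = normal,
       rmsd = sqrt(mean(resid^2)))
}

#' Test one point-acceptor halogen-bond geometry
#'
#' Checks the C-X...Y criteria for a donor carbon, halogen and acceptor
#' atom: distance X...Y strictly below the element-pair cutoff and angle
#' beta (at the halogen) strictly above `criteria$beta_min`.
#'
#' @param c_pos Donor carbon position (3-vector, Angstroms).
#' @param x_pos Halogen position.
#' @param y_pos Acceptor atom position.
#' @param x_element,y_element Element symbols of halogen and acceptor.
#' @param criteria [xbond_criteria()].
#' @return `NULL` if the geometry fails, else a list with `distance`
#'   (Angstroms) and `beta` (degrees).
#' @export
point_xbond_check <- function(c_pos, x_pos, y_pos, x_element, y_element,
                              criteria = xbond_criteria()) {
  d <- vnorm(x_pos - y_pos)
  if (d < 1e-12) stop("degenerate geometry: halogen and acceptor coincide")
  cutoff <- criteria_cutoff(criteria, x_element, y_element)
  if (d >= cutoff) return(NULL)
  beta <- vec_angle(c_pos, x_pos, y_pos)
  if (beta <= criteria$beta_min) return(NULL)
  list(distance = d, beta = beta, cutoff = cutoff)
}

#' Test one pi (ring-acceptor) halogen-bond geometry
#'
#' Checks the C-X...pi criteria against a fitted ring: centroid distance
#' `d < pi_d_max`, angle alpha between the ring normal and the
#' centroid-to-halogen vector (folded to `[0, 90]` so the normal's sign
#' is irrelevant) `alpha < alpha_max`, and angle theta = C-X...centroid
#' `theta > theta_min`; all strict.
#'
#' @param c_pos Donor carbon position (3-vector, Angstroms).
#' @param x_pos Halogen position.
#' @param ring List with `centroid` and unit `normal`, as from
#'   [ring_plane()].
#' @param criteria [xbond_criteria()].
#' @return `NULL` if the geometry fails, else a list with `distance`,
#'   `alpha` and `theta`.
#' @export
pi_xbond_check <- function(c_pos, x_pos, ring, criteria = xbond_criteria()) {
  v <- x_pos - ring$centroid
  d <- vnorm(v)
  if (d < 1e-12) stop("degenerate geometry: halogen coincides with ring centroid")
  if (d >= criteria$pi_d_max) return(NULL)
  cosang <- sum(v * ring$normal) / d
  alpha <- acos(min(1, max(-1, cosang))) * 180 / pi
  alpha <- min(alpha, 180 - alpha)
  if (alpha >= criteria$alpha_max) return(NULL)
  theta <- vec_angle(c_pos, x_pos, ring$centroid)
  if (theta <= criteria$theta_min) return(NULL)
  list(distance = d, alpha = alpha, theta = theta)
}
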