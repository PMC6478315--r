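# Physical constants (AMBER conventions).
KB_KCAL <- 0.0019872041   # Boltzmann constant, kcal/mol/K
K_COUL  <- 332.0636       # Coulomb constant, kcal*A/(mol*e^2)

#' Simulation settings
#'
#' Container for the global thermodynamic and cutoff settings of a
#' mixed-resolution simulation.  Defaults are the production values:
#' 300 K, 10 A atomistic nonbonded cutoff, 8 A native-contact cutoff.
#'
#' @param temperature Simulation temperature in K.
#' @param nonbonded_cutoff Atomistic nonbonded cutoff in Angstrom.
#' @param go_native_cutoff Cutoff for defining native contacts, Angstrom.
#' @param rng_seed Integer seed recorded for provenance (the caller is
#'   responsible for calling [set.seed()]; engine functions do not reseed).
#' @return An object of class `"mrmc_settings"` with fields `temperature`,
#'   `boltzmann_constant`, `beta` (= 1/kT, mol/kcal), `nonbonded_cutoff`,
#'   `go_native_cutoff` and `rng_seed`.
#' @export
simulation_settings <- function(temperature = 300,
                                nonbonded_cutoff = 10,
                                go_native_cutoff = 8,
                                rng_seed = NA_integer_) {
  stopifnot(temperature > 0, nonbonded_cutoff > 0, go_native_cutoff > 0)
  out <- list(
    temperature = temperature,
    boltzmann_constant = KB_KCAL,
    beta = 1 / (KB_KCAL * temperature),
    nonbonded_cutoff = nonbonded_cutoff,
    go_native_cutoff = go_native_cutoff,
    rng_seed = rng_seed
  )
  class(out) <- "mrmc_settings"
  out
}

#' @export
print.mrmc_settings <- function(x, ...) {
  cat("MRMC settings: T =", x$temperature, "K, beta =",
      format(x$beta, digits = 6), "mol/kcal\n")
  cat("  nonbonded cutoff:", x$nonbonded_cutoff, "A;  Go native cutoff:",
      x$go_native_cutoff, "A\n")
  invisible(x)
}

# Rotation matrix for rotation by `angle` radians about unit `axis`
# (Rodrigues formula).
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

# Rotate rows of xyz[idx, ] about the axis through points a and b.
rotate_about_axis <- function(xyz, idx, a, b, angle) {
  if (length(idx) == 0L || angle == 0) return(xyz)
  R <- rotation_matrix(b - a, angle)
  sub <- sweep(xyz[idx, , drop = FALSE], 2, a)
  xyz[idx, ] <- sweep(sub %*% t(R), 2, a, `+`)
  xyz
}

# Uniform random unit vector.
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Uniform random point in the ball of radius r (inverse-CDF radial sampling).
random_in_ball <- function(r) {
  random_unit_vector() * r * stats::runif(1)^(1 / 3)
}

# Kabsch superposition: rigid transform (rotation R, translation t) minimizing
# RMSD of moving onto target; apply as sweep(x, 2, cm) %*% R + ct.
# Returns list(R, center_moving, center_target, rmsd).
kabsch <- function(moving, target) {
  stopifnot(nrow(moving) == nrow(target), nrow(moving) >= 1)
  cm <- colMeans(moving); ct <- colMeans(target)
  P <- sweep(moving, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)          # right-multiply row vectors
  aligned <- P %*% R
  list(R = R, center_moving = cm, center_target = ct,
       rmsd = sqrt(mean(rowSums((aligned - Q)^2))))
}

# Apply a kabsch() result to a full coordinate set.
apply_superposition <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_moving) %*% fit$R, 2, fit$center_target, `+`)
}

rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Pairwise Euclidean distance matrix between rows of a and rows of b.
dist_cross <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
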