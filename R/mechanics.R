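#' Ligand layout of a circular adhesion complex
#'
#' Places `n_c = ceiling(pi a^2 / d^2)` ligands on a square lattice of pitch
#' `d` centred on the adhesion centre, ranked by distance to the centre (ties
#' broken by angle) and truncated to `n_c`. The count rule is the area of the
#' circular adhesion divided by the area per ligand; for the reference
#' geometry `a = 708` nm, `d = 100` nm it gives 158 ligands.
#'
#' @param a adhesion radius (nm).
#' @param d ligand spacing (nm).
#' @return an object of class `ligand_layout`: list with `a`, `d`, `n_c` and
#'   an `n_c x 2` matrix `positions` (nm).
#' @export
make_ligand_layout <- function(a, d) {
  if (!is.numeric(a) || !is.numeric(d) || a <= 0 || d <= 0) {
    stop("adhesion radius and ligand spacing must be positive", call. = FALSE)
  }
  n_c <- as.integer(ceiling(pi * a^2 / d^2))
  m <- ceiling(a / d) + 2
  g <- expand.grid(x = (-m:m) * d, y = (-m:m) * d)
  r <- sqrt(g$x^2 + g$y^2)
  th <- atan2(g$y, g$x)
  ord <- order(r, th)
  pos <- as.matrix(g[ord, , drop = FALSE])[seq_len(n_c), , drop = FALSE]
  dimnames(pos) <- list(NULL, c("x", "y"))
  structure(list(a = a, d = d, n_c = n_c, positions = pos),
            class = "ligand_layout")
}

#' Half-space Green's function compliance between two surface points
#'
#' In-plane displacement at separation `r` per unit point force applied along
#' `pull_dir` on the surface of a semi-infinite isotropic elastic medium:
#' `[(3 - 4 nu) + (r . pull_dir)^2 / |r|^2] / (16 pi mu (1 - nu) |r|)`.
#' Even in the separation (`G(r) = G(-r)`). The shear modulus is taken in kPa and converted to
#' pN/nm^2 internally, so the result is in nm/pN.
#'
#' @param r planar separation vector (nm), length 2.
#' @param pull_dir unit vector of the common pulling direction.
#' @param mu shear modulus (kPa).
#' @param nu Poisson ratio.
#' @return compliance (nm/pN).
#' @export
greens_coefficient <- function(r, pull_dir = c(1, 0), mu, nu = 0.5) {
  stopifnot(length(r) == 2, mu > 0)
  dist <- sqrt(sum(r^2))
  if (dist == 0) {
    stop("Green's function is singular at zero separation; evaluate at the self offset",
         call. = FALSE)
  }
  p <- pull_dir / sqrt(sum(pull_dir^2))
  mu_pn <- .kpa_to_pn_nm2(mu)
  ((3 - 4 * nu) + (sum(r * p))^2 / dist^2) / (16 * pi * mu_pn * (1 - nu) * dist)
}

#' Assemble the substrate compliance operator of a ligand layout
#'
#' Builds the `n_c x n_c` matrix `G` mapping the vector of ligand forces (pN,
#' all along the common pulling direction) to the substrate displacements at
#' the ligand positions (nm): `x_sub = G F`. Off-diagonal entries use the true
#' inter-ligand separation; the singular self term is evaluated at a fixed
#' offset (default 5 nm) along the pulling direction, so all diagonal entries
#' are equal.
#'
#' @param layout a [make_ligand_layout()] object.
#' @param E substrate Young's modulus (kPa).
#' @param nu Poisson ratio (default 0.5, incompressible hydrogel).
#' @param self_offset singularity-avoidance distance for the self term (nm).
#' @param pull_dir common in-plane pulling direction.
#' @return an object of class `green_operator`: list with `E`, `nu`, `mu`
#'   (kPa), `G` (nm/pN), `self_offset`, `pull_dir`.
#' @export
assemble_green_operator <- function(layout, E, nu = 0.5, self_offset = 5,
                                    pull_dir = c(1, 0)) {
  stopifnot(inherits(layout, "ligand_layout"), E > 0, self_offset > 0)
  mu <- E / (2 * (1 + nu))
  pos <- layout$positions
  n <- layout$n_c
  if (n > 1 && any(stats::dist(pos) < 1e-9)) {
    stop("duplicate ligand positions in layout", call. = FALSE)
  }
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      G[i, j] <- greens_coefficient(pos[j, ] - pos[i, ], pull_dir, mu, nu)
    }
  }
  diag(G) <- greens_coefficient(self_offset * pull_dir / sqrt(sum(pull_dir^2)),
                                pull_dir, mu, nu)
  structure(list(E = E, nu = nu, mu = mu, G = G,
                 self_offset = self_offset, pull_dir = pull_dir),
            class = "green_operator")
}

#' Substrate displacements under a ligand force vector
#'
#' `x_sub = G F`; linear, so superposition holds exactly.
#'
#' @param G a [assemble_green_operator()] object.
#' @param F_c per-ligand forces (pN), zero at free ligands.
#' @return displacements at the ligand positions (nm).
#' @export
substrate_displacements <- function(G, F_c) {
  stopifnot(inherits(G, "green_operator"))
  if (length(F_c) != nrow(G$G)) {
    stop("force vector length does not match the operator dimension", call. = FALSE)
  }
  drop(G$G %*% F_c)
}

#' Classical single-spring substrate stiffness
#'
#' The lumped stiffness `kappa_sub = 4 pi a E / 9` (pN/nm, with E in kPa and
#' a in nm) used by the classical clutch model to represent the whole
#' substrate under a circular adhesion of radius `a`.
#'
#' @param E Young's modulus (kPa).
#' @param a adhesion radius (nm).
#' @return stiffness (pN/nm).
#' @export
classic_substrate_stiffness <- function(E, a) {
  stopifnot(E >= 0, a > 0)
  4 * pi * a * .kpa_to_pn_nm2(E) / 9
}

#' Myosin motor ensemble
#'
#' @param n_m number of myosin motors.
#' @param F_m single-motor stall force (pN).
#' @param v_u unloaded actin retrograde-flow velocity (nm/s).
#' @return an object of class `motor_ensemble` with `F_stall = n_m * F_m`.
#' @export
motor_ensemble <- function(n_m, F_m = 2, v_u = 110) {
  stopifnot(n_m > 0, F_m > 0, v_u > 0)
  structure(list(n_m = n_m, F_m = F_m, v_u = v_u, F_stall = n_m * F_m),
            class = "motor_ensemble")
}

#' Actin retrograde-flow velocity under load
#'
#' Linear force-velocity relation `v = v_u (1 - F_sub / F_stall)`, clamped at
#' zero when the substrate reaction force exceeds the total myosin stall
#' force.
#'
#' @param F_sub total substrate reaction force (pN).
#' @param motors a [motor_ensemble()].
#' @return velocity (nm/s).
#' @export
actin_velocity <- function(F_sub, motors) {
  .check_force(F_sub)
  stopifnot(inherits(motors, "motor_ensemble"))
  pmax(0, motors$v_u * (1 - F_sub / motors$F_stall))
}
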