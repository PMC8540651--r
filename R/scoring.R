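## Physics-based rescoring: a Lennard-Jones 12-6 kernel with combining rules
## shared by both scoring functions and by trajectory profiling, an
## AutoDock-style weighted four-term free-energy estimate, and a FITTED-style
## estimate with the printed term coefficients (0.14 per rotor, 0.26 vdW,
## 0.035 electrostatic, 0.80 H-bond).

## Coulomb constant, kcal*Angstrom/(mol*e^2)
COULOMB_K <- 332.0637

#' Scoring parameters
#'
#' Configuration shared by [score_autodock()] and [score_fitted()]. The four
#' AutoDock term weights default to the published AutoDock 4.2 free-energy
#' calibration; the FITTED baseline `dG0` and per-interaction `scale_factor`
#' are not published and default to 0 and 1, so only the printed term
#' coefficients carry through by default.
#'
#' @param w_vdw,w_hbond,w_elec,w_sol dimensionless AutoDock term weights.
#' @param sigma desolvation Gaussian width (the distance weighting factor),
#'   Angstrom.
#' @param dielectric `"sigmoidal"` for the distance-dependent screened model
#'   (see [dielectric_at()]), or `"constant"`.
#' @param dielectric_constant value used when `dielectric = "constant"`.
#' @param hb_depth,hb_dist depth (kcal/mol) and position (Angstrom) of the
#'   12-10 hydrogen-bond well; `C` and `D` are derived so the well minimum is
#'   `-hb_depth` at `hb_dist`.
#' @param hb_width Gaussian width of the FITTED-style H-bond distance term,
#'   Angstrom.
#' @param hb_cone angular cone (degrees) beyond which the directional weight
#'   [hbond_directional_weight()] is zero.
#' @param dG0 FITTED baseline free energy, kcal/mol.
#' @param rotor_coef,vdw_coef,elec_coef,hb_coef FITTED term coefficients.
#' @param scale_factor FITTED per-interaction scale factor.
#' @param cutoff nonbonded cutoff, Angstrom (default 11, the van der
#'   Waals/Coulomb cutoff used for the simulations being analysed).
#' @param hbond_pairs_in_vdw if `FALSE` (default) donor-acceptor typed pairs
#'   are handled by the 12-10 term only and excluded from the 12-6 sum.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(w_vdw = 0.1662, w_hbond = 0.1209,
                           w_elec = 0.1406, w_sol = 0.1322,
                           sigma = 3.5,
                           dielectric = c("sigmoidal", "constant"),
                           dielectric_constant = 1,
                           hb_depth = 5.0, hb_dist = 1.9, hb_width = 0.5,
                           hb_cone = 90,
                           dG0 = 0, rotor_coef = 0.14, vdw_coef = 0.26,
                           elec_coef = 0.035, hb_coef = 0.80,
                           scale_factor = 1,
                           cutoff = 11,
                           hbond_pairs_in_vdw = FALSE) {
  dielectric <- match.arg(dielectric)
  p <- list(w_vdw = w_vdw, w_hbond = w_hbond, w_elec = w_elec, w_sol = w_sol,
            sigma = sigma, dielectric = dielectric,
            dielectric_constant = dielectric_constant,
            hb_depth = hb_depth, hb_dist = hb_dist, hb_width = hb_width,
            hb_cone = hb_cone, dG0 = dG0, rotor_coef = rotor_coef,
            vdw_coef = vdw_coef, elec_coef = elec_coef, hb_coef = hb_coef,
            scale_factor = scale_factor, cutoff = cutoff,
            hbond_pairs_in_vdw = hbond_pairs_in_vdw)
  num <- unlist(p[vapply(p, is.numeric, logical(1))])
  if (!all(is.finite(num))) stop("scoring parameters must be finite")
  if (sigma <= 0) stop("sigma must be > 0")
  if (cutoff <= 0) stop("cutoff must be > 0")
  class(p) <- "scoring_params"
  p
}

## vectorized 12-6 kernel with combining rules:
## eps_ij = sqrt(eps_i eps_j), R_ij = R_i + R_j,
## A = eps_ij R_ij^12, B = 2 eps_ij R_ij^6, E = A/r^12 - B/r^6
lj_kernel <- function(eps_i, eps_j, ri, rj, r) {
  if (any(r <= 0)) stop("singular LJ evaluation: interatomic distance <= 0")
  eps_ij <- sqrt(eps_i * eps_j)
  r_ij <- ri + rj
  sr6 <- (r_ij / r)^6
  eps_ij * (sr6^2 - 2 * sr6)
}

#' Lennard-Jones 12-6 pair energy
#'
#' Dispersion/repulsion energy of one atom pair with combining rules: the
#' pair well depth is the geometric mean of the atomic well depths, the pair
#' equilibrium distance the sum of the atomic half-equilibrium distances.
#' The minimum is exactly `-eps_ij` at `r = R_i + R_j`.
#'
#' @param atom_i,atom_j single-row atom data frames (or lists) carrying
#'   `eps`, `rmin_half` and, when `r` is omitted, `x`, `y`, `z`.
#' @param r interatomic distance in Angstrom; computed from coordinates when
#'   `NULL`.
#' @return pair energy, kcal/mol.
#' @export
lj_energy <- function(atom_i, atom_j, r = NULL) {
  gi <- function(a, f) if (is.data.frame(a)) a[[f]][1] else a[[f]]
  if (is.null(r)) {
    r <- sqrt(sum((c(gi(atom_i, "x"), gi(atom_i, "y"), gi(atom_i, "z")) -
                   c(gi(atom_j, "x"), gi(atom_j, "y"), gi(atom_j, "z")))^2))
  }
  eps_i <- gi(atom_i, "eps"); eps_j <- gi(atom_j, "eps")
  ri <- gi(atom_i, "rmin_half"); rj <- gi(atom_j, "rmin_half")
  if (anyNA(c(eps_i, eps_j, ri, rj)))
    stop("atoms are not parameterized (eps/rmin_half missing)")
  lj_kernel(eps_i, eps_j, ri, rj, r)
}

#' Distance-dependent dielectric
#'
#' Screened-Coulomb dielectric as a function of distance. The sigmoidal
#' model interpolates from vacuum-like screening at contact to bulk water at
#' long range: `eps(r) = A + B / (1 + k exp(-lambda B r))` with A = -8.5525,
#' k = 7.7839, lambda = 0.003627 and B = 78.4 - A (Mehler-Solmajer form).
#'
#' @param r distance(s), Angstrom.
#' @param params a [scoring_params()]; `dielectric = "constant"` returns the
#'   configured constant instead.
#' @return dielectric value(s), dimensionless.
#' @export
dielectric_at <- function(r, params = scoring_params()) {
  if (params$dielectric == "constant")
    return(rep(params$dielectric_constant, length(r)))
  A <- -8.5525; k <- 7.7839; lambda <- 0.003627; B <- 78.4 - A
  A + B / (1 + k * exp(-lambda * B * r))
}

#' Directional hydrogen-bond weight
#'
#' Smooth weight on the deviation angle `t` from ideal H-bond geometry:
#' `cos(pi/2 * t/cone)^2` inside the cone, 0 at and beyond it; 1 at `t = 0`.
#' Monotone non-increasing on `[0, cone]`.
#'
#' @param t deviation angle(s), degrees, in `[0, 180]`.
#' @param cone cone half-angle, degrees.
#' @return weight(s) in `[0, 1]`.
#' @export
hbond_directional_weight <- function(t, cone = 90) {
  stopifnot(all(t >= 0), all(t <= 180), cone > 0)
  w <- cos(pi / 2 * pmin(t, cone) / cone)^2
  w[t >= cone] <- 0
  w
}

## pair bookkeeping shared by both scoring functions: distances, typed-pair
## masks and (optionally) H-bond deviation angles for ligand x target atoms
pair_tables <- function(ligand, target, params) {
  la <- ligand$atoms; ta <- target$atoms
  r2 <- pair_dist2(as.matrix(la[, c("x", "y", "z")]),
                   as.matrix(ta[, c("x", "y", "z")]))
  r2[r2 < 0] <- 0
  r <- sqrt(r2)
  if (any(r < 0.01))
    stop("overlapping atoms (r < 0.01 Angstrom): singular pair energy")
  within <- r <= params$cutoff
  hb_pair <- outer(la$hb == "donor", ta$hb == "acceptor", "&") |
    outer(la$hb == "acceptor", ta$hb == "donor", "&")
  list(la = la, ta = ta, r = r, within = within, hb_pair = hb_pair)
}

## deviation angle (deg) for an H-bond pair: 180 minus the D-H...A angle when
## the donor carries a hydrogen in its residue within 1.3 A; 0 (ideal) when
## no explicit hydrogen is available to define the geometry.
hb_deviation_angle <- function(donor_struct, donor_idx, acc_xyz) {
  a <- donor_struct$atoms
  d_xyz <- as.numeric(a[donor_idx, c("x", "y", "z")])
  same_res <- which(a$resno == a$resno[donor_idx] &
                    a$chain == a$chain[donor_idx] & a$element == "H")
  if (length(same_res) == 0L) return(0)
  h_xyz <- as.matrix(a[same_res, c("x", "y", "z")])
  dh <- sqrt(rowSums(sweep(h_xyz, 2, d_xyz)^2))
  near <- which(dh <= 1.3)
  if (length(near) == 0L) return(0)
  ## pick the hydrogen best aligned with the acceptor
  best <- 180
  for (k in near) {
    hx <- h_xyz[k, ]
    v1 <- hx - d_xyz; v2 <- acc_xyz - hx
    ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    ang <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi  # 0 = colinear = ideal
    best <- min(best, ang)
  }
  best
}

## 12-10 well with C = 5 eps r0^12, D = 6 eps r0^10 so the minimum is -eps at
## r0; used for donor-acceptor typed pairs
hb_12_10 <- function(r, eps, r0) {
  C <- 5 * eps * r0^12
  D <- 6 * eps * r0^10
  C / r^12 - D / r^10
}

#' AutoDock-style binding free energy
#'
#' Weighted sum over ligand-target atom pairs within the nonbonded cutoff of
#' four terms: 12-6 dispersion/repulsion ([lj_energy()]), a directional
#' 12-10 hydrogen-bond well for donor-acceptor typed pairs, screened Coulomb
#' electrostatics with a configurable dielectric, and a Gaussian desolvation
#' term `(S_i V_j + S_j V_i) exp(-r^2 / (2 sigma^2))`.
#'
#' @param ligand,target parameterized [structure3d()] objects (see
#'   [assign_parameters()]).
#' @param params a [scoring_params()].
#' @return list with `total` (kcal/mol) and `breakdown`, a named vector of
#'   the four unweighted component sums (`vdw`, `hbond`, `elec`, `desolv`);
#'   `total` equals the weight-dotted breakdown.
#' @export
score_autodock <- function(ligand, target, params = scoring_params()) {
  require_parameters(ligand, "ligand"); require_parameters(target, "target")
  if (anyNA(ligand$atoms$charge) || anyNA(target$atoms$charge))
    stop("missing partial charges; electrostatics cannot be evaluated")
  pt <- pair_tables(ligand, target, params)
  r <- pt$r; within <- pt$within; hb <- pt$hb_pair
  la <- pt$la; ta <- pt$ta

  vdw_mask <- within & if (params$hbond_pairs_in_vdw) TRUE else !hb
  e_lj <- lj_kernel(outer(la$eps, ta$eps, function(a, b) a),
                    outer(la$eps, ta$eps, function(a, b) b),
                    outer(la$rmin_half, ta$rmin_half, function(a, b) a),
                    outer(la$rmin_half, ta$rmin_half, function(a, b) b),
                    pmax(r, 1e-12))
  vdw <- sum(e_lj[vdw_mask])

  hbond <- 0
  hb_idx <- which(hb & within, arr.ind = TRUE)
  if (nrow(hb_idx) > 0L) {
    for (k in seq_len(nrow(hb_idx))) {
      i <- hb_idx[k, 1]; j <- hb_idx[k, 2]
      if (la$hb[i] == "donor") {
        t_dev <- hb_deviation_angle(ligand, i, as.numeric(ta[j, c("x", "y", "z")]))
      } else {
        t_dev <- hb_deviation_angle(target, j, as.numeric(la[i, c("x", "y", "z")]))
      }
      w <- hbond_directional_weight(t_dev, params$hb_cone)
      hbond <- hbond + w * hb_12_10(r[i, j], params$hb_depth, params$hb_dist)
    }
  }

  eps_r <- matrix(dielectric_at(r, params), nrow(r), ncol(r))
  e_coul <- COULOMB_K * outer(la$charge, ta$charge) / (eps_r * r)
  elec <- sum(e_coul[within])

  ## atoms without solvation parameters contribute nothing to desolvation
  if (anyNA(la$solv_S) || anyNA(ta$solv_S) ||
      anyNA(la$solv_V) || anyNA(ta$solv_V)) {
    desolv <- 0
  } else {
    sv <- outer(la$solv_S, ta$solv_V) + t(outer(ta$solv_S, la$solv_V))
    gauss <- exp(-r^2 / (2 * params$sigma^2))
    desolv <- sum((sv * gauss)[within])
  }

  breakdown <- c(vdw = vdw, hbond = hbond, elec = elec, desolv = desolv)
  total <- params$w_vdw * vdw + params$w_hbond * hbond +
    params$w_elec * elec + params$w_sol * desolv
  list(total = total, breakdown = breakdown)
}

#' FITTED-style binding free energy
#'
#' `dG0 + 0.14 N_rot + scale * (0.26 U_vdw + 0.035 U_elec + 0.80 sum(f_hb))`,
#' where `U_vdw` sums [lj_energy()] over ligand-target pairs within the
#' cutoff, `U_elec` is the screened Coulomb sum, and `f_hb` is a directional
#' hydrogen-bond term evaluated per donor-acceptor pair as
#' `-hb_depth * exp(-(r - hb_dist)^2 / (2 hb_width^2)) * w(t)`.
#'
#' @inheritParams score_autodock
#' @param n_rot number of rotatable bonds of the ligand (>= 0); each adds
#'   `rotor_coef` (0.14 kcal/mol) of entropic penalty.
#' @return estimated binding free energy, kcal/mol.
#' @export
score_fitted <- function(ligand, target, n_rot, params = scoring_params()) {
  stopifnot(n_rot >= 0)
  require_parameters(ligand, "ligand"); require_parameters(target, "target")
  if (anyNA(ligand$atoms$charge) || anyNA(target$atoms$charge))
    stop("missing partial charges; electrostatics cannot be evaluated")
  pt <- pair_tables(ligand, target, params)
  r <- pt$r; within <- pt$within; la <- pt$la; ta <- pt$ta

  e_lj <- lj_kernel(outer(la$eps, ta$eps, function(a, b) a),
                    outer(la$eps, ta$eps, function(a, b) b),
                    outer(la$rmin_half, ta$rmin_half, function(a, b) a),
                    outer(la$rmin_half, ta$rmin_half, function(a, b) b),
                    pmax(r, 1e-12))
  u_vdw <- sum(e_lj[within])

  eps_r <- matrix(dielectric_at(r, params), nrow(r), ncol(r))
  u_elec <- sum((COULOMB_K * outer(la$charge, ta$charge) / (eps_r * r))[within])

  f_hb <- 0
  hb_idx <- which(pt$hb_pair & within, arr.ind = TRUE)
  if (nrow(hb_idx) > 0L) {
    for (k in seq_len(nrow(hb_idx))) {
      i <- hb_idx[k, 1]; j <- hb_idx[k, 2]
      if (la$hb[i] == "donor") {
        t_dev <- hb_deviation_angle(ligand, i, as.numeric(ta[j, c("x", "y", "z")]))
      } else {
        t_dev <- hb_deviation_angle(target, j, as.numeric(la[i, c("x", "y", "z")]))
      }
      w <- hbond_directional_weight(t_dev, params$hb_cone)
      f_hb <- f_hb - params$hb_depth *
        exp(-(r[i, j] - params$hb_dist)^2 / (2 * params$hb_width^2)) * w
    }
  }

  params$dG0 + params$rotor_coef * n_rot +
    params$scale_factor * (params$vdw_coef * u_vdw +
                           params$elec_coef * u_elec +
                           params$hb_coef * f_hb)
}
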