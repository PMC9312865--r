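#' @include structures-io.R
NULL

.ENERGY_TERMS <- c("eel14", "vdwaals", "eelec", "esurf", "egb")

#' Generalized-Born smoothing function
#'
#' The widely used pairwise effective distance
#' \deqn{f^{GB}_{ij} = [r_{ij}^2 + R_i R_j \exp(-r_{ij}^2 / 4 R_i R_j)]^{1/2}}
#' interpolating between the Coulomb distance at large separation and the
#' Born radius at zero separation. Symmetric in (i, j); vectorized.
#'
#' @param r interatomic distance(s), Angstrom (>= 0).
#' @param Ri,Rj effective Born radii, Angstrom (> 0).
#' @return effective distance(s), Angstrom.
#' @examples
#' fGB(0, 2, 2)              # = 2
#' fGB(4, 2, 3)              # sqrt(16 + 6 * exp(-16/24))
#' @export
fGB <- function(r, Ri, Rj) {
  if (any(Ri <= 0) || any(Rj <= 0))
    stop("Born radii must be positive")
  if (any(r < 0)) stop("distances must be non-negative")
  sqrt(r^2 + Ri * Rj * exp(-r^2 / (4 * Ri * Rj)))
}

# (3/4pi) * integral of |x - x_i|^-6 over the part of the sphere
# (radius a, center at distance d from atom i) lying outside the exclusion
# core |x - x_i| >= rhoi.  Shell decomposition; vectorized over (d, a).
.i6sphere <- function(d, a, rhoi) {
  out <- numeric(length(d))
  act <- d + a > rhoi
  if (!any(act)) return(out)
  d <- d[act]; a <- a[act]
  Fr <- function(r, d, a)
    -r^(-3) / 3 + r^(-2) / (4 * d) + (d^2 - a^2) * r^(-4) / (8 * d)
  L <- pmax(rhoi, abs(d - a))
  val <- 1.5 * (Fr(d + a, d, a) - Fr(L, d, a))
  # atom center engulfed by the neighbor sphere: add the fully-enclosed shells
  eng <- d < a & rhoi < (a - d)
  if (any(eng))
    val[eng] <- val[eng] + rhoi^(-3) - (a[eng] - d[eng])^(-3)
  out[act] <- val
  out
}

#' Effective Born radii (R6 descreening)
#'
#' Per-atom effective radii from the inverse-cubed relation
#' \deqn{R_i^{-3} = \rho_i^{-3} - \sum_{j \ne i} I_6(\rho_j, d_{ij})}
#' where \eqn{I_6} is the analytic integral of
#' \eqn{(3/4\pi)\,|r - r_i|^{-6}} over neighbor j's sphere, restricted to
#' the region outside atom i's own intrinsic sphere (overlap handled by
#' integrating only the non-overlapping part). Results are clamped below at
#' the intrinsic radius and the inverse cube is floored so radii stay
#' finite (maximum 30 Angstrom) for deeply buried atoms.
#'
#' @param structure a [ParameterizedStructure-class] with intrinsic radii.
#' @return numeric vector of effective radii (Angstrom) with attributes
#'   `methodTag` (`"R6-analytic-pairwise"`) and `intrinsic`.
#' @export
effectiveBornRadii <- function(structure) {
  a <- structure@atoms
  if (any(is.na(a$radius)))
    stop("all atoms need intrinsic radii; run assignParameters() first")
  n <- nrow(a)
  rho <- a$radius
  if (n == 1) {
    out <- rho
  } else {
    D <- as.matrix(stats::dist(as.matrix(a[, c("x", "y", "z")])))
    if (any(D[upper.tri(D)] <= 0))
      stop("coincident atoms: zero interatomic distance")
    inv3 <- numeric(n)
    for (i in seq_len(n)) {
      j <- setdiff(seq_len(n), i)
      descr <- sum(.i6sphere(D[i, j], rho[j], rho[i]))
      inv3[i] <- max(rho[i]^(-3) - descr, 30^(-3))
    }
    out <- pmax(rho, inv3^(-1 / 3))
  }
  attr(out, "methodTag") <- "R6-analytic-pairwise"
  attr(out, "intrinsic") <- rho
  out
}

#' Electrostatic size of a molecule
#'
#' The overall size entering the ALPB correction, computed as
#' \eqn{A = \sqrt{5/3}\, R_g} with \eqn{R_g} the radius of gyration of the
#' atom centers (exact for a uniformly filled ball). Single-atom fallback:
#' the atom's intrinsic radius.
#'
#' @param structure a [ParameterizedStructure-class].
#' @return A, Angstrom.
#' @export
electrostaticSize <- function(structure) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (n == 0) stop("structure has no atoms")
  if (n == 1) {
    r <- structure@atoms$radius[1]
    if (is.na(r)) stop("single-atom structure needs an intrinsic radius")
    return(r)
  }
  ctr <- colMeans(xyz)
  rg2 <- mean(rowSums(sweep(xyz, 2, ctr)^2))
  sqrt(5 / 3) * sqrt(rg2)
}

#' ALPB polar solvation energy
#'
#' \deqn{\Delta G_{pol} \approx -\frac{1}{2}
#'   \left(\frac{1}{\epsilon_{in}} - \frac{1}{\epsilon_{out}}\right)
#'   \frac{1}{1 + \beta\alpha} \sum_{ij} q_i q_j
#'   \left[\frac{1}{f^{GB}_{ij}} + \frac{\alpha\beta}{A}\right]}
#' with \eqn{\beta = \epsilon_{in}/\epsilon_{out}}, \eqn{\alpha = 0.571412}
#' and A the electrostatic size. The double sum runs over all ordered pairs
#' including i = j (self terms use \eqn{f = R_i}); the Coulomb constant
#' converts to kcal/mol.
#'
#' @param structure a [ParameterizedStructure-class] with charges and radii.
#' @param radii effective Born radii from [effectiveBornRadii()]
#'   (computed if `NULL`).
#' @param params a [GBParameters-class].
#' @return EGB, kcal/mol.
#' @export
polarSolvationEnergy <- function(structure, radii = NULL,
                                 params = gbParameters()) {
  if (is.null(radii)) radii <- effectiveBornRadii(structure)
  n <- nAtoms(structure)
  if (length(radii) != n)
    stop("Born radii do not match this structure")
  q <- structure@atoms$charge
  if (all(q == 0)) return(0)
  beta <- betaRatio(params)
  alpha <- params@alpha
  A <- electrostaticSize(structure)
  R <- as.numeric(radii)
  D <- if (n > 1) as.matrix(stats::dist(coords(structure))) else
    matrix(0, 1, 1)
  RR <- outer(R, R)
  f <- sqrt(D^2 + RR * exp(-D^2 / (4 * RR)))
  pair <- outer(q, q) * (1 / f + alpha * beta / A)
  pref <- -0.5 * params@coulombK *
    (1 / params@epsIn - 1 / params@epsOut) / (1 + beta * alpha)
  pref * sum(pair)
}

# N x N bond-graph path lengths (Inf when disconnected); used for
# 1-2/1-3/1-4 exclusion bookkeeping
.bondDistances <- function(structure) {
  n <- nAtoms(structure)
  b <- structure@bonds
  if (nrow(b) == 0) {
    m <- matrix(Inf, n, n); diag(m) <- 0; return(m)
  }
  g <- igraph::graph_from_edgelist(b, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::distances(g)
}

#' Coulomb energies with Amber exclusions
#'
#' Pairwise \eqn{k_e q_i q_j / (\epsilon_{in} r_{ij})}. Pairs separated by
#' one or two bonds are excluded; pairs separated by exactly three bonds
#' form the 1-4 term, divided by `scaleEel14` (default 1.2); all
#' more-distant (or unbonded) pairs form EELEC. No cutoff.
#'
#' @param structure a [ParameterizedStructure-class] with charges and bonds.
#' @param params a [GBParameters-class].
#' @return list with elements `eelec` and `eel14`, kcal/mol.
#' @export
coulombEnergies <- function(structure, params = gbParameters()) {
  n <- nAtoms(structure)
  if (n < 2) return(list(eelec = 0, eel14 = 0))
  q <- structure@atoms$charge
  D <- as.matrix(stats::dist(coords(structure)))
  G <- .bondDistances(structure)
  E <- params@coulombK * outer(q, q) / (params@epsIn * D)
  up <- upper.tri(D)
  list(eelec = sum(E[up & G >= 4]),
       eel14 = sum(E[up & G == 3]) / params@scaleEel14)
}

#' Lennard-Jones (van der Waals) energy
#'
#' 12-6 potential \eqn{\epsilon[(r_{min}/r)^{12} - 2 (r_{min}/r)^6]} with
#' Lorentz-Berthelot combining (\eqn{r_{min} = r^{min/2}_i + r^{min/2}_j},
#' \eqn{\epsilon = \sqrt{\epsilon_i \epsilon_j}}), the same 1-2/1-3
#' exclusions as [coulombEnergies()], 1-4 pairs divided by `scaleLJ14`
#' (default 2.0), and no cutoff.
#'
#' @param structure a [ParameterizedStructure-class] with LJ parameters.
#' @param params a [GBParameters-class].
#' @return VDWAALS, kcal/mol.
#' @export
ljEnergy <- function(structure, params = gbParameters()) {
  n <- nAtoms(structure)
  if (n < 2) return(0)
  a <- structure@atoms
  if (any(is.na(a$ljRminHalf)) || any(is.na(a$ljEpsilon)))
    stop("all atoms need LJ parameters; run assignParameters() first")
  D <- as.matrix(stats::dist(coords(structure)))
  G <- .bondDistances(structure)
  rmin <- outer(a$ljRminHalf, a$ljRminHalf, "+")
  epsm <- sqrt(outer(a$ljEpsilon, a$ljEpsilon))
  s6 <- (rmin / D)^6
  E <- epsm * (s6^2 - 2 * s6)
  up <- upper.tri(D)
  sum(E[up & G >= 4]) + sum(E[up & G == 3]) / params@scaleLJ14
}

# deterministic spherical Fibonacci point set (n x 3 unit vectors)
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(cos(phi) * s, sin(phi) * s, z)
}

# molecule-fixed orthonormal frame (principal axes of the atom centers,
# signs fixed by the largest-magnitude component) so that sampled surface
# areas are invariant under rigid motion of the structure
.principalFrame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  ctr <- sweep(xyz, 2, colMeans(xyz))
  V <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)$vectors
  for (k in 1:3) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Nonpolar solvation energy from solvent-accessible surface area
#'
#' Shrake-Rupley sphere sampling with a fixed deterministic spherical
#' Fibonacci point set (default 960 points per atom): each atom's sphere of
#' radius \eqn{\rho_i + probe} is sampled and points buried inside any other
#' atom's expanded sphere are discarded. Sampling directions are anchored in
#' the molecule's principal-axes frame, so the sampled area is invariant
#' under rigid motion of the structure. ESURF = surface tension times SASA,
#' with zero offset.
#'
#' @param structure a [ParameterizedStructure-class] with intrinsic radii.
#' @param params a [GBParameters-class] (probe radius, surface tension,
#'   points per atom).
#' @return list with `sasa` (Angstrom^2) and `esurf` (kcal/mol).
#' @export
nonpolarEnergy <- function(structure, params = gbParameters()) {
  a <- structure@atoms
  if (any(is.na(a$radius)))
    stop("all atoms need intrinsic radii; run assignParameters() first")
  n <- nrow(a)
  probe <- params@probeRadius
  rr <- a$radius + probe
  xyz <- coords(structure)
  pts <- .fibonacciSphere(params@sasaPoints) %*% t(.principalFrame(xyz))
  sasa <- 0
  if (n == 1) {
    sasa <- 4 * pi * rr[1]^2
  } else {
    D <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n)) {
      nb <- which(D[i, ] < rr[i] + rr & seq_len(n) != i)
      p <- sweep(pts * rr[i], 2, xyz[i, ], "+")
      free <- rep(TRUE, nrow(p))
      for (j in nb) {
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & d2 > rr[j]^2
        if (!any(free)) break
      }
      sasa <- sasa + 4 * pi * rr[i]^2 * mean(free)
    }
  }
  list(sasa = sasa, esurf = params@surfaceTension * sasa)
}

#' Full MM/GBSA energy breakdown of one structure
#'
#' Assembles the five per-structure energy terms -- 1-4 electrostatics
#' (`eel14`), van der Waals (`vdwaals`), electrostatics (`eelec`), nonpolar
#' solvation (`esurf`), polar solvation (`egb`) -- plus the electrostatic
#' size. Deterministic.
#'
#' @param structure a parameterized [ParameterizedStructure-class].
#' @param params a [GBParameters-class].
#' @return named numeric vector `eel14`, `vdwaals`, `eelec`, `esurf`,
#'   `egb`, `esize` (energies kcal/mol, esize Angstrom).
#' @export
energyBreakdown <- function(structure, params = gbParameters()) {
  cou <- coulombEnergies(structure, params)
  np <- nonpolarEnergy(structure, params)
  c(eel14 = cou$eel14,
    vdwaals = ljEnergy(structure, params),
    eelec = cou$eelec,
    esurf = np$esurf,
    egb = polarSolvationEnergy(structure, params = params),
    esize = electrostaticSize(structure))
}

#' Binding enthalpy from three energy breakdowns
#'
#' Per-term differences complex - receptor - ligand and their sum
#' \eqn{\Delta H}; all breakdowns must come from the same complex.
#'
#' @param complexEB,receptorEB,ligandEB outputs of [energyBreakdown()].
#' @return list with `dh` (kcal/mol) and `perTermDeltas` (named 5-vector).
#' @export
enthalpy <- function(complexEB, receptorEB, ligandEB) {
  d <- complexEB[.ENERGY_TERMS] - receptorEB[.ENERGY_TERMS] -
    ligandEB[.ENERGY_TERMS]
  list(dh = sum(d), perTermDeltas = d)
}

#' Entropy residual feature
#'
#' The entropic component is not computed physically; it is the residual
#' \eqn{T\Delta S = \Delta H - \Delta\Delta G_{exp}}, so that the -1 head
#' weight on this feature reconstructs
#' \eqn{\Delta\Delta G = \Delta H - T\Delta S} exactly. With no experimental
#' label the feature is 0 (inference mode) with a warning.
#'
#' @param ddgExp experimental binding free energy, kcal/mol (or `NA`).
#' @param dh computed binding enthalpy, kcal/mol.
#' @return TdS, kcal/mol.
#' @export
entropyFeature <- function(ddgExp, dh) {
  if (is.na(ddgExp)) {
    warning("no experimental label: entropy feature set to 0 (inference mode)")
    return(0)
  }
  dh - ddgExp
}

#' Names of the 16 physics features, in their fixed order
#'
#' For each energy term (`eel14`, `vdwaals`, `eelec`, `esurf`, `egb`) the
#' complex, receptor and ligand values, followed by the entropy residual.
#'
#' @return character vector of length 16.
#' @export
physicsFeatureNames <- function() {
  c(as.vector(t(outer(.ENERGY_TERMS, c("complex", "receptor", "ligand"),
                      paste, sep = "."))), "entropy")
}

#' Thermodynamic initialization pattern for the physics head
#'
#' +1 for every complex term, -1 for every receptor and ligand term, -1 for
#' the entropy residual: the dot product of this pattern with a physics
#' feature vector is \eqn{\Delta H - T\Delta S = \Delta\Delta G}.
#'
#' @return named numeric vector of length 16.
#' @export
physicsInitPattern <- function() {
  stats::setNames(c(rep(c(1, -1, -1), length(.ENERGY_TERMS)), -1),
                  physicsFeatureNames())
}

#' The 16-element physics feature vector of a labeled complex
#'
#' Runs [energyBreakdown()] on the complex, receptor and ligand structures
#' and appends the entropy residual ([entropyFeature()]).
#'
#' @param lc a [LabeledComplex-class].
#' @param params a [GBParameters-class].
#' @return named numeric vector of length 16 (see [physicsFeatureNames()]),
#'   with attribute `dh` carrying the binding enthalpy.
#' @export
physicsFeatures <- function(lc, params = gbParameters()) {
  ebC <- energyBreakdown(lc@complexStructure, params)
  ebR <- energyBreakdown(lc@receptor, params)
  ebL <- energyBreakdown(lc@ligand, params)
  ent <- enthalpy(ebC, ebR, ebL)
  vals <- as.vector(rbind(ebC[.ENERGY_TERMS], ebR[.ENERGY_TERMS],
                          ebL[.ENERGY_TERMS]))
  out <- stats::setNames(c(vals, entropyFeature(lc@ddgExp, ent$dh)),
                         physicsFeatureNames())
  attr(out, "dh") <- ent$dh
  out
}
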