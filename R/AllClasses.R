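#' @include PGBind-package.R
NULL

.ATOM_COLS <- c("element", "x", "y", "z", "charge", "radius",
                "ljRminHalf", "ljEpsilon", "resname", "isSolvent")

#' Parameterized molecular structure
#'
#' Atoms with coordinates (Angstrom), partial charges (e), intrinsic
#' Born/cavity radii (Angstrom), Lennard-Jones parameters
#' (rmin/2 in Angstrom, epsilon in kcal/mol) and bond connectivity.
#' Unset charges are 0 and unset radii/LJ parameters are `NA` until
#' [assignParameters()] fills them in.
#'
#' @slot atoms data.frame with columns `element`, `x`, `y`, `z`, `charge`,
#'   `radius`, `ljRminHalf`, `ljEpsilon`, `resname`, `isSolvent`.
#' @slot bonds two-column integer matrix of 1-based atom index pairs.
#' @slot role one of `"complex"`, `"receptor"`, `"ligand"`.
#' @slot name identifier string.
#' @exportClass ParameterizedStructure
setClass("ParameterizedStructure",
  representation(atoms = "data.frame", bonds = "matrix",
                 role = "character", name = "character"),
  prototype(atoms = data.frame(), bonds = matrix(integer(0), ncol = 2),
            role = "complex", name = ""))

setValidity("ParameterizedStructure", function(object) {
  a <- object@atoms
  if (nrow(a) > 0 && !all(.ATOM_COLS %in% names(a)))
    return(paste("atoms must have columns:", paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(a) > 0) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) return("atom positions must be finite")
    r <- a$radius
    if (any(!is.na(r) & r <= 0)) return("intrinsic radii must be positive")
    eps <- a$ljEpsilon
    if (any(!is.na(eps) & eps < 0)) return("ljEpsilon must be non-negative")
  }
  b <- object@bonds
  if (ncol(b) != 2) return("bonds must have two columns")
  if (nrow(b) > 0) {
    if (any(b < 1L | b > nrow(a))) return("bond indices out of range")
    if (any(b[, 1] == b[, 2])) return("self-bonds are not allowed")
  }
  if (length(object@role) != 1 ||
      !object@role %in% c("complex", "receptor", "ligand"))
    return("role must be one of complex, receptor, ligand")
  TRUE
})

#' Labeled receptor-ligand complex
#'
#' A complex with its receptor/ligand split (single-conformation bound-state
#' convention: the parts carry the identical coordinates and parameters they
#' have inside the complex) and an optional experimental binding free energy
#' label in kcal/mol.
#'
#' @slot complexStructure,receptor,ligand [ParameterizedStructure-class]
#'   objects.
#' @slot receptorIndices,ligandIndices 1-based indices of the parts' atoms
#'   within the complex, order-preserving.
#' @slot ddgExp experimental binding free energy, kcal/mol (`NA` if absent).
#' @slot name identifier string.
#' @exportClass LabeledComplex
setClass("LabeledComplex",
  representation(complexStructure = "ParameterizedStructure",
                 receptor = "ParameterizedStructure",
                 ligand = "ParameterizedStructure",
                 receptorIndices = "integer", ligandIndices = "integer",
                 ddgExp = "numeric", name = "character"),
  prototype(ddgExp = NA_real_, name = ""))

setValidity("LabeledComplex", function(object) {
  nc <- nrow(object@complexStructure@atoms)
  nr <- nrow(object@receptor@atoms)
  nl <- nrow(object@ligand@atoms)
  if (nc != nr + nl)
    return("complex atom count must equal receptor + ligand atom counts")
  if (nr == 0 || nl == 0) return("receptor and ligand must be non-empty")
  idx <- c(object@receptorIndices, object@ligandIndices)
  if (length(idx) != nc || !setequal(idx, seq_len(nc)))
    return("receptor/ligand indices must partition the complex atoms")
  ca <- object@complexStructure@atoms
  for (part in list(list(object@receptor, object@receptorIndices),
                    list(object@ligand, object@ligandIndices))) {
    pa <- part[[1]]@atoms
    sub <- ca[part[[2]], , drop = FALSE]
    num <- c("x", "y", "z", "charge", "radius", "ljRminHalf", "ljEpsilon")
    if (!isTRUE(all.equal(as.matrix(sub[, num]), as.matrix(pa[, num]),
                          tolerance = 1e-9, check.attributes = FALSE)))
      return("part atom parameters must match their copies inside the complex")
  }
  if (length(object@ddgExp) != 1) return("ddgExp must be a single value")
  TRUE
})

#' Generalized-Born / ALPB parameters and energy-engine settings
#'
#' @slot epsIn solute dielectric (dimensionless, >= 1).
#' @slot epsOut solvent dielectric (> epsIn).
#' @slot alpha ALPB constant, 0.571412.
#' @slot temperature Kelvin.
#' @slot probeRadius solvent probe radius, Angstrom.
#' @slot surfaceTension nonpolar surface coefficient, kcal/(mol A^2).
#' @slot scaleEel14 divisor applied to 1-4 electrostatics.
#' @slot scaleLJ14 divisor applied to 1-4 Lennard-Jones terms.
#' @slot coulombK Coulomb constant, kcal A / (mol e^2).
#' @slot sasaPoints sphere-sampling points per atom for SASA.
#' @exportClass GBParameters
setClass("GBParameters",
  representation(epsIn = "numeric", epsOut = "numeric", alpha = "numeric",
                 temperature = "numeric", probeRadius = "numeric",
                 surfaceTension = "numeric", scaleEel14 = "numeric",
                 scaleLJ14 = "numeric", coulombK = "numeric",
                 sasaPoints = "integer"))

setValidity("GBParameters", function(object) {
  if (object@epsIn < 1) return("epsIn must be >= 1")
  if (object@epsOut <= object@epsIn) return("epsOut must exceed epsIn")
  if (object@probeRadius < 0) return("probeRadius must be non-negative")
  if (object@sasaPoints < 10) return("sasaPoints must be at least 10")
  TRUE
})

#' Construct GB/ALPB parameters
#'
#' Defaults follow Amber conventions: vacuum solute dielectric, water solvent
#' dielectric 78.5, T = 298.15 K, 1.4 Angstrom probe, surface tension
#' 0.0072 kcal/(mol A^2), 1-4 scaling divisors 1.2 (electrostatic) and 2.0
#' (Lennard-Jones), Coulomb constant 332.0637 kcal A/(mol e^2).
#'
#' @param epsIn,epsOut solute and solvent dielectric constants.
#' @param alpha ALPB constant.
#' @param temperature Kelvin.
#' @param probeRadius solvent probe radius, Angstrom.
#' @param surfaceTension kcal/(mol A^2).
#' @param scaleEel14,scaleLJ14 1-4 scaling divisors.
#' @param coulombK Coulomb constant, kcal A/(mol e^2).
#' @param sasaPoints SASA sampling points per atom.
#' @return A [GBParameters-class] object.
#' @examples
#' gbParameters(epsOut = 80)
#' @export
gbParameters <- function(epsIn = 1, epsOut = 78.5, alpha = 0.571412,
                         temperature = 298.15, probeRadius = 1.4,
                         surfaceTension = 0.0072, scaleEel14 = 1.2,
                         scaleLJ14 = 2.0, coulombK = 332.0637,
                         sasaPoints = 960L) {
  new("GBParameters", epsIn = epsIn, epsOut = epsOut, alpha = alpha,
      temperature = temperature, probeRadius = probeRadius,
      surfaceTension = surfaceTension, scaleEel14 = scaleEel14,
      scaleLJ14 = scaleLJ14, coulombK = coulombK,
      sasaPoints = as.integer(sasaPoints))
}

#' beta = epsIn/epsOut for a GBParameters object
#' @param params a [GBParameters-class] object.
#' @return numeric scalar.
#' @export
betaRatio <- function(params) params@epsIn / params@epsOut

#' Atom graph: per-atom features plus neighbor lists
#'
#' @slot features numeric matrix, one row per atom, exactly 75 columns
#'   (the ConvMol-style one-hot schema, see [featureSchema()]).
#' @slot neighbors integer matrix with `k` columns; entry 0 is the sentinel
#'   for a missing neighbor.
#' @exportClass AtomGraph
setClass("AtomGraph",
  representation(features = "matrix", neighbors = "matrix"))

setValidity("AtomGraph", function(object) {
  if (ncol(object@features) != 75L)
    return("feature width must be exactly 75")
  if (nrow(object@neighbors) != nrow(object@features))
    return("neighbors must have one row per atom")
  nb <- object@neighbors
  if (nrow(nb) > 0 && any(nb < 0L | nb > nrow(object@features)))
    return("neighbor indices out of range")
  TRUE
})

#' Batched atom graphs
#'
#' Row-concatenated atom features with per-graph membership so graph-level
#' pooling can segment the batch. [unbatchGraphs()] recovers the originals.
#'
#' @slot features concatenated feature rows.
#' @slot neighbors concatenated, re-indexed neighbor lists (0 sentinel).
#' @slot membership integer graph id (1-based) per atom row.
#' @slot sizes atoms per graph.
#' @exportClass BatchedGraphs
setClass("BatchedGraphs",
  representation(features = "matrix", neighbors = "matrix",
                 membership = "integer", sizes = "integer"))

#' Physics-guided neural network model
#'
#' Holds the GraphConv weights, batch-norm running statistics, the M-head
#' dense weights and the interpretable final-layer coefficients, together
#' with the training configuration and per-epoch loss log.
#'
#' @slot weights named list of weight arrays.
#' @slot config named list from [pgnnConfig()].
#' @slot trainingLog data.frame with columns `epoch`, `trainLoss`
#'   (and `valLoss` when a validation set was supplied).
#' @slot usePhysics logical; `FALSE` for the graph-only ablation.
#' @exportClass PGNNModel
setClass("PGNNModel",
  representation(weights = "list", config = "list",
                 trainingLog = "data.frame", usePhysics = "logical"),
  prototype(usePhysics = TRUE))

setValidity("PGNNModel", function(object) {
  w <- object@weights
  if (length(w) > 0) {
    if (length(w$headW) != 17L)
      return("final-layer coefficient vector must have length 17 (16 physics + M)")
  }
  TRUE
})

setMethod("show", "ParameterizedStructure", function(object) {
  cat(sprintf("ParameterizedStructure '%s' (%s): %d atoms, %d bonds\n",
              object@name, object@role, nrow(object@atoms),
              nrow(object@bonds)))
  if (nrow(object@atoms) > 0) {
    tab <- table(object@atoms$element)
    cat("  elements:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = " "), "\n")
    cat(sprintf("  total charge: %.4f e\n", sum(object@atoms$charge)))
  }
})

setMethod("show", "LabeledComplex", function(object) {
  cat(sprintf("LabeledComplex '%s': complex %d = receptor %d + ligand %d atoms",
              object@name, nrow(object@complexStructure@atoms),
              nrow(object@receptor@atoms), nrow(object@ligand@atoms)))
  if (!is.na(object@ddgExp))
    cat(sprintf("; ddG(exp) = %.3f kcal/mol", object@ddgExp))
  cat("\n")
})

setMethod("show", "GBParameters", function(object) {
  cat(sprintf(
    "GBParameters: epsIn=%g epsOut=%g alpha=%g beta=%g T=%g K probe=%g A\n",
    object@epsIn, object@epsOut, object@alpha, betaRatio(object),
    object@temperature, object@probeRadius))
})

setMethod("show", "AtomGraph", function(object) {
  cat(sprintf("AtomGraph: %d atoms x %d features, k=%d neighbor slots\n",
              nrow(object@features), ncol(object@features),
              ncol(object@neighbors)))
})

setMethod("show", "PGNNModel", function(object) {
  kind <- if (object@usePhysics) "hybrid physics+graph" else
    "graph-only (ablation)"
  trained <- if (nrow(object@trainingLog) > 0)
    sprintf("trained %d epochs", max(object@trainingLog$epoch)) else
    "untrained (physics-initialized)"
  cat(sprintf("PGNNModel (%s), %s\n", kind, trained))
})

#' Number of atoms in a structure or graph
#' @param x a [ParameterizedStructure-class] or [AtomGraph-class].
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
setMethod("nAtoms", "ParameterizedStructure", function(x) nrow(x@atoms))

#' @rdname nAtoms
setMethod("nAtoms", "AtomGraph", function(x) nrow(x@features))

#' Atom table of a structure
#' @param x a [ParameterizedStructure-class].
#' @return data.frame of atoms.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
setMethod("atomTable", "ParameterizedStructure", function(x) x@atoms)

#' Bond index matrix of a structure
#' @param x a [ParameterizedStructure-class].
#' @return two-column integer matrix of 1-based index pairs.
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))

#' @rdname bondTable
setMethod("bondTable", "ParameterizedStructure", function(x) x@bonds)

#' Total partial charge of a structure (e)
#' @param x a [ParameterizedStructure-class].
#' @return numeric scalar, elementary charges.
#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))

#' @rdname totalCharge
setMethod("totalCharge", "ParameterizedStructure",
          function(x) sum(x@atoms$charge))

#' Atom coordinates as an N x 3 matrix
#' @param x a [ParameterizedStructure-class].
#' @return numeric matrix (Angstrom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
setMethod("coords", "ParameterizedStructure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z"), drop = FALSE]))

# internal constructor for a structure from an atom table + bonds
.newStructure <- function(atoms, bonds = NULL, role = "complex", name = "") {
  if (is.null(bonds) || length(bonds) == 0)
    bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  rownames(atoms) <- NULL
  new("ParameterizedStructure", atoms = atoms, bonds = bonds,
      role = role, name = name)
}

# empty atom table with the canonical columns
.emptyAtoms <- function(n = 0) {
  data.frame(element = character(n), x = numeric(n), y = numeric(n),
             z = numeric(n), charge = numeric(n), radius = rep(NA_real_, n),
             ljRminHalf = rep(NA_real_, n), ljEpsilon = rep(NA_real_, n),
             resname = character(n), isSolvent = logical(n),
             stringsAsFactors = FALSE)
}
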