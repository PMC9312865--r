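#' @include AllClasses.R
NULL

.ATOM_SYMBOLS <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg",
                   "Na", "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl",
                   "Yb", "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn",
                   "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
                   "Zr", "Cr", "Pt", "Hg", "Pb")
.HYB_STATES <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
.STD_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3, F = 1,
                  Cl = 1, Br = 1, I = 1)

#' The 75-wide per-atom feature schema
#'
#' Ordered one-hot blocks following the Duvenaud/ConvMol convention:
#' atom type (43 symbols + other = 44), degree 0-10 (11), implicit valence
#' 0-6 (7), formal charge (1), radical electrons (1), hybridization
#' sp/sp2/sp3/sp3d/sp3d2 (5), aromaticity (1), total hydrogens 0-4 (5).
#' Block widths sum to exactly 75.
#'
#' @return data.frame with columns `block`, `width`, `offset`.
#' @export
featureSchema <- function() {
  w <- c(atomType = 44L, degree = 11L, implicitValence = 7L,
         formalCharge = 1L, radicalElectrons = 1L, hybridization = 5L,
         aromatic = 1L, totalHydrogens = 5L)
  data.frame(block = names(w), width = as.integer(w),
             offset = cumsum(c(0L, w[-length(w)])),
             row.names = NULL, stringsAsFactors = FALSE)
}

# atoms that sit on a 5- or 6-cycle of the bond graph; for each such atom
# record whether every member of some such cycle is C/N/O/S with degree <= 3
.ringAromaticity <- function(n, bonds, element, degree) {
  arom <- logical(n)
  if (nrow(bonds) == 0 || n < 5) return(arom)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  okAtom <- element %in% c("C", "N", "O", "S") & degree <= 3
  for (e in seq_len(nrow(bonds))) {
    u <- bonds[e, 1]; v <- bonds[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, u, v)$vpath[[1]])
    ring <- as.integer(sp)
    if (length(ring) %in% c(5L, 6L) && all(okAtom[ring]))
      arom[ring] <- TRUE
  }
  arom
}

# documented fallback hybridization perception from bond counts
.hybridization <- function(element, degree, aromatic) {
  vapply(seq_along(element), function(i) {
    el <- element[i]; d <- degree[i]
    if (d >= 6) return("sp3d2")
    if (d == 5) return("sp3d")
    if (aromatic[i]) return("sp2")
    if (el == "C") return(if (d >= 4) "sp3" else if (d == 3) "sp2" else "sp")
    if (el == "N") return(if (d >= 3) "sp3" else if (d == 2) "sp2" else "sp")
    if (el %in% c("O", "S", "P")) return("sp3")
    NA_character_  # H, metals: unhybridized, block stays all-zero
  }, character(1))
}

#' Per-atom neighbor lists
#'
#' Bonded neighbors first (ascending index), completed with the nearest
#' non-bonded atoms by 3D distance up to `k` total (`mode = "hybrid"`,
#' default). `mode = "bond"` keeps only bonded neighbors; `mode =
#' "spatial"` uses pure distance ranking. Distance ties are broken by the
#' lower atom index; missing slots are padded with the sentinel 0.
#'
#' @param structure a [ParameterizedStructure-class].
#' @param k neighbor slots per atom (default 10).
#' @param mode `"hybrid"`, `"bond"` or `"spatial"`.
#' @return integer matrix, one row per atom, `k` columns.
#' @export
neighborLists <- function(structure, k = 10L,
                          mode = c("hybrid", "bond", "spatial")) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be at least 1")
  n <- nAtoms(structure)
  nb <- matrix(0L, n, k)
  if (n == 0) return(nb)
  b <- structure@bonds
  adj <- vector("list", n)
  if (nrow(b) > 0 && mode != "spatial") {
    for (r in seq_len(nrow(b))) {
      adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
      adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  D <- if (n > 1 && mode != "bond")
    as.matrix(stats::dist(coords(structure))) else NULL
  for (i in seq_len(n)) {
    bonded <- if (mode == "spatial") integer(0) else adj[[i]]
    lst <- utils::head(bonded, k)
    if (mode != "bond" && length(lst) < k && n > 1) {
      cand <- setdiff(seq_len(n), c(i, lst))
      cand <- cand[order(D[i, cand], cand)]
      lst <- c(lst, utils::head(cand, k - length(lst)))
    }
    if (length(lst) > 0) nb[i, seq_along(lst)] <- as.integer(lst)
  }
  nb
}

#' Featurize a structure as an atom graph
#'
#' Encodes every atom as a 75-wide feature row under [featureSchema()] and
#' attaches `k`-slot neighbor lists ([neighborLists()]). Elements outside
#' the symbol list fall in the "other" slot (never an error). Hybridization
#' and aromaticity are perceived from bond counts and 5/6-ring detection
#' (documented fallback for structures without cheminformatic annotation);
#' formal charges and radical electrons are 0 for such inputs.
#'
#' @param structure a [ParameterizedStructure-class] with elements and
#'   bonds.
#' @param k neighbor slots per atom (default 10).
#' @param mode neighbor semantics, see [neighborLists()].
#' @return An [AtomGraph-class].
#' @export
featurizeAtoms <- function(structure, k = 10L,
                           mode = c("hybrid", "bond", "spatial")) {
  mode <- match.arg(mode)
  a <- structure@atoms
  n <- nrow(a)
  sch <- featureSchema()
  X <- matrix(0, n, 75L)
  if (n > 0) {
    off <- stats::setNames(sch$offset, sch$block)
    b <- structure@bonds
    degree <- integer(n)
    nH <- integer(n)
    if (nrow(b) > 0) {
      tab <- table(factor(c(b[, 1], b[, 2]), levels = seq_len(n)))
      degree <- as.integer(tab)
      isH <- a$element == "H"
      hEnds <- c(b[, 1][isH[b[, 2]]], b[, 2][isH[b[, 1]]])
      if (length(hEnds) > 0) {
        th <- table(factor(hEnds, levels = seq_len(n)))
        nH <- as.integer(th)
      }
    }
    arom <- .ringAromaticity(n, b, a$element, degree)
    hyb <- .hybridization(a$element, degree, arom)
    stdVal <- .STD_VALENCE[a$element]
    stdVal[is.na(stdVal)] <- 0
    implVal <- pmin(pmax(stdVal - degree, 0), 6)
    for (i in seq_len(n)) {
      slot <- match(a$element[i], .ATOM_SYMBOLS)
      if (is.na(slot)) slot <- 44L
      X[i, off["atomType"] + slot] <- 1
      X[i, off["degree"] + min(degree[i], 10L) + 1L] <- 1
      X[i, off["implicitValence"] + implVal[i] + 1L] <- 1
      X[i, off["formalCharge"] + 1L] <- 0
      X[i, off["radicalElectrons"] + 1L] <- 0
      if (!is.na(hyb[i]))
        X[i, off["hybridization"] + match(hyb[i], .HYB_STATES)] <- 1
      X[i, off["aromatic"] + 1L] <- as.numeric(arom[i])
      X[i, off["totalHydrogens"] + min(nH[i], 4L) + 1L] <- 1
    }
  }
  new("AtomGraph", features = X,
      neighbors = neighborLists(structure, k = k, mode = mode))
}

#' Batch atom graphs for a joint forward pass
#'
#' Concatenates atom rows, re-indexes neighbor lists into the batch frame
#' and records per-graph membership so graph-level pooling can segment the
#' batch. [unbatchGraphs()] recovers the originals exactly.
#'
#' @param graphs non-empty list of [AtomGraph-class] objects.
#' @return A [BatchedGraphs-class].
#' @export
batchGraphs <- function(graphs) {
  if (length(graphs) == 0) stop("need at least one graph to batch")
  sizes <- vapply(graphs, nAtoms, integer(1))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  feats <- do.call(rbind, lapply(graphs, function(g) g@features))
  nbs <- do.call(rbind, mapply(function(g, o) {
    nb <- g@neighbors
    nb[nb > 0L] <- nb[nb > 0L] + o
    nb
  }, graphs, offs, SIMPLIFY = FALSE))
  new("BatchedGraphs", features = feats, neighbors = nbs,
      membership = rep(seq_along(graphs), sizes),
      sizes = as.integer(sizes))
}

#' Recover individual graphs from a batch
#' @param batched a [BatchedGraphs-class].
#' @return list of [AtomGraph-class] objects.
#' @export
unbatchGraphs <- function(batched) {
  offs <- cumsum(c(0L, batched@sizes[-length(batched@sizes)]))
  lapply(seq_along(batched@sizes), function(gi) {
    rows <- which(batched@membership == gi)
    nb <- batched@neighbors[rows, , drop = FALSE]
    nb[nb > 0L] <- nb[nb > 0L] - offs[gi]
    new("AtomGraph", features = batched@features[rows, , drop = FALSE],
        neighbors = nb)
  })
}
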