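# in-code fixtures and independent brute-force oracles

mkStruct <- function(elements, xyz, charge = 0, radius = 1.5,
                     rminHalf = 1.7, ljEps = 0.1, bonds = NULL,
                     resname = "MOL", role = "complex", name = "fixture") {
  n <- length(elements)
  xyz <- matrix(xyz, ncol = 3)
  atoms <- data.frame(
    element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), radius = rep_len(radius, n),
    ljRminHalf = rep_len(rminHalf, n), ljEpsilon = rep_len(ljEps, n),
    resname = rep_len(resname, n), isSolvent = FALSE,
    stringsAsFactors = FALSE)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  methods::new("ParameterizedStructure", atoms = atoms,
               bonds = matrix(as.integer(bonds), ncol = 2),
               role = role, name = name)
}

# breadth-first bond-path lengths, independent of the package's route
bfBondDist <- function(n, bonds) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(bonds) > 0) for (r in seq_len(nrow(bonds))) {
    adj[[bonds[r, 1]]] <- c(adj[[bonds[r, 1]]], bonds[r, 2])
    adj[[bonds[r, 2]]] <- c(adj[[bonds[r, 2]]], bonds[r, 1])
  }
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (src in seq_len(n)) {
    frontier <- src; d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[src, nxt] == Inf]
      D[src, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# naive double-loop Coulomb with Amber exclusions
bfCoulomb <- function(st, ke = 332.0637, epsIn = 1, scale14 = 1.2) {
  a <- st@atoms; n <- nrow(a)
  G <- bfBondDist(n, st@bonds)
  eelec <- 0; eel14 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(a$x[j], a$y[j], a$z[j]))^2))
    e <- ke * a$charge[i] * a$charge[j] / (epsIn * r)
    if (G[i, j] == 3) eel14 <- eel14 + e / scale14
    else if (G[i, j] >= 4) eelec <- eelec + e
  }
  list(eelec = eelec, eel14 = eel14)
}

bfLJ <- function(st, scale14 = 2.0) {
  a <- st@atoms; n <- nrow(a)
  G <- bfBondDist(n, st@bonds)
  out <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    if (G[i, j] < 3) next
    r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(a$x[j], a$y[j], a$z[j]))^2))
    rmin <- a$ljRminHalf[i] + a$ljRminHalf[j]
    eps <- sqrt(a$ljEpsilon[i] * a$ljEpsilon[j])
    e <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    out <- out + if (G[i, j] == 3) e / scale14 else e
  }
  out
}

# naive double-loop ALPB polar energy (ordered pairs incl. self terms)
bfPolar <- function(st, R, params) {
  a <- st@atoms; n <- nrow(a)
  beta <- params@epsIn / params@epsOut
  A <- electrostaticSize(st)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(a$x[j], a$y[j], a$z[j]))^2))
    f <- sqrt(r^2 + R[i] * R[j] * exp(-r^2 / (4 * R[i] * R[j])))
    tot <- tot + a$charge[i] * a$charge[j] *
      (1 / f + params@alpha * beta / A)
  }
  -0.5 * params@coulombK * (1 / params@epsIn - 1 / params@epsOut) /
    (1 + beta * params@alpha) * tot
}

# Monte-Carlo descreening integral for the R6 effective radius of atom i
mcBornRadius <- function(st, i, nSample = 1e6, seed = 42) {
  a <- st@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rho <- a$radius
  descr <- 0
  withr::with_seed(seed, {
    for (j in setdiff(seq_len(nrow(a)), i)) {
      u <- matrix(stats::rnorm(3 * nSample), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- rho[j] * stats::runif(nSample)^(1 / 3)
      pts <- sweep(u * rad, 2, xyz[j, ], "+")
      r2 <- rowSums(sweep(pts, 2, xyz[i, ])^2)
      vals <- ifelse(r2 >= rho[i]^2, r2^(-3), 0)
      descr <- descr + (3 / (4 * pi)) * (4 / 3 * pi * rho[j]^3) * mean(vals)
    }
  })
  max(rho[i], (rho[i]^(-3) - descr)^(-1 / 3))
}

rigidMotion <- function(st, angle = 0.7, shift = c(3, -2, 5)) {
  ax <- c(1, 2, 2) / 3
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  Rm <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(st@atoms[, c("x", "y", "z")]) %*% t(Rm)
  st@atoms$x <- xyz[, 1] + shift[1]
  st@atoms$y <- xyz[, 2] + shift[2]
  st@atoms$z <- xyz[, 3] + shift[3]
  st
}

tinyDataset <- function(n = 6, seed = 1, s = 0, noise = 0,
                        hostRange = c(10L, 14L), guestRange = c(3L, 4L)) {
  makeLabeledDataset(fixtureSpec(
    nComplexes = n, atomsPerHost = hostRange, atomsPerGuest = guestRange,
    nonlinearityAmplitude = s, labelNoiseSd = noise, seed = seed))
}

tinyConfig <- function(epochs = 3, seed = 1, batchSize = 4L)
  pgnnConfig(epochs = epochs, seed = seed, batchSize = batchSize,
             headHidden = 8L)
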