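#' @include featurize.R energy.R
NULL

#' PGNN training configuration
#'
#' Defaults follow the study conditions: 2 GraphConv layers of fixed
#' channel size 75 (matching the featurizer width), 10 neighbor slots,
#' 100 epochs at learning rate 0.001 with an Adam optimizer and MSE loss.
#' Batch size 32 and the M-head hidden width 32 are package defaults
#' (documented configuration, not constants of the method).
#'
#' @param nLayers number of GraphConv layers.
#' @param channels channel width; fixed at 75 (the feature width).
#' @param kNeighbors neighbor slots per atom.
#' @param epochs training epochs.
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param seed integer seed controlling init and shuffling.
#' @param optimizer only `"adam"` is implemented.
#' @param headHidden hidden width of the first ReLU dense layer reducing
#'   the gathered 75-vector to the scalar model variable M.
#' @param bnEps,bnMomentum batch-norm variance floor and running-statistic
#'   update rate.
#' @return named list of settings.
#' @export
pgnnConfig <- function(nLayers = 2L, channels = 75L, kNeighbors = 10L,
                       epochs = 100L, learningRate = 0.001,
                       batchSize = 32L, seed = 1L, optimizer = "adam",
                       headHidden = 32L, bnEps = 1e-5, bnMomentum = 0.1) {
  if (epochs < 1) stop("epochs must be at least 1")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (channels != 75L) stop("channel width is fixed at the feature width 75")
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  list(nLayers = as.integer(nLayers), channels = 75L,
       kNeighbors = as.integer(kNeighbors), epochs = as.integer(epochs),
       learningRate = learningRate, batchSize = as.integer(batchSize),
       seed = as.integer(seed), optimizer = optimizer,
       headHidden = as.integer(headHidden), bnEps = bnEps,
       bnMomentum = bnMomentum)
}

# run expr under a private RNG stream; caller's RNG state is untouched
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.glorot <- function(nin, nout)
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)

#' Create a physics-initialized PGNN model
#'
#' GraphConv and first M-head layer weights are Glorot-random (seeded); the
#' output layer of the M head is zero-initialized so the model variable M
#' is exactly 0 before training, and the final dense layer is set to the
#' thermodynamic pattern: +1 for every complex energy term, -1 for every
#' receptor and ligand term, -1 for the entropy residual, 0.5 for the model
#' variable, bias 0. A freshly created model therefore reproduces
#' \eqn{\Delta\Delta G = \Delta H - T\Delta S} exactly on physics-consistent
#' data.
#'
#' @param config from [pgnnConfig()].
#' @param usePhysics `FALSE` builds the graph-only ablation (the physics
#'   vector is zeroed during training and prediction).
#' @return A [PGNNModel-class].
#' @export
pgnnModel <- function(config = pgnnConfig(), usePhysics = TRUE) {
  ch <- config$channels
  h <- config$headHidden
  w <- .withSeed(config$seed, {
    w <- list(Wself = list(), Wnbr = list(), bConv = list(),
              bnMean = list(), bnVar = list())
    for (l in seq_len(config$nLayers)) {
      w$Wself[[l]] <- .glorot(ch, ch)
      w$Wnbr[[l]] <- .glorot(ch, ch)
      w$bConv[[l]] <- numeric(ch)
      w$bnMean[[l]] <- numeric(ch)
      w$bnVar[[l]] <- rep(1, ch)
    }
    w$W1 <- .glorot(ch, h)
    w$b1 <- numeric(h)
    w$W2 <- matrix(0, h, 1)   # zero output layer: M = 0 at initialization
    w$b2 <- 0
    w
  })
  w$headW <- stats::setNames(c(physicsInitPattern(), 0.5),
                             c(physicsFeatureNames(), "modelVariable"))
  w$headB <- 0
  new("PGNNModel", weights = w, config = config,
      trainingLog = data.frame(), usePhysics = usePhysics)
}

#' One GraphConv layer
#'
#' Slot s of the output holds
#' \eqn{\tanh(W_{self} h_i + W_{nbr} h_{n(i,s)} + b)}; sentinel slots
#' (neighbor index 0) omit the neighbor term. Output is bounded in (-1, 1).
#'
#' @param graphState N x 75 node-state matrix.
#' @param neighbors N x k integer neighbor matrix (0 sentinel).
#' @param Wself,Wnbr 75 x 75 weight matrices.
#' @param b length-75 bias.
#' @return N x 75 x k array.
#' @export
graphConvLayer <- function(graphState, neighbors, Wself, Wnbr, b) {
  if (ncol(graphState) != nrow(Wself) || ncol(Wself) != length(b))
    stop("dimension mismatch between graph state and layer weights")
  slots <- .convSlots(graphState, neighbors, Wself, Wnbr, b)
  arr <- array(0, c(nrow(graphState), ncol(Wself), ncol(neighbors)))
  for (s in seq_along(slots)) arr[, , s] <- slots[[s]]
  arr
}

# list of k matrices (N x ch), slot s = tanh(selfPart + nbrPart_s)
.convSlots <- function(H, nb, Wself, Wnbr, b) {
  selfPart <- sweep(H %*% Wself, 2, b, "+")
  nbrPart <- H %*% Wnbr
  lapply(seq_len(ncol(nb)), function(s) {
    pre <- selfPart
    idx <- nb[, s]
    valid <- idx > 0L
    if (any(valid))
      pre[valid, ] <- pre[valid, , drop = FALSE] +
        nbrPart[idx[valid], , drop = FALSE]
    tanh(pre)
  })
}

# batch-norm statistics over all (atom, slot) entries per channel
.bnStats <- function(slots) {
  S <- do.call(rbind, slots)
  mu <- colMeans(S)
  list(mu = mu, var = colMeans(S^2) - mu^2)
}

#' Batch normalization followed by neighbor max-pooling
#'
#' Normalizes each channel over all (atom, slot) entries (training mode:
#' batch statistics; eval mode: the supplied running statistics), then takes
#' the maximum over the neighbor axis.
#'
#' @param convOut N x 75 x k array from [graphConvLayer()].
#' @param mode `"train"` or `"eval"`.
#' @param runningMean,runningVar per-channel statistics used in eval mode.
#' @param eps variance floor.
#' @return N x 75 matrix.
#' @export
poolAndNormalize <- function(convOut, mode = c("eval", "train"),
                             runningMean = NULL, runningVar = NULL,
                             eps = 1e-5) {
  mode <- match.arg(mode)
  slots <- lapply(seq_len(dim(convOut)[3]), function(s) convOut[, , s])
  if (mode == "train") {
    st <- .bnStats(slots)
    mu <- st$mu; v <- st$var
  } else {
    if (is.null(runningMean) || is.null(runningVar))
      stop("eval mode needs running statistics")
    mu <- runningMean; v <- runningVar
  }
  pooled <- .poolSlots(slots, mu, v, eps)$pooled
  pooled
}

# normalize slots and max-pool; records argmax slot for backprop
.poolSlots <- function(slots, mu, v, eps) {
  sdv <- sqrt(v + eps)
  norm <- lapply(slots, function(S) sweep(sweep(S, 2, mu), 2, sdv, "/"))
  pooled <- norm[[1]]
  arg <- matrix(1L, nrow(pooled), ncol(pooled))
  for (s in seq_along(norm)[-1]) {
    upd <- norm[[s]] > pooled
    pooled[upd] <- norm[[s]][upd]
    arg[upd] <- s
  }
  list(pooled = pooled, argmax = arg, sdv = sdv)
}

#' GraphGather: aggregate node states into per-graph vectors
#'
#' Sums member-atom rows per graph and applies tanh; permutation-invariant
#' in the atom order.
#'
#' @param nodeFeatures N x 75 matrix.
#' @param membership integer graph id per row.
#' @return one 75-vector per graph (matrix, graphs x 75).
#' @export
graphGather <- function(nodeFeatures, membership) {
  if (length(membership) != nrow(nodeFeatures))
    stop("membership must cover all node rows")
  tanh(rowsum(nodeFeatures, group = membership, reorder = TRUE))
}

#' The scalar model variable M
#'
#' Two ReLU dense layers reduce a gathered 75-vector to one scalar.
#'
#' @param gathered graphs x 75 matrix (or a single 75-vector).
#' @param W1,b1,W2,b2 dense-layer weights.
#' @return numeric vector, one M per graph (each >= 0 through the final
#'   ReLU).
#' @export
modelVariable <- function(gathered, W1, b1, W2, b2) {
  if (is.null(dim(gathered))) gathered <- matrix(gathered, nrow = 1)
  A1 <- pmax(sweep(gathered %*% W1, 2, b1, "+"), 0)
  as.numeric(pmax(A1 %*% W2 + b2, 0))
}

# full forward pass over a batch; returns prediction and (optionally) the
# caches needed for backprop.  P: B x 16 matrix (zeroed for the ablation).
.forward <- function(model, batched, P, mode = "eval", keepCache = FALSE) {
  w <- model@weights
  cfg <- model@config
  H <- batched@features
  nb <- batched@neighbors
  caches <- vector("list", cfg$nLayers)
  batchStats <- vector("list", cfg$nLayers)
  for (l in seq_len(cfg$nLayers)) {
    slots <- .convSlots(H, nb, w$Wself[[l]], w$Wnbr[[l]], w$bConv[[l]])
    if (mode == "train") {
      st <- .bnStats(slots)
      batchStats[[l]] <- st
      mu <- st$mu; v <- st$var
    } else {
      mu <- w$bnMean[[l]]; v <- w$bnVar[[l]]
    }
    pl <- .poolSlots(slots, mu, v, cfg$bnEps)
    if (keepCache)
      caches[[l]] <- list(input = H, slots = slots, argmax = pl$argmax,
                          sdv = pl$sdv)
    H <- pl$pooled
  }
  sums <- rowsum(H, group = batched@membership, reorder = TRUE)
  G <- tanh(sums)
  Z1 <- sweep(G %*% w$W1, 2, w$b1, "+")
  A1 <- pmax(Z1, 0)
  Z2 <- as.numeric(A1 %*% w$W2 + w$b2)
  M <- pmax(Z2, 0)
  physPart <- if (model@usePhysics) as.numeric(P %*% w$headW[1:16]) else 0
  pred <- as.numeric(physPart + M * unname(w$headW[17]) + w$headB)
  out <- list(pred = pred, M = M)
  if (keepCache)
    out <- c(out, list(caches = caches, batchStats = batchStats,
                       H = H, G = G, Z1 = Z1, A1 = A1, Z2 = Z2,
                       P = P, batched = batched))
  out
}

# ReLU subgradient; taken as 1 at exactly 0 so the zero-initialized M-head
# output layer still receives gradient
.dRelu <- function(z) as.numeric(z >= 0)

# backward pass; returns gradients for every trainable parameter
.backward <- function(model, fw, y) {
  w <- model@weights
  cfg <- model@config
  B <- length(y)
  dPred <- 2 * (fw$pred - y) / B
  g <- list()
  g$headW <- c(if (model@usePhysics) as.numeric(crossprod(fw$P, dPred))
               else numeric(16),
               sum(dPred * fw$M))
  g$headB <- sum(dPred)
  dM <- dPred * w$headW[17]
  dZ2 <- dM * .dRelu(fw$Z2)
  g$W2 <- crossprod(fw$A1, matrix(dZ2, ncol = 1))
  g$b2 <- sum(dZ2)
  dA1 <- matrix(dZ2, ncol = 1) %*% t(w$W2)
  dZ1 <- dA1 * (fw$Z1 >= 0)
  g$W1 <- crossprod(fw$G, dZ1)
  g$b1 <- colSums(dZ1)
  dG <- dZ1 %*% t(w$W1)
  dSums <- dG * (1 - fw$G^2)
  dH <- dSums[fw$batched@membership, , drop = FALSE]
  nb <- fw$batched@neighbors
  g$Wself <- g$Wnbr <- g$bConv <- vector("list", cfg$nLayers)
  for (l in rev(seq_len(cfg$nLayers))) {
    cc <- fw$caches[[l]]
    H <- cc$input
    dPreSum <- matrix(0, nrow(H), ncol(H))
    dWnbr <- matrix(0, ncol(H), ncol(H))
    dHprev <- matrix(0, nrow(H), ncol(H))
    for (s in seq_along(cc$slots)) {
      sel <- cc$argmax == s
      if (!any(sel)) next
      # max-pool routes gradient to the winning slot; batch-norm statistics
      # are treated as constants, so the BN backward is a per-channel scale
      dNorm <- matrix(0, nrow(H), ncol(H))
      dNorm[sel] <- dH[sel]
      dOut <- sweep(dNorm, 2, cc$sdv, "/")
      dPre <- dOut * (1 - cc$slots[[s]]^2)
      dPreSum <- dPreSum + dPre
      idx <- nb[, s]
      valid <- which(idx > 0L)
      if (length(valid) > 0) {
        dWnbr <- dWnbr + crossprod(H[idx[valid], , drop = FALSE],
                                   dPre[valid, , drop = FALSE])
        contrib <- dPre[valid, , drop = FALSE] %*% t(model@weights$Wnbr[[l]])
        agg <- rowsum(contrib, group = idx[valid])
        rows <- as.integer(rownames(agg))
        dHprev[rows, ] <- dHprev[rows, , drop = FALSE] + agg
      }
    }
    g$bConv[[l]] <- colSums(dPreSum)
    g$Wself[[l]] <- crossprod(H, dPreSum)
    g$Wnbr[[l]] <- dWnbr
    dHprev <- dHprev + dPreSum %*% t(model@weights$Wself[[l]])
    dH <- dHprev
  }
  g
}

# flatten trainable parameters to a named list of arrays for Adam
.paramNames <- function(cfg) {
  c(unlist(lapply(seq_len(cfg$nLayers), function(l)
    paste0(c("Wself", "Wnbr", "bConv"), ".", l))),
    "W1", "b1", "W2", "b2", "headW", "headB")
}

.getParam <- function(w, nm) {
  if (grepl("\\.", nm)) {
    p <- strsplit(nm, "\\.")[[1]]
    w[[p[1]]][[as.integer(p[2])]]
  } else w[[nm]]
}

.setParam <- function(w, nm, val) {
  if (grepl("\\.", nm)) {
    p <- strsplit(nm, "\\.")[[1]]
    w[[p[1]]][[as.integer(p[2])]] <- val
  } else w[[nm]] <- val
  w
}

#' Train a PGNN model
#'
#' Minibatch Adam on the mean-squared error between predicted and
#' experimental \eqn{\Delta\Delta G}. The physics head is initialized to
#' the thermodynamic pattern before the first step (see [pgnnModel()]).
#' Fully reproducible for a fixed `config$seed` on one thread.
#'
#' @param dataset non-empty list of items, each a list with elements
#'   `graph` ([AtomGraph-class]), `P` (length-16 physics vector) and `ddg`
#'   (label, kcal/mol), as produced by [makeLabeledDataset()].
#' @param config from [pgnnConfig()].
#' @param valData optional held-out items; their loss is logged per epoch.
#' @param usePhysics `FALSE` trains the graph-only ablation (physics
#'   vectors zeroed, head free).
#' @return A trained [PGNNModel-class] with a populated `trainingLog`.
#' @export
trainPGNN <- function(dataset, config = pgnnConfig(), valData = NULL,
                      usePhysics = TRUE) {
  if (length(dataset) == 0) stop("dataset is empty")
  model <- pgnnModel(config, usePhysics = usePhysics)
  n <- length(dataset)
  graphs <- lapply(dataset, `[[`, "graph")
  Pall <- do.call(rbind, lapply(dataset, `[[`, "P"))
  if (!usePhysics) Pall[] <- 0
  y <- vapply(dataset, `[[`, numeric(1), "ddg")
  valBatch <- NULL
  if (!is.null(valData) && length(valData) > 0) {
    valBatch <- list(
      b = batchGraphs(lapply(valData, `[[`, "graph")),
      P = {
        vp <- do.call(rbind, lapply(valData, `[[`, "P"))
        if (!usePhysics) vp[] <- 0
        vp
      },
      y = vapply(valData, `[[`, numeric(1), "ddg"))
  }
  nms <- .paramNames(config)
  mAdam <- vAdam <- stats::setNames(
    lapply(nms, function(nm) .getParam(model@weights, nm) * 0), nms)
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  tstep <- 0
  log <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                    valLoss = numeric(0))
  .withSeed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      epLoss <- 0
      for (st in starts) {
        idx <- ord[st:min(st + config$batchSize - 1, n)]
        batched <- batchGraphs(graphs[idx])
        P <- Pall[idx, , drop = FALSE]
        fw <- .forward(model, batched, P, mode = "train", keepCache = TRUE)
        loss <- mean((fw$pred - y[idx])^2)
        epLoss <- epLoss + loss * length(idx)
        # update running batch-norm statistics
        for (l in seq_len(config$nLayers)) {
          bs <- fw$batchStats[[l]]
          mom <- config$bnMomentum
          model@weights$bnMean[[l]] <-
            (1 - mom) * model@weights$bnMean[[l]] + mom * bs$mu
          model@weights$bnVar[[l]] <-
            (1 - mom) * model@weights$bnVar[[l]] + mom * bs$var
        }
        g <- .backward(model, fw, y[idx])
        tstep <- tstep + 1
        for (nm in nms) {
          grad <- .getParam(g, nm)
          if (is.null(grad)) next
          mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * grad
          vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * grad^2
          mh <- mAdam[[nm]] / (1 - beta1^tstep)
          vh <- vAdam[[nm]] / (1 - beta2^tstep)
          model@weights <- .setParam(
            model@weights, nm,
            .getParam(model@weights, nm) -
              config$learningRate * mh / (sqrt(vh) + adamEps))
        }
      }
      vl <- NA_real_
      if (!is.null(valBatch)) {
        fv <- .forward(model, valBatch$b, valBatch$P, mode = "eval")
        vl <- mean((fv$pred - valBatch$y)^2)
      }
      log <- rbind(log, data.frame(epoch = ep, trainLoss = epLoss / n,
                                   valLoss = vl))
    }
  })
  model@trainingLog <- log
  validObject(model)
  model
}

#' Predict binding free energy
#'
#' Eval-mode forward pass: \eqn{\Delta\Delta G_{pred} = w \cdot (P, M) + b}.
#'
#' @param model a [PGNNModel-class].
#' @param graph an [AtomGraph-class], a [BatchedGraphs-class], or a list of
#'   dataset items (each with `graph` and `P`).
#' @param P physics feature vector(s): length-16 vector or graphs x 16
#'   matrix (ignored when `graph` is an item list).
#' @return numeric vector of predictions, kcal/mol.
#' @export
predictDdg <- function(model, graph, P = NULL) {
  if (is.list(graph) && !is(graph, "AtomGraph") &&
      !is(graph, "BatchedGraphs")) {
    P <- do.call(rbind, lapply(graph, `[[`, "P"))
    graph <- batchGraphs(lapply(graph, `[[`, "graph"))
  }
  if (is(graph, "AtomGraph")) graph <- batchGraphs(list(graph))
  if (is.null(P)) stop("physics feature vector(s) P required")
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  if (ncol(P) != 16L) stop("P must have exactly 16 columns")
  if (!model@usePhysics) P[] <- 0
  .forward(model, graph, P, mode = "eval")$pred
}

.TERM_LABELS <- c(vdwaals = "VDWAALS", eelec = "EELEC", esurf = "ESURF",
                  egb = "EGB", eel14 = "1-4-eel")

#' Interpretable final-layer coefficients
#'
#' The 16 physics coefficients plus the model-variable coefficient of the
#' final dense layer, arranged per energy term with receptor, ligand and
#' complex columns; the entropy and model-variable coefficients appear in
#' the `value` column. A fresh model shows the initialization pattern.
#'
#' @param model a [PGNNModel-class].
#' @return data.frame with columns `parameter`, `receptor`, `ligand`,
#'   `complex`, `value`.
#' @export
headCoefficients <- function(model) {
  hw <- model@weights$headW
  rows <- lapply(names(.TERM_LABELS), function(term) {
    data.frame(parameter = .TERM_LABELS[[term]],
               receptor = hw[[paste0(term, ".receptor")]],
               ligand = hw[[paste0(term, ".ligand")]],
               complex = hw[[paste0(term, ".complex")]],
               value = NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out,
               data.frame(parameter = "Entropy", receptor = NA_real_,
                          ligand = NA_real_, complex = NA_real_,
                          value = hw[["entropy"]]),
               data.frame(parameter = "Model variable", receptor = NA_real_,
                          ligand = NA_real_, complex = NA_real_,
                          value = hw[["modelVariable"]]))
  rownames(out) <- NULL
  out
}
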