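## Minimal CNN graph engine.
##
## A network is an ordered list of nodes (a DAG in topological order). Each
## node is a list(name, type, inputs = character(), ...params). Supported
## types: input, conv, bn, relu, maxpool, gap (global average pool), fc,
## softmax, add, concat. Activations are (H, W, C) arrays or plain numeric
## vectors. Convolution weights are stored as (kh*kw*C) x F matrices matching
## the im2col row order; fc weights as (in x out). Forward and reverse-mode
## backward are implemented for every type, which is what feature
## extraction, head/full fine-tuning and Grad-CAM need.

## ------------------------------------------------------------ graph builder

newGraphBuilder <- function(inputSize) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list(list(name = "input", type = "input", inputs = character()))
  env$shapes <- list(input = inputSize)
  env$last <- "input"
  env
}

gbShape <- function(gb, name = gb$last) gb$shapes[[name]]

gbAdd <- function(gb, node, shape, after = TRUE) {
  gb$nodes[[length(gb$nodes) + 1L]] <- node
  gb$shapes[[node$name]] <- shape
  if (after) gb$last <- node$name
  invisible(node$name)
}

convOutDim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

gbConv <- function(gb, name, k, outC, stride = 1L, pad = 0L,
                   input = gb$last) {
  s <- gbShape(gb, input)
  fanIn <- k * k * s[3L]
  W <- matrix(rnorm(fanIn * outC, sd = sqrt(2 / fanIn)), fanIn, outC)
  shape <- c(convOutDim(s[1L], k, stride, pad),
             convOutDim(s[2L], k, stride, pad), outC)
  gbAdd(gb, list(name = name, type = "conv", inputs = input, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad),
                 inC = s[3L], outC = as.integer(outC), W = W,
                 b = numeric(outC)), shape)
}

gbBN <- function(gb, name, input = gb$last) {
  s <- gbShape(gb, input)
  C <- s[3L]
  gbAdd(gb, list(name = name, type = "bn", inputs = input,
                 gamma = rep(1, C), beta = numeric(C), mean = numeric(C),
                 var = rep(1, C), eps = 1e-5), s)
}

gbRelu <- function(gb, name, input = gb$last)
  gbAdd(gb, list(name = name, type = "relu", inputs = input),
        gbShape(gb, input))

gbMaxPool <- function(gb, name, k, stride, pad = 0L, input = gb$last) {
  s <- gbShape(gb, input)
  shape <- c(convOutDim(s[1L], k, stride, pad),
             convOutDim(s[2L], k, stride, pad), s[3L])
  gbAdd(gb, list(name = name, type = "maxpool", inputs = input,
                 k = as.integer(k), stride = as.integer(stride),
                 pad = as.integer(pad)), shape)
}

gbGap <- function(gb, name, input = gb$last) {
  s <- gbShape(gb, input)
  gbAdd(gb, list(name = name, type = "gap", inputs = input), s[3L])
}

gbFC <- function(gb, name, outDim, input = gb$last) {
  inDim <- prod(gbShape(gb, input))
  W <- matrix(rnorm(inDim * outDim, sd = sqrt(2 / inDim)), inDim, outDim)
  gbAdd(gb, list(name = name, type = "fc", inputs = input,
                 inShape = gbShape(gb, input), W = W, b = numeric(outDim)),
        as.integer(outDim))
}

gbSoftmax <- function(gb, name, input = gb$last)
  gbAdd(gb, list(name = name, type = "softmax", inputs = input),
        gbShape(gb, input))

gbAddNode <- function(gb, name, inputs) {
  gbAdd(gb, list(name = name, type = "add", inputs = inputs),
        gbShape(gb, inputs[1L]))
}

gbConcat <- function(gb, name, inputs) {
  shp <- gbShape(gb, inputs[1L])
  cs <- vapply(inputs, function(i) gbShape(gb, i)[3L], integer(1L))
  gbAdd(gb, list(name = name, type = "concat", inputs = inputs,
                 channels = as.integer(cs)), c(shp[1:2], sum(cs)))
}

## ----------------------------------------------------------------- forward

flatToShape <- function(v, shape) {
  if (length(shape) == 1L) return(as.numeric(v))
  aperm(array(v, rev(shape)), c(3L, 2L, 1L))
}

nodeForward <- function(node, acts, aux) {
  getIn <- function(i = 1L) acts[[node$inputs[i]]]
  switch(node$type,
    conv = {
      x <- getIn()
      d <- dim(x)
      cols <- im2col_cpp(as.numeric(x), d[1L], d[2L], d[3L],
                         node$k, node$k, node$stride, node$pad)
      outH <- convOutDim(d[1L], node$k, node$stride, node$pad)
      outW <- convOutDim(d[2L], node$k, node$stride, node$pad)
      y <- crossprod(node$W, cols) + node$b     # F x P (+ recycled bias)
      array(t(y), c(outH, outW, node$outC))
    },
    bn = {
      x <- getIn()
      d <- dim(x)
      sc <- node$gamma / sqrt(node$var + node$eps)
      sh <- node$beta - node$mean * sc
      x * rep(sc, each = d[1L] * d[2L]) + rep(sh, each = d[1L] * d[2L])
    },
    relu = pmax(getIn(), 0),
    maxpool = {
      x <- getIn()
      d <- dim(x)
      r <- maxpool_cpp(as.numeric(x), d[1L], d[2L], d[3L],
                       node$k, node$stride, node$pad)
      aux[[node$name]] <- list(argmax = r$argmax, nIn = length(x))
      array(r$values, c(r$outH, r$outW, d[3L]))
    },
    gap = {
      x <- getIn()
      apply(x, 3L, mean)
    },
    fc = {
      v <- getIn()
      if (!is.null(dim(v))) v <- flattenRowMajor(v)
      as.numeric(crossprod(node$W, v)) + node$b
    },
    softmax = {
      v <- getIn()
      e <- exp(v - max(v))
      e / sum(e)
    },
    add = getIn(1L) + getIn(2L),
    concat = {
      parts <- lapply(node$inputs, function(nm) acts[[nm]])
      d <- dim(parts[[1L]])
      array(unlist(parts, use.names = FALSE),
            c(d[1L], d[2L], sum(node$channels)))
    },
    stop("unknown node type ", node$type))
}

# Forward pass; returns an environment with acts[[name]] (and aux for pools).
# `upto` stops early once the named node is computed. Only nodes needed are
# evaluated in graph order.
nnForward <- function(model, x, upto = NULL) {
  graph <- if (is(model, "CnnModel")) model@graph else model
  cache <- new.env(parent = emptyenv())
  cache$acts <- new.env(parent = emptyenv())
  cache$aux <- new.env(parent = emptyenv())
  cache$acts[["input"]] <- x
  for (node in graph) {
    if (node$type == "input") next
    cache$acts[[node$name]] <- nodeForward(node, cache$acts, cache$aux)
    if (!is.null(upto) && node$name == upto) break
  }
  cache
}

getActivation <- function(cache, name) {
  a <- cache$acts[[name]]
  if (is.null(a)) stopf("no activation cached for layer '%s'", name)
  a
}

## ---------------------------------------------------------------- backward

# Reverse-mode gradients. seedGrads: named list of gradients w.r.t. node
# outputs. Returns list(dActs = env, dParams = named list per node of
# list(W=, b=) / list(gamma=, beta=)). stopAt: node name below which
# gradients are not propagated (saves work for Grad-CAM).
nnBackward <- function(model, cache, seedGrads, needParams = FALSE,
                       stopAt = NULL) {
  graph <- if (is(model, "CnnModel")) model@graph else model
  acts <- cache$acts
  dA <- new.env(parent = emptyenv())
  for (nm in names(seedGrads)) dA[[nm]] <- seedGrads[[nm]]
  dParams <- list()
  addGrad <- function(name, g) {
    cur <- dA[[name]]
    dA[[name]] <- if (is.null(cur)) g else cur + g
  }
  for (i in rev(seq_along(graph))) {
    node <- graph[[i]]
    if (node$type == "input") next
    g <- dA[[node$name]]
    if (is.null(g)) next
    if (!is.null(stopAt) && node$name == stopAt) next  # keep grad, stop here
    inName <- node$inputs
    switch(node$type,
      conv = {
        x <- acts[[inName]]
        d <- dim(x)
        P <- prod(dim(g)[1:2])
        gMat <- matrix(g, nrow = P)                 # P x F
        if (needParams) {
          cols <- im2col_cpp(as.numeric(x), d[1L], d[2L], d[3L],
                             node$k, node$k, node$stride, node$pad)
          dParams[[node$name]] <- list(W = cols %*% gMat, b = colSums(gMat))
        }
        dCols <- node$W %*% t(gMat)                  # (khkwC) x P
        dx <- col2im_cpp(dCols, d[1L], d[2L], d[3L],
                         node$k, node$k, node$stride, node$pad)
        addGrad(inName, array(dx, d))
      },
      bn = {
        x <- acts[[inName]]
        d <- dim(x)
        sc <- node$gamma / sqrt(node$var + node$eps)
        if (needParams) {
          xhat <- (x - rep(node$mean, each = d[1L] * d[2L])) *
            rep(1 / sqrt(node$var + node$eps), each = d[1L] * d[2L])
          dParams[[node$name]] <- list(
            gamma = apply(g * xhat, 3L, sum), beta = apply(g, 3L, sum))
        }
        addGrad(inName, g * rep(sc, each = d[1L] * d[2L]))
      },
      relu = addGrad(inName, g * (acts[[inName]] > 0)),
      maxpool = {
        info <- cache$aux[[node$name]]
        dx <- maxpool_backward_cpp(as.numeric(g), info$argmax, info$nIn)
        addGrad(inName, array(dx, dim(acts[[inName]])))
      },
      gap = {
        x <- acts[[inName]]
        d <- dim(x)
        addGrad(inName, array(rep(g / (d[1L] * d[2L]), each = d[1L] * d[2L]), d))
      },
      fc = {
        v <- acts[[inName]]
        shaped <- !is.null(dim(v))
        if (shaped) v <- flattenRowMajor(v)
        if (needParams)
          dParams[[node$name]] <- list(W = outer(v, as.numeric(g)),
                                       b = as.numeric(g))
        din <- as.numeric(node$W %*% g)
        addGrad(inName, if (shaped) flatToShape(din, dim(acts[[inName]]))
                        else din)
      },
      softmax = {
        p <- acts[[node$name]]
        addGrad(inName, p * (g - sum(g * p)))
      },
      add = {
        addGrad(node$inputs[1L], g)
        addGrad(node$inputs[2L], g)
      },
      concat = {
        off <- 0L
        for (j in seq_along(node$inputs)) {
          cj <- node$channels[j]
          addGrad(node$inputs[j], g[, , off + seq_len(cj), drop = FALSE])
          off <- off + cj
        }
      })
  }
  list(dActs = dA, dParams = dParams)
}

# In-place-ish parameter update (returns new graph). upd: named list per node
# of parameter deltas to ADD.
graphApplyDeltas <- function(graph, deltas) {
  for (nm in names(deltas)) {
    for (node_i in seq_along(graph)) {
      if (graph[[node_i]]$name == nm) {
        for (p in names(deltas[[nm]]))
          graph[[node_i]][[p]] <- graph[[node_i]][[p]] + deltas[[nm]][[p]]
        break
      }
    }
  }
  graph
}

graphNode <- function(graph, name) {
  for (node in graph) if (node$name == name) return(node)
  stopf("no node named '%s'", name)
}

graphTrainableNodes <- function(graph)
  vapply(graph, function(n) n$name, character(1L))[
    vapply(graph, function(n) n$type %in% c("conv", "fc", "bn"), logical(1L))]
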