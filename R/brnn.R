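#' Parameters of one bidirectional recurrent stage
#'
#' A stage is three two-layered feed-forward subnets sharing the per-residue
#' input: a forward-transition net producing the N-terminal hidden chain, a
#' backward-transition net producing the C-terminal chain, and an output net
#' mapping (input, forward state, backward state) to class probabilities.
#' Each transition net sees the current input plus the `span` previous (or
#' following) hidden states; states beyond the sequence ends are zero.
#' Hidden layers use the hyperbolic tangent; the output is a softmax.
#' Weights are initialised uniformly in +/- 1/sqrt(fan-in) from the current
#' RNG state.
#'
#' @param d input width per residue.
#' @param m number of output classes (default 2: ordered/disordered).
#' @param state_width width of the hidden-state chains (default 11).
#' @param hidden_width width of each subnet's hidden layer (default 11).
#' @param span shortcut span S: number of prior/following states fed to the
#'   transition nets (default 2).
#' @return an object of class `brnn_stage`.
#' @export
brnn_stage <- function(d, m = 2L, state_width = 11L, hidden_width = 11L,
                       span = 2L) {
  stopifnot(d >= 1L, m >= 2L, state_width >= 1L, hidden_width >= 1L,
            span >= 1L)
  H <- as.integer(state_width); K <- as.integer(hidden_width)
  S <- as.integer(span); d <- as.integer(d); m <- as.integer(m)
  init <- function(nr, nc) {
    lim <- 1 / sqrt(nc)
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  st <- list(
    WF1 = init(K, d + S * H), bF1 = numeric(K),
    WF2 = init(H, K),         bF2 = numeric(H),
    WB1 = init(K, d + S * H), bB1 = numeric(K),
    WB2 = init(H, K),         bB2 = numeric(H),
    WO1 = init(K, d + 2L * H), bO1 = numeric(K),
    WO2 = init(m, K),         bO2 = numeric(m),
    d = d, m = m, state_width = H, hidden_width = K, span = S)
  structure(st, class = "brnn_stage")
}

#' Geometry of the second-stage filter
#'
#' The filter network's input at position j is the first-stage output at j
#' followed by `2p + 1` averages of first-stage outputs over contiguous
#' windows of width `2w + 1` anchored at `k_f = j + f(2w + 1)` for
#' `f = -p..p`, so the filter sees roughly `(2p + 1)(2w + 1)` residues of
#' semi-global context.  Total filter-input width: `m * (2p + 2)`.
#'
#' @param w half-window (default 7, i.e. 15-residue windows).
#' @param p half-count of windows (default 10, i.e. 21 windows spanning 315
#'   residues).
#' @param m number of classes (default 2).
#' @return an object of class `filter_geometry`.
#' @export
filter_geometry <- function(w = 7L, p = 10L, m = 2L) {
  stopifnot(w >= 0L, p >= 0L, m >= 2L)
  structure(list(w = as.integer(w), p = as.integer(p), m = as.integer(m)),
            class = "filter_geometry")
}

#' Filter-input width implied by a geometry
#' @param geometry a [filter_geometry()].
#' @return integer `m * (2p + 2)`.
#' @export
filter_width <- function(geometry) {
  geometry$m * (2L * geometry$p + 2L)
}

#' Two-stage bidirectional recurrent model
#'
#' Stage 1 maps the per-residue input encoding to class probabilities;
#' stage 2 (the filter network, itself a bidirectional recurrent stage)
#' refines them from window-averaged stage-1 outputs.
#'
#' @param d per-residue input width (21/28/24/31 depending on the variant).
#' @param geometry a [filter_geometry()].
#' @param state_width,hidden_width,span stage sizes, shared by both stages;
#'   see [brnn_stage()].
#' @return an object of class `two_stage_model`.
#' @export
two_stage_model <- function(d, geometry = filter_geometry(),
                            state_width = 11L, hidden_width = 11L,
                            span = 2L) {
  m <- geometry$m
  structure(list(
    stage1 = brnn_stage(d, m, state_width, hidden_width, span),
    stage2 = brnn_stage(filter_width(geometry), m, state_width,
                        hidden_width, span),
    geometry = geometry), class = "two_stage_model")
}

#' Forward pass of a single recurrent stage
#'
#' @param stage a [brnn_stage()].
#' @param inputs N x d numeric matrix of per-residue encodings.
#' @return N x m matrix of class probabilities; rows sum to 1.
#' @export
stage_forward <- function(stage, inputs) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != stage$d)
    stop("input width ", ncol(inputs), " != stage width ", stage$d)
  cpp_stage_forward(unclass(stage), inputs)
}

#' Second-stage filter inputs from first-stage outputs
#'
#' @param stage1_out N x m matrix of first-stage probabilities.
#' @param geometry a [filter_geometry()].
#' @return N x (m(2p+2)) matrix: per position, the stage-1 values followed
#'   by the 2p+1 window averages (windows anchored from f = -p to +p).
#'   Positions outside the chain are excluded from each average's divisor.
#' @export
build_filter_inputs <- function(stage1_out, geometry) {
  stage1_out <- as.matrix(stage1_out)
  if (ncol(stage1_out) != geometry$m)
    stop("stage-1 output width != geometry class count m")
  cpp_filter_inputs(stage1_out, geometry$w, geometry$p)
}

#' Forward pass of the full two-stage model
#'
#' @param model a [two_stage_model()].
#' @param inputs N x d input matrix.
#' @param both also return the stage-1 probabilities?
#' @return N x m matrix of final probabilities (rows sum to 1), or a list
#'   with elements `stage1` and `output` when `both = TRUE`.
#' @export
two_stage_predict <- function(model, inputs, both = FALSE) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != model$stage1$d)
    stop("input width ", ncol(inputs), " != model input width ",
         model$stage1$d)
  res <- cpp_two_stage_forward(unclass(model$stage1), unclass(model$stage2),
                               model$geometry$w, model$geometry$p, inputs)
  if (both) res else res$output
}

#' Joint two-stage loss and analytic gradient
#'
#' The training loss is the sum over residues of the cross-entropy at the
#' final output plus the cross-entropy at the stage-1 output (auxiliary
#' supervision); the gradient is exact backpropagation through structure,
#' including the path from stage 2 through the window filter into stage 1.
#'
#' @param model a [two_stage_model()].
#' @param inputs N x d input matrix.
#' @param labels binary string or 0/1 vector of length N.
#' @return list: `loss` (joint, summed over residues), `loss_final`, `n`,
#'   `grad1`/`grad2` (gradients shaped like the stage parameters), `output`
#'   and `stage1` probability matrices.
#' @export
two_stage_grad <- function(model, inputs, labels) {
  y <- label_vector(labels)
  inputs <- as.matrix(inputs)
  if (length(y) != nrow(inputs)) stop("label length != number of residues")
  cpp_two_stage_grad(unclass(model$stage1), unclass(model$stage2),
                     model$geometry$w, model$geometry$p, inputs, y)
}

#' @rdname two_stage_grad
#' @export
two_stage_loss <- function(model, inputs, labels) {
  y <- label_vector(labels)
  cpp_two_stage_loss(unclass(model$stage1), unclass(model$stage2),
                     model$geometry$w, model$geometry$p, as.matrix(inputs), y)
}

STAGE_PAR_NAMES <- c("WF1", "bF1", "WF2", "bF2", "WB1", "bB1", "WB2", "bB2",
                     "WO1", "bO1", "WO2", "bO2")

#' Flatten a two-stage model's parameters to a named numeric vector
#' @param model a [two_stage_model()].
#' @return named numeric vector (stage1 then stage2, each in fixed
#'   parameter order).
#' @export
flatten_params <- function(model) {
  unlist(lapply(c(stage1 = "stage1", stage2 = "stage2"), function(sn) {
    st <- model[[sn]]
    unlist(lapply(STAGE_PAR_NAMES, function(pn) {
      v <- as.numeric(st[[pn]])
      names(v) <- paste0(sn, ".", pn, ".", seq_along(v))
      v
    }))
  }), use.names = TRUE)
}

#' Rebuild a two-stage model from a flat parameter vector
#' @param model template [two_stage_model()] providing the shapes.
#' @param theta numeric vector as produced by [flatten_params()].
#' @return a [two_stage_model()] with the new parameters.
#' @export
unflatten_params <- function(model, theta) {
  pos <- 0L
  for (sn in c("stage1", "stage2")) {
    for (pn in STAGE_PAR_NAMES) {
      cur <- model[[sn]][[pn]]
      k <- length(cur)
      val <- theta[(pos + 1L):(pos + k)]
      model[[sn]][[pn]] <- if (is.matrix(cur))
        matrix(val, nrow(cur), ncol(cur)) else as.numeric(val)
      pos <- pos + k
    }
  }
  stopifnot(pos == length(theta))
  model
}

# elementwise in-place-style update: model parameters += factor * grads
#' @noRd
apply_update <- function(model, grads, factor) {
  for (sn in c("stage1", "stage2")) {
    g <- grads[[if (sn == "stage1") "grad1" else "grad2"]]
    for (pn in STAGE_PAR_NAMES)
      model[[sn]][[pn]] <- model[[sn]][[pn]] + factor * g[[pn]]
  }
  model
}

#' @noRd
accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g[c("grad1", "grad2")])
  for (gn in c("grad1", "grad2"))
    for (pn in STAGE_PAR_NAMES)
      acc[[gn]][[pn]] <- acc[[gn]][[pn]] + g[[gn]][[pn]]
  acc
}

#' Feed-forward baseline network
#'
#' A standard single-hidden-layer network over a fixed sliding window of
#' per-residue encodings (zero-padded at the termini), the conventional
#' baseline for recurrent sequence labellers.  Default geometry: window of
#' 21 residues, 20 hidden units.
#'
#' @param d per-residue input width.
#' @param window odd window length in residues (default 21).
#' @param hidden hidden units (default 20).
#' @param m classes (default 2).
#' @return an object of class `nn_baseline`.
#' @export
nn_baseline <- function(d, window = 21L, hidden = 20L, m = 2L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  fanin <- window * d
  lim1 <- 1 / sqrt(fanin); lim2 <- 1 / sqrt(hidden)
  structure(list(
    W1 = matrix(runif(hidden * fanin, -lim1, lim1), hidden, fanin),
    b1 = numeric(hidden),
    W2 = matrix(runif(m * hidden, -lim2, lim2), m, hidden),
    b2 = numeric(m),
    d = as.integer(d), window = window, hidden = as.integer(hidden),
    m = as.integer(m)), class = "nn_baseline")
}

#' Forward pass of the feed-forward baseline
#'
#' @param nn an [nn_baseline()].
#' @param inputs N x d input matrix.
#' @return N x m matrix of class probabilities.
#' @export
nn_baseline_forward <- function(nn, inputs) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != nn$d)
    stop("input width ", ncol(inputs), " != network input width ", nn$d)
  n <- nrow(inputs)
  hw <- (nn$window - 1L) %/% 2L
  pad <- rbind(matrix(0, hw, nn$d), inputs, matrix(0, hw, nn$d))
  Xw <- do.call(cbind, lapply(0:(nn$window - 1L), function(o)
    pad[(1L + o):(n + o), , drop = FALSE]))
  Hh <- tanh(sweep(Xw %*% t(nn$W1), 2L, nn$b1, `+`))
  logits <- sweep(Hh %*% t(nn$W2), 2L, nn$b2, `+`)
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}
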