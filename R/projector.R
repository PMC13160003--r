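#' Projection head configuration
#'
#' Describes the multilayer perceptron that maps fixed base embeddings (e.g.
#' frozen protein-language-model features of dimension `input_dim`) to the
#' `output_dim`-dimensional representation space used for contrastive training
#' and nearest-neighbour transfer. The head's output is always
#' \eqn{\ell_2}-normalized, so representations live on the unit sphere and
#' inner products are cosine similarities.
#'
#' The default architecture is two hidden layers of width
#' `max(output_dim, input_dim / 2)` with a smooth `tanh` nonlinearity; depth,
#' widths and nonlinearity are configurable and not claimed to be canonical.
#'
#' @param input_dim Base embedding dimension `d` (>= 1).
#' @param output_dim Projection dimension `D` (>= 2), default 128.
#' @param hidden Integer vector of hidden layer widths; `integer(0)` gives a
#'   single affine layer. Default: two layers of `max(output_dim, input_dim/2)`.
#' @param nonlinearity `"tanh"` (default) or `"relu"`.
#' @param seed Integer seed for parameter initialization.
#' @return A list of class `projection_config`.
#' @export
projection_config <- function(input_dim, output_dim = 128L,
                              hidden = NULL, nonlinearity = c("tanh", "relu"),
                              seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  input_dim <- as.integer(input_dim)
  output_dim <- as.integer(output_dim)
  if (is.null(hidden)) {
    hidden <- rep(max(output_dim, ceiling(input_dim / 2)), 2L)
  }
  hidden <- as.integer(hidden)
  if (input_dim < 1L || output_dim < 2L || any(hidden < 1L)) {
    rlang::abort("Invalid dimensions: need input_dim >= 1, output_dim >= 2, hidden >= 1.")
  }
  structure(list(input_dim = input_dim, output_dim = output_dim,
                 hidden = hidden, nonlinearity = nonlinearity,
                 seed = as.integer(seed)),
            class = "projection_config")
}

#' Initialize a projection head
#'
#' Draws weights from a seeded Glorot-scaled normal distribution; the same
#' configuration and seed always yield identical parameters.
#'
#' @param config A [projection_config()].
#' @return A list of class `projector` with elements `config` and `layers`
#'   (each layer a list with weight matrix `W` (in x out) and bias `b`).
#' @export
init_projector <- function(config) {
  stopifnot(inherits(config, "projection_config"))
  dims <- c(config$input_dim, config$hidden, config$output_dim)
  layers <- withr::with_seed(config$seed, {
    purrr::map(seq_len(length(dims) - 1L), function(i) {
      n_in <- dims[i]; n_out <- dims[i + 1L]
      sd <- sqrt(2 / (n_in + n_out))
      list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
           b = numeric(n_out))
    })
  })
  structure(list(config = config, layers = layers), class = "projector")
}

#' @export
print.projector <- function(x, ...) {
  dims <- c(x$config$input_dim, x$config$hidden, x$config$output_dim)
  cat("MLP projection head:", paste(dims, collapse = " -> "),
      sprintf("(%s), l2-normalized output\n", x$config$nonlinearity))
  invisible(x)
}

act_fun <- function(a, kind) {
  switch(kind, tanh = tanh(a), relu = pmax(a, 0))
}
act_grad <- function(a, t, kind) {
  # derivative in terms of pre-activation a and activation t
  switch(kind, tanh = 1 - t^2, relu = (a > 0) + 0)
}

# Forward pass keeping intermediates for backprop.
# x: n x d matrix. Returns list(z, y, norms, pre, post).
projector_forward <- function(projector, x) {
  kind <- projector$config$nonlinearity
  L <- length(projector$layers)
  pre <- vector("list", L)
  post <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    a <- h %*% projector$layers[[i]]$W
    a <- sweep(a, 2L, projector$layers[[i]]$b, "+")
    pre[[i]] <- a
    h <- if (i < L) act_fun(a, kind) else a
    post[[i]] <- h
  }
  y <- h
  norms <- sqrt(rowSums(y^2))
  if (any(norms < 1e-12)) {
    rlang::abort("Degenerate embedding: pre-normalization projector output has (near-)zero norm.")
  }
  z <- y / norms
  list(z = z, y = y, norms = norms, pre = pre, post = post, input = x)
}

#' Project base embeddings onto the unit sphere
#'
#' Applies the MLP head and \eqn{\ell_2}-normalizes each output row, yielding
#' unit vectors in the representation space. A single vector may be given in
#' place of a one-row matrix.
#'
#' @param projector A `projector` (see [init_projector()]).
#' @param x Numeric matrix (rows = embeddings, `input_dim` columns) or a
#'   single vector of length `input_dim`. Rownames are preserved.
#' @return A numeric matrix of unit rows with `output_dim` columns.
#' @export
project <- function(projector, x) {
  stopifnot(inherits(projector, "projector"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != projector$config$input_dim) {
    rlang::abort(sprintf("Input has %d columns; projector expects %d.",
                         ncol(x), projector$config$input_dim))
  }
  z <- projector_forward(projector, x)$z
  rownames(z) <- rownames(x)
  z
}

# Backpropagate dL/dz through normalization and the MLP.
# fwd: output of projector_forward; dz: n x D gradient wrt z.
# Returns list(param = list per layer (dW, db), input = n x d gradient wrt x).
projector_backward <- function(projector, fwd, dz) {
  kind <- projector$config$nonlinearity
  L <- length(projector$layers)
  # through z = y / ||y||: dy = (dz - (z . dz) z) / ||y||
  zdot <- rowSums(fwd$z * dz)
  dy <- (dz - fwd$z * zdot) / fwd$norms
  grads <- vector("list", L)
  d <- dy
  for (i in rev(seq_len(L))) {
    inp <- if (i == 1L) fwd$input else fwd$post[[i - 1L]]
    grads[[i]] <- list(dW = crossprod(inp, d), db = colSums(d))
    d <- d %*% t(projector$layers[[i]]$W)
    if (i > 1L) d <- d * act_grad(fwd$pre[[i - 1L]], fwd$post[[i - 1L]], kind)
  }
  list(param = grads, input = d)
}

#' Save a projection head to a self-describing text file
#'
#' Serializes the configuration and all parameters as JSON with doubles
#' written at 17 significant digits, which round-trips IEEE doubles exactly:
#' [read_projector()] restores bit-identical behaviour.
#'
#' @param projector A `projector`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_projector <- function(projector, path) {
  stopifnot(inherits(projector, "projector"))
  fmt <- function(x) sprintf("%.17g", x)
  payload <- list(
    format = "ecembed-projector-1",
    config = unclass(projector$config),
    layers = purrr::map(projector$layers, function(l) {
      list(dim = dim(l$W), W = fmt(as.numeric(l$W)), b = fmt(l$b))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a projection head saved by [write_projector()]
#'
#' @param path File path.
#' @return A `projector` with bit-identical parameters.
#' @export
read_projector <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "ecembed-projector-1")) {
    rlang::abort("Not an ecembed projector file.")
  }
  cfg <- projection_config(
    input_dim = payload$config$input_dim,
    output_dim = payload$config$output_dim,
    hidden = payload$config$hidden,
    nonlinearity = payload$config$nonlinearity,
    seed = payload$config$seed
  )
  layers <- if (is.data.frame(payload$layers)) {
    # jsonlite may simplify a list of homogeneous records; re-split by row
    purrr::map(seq_len(nrow(payload$layers)), function(i) as.list(payload$layers[i, ]))
  } else payload$layers
  layers <- purrr::map(layers, function(l) {
    dm <- unlist(l$dim)
    list(W = matrix(as.numeric(unlist(l$W)), dm[1L], dm[2L]),
         b = as.numeric(unlist(l$b)))
  })
  structure(list(config = cfg, layers = layers), class = "projector")
}
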