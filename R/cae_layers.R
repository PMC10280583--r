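# Internal layer primitives for the 1D convolutional autoencoder.
#
# A sample flows through the network as an (length x channels) matrix; dense
# stages use 1 x n matrices. Convolutions are stride-1 with "same" zero
# padding; pooling is non-overlapping max pooling of size 2; upsampling is
# nearest-neighbour repetition by 2. A transposed convolution with stride 1
# and same padding is an ordinary convolution with a reparameterised kernel,
# so decoder layers reuse the conv primitive.

act_fun <- function(z, act) if (act == "tanh") tanh(z) else z
act_grad <- function(a, act) if (act == "tanh") 1 - a^2 else 1

# im2col for same-padded stride-1 conv: (L x cin) -> (L x k*cin),
# column block t holds the input shifted by tap t.
im2col <- function(x, k) {
  L <- nrow(x); cin <- ncol(x); h <- (k - 1L) %/% 2L
  xp <- rbind(matrix(0, h, cin), x, matrix(0, h, cin))
  cols <- matrix(0, L, k * cin)
  for (t in seq_len(k))
    cols[, ((t - 1L) * cin + 1L):(t * cin)] <- xp[t:(t + L - 1L), , drop = FALSE]
  cols
}

col2im <- function(dcols, k, L, cin) {
  h <- (k - 1L) %/% 2L
  dxp <- matrix(0, L + 2L * h, cin)
  for (t in seq_len(k))
    dxp[t:(t + L - 1L), ] <- dxp[t:(t + L - 1L), ] +
      dcols[, ((t - 1L) * cin + 1L):(t * cin), drop = FALSE]
  dxp[(h + 1L):(h + L), , drop = FALSE]
}

layer_conv <- function(k, cin, cout, act) {
  list(type = "conv", k = k, cin = cin, cout = cout, act = act,
       W = matrix(0, k * cin, cout), b = numeric(cout))
}
layer_dense <- function(nin, nout, act) {
  list(type = "dense", nin = nin, nout = nout, act = act,
       W = matrix(0, nin, nout), b = numeric(nout))
}
layer_pool <- function() list(type = "pool", size = 2L)
layer_upsample <- function() list(type = "upsample", size = 2L)
layer_flatten <- function(L, C) list(type = "flatten", L = L, C = C)
layer_reshape <- function(L, C) list(type = "reshape", L = L, C = C)

# Glorot-uniform init; conv fans use k * channels.
init_layer <- function(layer) {
  if (layer$type == "conv") {
    lim <- sqrt(6 / (layer$k * layer$cin + layer$k * layer$cout))
    layer$W[] <- stats::runif(length(layer$W), -lim, lim)
  } else if (layer$type == "dense") {
    lim <- sqrt(6 / (layer$nin + layer$nout))
    layer$W[] <- stats::runif(length(layer$W), -lim, lim)
  }
  layer
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      xcol <- im2col(x, layer$k)
      a <- act_fun(xcol %*% layer$W +
                     matrix(layer$b, nrow(x), layer$cout, byrow = TRUE),
                   layer$act)
      list(out = a, cache = list(xcol = xcol, a = a, L = nrow(x)))
    },
    dense = {
      a <- act_fun(x %*% layer$W +
                     matrix(layer$b, nrow(x), layer$nout, byrow = TRUE),
                   layer$act)
      list(out = a, cache = list(x = x, a = a))
    },
    pool = {
      L <- nrow(x)
      odd <- x[seq(1L, L, 2L), , drop = FALSE]
      even <- x[seq(2L, L, 2L), , drop = FALSE]
      first <- odd >= even               # ties routed to the first element
      list(out = pmax(odd, even), cache = list(first = first))
    },
    upsample = {
      L <- nrow(x)
      out <- x[rep(seq_len(L), each = 2L), , drop = FALSE]
      list(out = out, cache = NULL)
    },
    flatten = list(out = matrix(as.vector(x), 1L), cache = NULL),
    reshape = list(out = matrix(as.vector(x), layer$L, layer$C),
                   cache = NULL))
}

# returns list(dx, dW = , db = ) (dW/db NULL for parameterless layers)
layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      dz <- dout * act_grad(cache$a, layer$act)
      list(dx = col2im(dz %*% t(layer$W), layer$k, cache$L, layer$cin),
           dW = crossprod(cache$xcol, dz), db = colSums(dz))
    },
    dense = {
      dz <- dout * act_grad(cache$a, layer$act)
      list(dx = dz %*% t(layer$W),
           dW = crossprod(cache$x, dz), db = colSums(dz))
    },
    pool = {
      L2 <- nrow(dout)
      dx <- matrix(0, 2L * L2, ncol(dout))
      dx[seq(1L, 2L * L2, 2L), ] <- dout * cache$first
      dx[seq(2L, 2L * L2, 2L), ] <- dout * !cache$first
      list(dx = dx, dW = NULL, db = NULL)
    },
    upsample = {
      L2 <- nrow(dout)
      list(dx = dout[seq(1L, L2, 2L), , drop = FALSE] +
             dout[seq(2L, L2, 2L), , drop = FALSE],
           dW = NULL, db = NULL)
    },
    flatten = list(dx = matrix(as.vector(dout), layer$L, layer$C),
                   dW = NULL, db = NULL),
    reshape = list(dx = matrix(as.vector(dout), 1L),
                   dW = NULL, db = NULL))
}
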