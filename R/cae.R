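#' Configuration of the 1D convolutional autoencoder
#'
#' Defaults reproduce the benchmark architecture for 700-channel spectra:
#' encoder Conv1D(16, k=5, same, tanh) - MaxPool(2) - Conv1D(32, k=5, same,
#' tanh) - MaxPool(2) - Flatten - Dense(64, tanh) - Dense(latent, tanh);
#' decoder Dense(flatten, tanh) - Reshape - ConvT(32, k=3, same, tanh) -
#' Upsample(2) - ConvT(16, k=3, same, tanh) - Upsample(2) - ConvT(1, k=3,
#' same, linear). Training uses Adam (lr 0.001, beta1 0.9, beta2 0.999,
#' eps 1e-8) on the mean squared reconstruction error for at most 20 epochs,
#' stopping early when the validation loss rises on two consecutive epochs.
#'
#' @param input_length number of spectral channels; must be divisible by
#'   `pool_size^2` (700 pools to 350 then 175).
#' @param kernel_size odd encoder convolution kernel length.
#' @param decoder_kernel_size odd decoder convolution kernel length.
#' @param latent_dim bottleneck width (number of latent variables).
#' @param encoder_filters filter counts of the two encoder convolutions.
#' @param dense_hidden width of the intermediate encoder dense layer.
#' @param pool_size max-pooling width (non-overlapping).
#' @param batch_size minibatch size for Adam.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param max_epochs training epoch cap.
#' @param patience consecutive validation-loss rises that trigger early stop.
#' @param validation_fraction fraction of the calibration spectra held out
#'   (seeded) to track validation loss.
#' @param seed integer seed for weight initialisation.
#' @return object of class `cae_config`.
#' @export
cae_config <- function(input_length = 700L, kernel_size = 5L,
                       decoder_kernel_size = 3L, latent_dim = 32L,
                       encoder_filters = c(16L, 32L), dense_hidden = 64L,
                       pool_size = 2L, batch_size = 16L,
                       learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, max_epochs = 20L, patience = 2L,
                       validation_fraction = 0.2, seed = 1L) {
  cfg <- list(input_length = as.integer(input_length),
              kernel_size = as.integer(kernel_size),
              decoder_kernel_size = as.integer(decoder_kernel_size),
              latent_dim = as.integer(latent_dim),
              encoder_filters = as.integer(encoder_filters),
              dense_hidden = as.integer(dense_hidden),
              pool_size = as.integer(pool_size),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
              epsilon = epsilon, max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  if (cfg$input_length %% cfg$pool_size^2 != 0)
    stop("input_length must be divisible by pool_size^2 (",
         cfg$pool_size^2, ")")
  if (cfg$kernel_size %% 2 == 0 || cfg$decoder_kernel_size %% 2 == 0)
    stop("kernel sizes must be odd")
  if (cfg$latent_dim < 1 || cfg$max_epochs < 1)
    stop("latent_dim and max_epochs must be >= 1")
  if (length(cfg$encoder_filters) != 2)
    stop("encoder_filters must give exactly two filter counts")
  structure(cfg, class = "cae_config")
}

#' Build an untrained convolutional autoencoder
#'
#' Assembles the encoder/decoder layer chain for `config` and initialises
#' all weights from a seeded Glorot-uniform generator (biases start at 0).
#'
#' @param config a [cae_config()].
#' @return object of class `cae_model` with fields `config`, `layers`,
#'   `n_encoder_layers`, `scaling` (NULL until trained), `trained`,
#'   `training_log`.
#' @examples
#' m <- build_cae(cae_config())
#' sum(count_parameters(m)$n_parameters)  # 550737
#' @export
build_cae <- function(config = cae_config()) {
  stopifnot(inherits(config, "cae_config"))
  L <- config$input_length
  f <- config$encoder_filters
  L2 <- L %/% config$pool_size
  L4 <- L2 %/% config$pool_size
  flat <- L4 * f[2]
  enc <- list(layer_conv(config$kernel_size, 1L, f[1], "tanh"),
              layer_pool(),
              layer_conv(config$kernel_size, f[1], f[2], "tanh"),
              layer_pool(),
              layer_flatten(L4, f[2]),
              layer_dense(flat, config$dense_hidden, "tanh"),
              layer_dense(config$dense_hidden, config$latent_dim, "tanh"))
  dec <- list(layer_dense(config$latent_dim, flat, "tanh"),
              layer_reshape(L4, f[2]),
              layer_conv(config$decoder_kernel_size, f[2], f[2], "tanh"),
              layer_upsample(),
              layer_conv(config$decoder_kernel_size, f[2], f[1], "tanh"),
              layer_upsample(),
              layer_conv(config$decoder_kernel_size, f[1], 1L, "linear"))
  layers <- withr::with_seed(config$seed, lapply(c(enc, dec), init_layer))
  structure(list(config = config, layers = layers,
                 n_encoder_layers = length(enc), scaling = NULL,
                 trained = FALSE, training_log = NULL),
            class = "cae_model")
}

#' @export
print.cae_model <- function(x, ...) {
  cat("<cae_model> input ", x$config$input_length, " -> latent ",
      x$config$latent_dim,
      if (x$trained) " [trained]" else " [untrained]", "\n", sep = "")
  invisible(x)
}

#' Per-layer trainable parameter counts
#'
#' Tabulates, for every encoder and decoder stage, its type, output shape
#' and number of trainable parameters (conv: `filters * kernel * in_channels
#' + filters`; dense: `in * out + out`; pooling, upsampling, flatten and
#' reshape contribute 0).
#'
#' @param model a [build_cae()] result.
#' @return `data.frame` with columns `submodel`, `stage`, `type`,
#'   `output_shape`, `n_parameters`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cae_model"))
  cfg <- model$config
  shape <- function(L, C) if (is.na(C)) sprintf("(%d)", L)
                          else sprintf("(%d, %d)", L, C)
  rows <- list()
  add <- function(sub, type, out, n)
    rows[[length(rows) + 1L]] <<- data.frame(submodel = sub, type = type,
                                             output_shape = out,
                                             n_parameters = n)
  L <- cfg$input_length
  add("encoder", "Input", shape(L, 1L), 0L)
  cur_len <- L
  for (ly in model$layers[seq_len(model$n_encoder_layers)]) {
    if (ly$type == "conv") {
      add("encoder", "Conv1D", shape(cur_len, ly$cout),
          length(ly$W) + length(ly$b))
    } else if (ly$type == "pool") {
      cur_len <- cur_len %/% ly$size
      add("encoder", "MaxPooling", shape(cur_len, cfg$encoder_filters[
        sum(vapply(rows, function(r) r$type == "Conv1D", logical(1)))]), 0L)
    } else if (ly$type == "flatten") {
      add("encoder", "Flatten", shape(ly$L * ly$C, NA), 0L)
    } else if (ly$type == "dense") {
      add("encoder", "Dense", shape(ly$nout, NA), length(ly$W) + length(ly$b))
    }
  }
  dec <- model$layers[-seq_len(model$n_encoder_layers)]
  add("decoder", "Input", shape(cfg$latent_dim, NA), 0L)
  cur_len <- cfg$input_length %/% cfg$pool_size^2
  for (ly in dec) {
    if (ly$type == "dense") {
      add("decoder", "Dense", shape(ly$nout, NA), length(ly$W) + length(ly$b))
    } else if (ly$type == "reshape") {
      add("decoder", "Reshape", shape(ly$L, ly$C), 0L)
    } else if (ly$type == "conv") {
      add("decoder", "Conv1D_Transpose", shape(cur_len, ly$cout),
          length(ly$W) + length(ly$b))
    } else if (ly$type == "upsample") {
      cur_len <- cur_len * ly$size
      prev <- rows[[length(rows)]]
      ch <- as.integer(sub(".*, (\\d+)\\)", "\\1", prev$output_shape))
      add("decoder", "Upsampling", shape(cur_len, ch), 0L)
    }
  }
  out <- do.call(rbind, rows)
  out$stage <- stats::ave(seq_len(nrow(out)), out$submodel, FUN = seq_along)
  out[c("submodel", "stage", "type", "output_shape", "n_parameters")]
}

# ---- forward / gradient machinery -----------------------------------------

# full forward pass on one scaled spectrum (length-L vector);
# returns list(out = L x 1 matrix, caches, latent)
cae_forward <- function(model, x, n_layers = length(model$layers)) {
  cur <- matrix(x, ncol = 1L)
  caches <- vector("list", n_layers)
  latent <- NULL
  for (i in seq_len(n_layers)) {
    step <- layer_forward(model$layers[[i]], cur)
    caches[[i]] <- step$cache
    cur <- step$out
    if (i == model$n_encoder_layers) latent <- as.numeric(cur)
  }
  list(out = cur, caches = caches, latent = latent)
}

# mean squared reconstruction loss and parameter gradients over a batch
# of scaled spectra (rows of X); gradients are averaged over the batch.
cae_loss_grad <- function(model, X) {
  n <- nrow(X)
  L <- ncol(X)
  nl <- length(model$layers)
  gW <- lapply(model$layers, function(ly)
    if (!is.null(ly$W)) ly$W * 0 else NULL)
  gb <- lapply(model$layers, function(ly)
    if (!is.null(ly$b)) ly$b * 0 else NULL)
  loss <- 0
  for (s in seq_len(n)) {
    fwd <- cae_forward(model, X[s, ])
    resid <- as.numeric(fwd$out) - X[s, ]
    loss <- loss + mean(resid^2)
    dcur <- matrix(2 * resid / (L * n), ncol = 1L)
    for (i in rev(seq_len(nl))) {
      bk <- layer_backward(model$layers[[i]], dcur, fwd$caches[[i]])
      if (!is.null(bk$dW)) {
        gW[[i]] <- gW[[i]] + bk$dW
        gb[[i]] <- gb[[i]] + bk$db
      }
      dcur <- bk$dx
    }
  }
  list(loss = loss / n, gW = gW, gb = gb)
}

cae_batch_loss <- function(model, X) {
  mean(vapply(seq_len(nrow(X)), function(s) {
    out <- as.numeric(cae_forward(model, X[s, ])$out)
    mean((out - X[s, ])^2)
  }, numeric(1)))
}

# flat parameter vector accessors (used by the finite-difference oracle)
cae_get_params <- function(model) {
  unlist(lapply(model$layers, function(ly) c(ly$W, ly$b)))
}
cae_set_params <- function(model, theta) {
  pos <- 0L
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (!is.null(ly$W)) {
      nw <- length(ly$W)
      model$layers[[i]]$W[] <- theta[(pos + 1L):(pos + nw)]
      pos <- pos + nw
      nb <- length(ly$b)
      model$layers[[i]]$b[] <- theta[(pos + 1L):(pos + nb)]
      pos <- pos + nb
    }
  }
  stopifnot(pos == length(theta))
  model
}

# ---- input scaling ---------------------------------------------------------

# per-channel min-max scaling of calibration spectra to [-1, 1]
# (tanh-compatible); degenerate channels (zero range) map to 0.
fit_scaling <- function(X) {
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  center <- (mn + mx) / 2
  half <- (mx - mn) / 2
  half[half < 1e-12] <- 1
  list(center = center, half = half)
}
scale_spectra <- function(scaling, X)
  sweep(sweep(X, 2, scaling$center), 2, scaling$half, "/")
unscale_spectra <- function(scaling, X)
  sweep(sweep(X, 2, scaling$half, "*"), 2, scaling$center, "+")

# ---- training --------------------------------------------------------------

# number of consecutive validation-loss rises at the end of the sequence;
# training stops once this reaches `patience`, and the weights of the
# best-validation epoch are restored (e.g. losses 5,4,3,4,5 stop after the
# second rise with epoch 3 restored).
n_trailing_rises <- function(v) {
  r <- 0L
  i <- length(v)
  while (i >= 2L && v[i] > v[i - 1L]) {
    r <- r + 1L
    i <- i - 1L
  }
  r
}

#' Train the autoencoder on calibration spectra
#'
#' Unsupervised: only the absorbance matrix is seen, never reference values.
#' Spectra are min-max scaled to [-1, 1] per channel (scaling fitted on the
#' calibration set and stored with the model), a seeded fraction of the
#' calibration samples is held out to track validation loss, and the
#' remaining samples are optimised with minibatch Adam on the mean squared
#' reconstruction error. Training stops at `max_epochs` or as soon as the
#' validation loss has risen on `patience` consecutive epochs; the weights
#' with the best validation loss are restored either way. Fully reproducible
#' for a fixed seed.
#'
#' @param model an untrained (or trained) [build_cae()] model.
#' @param calibration a [spectra_set] or numeric matrix of calibration
#'   spectra (rows), channel count matching `config$input_length`.
#' @param seed integer seed driving the validation split, shuffling and any
#'   other randomness of this call.
#' @return the trained `cae_model`; its `training_log` is a `data.frame`
#'   (`epoch`, `train_loss`, `val_loss`) with attribute `stopped_early`.
#' @export
train_cae <- function(model, calibration, seed = 1L) {
  stopifnot(inherits(model, "cae_model"))
  X <- if (inherits(calibration, "spectra_set")) calibration$absorbance
       else as.matrix(calibration)
  cfg <- model$config
  if (ncol(X) != cfg$input_length)
    stop("calibration has ", ncol(X), " channels; model expects ",
         cfg$input_length)
  model$scaling <- fit_scaling(X)
  Xs <- scale_spectra(model$scaling, X)
  n <- nrow(Xs)
  withr::with_seed(as.integer(seed), {
    n_val <- max(1L, round(cfg$validation_fraction * n))
    if (n_val >= n) stop("too few samples for a validation holdout")
    val_idx <- sample(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)
    mW <- lapply(model$layers, function(ly) if (!is.null(ly$W)) ly$W * 0)
    vW <- mW
    mb <- lapply(model$layers, function(ly) if (!is.null(ly$b)) ly$b * 0)
    vb <- mb
    tstep <- 0L
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
    best_val <- Inf
    best_layers <- model$layers
    rises <- 0L
    stopped_early <- FALSE
    for (epoch in seq_len(cfg$max_epochs)) {
      order <- sample(train_idx)
      batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
      for (bt in batches) {
        g <- cae_loss_grad(model, Xs[bt, , drop = FALSE])
        if (!is.finite(g$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        tstep <- tstep + 1L
        c1 <- 1 - cfg$beta1^tstep
        c2 <- 1 - cfg$beta2^tstep
        for (i in seq_along(model$layers)) {
          if (is.null(g$gW[[i]])) next
          mW[[i]] <- cfg$beta1 * mW[[i]] + (1 - cfg$beta1) * g$gW[[i]]
          vW[[i]] <- cfg$beta2 * vW[[i]] + (1 - cfg$beta2) * g$gW[[i]]^2
          model$layers[[i]]$W <- model$layers[[i]]$W -
            cfg$learning_rate * (mW[[i]] / c1) /
            (sqrt(vW[[i]] / c2) + cfg$epsilon)
          mb[[i]] <- cfg$beta1 * mb[[i]] + (1 - cfg$beta1) * g$gb[[i]]
          vb[[i]] <- cfg$beta2 * vb[[i]] + (1 - cfg$beta2) * g$gb[[i]]^2
          model$layers[[i]]$b <- model$layers[[i]]$b -
            cfg$learning_rate * (mb[[i]] / c1) /
            (sqrt(vb[[i]] / c2) + cfg$epsilon)
        }
      }
      train_loss <- cae_batch_loss(model, Xs[train_idx, , drop = FALSE])
      val_loss <- cae_batch_loss(model, Xs[val_idx, , drop = FALSE])
      log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_layers <- model$layers
      }
      rises <- n_trailing_rises(log$val_loss)
      if (rises >= cfg$patience) {
        stopped_early <- TRUE
        break
      }
    }
    model$layers <- best_layers
    attr(log, "stopped_early") <- stopped_early
    model$training_log <- log
    model$trained <- TRUE
  })
  model
}

#' Encode spectra to latent variables
#'
#' @param model a trained `cae_model`.
#' @param spectra a [spectra_set] or numeric matrix of spectra in rows.
#' @return numeric matrix (samples x latent_dim); every entry lies strictly
#'   inside (-1, 1) because the bottleneck activation is tanh.
#' @export
encode <- function(model, spectra) {
  X <- check_trained_input(model, spectra)
  Xs <- scale_spectra(model$scaling, X)
  out <- t(vapply(seq_len(nrow(Xs)), function(s)
    cae_forward(model, Xs[s, ], n_layers = model$n_encoder_layers)$latent,
    numeric(model$config$latent_dim)))
  rownames(out) <- rownames(X)
  colnames(out) <- paste0("LV", seq_len(model$config$latent_dim))
  out
}

#' Reconstruct spectra through the full autoencoder
#'
#' @inheritParams encode
#' @return numeric matrix on the original absorbance scale, same shape as
#'   the input.
#' @export
reconstruct <- function(model, spectra) {
  X <- check_trained_input(model, spectra)
  Xs <- scale_spectra(model$scaling, X)
  rec <- t(vapply(seq_len(nrow(Xs)), function(s)
    as.numeric(cae_forward(model, Xs[s, ])$out),
    numeric(ncol(Xs))))
  out <- unscale_spectra(model$scaling, rec)
  dimnames(out) <- dimnames(X)
  out
}

check_trained_input <- function(model, spectra) {
  stopifnot(inherits(model, "cae_model"))
  if (!model$trained) stop("model is untrained; call train_cae() first")
  X <- if (inherits(spectra, "spectra_set")) {
    out <- spectra$absorbance
    rownames(out) <- spectra$sample_ids
    out
  } else as.matrix(spectra)
  if (ncol(X) != model$config$input_length)
    stop("channel count mismatch: ", ncol(X), " vs ",
         model$config$input_length)
  X
}

#' Random-search hyperparameter selection
#'
#' Samples configurations uniformly without replacement from the Cartesian
#' product of a lookup table (axes such as `kernel_size`, `latent_dim`,
#' `batch_size`), trains each candidate on the calibration spectra, and
#' ranks them by best validation loss, breaking ties by smaller latent
#' dimension and then smaller total parameter count.
#'
#' @param space named list of hyperparameter values, e.g.
#'   `list(kernel_size = c(3, 5, 7), latent_dim = c(2, 4, 8, 16, 32),
#'   batch_size = c(8, 16, 32))`.
#' @param calibration a [spectra_set] or matrix of calibration spectra.
#' @param n_trials number of configurations to try; must not exceed the
#'   number of unique configurations.
#' @param seed integer seed (drives sampling, weight init and training).
#' @param base_config `cae_config` supplying all fields not in `space`.
#' @return list with `best_config` (a `cae_config`), `best_model` (its
#'   trained model) and `trials` (a `data.frame` log, one row per trial).
#' @export
random_search <- function(space, calibration, n_trials, seed = 1L,
                          base_config = cae_config()) {
  stopifnot(length(space) >= 1, n_trials >= 1)
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  if (n_trials > nrow(grid))
    stop("n_trials (", n_trials, ") exceeds the ", nrow(grid),
         " unique configurations")
  picks <- withr::with_seed(as.integer(seed), sample(nrow(grid), n_trials))
  trials <- vector("list", n_trials)
  models <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    over <- as.list(grid[picks[i], , drop = FALSE])
    cfg <- do.call(cae_config,
                   utils::modifyList(unclass_config(base_config),
                                     c(over, list(seed = base_config$seed))))
    mod <- train_cae(build_cae(cfg), calibration, seed = seed)
    models[[i]] <- mod
    trials[[i]] <- data.frame(
      trial = i, over,
      val_loss = min(mod$training_log$val_loss),
      n_parameters = sum(count_parameters(mod)$n_parameters),
      epochs = nrow(mod$training_log))
  }
  trials <- do.call(rbind, trials)
  latent <- if ("latent_dim" %in% names(trials)) trials$latent_dim
            else rep(base_config$latent_dim, n_trials)
  rank <- order(trials$val_loss, latent, trials$n_parameters)
  best <- rank[1]
  list(best_config = models[[best]]$config, best_model = models[[best]],
       trials = trials)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out[names(out) != ""]
}

# ---- persistence -----------------------------------------------------------

#' Save / load a CAE model as a directory of portable text artifacts
#'
#' The directory holds `config.json`, `scaling.json`, one JSON array file
#' per layer's weights and biases, and `training_log.csv`.
#'
#' @param model a `cae_model`.
#' @param dir directory path (created if missing).
#' @return `load_cae` returns the restored `cae_model`.
#' @export
save_cae <- function(model, dir) {
  stopifnot(inherits(model, "cae_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass_config(model$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$scaling))
    jsonlite::write_json(model$scaling, file.path(dir, "scaling.json"),
                         digits = NA)
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (is.null(ly$W)) next
    jsonlite::write_json(list(W = ly$W, b = ly$b, dim = dim(ly$W)),
                         file.path(dir, sprintf("layer_%02d.json", i)),
                         digits = NA)
  }
  if (!is.null(model$training_log))
    utils::write.csv(model$training_log,
                     file.path(dir, "training_log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_cae
#' @export
load_cae <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfgl$encoder_filters <- as.integer(cfgl$encoder_filters)
  model <- build_cae(do.call(cae_config, cfgl))
  for (i in seq_along(model$layers)) {
    path <- file.path(dir, sprintf("layer_%02d.json", i))
    if (!file.exists(path)) next
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    W <- x$W
    stopifnot(identical(dim(W), as.integer(x$dim)))
    model$layers[[i]]$W <- W
    model$layers[[i]]$b <- as.numeric(x$b)
  }
  scaling_path <- file.path(dir, "scaling.json")
  if (file.exists(scaling_path)) {
    sc <- jsonlite::read_json(scaling_path, simplifyVector = TRUE)
    model$scaling <- list(center = as.numeric(sc$center),
                          half = as.numeric(sc$half))
    model$trained <- TRUE
  }
  log_path <- file.path(dir, "training_log.csv")
  if (file.exists(log_path))
    model$training_log <- utils::read.csv(log_path)
  model
}
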