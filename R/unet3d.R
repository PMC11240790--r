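#' Residual 3D U-Net configuration
#'
#' One architecture definition serves every cascade stage; the full-scale
#' variant uses four resolution levels with 32/64/128/256 filters, while
#' phantom-scale stages shrink depth and width. Each level is a residual
#' unit of two 3x3x3 convolutions with instance normalization and ReLU; the
#' encoder halves resolution per level (2x average pooling), the decoder
#' mirrors it with nearest-neighbour upsampling and skip concatenation. The
#' per-voxel head is sigmoid for single-label tasks and softmax across
#' channels for the multi-label duct model.
#'
#' @param in_channels input channels (1 for pancreas/duct stages; 4 for the
#'   tumor stage: CT + pancreas + common bile duct + pancreatic duct).
#' @param out_channels output channels (1 per binary task; 3 for the
#'   multi-label duct model including background).
#' @param depth number of resolution levels.
#' @param filters integer vector, one strictly increasing entry per level.
#' @param residual use residual units (identity/projection shortcuts).
#' @param head `"sigmoid"` or `"softmax"`.
#' @return A `pd_network_config`.
#' @export
network_config <- function(in_channels = 1, out_channels = 1, depth = 4,
                           filters = c(32, 64, 128, 256), residual = TRUE,
                           head = c("sigmoid", "softmax")) {
  head <- match.arg(head)
  if (length(filters) != depth) stop("filters must have one entry per level")
  if (depth > 1 && any(diff(filters) <= 0)) stop("filters must be strictly increasing")
  if (in_channels < 1 || out_channels < 1) stop("channel counts must be >= 1")
  if (head == "softmax" && out_channels < 2)
    stop("softmax head needs >= 2 output channels")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth), filters = as.integer(filters),
                 residual = isTRUE(residual), head = head),
            class = "pd_network_config")
}

he_init <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

block_params <- function(cin, cout, residual) {
  prm <- list(w1 = he_init(3, cin, cout), b1 = numeric(cout),
              g1 = rep(1, cout), n1 = numeric(cout),
              w2 = he_init(3, cout, cout), b2 = numeric(cout),
              g2 = rep(1, cout), n2 = numeric(cout))
  if (residual && cin != cout)
    prm <- c(prm, list(wp = he_init(1, cin, cout), bp = numeric(cout)))
  prm
}

#' Build a (deterministically initialized) segmentation model
#'
#' @param config a [network_config()].
#' @param seed integer; He-normal initialization is reproducible per seed.
#' @param stage,fold optional training metadata carried on the model.
#' @return A `pd_segmodel`.
#' @export
build_model <- function(config, seed = 1L, stage = NA_character_, fold = NA_integer_) {
  stopifnot(inherits(config, "pd_network_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  D <- config$depth; f <- config$filters
  prm <- list()
  cin <- config$in_channels
  for (l in seq_len(D)) {            # encoder (level D = bottleneck)
    prm[[paste0("enc", l)]] <- block_params(cin, f[l], config$residual)
    cin <- f[l]
  }
  if (D > 1) for (l in (D - 1):1)    # decoder
    prm[[paste0("dec", l)]] <- block_params(f[l + 1] + f[l], f[l], config$residual)
  prm$final <- list(w = he_init(1, f[1], config$out_channels),
                    b = numeric(config$out_channels))
  structure(list(config = config, params = prm,
                 training_meta = list(stage = stage, fold = fold, seed = seed)),
            class = "pd_segmodel")
}

#' Number of learnable parameters
#' @param model a `pd_segmodel`.
#' @export
n_parameters <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

# ---- forward / backward ----------------------------------------------------

block_fwd <- function(x, prm, residual, keep_cache = FALSE) {
  c1 <- nn_conv_fwd(x, prm$w1, prm$b1, want_cols = keep_cache)
  h1 <- if (keep_cache) c1$y else c1
  n1 <- nn_inorm_fwd(h1, prm$g1, prm$n1)
  r1 <- nn_relu_fwd(n1$y)
  c2 <- nn_conv_fwd(r1, prm$w2, prm$b2, want_cols = keep_cache)
  h2 <- if (keep_cache) c2$y else c2
  n2 <- nn_inorm_fwd(h2, prm$g2, prm$n2)
  z <- n2$y
  if (residual) {
    s <- if (!is.null(prm$wp)) nn_conv_fwd(x, prm$wp, prm$bp) else x
    z <- z + s
  }
  y <- nn_relu_fwd(z)
  if (!keep_cache) return(list(y = y))
  list(y = y, x = x, n1 = n1, r1 = r1, n2 = n2,
       cols1 = c1$cols, cols2 = c2$cols)
}

block_bwd <- function(cache, prm, residual, gy) {
  gz <- nn_relu_bwd(cache$y, gy)
  g <- list()
  bi2 <- nn_inorm_bwd(cache$n2, prm$g2, gz)
  g$g2 <- bi2$gg; g$n2 <- bi2$gb
  bc2 <- nn_conv_bwd(cache$r1, prm$w2, bi2$gx, cols = cache$cols2)
  g$w2 <- bc2$gw; g$b2 <- bc2$gb
  gr1 <- nn_relu_bwd(cache$r1, bc2$gx)
  bi1 <- nn_inorm_bwd(cache$n1, prm$g1, gr1)
  g$g1 <- bi1$gg; g$n1 <- bi1$gb
  bc1 <- nn_conv_bwd(cache$x, prm$w1, bi1$gx, cols = cache$cols1)
  g$w1 <- bc1$gw; g$b1 <- bc1$gb
  gx <- bc1$gx
  if (residual) {
    if (!is.null(prm$wp)) {
      bp <- nn_conv_bwd(cache$x, prm$wp, gz)
      g$wp <- bp$gw; g$bp <- bp$gb
      gx <- gx + bp$gx
    } else gx <- gx + gz
  }
  list(gx = gx, grads = g)
}

unet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config; prm <- model$params
  D <- cfg$depth
  caches <- list(); skips <- list(); skip_dims <- list()
  for (l in seq_len(D)) {
    bl <- block_fwd(x, prm[[paste0("enc", l)]], cfg$residual, keep_cache)
    caches[[paste0("enc", l)]] <- bl
    if (l < D) { skips[[l]] <- bl$y; x <- nn_pool2(bl$y) } else x <- bl$y
  }
  if (D > 1) for (l in (D - 1):1) {
    up <- nn_up2(x)
    cat_in <- nn_concat(up, skips[[l]])
    caches[[paste0("split", l)]] <- dim(up)[4]
    bl <- block_fwd(cat_in, prm[[paste0("dec", l)]], cfg$residual, keep_cache)
    caches[[paste0("dec", l)]] <- bl
    x <- bl$y
  }
  logits <- nn_conv_fwd(x, prm$final$w, prm$final$b)
  list(logits = logits, caches = caches, last = x)
}

unet_backward <- function(model, fw, dlogits) {
  cfg <- model$config; prm <- model$params
  D <- cfg$depth
  grads <- list()
  bfin <- nn_conv_bwd(fw$last, prm$final$w, dlogits)
  grads$final <- list(w = bfin$gw, b = bfin$gb)
  gx <- bfin$gx
  gskip <- list()
  if (D > 1) for (l in 1:(D - 1)) {
    bb <- block_bwd(fw$caches[[paste0("dec", l)]], prm[[paste0("dec", l)]],
                    cfg$residual, gx)
    grads[[paste0("dec", l)]] <- bb$grads
    nup <- fw$caches[[paste0("split", l)]]
    nc <- dim(bb$gx)[4]
    gskip[[l]] <- bb$gx[, , , (nup + 1):nc, drop = FALSE]
    gx <- nn_up2_bwd(bb$gx[, , , seq_len(nup), drop = FALSE])
  }
  for (l in D:1) {
    if (l < D) gx <- nn_pool2_bwd(gx, NULL) + gskip[[l]]
    bb <- block_bwd(fw$caches[[paste0("enc", l)]], prm[[paste0("enc", l)]],
                    cfg$residual, gx)
    grads[[paste0("enc", l)]] <- bb$grads
    gx <- bb$gx
  }
  grads
}

# ---- prediction API --------------------------------------------------------

as_input4d <- function(input) {
  if (inherits(input, "pd_volume")) input <- input$data
  input <- as.array(input)
  if (length(dim(input)) == 3L) dim(input) <- c(dim(input), 1L)
  if (length(dim(input)) != 4L) stop("input must be a 3D or 4D array")
  input
}

#' Per-voxel class probabilities
#'
#' Runs a model on a multi-channel 3D grid. Output spatial shape equals the
#' input spatial shape; values are in `[0, 1]`, and a softmax head sums to 1
#' across channels at every voxel.
#'
#' @param model a model built by [build_model()], [const_model()] or
#'   [fn_model()].
#' @param input 3D array (single channel) or 4D (x, y, z, channel) array.
#' @return 4D probability array (x, y, z, out_channels).
#' @export
predict_proba <- function(model, input) UseMethod("predict_proba")

#' @export
predict_proba.pd_segmodel <- function(model, input) {
  x <- as_input4d(input)
  cfg <- model$config
  if (dim(x)[4] != cfg$in_channels)
    stop(sprintf("input has %d channels but the model expects %d",
                 dim(x)[4], cfg$in_channels))
  div <- 2^(cfg$depth - 1)
  if (any(dim(x)[1:3] %% div != 0))
    stop(sprintf("spatial extent %s must be divisible by %d (depth %d)",
                 paste(dim(x)[1:3], collapse = "x"), div, cfg$depth))
  fw <- unet_forward(model, x, keep_cache = FALSE)
  if (cfg$head == "sigmoid") nn_sigmoid(fw$logits) else nn_softmax(fw$logits)
}

#' Constant-probability model (testing / degenerate baselines)
#' @param value constant probability emitted at every voxel.
#' @param in_channels,out_channels channel contract.
#' @export
const_model <- function(value, in_channels = 1, out_channels = 1) {
  structure(list(value = value, in_channels = in_channels,
                 out_channels = out_channels), class = "pd_const_model")
}

#' @export
predict_proba.pd_const_model <- function(model, input) {
  x <- as_input4d(input)
  if (dim(x)[4] != model$in_channels) stop("input channel mismatch")
  array(model$value, dim = c(dim(x)[1:3], model$out_channels))
}

#' Function-backed model (testing)
#' @param fn function(4D input array) -> 4D probability array.
#' @param in_channels,out_channels channel contract.
#' @export
fn_model <- function(fn, in_channels = 1, out_channels = 1) {
  structure(list(fn = fn, in_channels = in_channels,
                 out_channels = out_channels), class = "pd_fn_model")
}

#' @export
predict_proba.pd_fn_model <- function(model, input) {
  x <- as_input4d(input)
  if (dim(x)[4] != model$in_channels) stop("input channel mismatch")
  out <- model$fn(x)
  if (length(dim(out)) == 3L) dim(out) <- c(dim(out), 1L)
  out
}

#' Oracle model: the cascade substitutes ground truth for this stage
#'
#' Used to verify that the cascade plumbing adds zero error: a stage holding
#' an oracle model emits the ground-truth mask of its structure(s) instead of
#' a network prediction, so every downstream quantity should be exact.
#'
#' @param structures character vector of structure names this stage emits.
#' @export
oracle_model <- function(structures) {
  structure(list(structures = structures), class = "pd_oracle_model")
}

#' @export
predict_proba.pd_oracle_model <- function(model, input) {
  stop("oracle models are resolved by the cascade against ground truth; ",
       "they cannot be called directly")
}

is_oracle <- function(model) inherits(model, "pd_oracle_model")
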