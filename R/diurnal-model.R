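# Multi-modal 1D convolutional classifier over 24-hour activity profiles.
#
# Architecture: conv(1 -> C1, kernel k, same zero-padding, stride 1) ->
# batch norm -> ReLU -> conv(C1 -> C2) -> batch norm -> ReLU -> global
# average pooling over the 24 positions, concatenated with a month
# embedding, a sex embedding, and ReLU(linear(age, weight)), then a
# two-layer classifier head with softmax output. Trained with Adam on
# cross-entropy. Implemented directly on base-R matrices: convolutions are
# im2col patch matrices times weight matrices, so every step is a dense
# matrix product and backpropagation is derived layer by layer (verified in
# the test suite by finite-difference gradient checks).

#' Classifier architecture and training hyperparameters
#'
#' Defaults follow the published configuration where one is stated
#' (16/32 convolution filters, 30 epochs, batch size 64, learning rate
#' 0.001, two classes) and smallest-sensible values elsewhere (kernel 3,
#' month/sex embedding dimensions 4/2, projector width 8, hidden width 32).
#'
#' @param conv_filters Length-2 integer vector of filter counts.
#' @param kernel_size Odd convolution kernel width.
#' @param embed_dim_month,embed_dim_sex Embedding dimensions.
#' @param projector_dim Output width of the age/weight projector.
#' @param classifier_hidden Hidden width of the classifier head.
#' @param n_classes Number of classes (2 supported).
#' @param epochs Training epochs per fold (0 returns an untrained model).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Seed for initialization and epoch shuffling.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_filters = c(16L, 32L),
                         kernel_size = 3L,
                         embed_dim_month = 4L,
                         embed_dim_sex = 2L,
                         projector_dim = 8L,
                         classifier_hidden = 32L,
                         n_classes = 2L,
                         epochs = 30L,
                         batch_size = 64L,
                         learning_rate = 0.001,
                         seed = 1L) {
  cfg <- list(conv_filters = as.integer(conv_filters),
              kernel_size = as.integer(kernel_size),
              embed_dim_month = as.integer(embed_dim_month),
              embed_dim_sex = as.integer(embed_dim_sex),
              projector_dim = as.integer(projector_dim),
              classifier_hidden = as.integer(classifier_hidden),
              n_classes = as.integer(n_classes),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              seed = as.integer(seed))
  stopifnot(length(cfg$conv_filters) == 2, all(cfg$conv_filters >= 1),
            cfg$kernel_size >= 1, cfg$kernel_size %% 2 == 1,
            cfg$embed_dim_month >= 1, cfg$embed_dim_sex >= 1,
            cfg$projector_dim >= 1, cfg$classifier_hidden >= 1,
            cfg$epochs >= 0, cfg$batch_size >= 1, cfg$learning_rate > 0)
  if (cfg$n_classes != 2L) {
    stop("only two-class models are supported", call. = FALSE)
  }
  structure(cfg, class = "model_config")
}

# --- parameters ------------------------------------------------------------

init_params <- function(config) {
  k <- config$kernel_size
  c1 <- config$conv_filters[1]
  c2 <- config$conv_filters[2]
  dm <- config$embed_dim_month
  ds <- config$embed_dim_sex
  pd <- config$projector_dim
  hd <- config$classifier_hidden
  d_cat <- c2 + dm + ds + pd
  he <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  }
  list(
    W1 = he(k, c1), b1 = numeric(c1),
    g1 = rep(1, c1), be1 = numeric(c1),
    W2 = he(k * c1, c2), b2 = numeric(c2),
    g2 = rep(1, c2), be2 = numeric(c2),
    Em = matrix(stats::rnorm(12 * dm, 0, 0.1), 12, dm),
    Es = matrix(stats::rnorm(2 * ds, 0, 0.1), 2, ds),
    Wp = he(2, pd), bp = numeric(pd),
    Wh = he(d_cat, hd), bh = numeric(hd),
    Wo = he(hd, 2), bo = numeric(2)
  )
}

init_bn <- function(config) {
  c1 <- config$conv_filters[1]
  c2 <- config$conv_filters[2]
  list(m1 = numeric(c1), v1 = rep(1, c1),
       m2 = numeric(c2), v2 = rep(1, c2))
}

#' Number of learned parameters of a model
#'
#' @param model A trained or untrained `diurnal_model` (or its parameter
#'   list).
#' @return Total count of weights, biases, batch-norm scales/shifts and
#'   embedding entries.
#' @export
n_parameters <- function(model) {
  params <- if (inherits(model, "diurnal_model")) model$params else model
  sum(vapply(params, length, numeric(1)))
}

# --- forward / backward ----------------------------------------------------

addb <- function(m, b) m + rep(b, each = nrow(m))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# im2col patch matrix: rows ordered participant-fastest within position.
conv_patches <- function(h, n_b, len, half) {
  n_ch <- ncol(h)
  pad <- matrix(0, half * n_b, n_ch)
  hp <- rbind(pad, h, pad)
  k <- 2L * half + 1L
  out <- matrix(0, n_b * len, n_ch * k)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * n_b + 1L):((j - 1L) * n_b + n_b * len)
    out[, ((j - 1L) * n_ch + 1L):(j * n_ch)] <- hp[rows, , drop = FALSE]
  }
  out
}

nn_forward <- function(params, bn, x, month, sex_idx, znum,
                       train = FALSE, keep_cache = FALSE) {
  n_b <- nrow(x)
  len <- 24L
  half <- (nrow(params$W1) - 1L) %/% 2L
  c2 <- ncol(params$W2)

  p1 <- conv_patches(matrix(as.vector(x), n_b * len, 1L), n_b, len, half)
  # conv_patches expects channel-major rows; for a single channel the
  # profile matrix must first be laid out participant-fastest by position:
  # column j of x stacked, which is exactly as.vector(x).
  z1 <- addb(p1 %*% params$W1, params$b1)
  bn1 <- bn_forward(z1, params$g1, params$be1, bn$m1, bn$v1, train)
  a1 <- bn1$out
  h1 <- a1 * (a1 > 0)

  p2 <- conv_patches(h1, n_b, len, half)
  z2 <- addb(p2 %*% params$W2, params$b2)
  bn2 <- bn_forward(z2, params$g2, params$be2, bn$m2, bn$v2, train)
  a2 <- bn2$out
  h2 <- a2 * (a2 > 0)

  # Global average pooling: mean over the 24 positions per filter.
  pooled <- matrix(colMeans(aperm(array(h2, c(n_b, len, c2)),
                                  c(2, 1, 3)), dims = 1), n_b, c2)

  em <- params$Em[month, , drop = FALSE]
  es <- params$Es[sex_idx, , drop = FALSE]
  zp <- addb(znum %*% params$Wp, params$bp)
  pn <- zp * (zp > 0)
  cc <- cbind(pooled, em, es, pn)
  zh <- addb(cc %*% params$Wh, params$bh)
  hd <- zh * (zh > 0)
  logits <- addb(hd %*% params$Wo, params$bo)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  prob <- e / rowSums(e)

  new_bn <- bn
  if (train) {
    new_bn$m1 <- bn1$run_mean; new_bn$v1 <- bn1$run_var
    new_bn$m2 <- bn2$run_mean; new_bn$v2 <- bn2$run_var
  }
  cache <- NULL
  if (keep_cache) {
    cache <- list(n_b = n_b, p1 = p1, xh1 = bn1$xhat, inv1 = bn1$inv,
                  a1 = a1, p2 = p2, xh2 = bn2$xhat, inv2 = bn2$inv,
                  a2 = a2, month = month, sex_idx = sex_idx, znum = znum,
                  pn = pn, cc = cc, hd = hd, prob = prob, half = half)
  }
  list(prob = prob, bn = new_bn, cache = cache)
}

bn_forward <- function(z, gamma, beta, run_mean, run_var, train) {
  n <- nrow(z)
  if (train) {
    mu <- colMeans(z)
    v <- colMeans(z * z) - mu^2
    v <- pmax(v, 0)
    unbiased <- if (n > 1) v * n / (n - 1) else v
    run_mean <- (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu
    run_var <- (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * unbiased
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- (z - rep(mu, each = n)) * rep(inv, each = n)
  out <- addb(xhat * rep(gamma, each = n), beta)
  list(out = out, xhat = xhat, inv = inv,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, xhat, inv, gamma) {
  n <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxh <- dy * rep(gamma, each = n)
  s1 <- colSums(dxh)
  s2 <- colSums(dxh * xhat)
  dz <- (dxh - rep(s1 / n, each = n) -
           xhat * rep(s2 / n, each = n)) * rep(inv, each = n)
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# Scatter patch-matrix gradients back onto the (padded) feature rows.
unpatch <- function(dp, n_b, len, half, n_ch) {
  k <- 2L * half + 1L
  dhp <- matrix(0, n_b * (len + 2L * half), n_ch)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * n_b + 1L):((j - 1L) * n_b + n_b * len)
    dhp[rows, ] <- dhp[rows, ] +
      dp[, ((j - 1L) * n_ch + 1L):(j * n_ch), drop = FALSE]
  }
  dhp[(half * n_b + 1L):(half * n_b + n_b * len), , drop = FALSE]
}

nn_backward <- function(params, cache, y_onehot) {
  n_b <- cache$n_b
  len <- 24L
  half <- cache$half
  c1 <- ncol(params$W1)
  c2 <- ncol(params$W2)
  dm <- ncol(params$Em)
  ds <- ncol(params$Es)
  pd <- ncol(params$Wp)

  dlog <- (cache$prob - y_onehot) / n_b
  d_wo <- crossprod(cache$hd, dlog)
  d_bo <- colSums(dlog)
  dhd <- dlog %*% t(params$Wo)
  dzh <- dhd * (cache$hd > 0)
  d_wh <- crossprod(cache$cc, dzh)
  d_bh <- colSums(dzh)
  dcc <- dzh %*% t(params$Wh)

  dpooled <- dcc[, seq_len(c2), drop = FALSE]
  dem <- dcc[, c2 + seq_len(dm), drop = FALSE]
  des <- dcc[, c2 + dm + seq_len(ds), drop = FALSE]
  dpn <- dcc[, c2 + dm + ds + seq_len(pd), drop = FALSE]

  d_em <- matrix(0, 12, dm)
  rs <- rowsum(dem, cache$month)
  d_em[as.integer(rownames(rs)), ] <- rs
  d_es <- matrix(0, 2, ds)
  rs <- rowsum(des, cache$sex_idx)
  d_es[as.integer(rownames(rs)), ] <- rs

  dzp <- dpn * (cache$pn > 0)
  d_wp <- crossprod(cache$znum, dzp)
  d_bp <- colSums(dzp)

  dh2 <- dpooled[rep(seq_len(n_b), len), , drop = FALSE] / len
  da2 <- dh2 * (cache$a2 > 0)
  bb2 <- bn_backward(da2, cache$xh2, cache$inv2, params$g2)
  d_w2 <- crossprod(cache$p2, bb2$dz)
  d_b2 <- colSums(bb2$dz)
  dp2 <- bb2$dz %*% t(params$W2)
  dh1 <- unpatch(dp2, n_b, len, half, c1)
  da1 <- dh1 * (cache$a1 > 0)
  bb1 <- bn_backward(da1, cache$xh1, cache$inv1, params$g1)
  d_w1 <- crossprod(cache$p1, bb1$dz)
  d_b1 <- colSums(bb1$dz)

  list(W1 = d_w1, b1 = d_b1, g1 = bb1$dgamma, be1 = bb1$dbeta,
       W2 = d_w2, b2 = d_b2, g2 = bb2$dgamma, be2 = bb2$dbeta,
       Em = d_em, Es = d_es, Wp = d_wp, bp = d_bp,
       Wh = d_wh, bh = d_bh, Wo = d_wo, bo = d_bo)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- input preparation -----------------------------------------------------

fit_scaler <- function(data) {
  h <- as.matrix(data[, HOUR_COLS])
  h_sd <- apply(h, 2, stats::sd)
  h_sd[!is.finite(h_sd) | h_sd == 0] <- 1
  num <- cbind(data$age, data$weight)
  num_sd <- apply(num, 2, stats::sd)
  num_sd[!is.finite(num_sd) | num_sd == 0] <- 1
  list(h_mean = colMeans(h), h_sd = h_sd,
       num_mean = colMeans(num), num_sd = num_sd,
       sex_levels = c("female", "male"))
}

model_inputs <- function(data, scaler) {
  h <- as.matrix(data[, HOUR_COLS])
  if (ncol(h) != 24) stop("profile must have exactly 24 hourly values",
                          call. = FALSE)
  x <- sweep(sweep(h, 2, scaler$h_mean), 2, scaler$h_sd, "/")
  month <- as.integer(data$month)
  if (any(is.na(month)) || any(month < 1) || any(month > 12)) {
    stop("`month` must be an integer in 1..12", call. = FALSE)
  }
  sex_idx <- match(as.character(data$sex), scaler$sex_levels)
  if (any(is.na(sex_idx))) {
    stop("unknown sex category; expected one of: ",
         paste(scaler$sex_levels, collapse = ", "), call. = FALSE)
  }
  num <- cbind(data$age, data$weight)
  znum <- sweep(sweep(num, 2, scaler$num_mean), 2, scaler$num_sd, "/")
  list(x = x, month = month, sex_idx = sex_idx, znum = znum)
}

# --- training and prediction ----------------------------------------------

#' Train the classifier on one training fold
#'
#' Standardizes inputs with statistics from `data` only (per-hour and
#' per-numeric-covariate z-scores), then minimizes cross-entropy with Adam
#' at the configured learning rate for exactly `epochs` epochs over
#' shuffled mini-batches of `batch_size`. No early stopping, weight decay
#' or dropout. Fully seeded: identical data and configuration give
#' byte-identical parameters.
#'
#' @param data Training records (columns `h00`..`h23`, `month`, `sex`,
#'   `age`, `weight`).
#' @param labels Integer 0/1 vector, one per row; both classes must have
#'   at least two members.
#' @param config A [model_config()].
#'
#' @return A `diurnal_model`: learned parameters, batch-norm running
#'   statistics (frozen at inference), the fitted standardization state,
#'   the configuration snapshot and the per-epoch training-loss history.
#' @export
train_fold <- function(data, labels, config) {
  stopifnot(inherits(config, "model_config"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(data)) {
    stop("`labels` must match `data` rows", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be 0/1", call. = FALSE)
  }
  counts <- c(sum(labels == 0L), sum(labels == 1L))
  if (any(counts == 0L)) {
    stop("single-class training set: both classes are required",
         call. = FALSE)
  }
  if (any(counts < 2L)) {
    stop("each class needs at least 2 training examples", call. = FALSE)
  }
  scaler <- fit_scaler(data)
  inp <- model_inputs(data, scaler)
  n <- nrow(data)
  y <- cbind(as.numeric(labels == 0L), as.numeric(labels == 1L))

  fitted <- withr::with_seed(config$seed, {
    params <- init_params(config)
    bn <- init_bn(config)
    opt <- adam_init(params)
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        b <- idx[s:min(s + config$batch_size - 1L, n)]
        fw <- nn_forward(params, bn,
                         inp$x[b, , drop = FALSE], inp$month[b],
                         inp$sex_idx[b], inp$znum[b, , drop = FALSE],
                         train = TRUE, keep_cache = TRUE)
        bn <- fw$bn
        p_true <- rowSums(fw$prob * y[b, , drop = FALSE])
        ep_loss <- ep_loss - sum(log(pmax(p_true, 1e-12)))
        grads <- nn_backward(params, fw$cache, y[b, , drop = FALSE])
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      loss_hist[ep] <- ep_loss / n
    }
    list(params = params, bn = bn, loss = loss_hist)
  })

  structure(list(params = fitted$params, bn = fitted$bn, scaler = scaler,
                 config = config, loss_history = fitted$loss),
            class = "diurnal_model")
}

#' Predict class labels and probabilities
#'
#' Runs the network in evaluation mode (batch normalization uses the
#' stored running statistics, never the statistics of the prediction
#' batch), so batched and one-at-a-time prediction are identical and
#' repeated application is deterministic.
#'
#' @param object A `diurnal_model` from [train_fold()].
#' @param data Records to score (same columns as training).
#' @param ... Unused.
#'
#' @return List with `labels` (integer 0/1 argmax), `prob1` (class-1
#'   probability) and `prob` (n x 2 matrix).
#' @export
predict.diurnal_model <- function(object, data, ...) {
  if (nrow(data) == 0) {
    return(list(labels = integer(0), prob1 = numeric(0),
                prob = matrix(numeric(0), 0, 2)))
  }
  inp <- model_inputs(data, object$scaler)
  fw <- nn_forward(object$params, object$bn, inp$x, inp$month,
                   inp$sex_idx, inp$znum, train = FALSE)
  list(labels = as.integer(fw$prob[, 2] > fw$prob[, 1]),
       prob1 = fw$prob[, 2],
       prob = fw$prob)
}

#' Forward pass for a single participant
#'
#' @param model A `diurnal_model`.
#' @param profile Numeric vector of exactly 24 hourly values.
#' @param month Integer month 1--12.
#' @param sex `"female"` or `"male"`.
#' @param age,weight Numeric covariates (years, kg).
#'
#' @return Length-2 probability vector (class 0, class 1); sums to 1.
#' @export
model_forward <- function(model, profile, month, sex, age, weight) {
  if (length(profile) != 24) {
    stop("`profile` must have exactly 24 values", call. = FALSE)
  }
  row <- as.data.frame(as.list(stats::setNames(profile, HOUR_COLS)))
  row$month <- month
  row$sex <- sex
  row$age <- age
  row$weight <- weight
  pr <- predict.diurnal_model(model, row)
  c(pr$prob[1, 1], pr$prob[1, 2])
}
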