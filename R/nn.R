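# Minimal dense feed-forward network trained with Adam, in base R matrix
# code. Hidden layers use relu. Two heads: "softmax" (categorical
# cross-entropy) and "relu" (single rectified output trained with mean
# absolute percentage error, for strictly positive targets).

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1L], 0, sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1L]),
      b = rep(0, sizes[l + 1L]))
  }
  # start the rectified output active
  layers[[length(layers)]]$b[] <- 1
  layers
}

mlp_forward <- function(layers, X, head) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, "+")
    if (l < nl) Z[Z < 0] <- 0
    else if (head == "relu") Z[Z < 0] <- 0
    else if (head == "softmax") {
      Z <- Z - apply(Z, 1L, max)
      E <- exp(Z)
      Z <- E / rowSums(E)
    }
    acts[[l + 1L]] <- Z
  }
  acts
}

# gradient of the loss at the pre-activation of the output layer
mlp_out_grad <- function(out, Y, head) {
  n <- nrow(out)
  if (head == "softmax") (out - Y) / n
  else {
    # percentage-error gradient, smoothed near zero residual (|rel| < 1e-2
    # transitions to quadratic) so the optimum is a true stationary point
    ay <- pmax(abs(Y), .Machine$double.eps)
    rel <- (out - Y) / ay
    g <- sign(rel) * pmin(1, abs(rel) / 0.01) / ay / n
    g[out <= 0 & g > 0] <- 0  # rectified output: no gradient below zero
    g
  }
}

mlp_train <- function(X, Y, head = c("softmax", "relu"), hidden = c(32, 32, 32),
                      epochs = 100, batch_size = nrow(X), lr = 1e-3,
                      verbose = FALSE) {
  head <- match.arg(head)
  n_out <- ncol(Y)
  layers <- mlp_init(ncol(X), hidden, n_out)
  nl <- length(layers)
  mW <- vW <- lapply(layers, function(l) l$W * 0)
  mb <- vb <- lapply(layers, function(l) l$b * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    # linear decay to 1% of the initial rate: settles the sign-based
    # percentage-error gradient, which otherwise oscillates at fixed step
    lr_ep <- lr * (1 - 0.99 * (ep - 1) / max(1L, epochs - 1L))
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      acts <- mlp_forward(layers, X[idx, , drop = FALSE], head)
      delta <- mlp_out_grad(acts[[nl + 1L]], Y[idx, , drop = FALSE], head)
      step <- step + 1L
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(layers[[l]]$W)
          delta[acts[[l]] <= 0] <- 0
        }
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
        layers[[l]]$W <- layers[[l]]$W -
          lr_ep * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          lr_ep * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    if (verbose && ep %% max(1L, epochs %/% 10L) == 0L) {
      out <- mlp_forward(layers, X, head)[[nl + 1L]]
      loss <- if (head == "softmax")
        -mean(log(pmax(rowSums(out * Y), 1e-12)))
      else mean(abs(Y - out) / pmax(abs(Y), .Machine$double.eps))
      message(sprintf("epoch %d loss %.4f", ep, loss))
    }
  }
  structure(list(layers = layers, head = head, hidden = hidden),
            class = "genarch_mlp")
}

mlp_predict <- function(net, X) {
  mlp_forward(net$layers, X, net$head)[[length(net$layers) + 1L]]
}
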