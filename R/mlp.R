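# R-side wrappers around the compiled network trainer (src/mlp.cpp).
# The seed is applied here so all init/shuffle/dropout draws come from R's
# RNG stream; training is single-threaded and deterministic given the seed.

train_mlp <- function(X, y, k_out, hidden = c(500, 250), dropout = 0.25,
                      epochs = 30, batch_size = 128, lr = 1e-3,
                      patience = 2, min_delta = 5e-3, seed = 1L) {
  Xd <- as.matrix(X)
  with_seed(seed, {
    cpp_train_mlp(Xd, as.integer(y), as.integer(k_out), as.integer(hidden),
                  dropout, as.integer(epochs), as.integer(batch_size),
                  lr, as.integer(patience), min_delta)
  })
}

predict_mlp <- function(net, X, type = c("class", "prob")) {
  type <- match.arg(type)
  P <- cpp_mlp_predict(as.matrix(X), net)
  if (type == "prob") P else max.col(P, ties.method = "first")
}
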