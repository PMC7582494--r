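# The desk-scale 4-class shape classification study: 400 training and 100
# test clouds of 256 points, k = 20. Three models are trained from seeds
# 1..3 (40 of the 400 training clouds held out as validation; training stops
# once validation accuracy saturates, within the 30-epoch budget). The fits
# are cached so the learning and robustness tests share them.

.toy_cache <- new.env(parent = emptyenv())

toy_study <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  ds <- make_dataset(4, 125, split = 0.8, seed = seed, n = 256)
  set.seed(seed)
  vi <- sample(length(ds$train), 40)
  cfg <- classifier_config(n_classes = 4, layers = c(16L, 16L, 32L), k = 20L,
                           global_width = 64L, mask_hidden = 32L,
                           head = c(32L, 16L), graph = "coords")
  model <- init_classifier(cfg, seed = seed)
  tcfg <- train_config(epochs = 30, batch_size = 16, seed = seed,
                       early_stop_oa = 100)
  fit <- train_model(ds$train[-vi], model, tcfg, val = ds$train[vi])
  out <- list(model = fit$model, log = fit$log, test = ds$test)
  .toy_cache[[key]] <- out
  out
}
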