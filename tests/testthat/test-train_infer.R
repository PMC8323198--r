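test_that("the triangular schedule hits its bounds and period", {
  L <- 100L
  expect_equal(cyclical_lr(0, cycle_length = L), 1e-6)
  expect_equal(cyclical_lr(L, cycle_length = L), 1e-3)
  expect_equal(cyclical_lr(L / 2, cycle_length = L), (1e-6 + 1e-3) / 2)
  expect_equal(cyclical_lr(L / 2, cycle_length = L), 5.005e-4)
  it <- 0:(6 * L)
  lr <- cyclical_lr(it, cycle_length = L)
  expect_true(all(lr >= 1e-6 & lr <= 1e-3))
  # periodic with period 2L
  expect_equal(cyclical_lr(it, cycle_length = L),
               cyclical_lr(it + 2L * L, cycle_length = L))
})

test_that("case-level splits are disjoint, exhaustive and reproducible", {
  cases <- lapply(1:10, function(i)
    list(case_id = sprintf("c%02d", i)))
  sp <- split_dataset(cases, 0.2, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 2)
  ids <- function(x) vapply(x, `[[`, "", "case_id")
  expect_length(intersect(ids(sp$train), ids(sp$validation)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$validation)), ids(cases))
  sp2 <- split_dataset(cases, 0.2, seed = 4)
  expect_identical(ids(sp$validation), ids(sp2$validation))
  sp3 <- split_dataset(cases, 0.2, seed = 5)
  expect_false(identical(ids(sp$validation), ids(sp3$validation)))
})

test_that("one optimizer step reduces every selectable loss on a fixed batch", {
  cfg <- net_config(input_size = 32L,
                    stage_channels = c(4L, 6L, 8L, 10L, 12L),
                    fusing_channels = 8L, dropout = 0)
  S <- 32L; B <- 2L
  params <- tiny_phantom_params()
  cs <- generate_case(params, seed = 17)
  cs <- normalize_case(cs)
  slices <- extract_slices(cs, keep_empty = FALSE)
  with_tumor <- Filter(function(s) any(s$labels > 0), slices)
  batch <- with_tumor[1:B]
  X <- msffn:::slices_to_batch(batch)
  G <- msffn:::slices_to_onehot(batch)
  for (loss in c("ce", "sliced_dice", "combined_dice", "hl1", "hl2")) {
    net <- msffn_net(cfg, seed = 18)
    opt <- msffn:::adam_init(net$params)
    f <- msffn:::net_forward(net, X, S, S, B, training = TRUE,
                             keep_cache = TRUE)
    l0 <- seg_loss(f$P, G, loss)
    dP <- seg_loss_grad(f$P, G, loss)
    dL <- msffn:::softmax_backward(f$P, dP)
    gr <- msffn:::net_backward(net, f, dL, S, S, B)
    upd <- msffn:::adam_step(net$params, gr, opt, lr = 1e-3)
    net$params <- upd$params
    f1 <- msffn:::net_forward(net, X, S, S, B, training = TRUE,
                              keep_cache = FALSE)
    l1 <- seg_loss(f1$P, G, loss)
    expect_lt(l1, l0)
  }
})

test_that("training is reproducible and tracks a best checkpoint", {
  params <- tiny_phantom_params()
  cases <- generate_cohort(5, params, seed = 500)
  sp <- split_dataset(cases, 0.2, seed = 1)
  cfg <- net_config(input_size = 32L,
                    stage_channels = c(4L, 6L, 8L, 10L, 12L),
                    fusing_channels = 8L)
  ctl <- train_control(batch_size = 4L, epochs = 2L, loss = "hl2",
                       slices_per_case = 2L, seed = 33)
  fit1 <- msffn_train(msffn_net(cfg, seed = 30), sp$train, sp$validation, ctl)
  fit2 <- msffn_train(msffn_net(cfg, seed = 30), sp$train, sp$validation, ctl)
  expect_identical(fit1$history, fit2$history)
  expect_s3_class(fit1, "msffn_fit")
  expect_true(all(c("train_loss", "val_loss", "val_dsc_complete") %in%
                    names(fit1$history)))
  expect_true(all(is.finite(fit1$history$train_loss)))
  # the selected epoch carries the smallest validation loss seen
  expect_equal(fit1$history$val_loss[fit1$best_epoch],
               min(fit1$history$val_loss))
  # methods on the fit object
  expect_output(print(fit1), "msffn_fit")
  expect_named(coef(fit1), names(fit1$net$params))
  grDevices::pdf(NULL)
  expect_silent(plot(fit1))
  grDevices::dev.off()
})

test_that("prediction reassembles full volumes and ensembles average", {
  params <- tiny_phantom_params()
  cs <- generate_case(params, seed = 600)
  cfg <- net_config(input_size = 32L,
                    stage_channels = c(4L, 6L, 8L, 10L, 12L),
                    fusing_channels = 8L)
  net <- msffn_net(cfg, seed = 31)
  pred <- predict_case(net, cs)
  expect_identical(dim(pred), dim(cs$labels))
  expect_true(all(pred %in% 0:4))

  # an ensemble of five copies of one model predicts like that model
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(net, ck)
  ens <- build_ensemble(list(ck, ck, net, net, net))
  expect_length(ens$nets, 5)
  pred_e <- predict_case(ens, cs)
  expect_identical(pred_e, pred)
  pred_v <- predict_case(ens, cs, fuse = "vote")
  expect_identical(pred_v, pred)

  expect_error(build_ensemble(list(tempfile(fileext = ".rds"))), "not found")
  expect_error(build_ensemble(list()), "empty")

  # checkpoints restore predictions exactly
  reloaded <- load_checkpoint(ck)
  expect_identical(predict_case(reloaded, cs), pred)
})

test_that("slice batching utilities invert each other", {
  set.seed(77)
  imgs <- lapply(1:3, function(i) array(rnorm(8 * 8 * 4), dim = c(8, 8, 4)))
  X <- msffn:::images_to_batch(imgs)
  back <- msffn:::batch_to_images(X, 8L, 8L, 3L)
  for (i in 1:3) expect_equal(back[[i]], imgs[[i]])
})
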