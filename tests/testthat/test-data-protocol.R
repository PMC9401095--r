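# Smallest-class-referenced split, augmentation operators, and
# augmentation-based upsampling.

test_that("split: smallest class defines an equal validation size for every class", {
  cls <- list(A = paste0("a", 1:1000), B = paste0("b", 1:100))
  sp <- split_by_smallest_class(cls, ratio = 0.8, seed = 1)
  expect_length(sp$val$A, 20)
  expect_length(sp$val$B, 20)
  expect_length(sp$train$A, 980)
  expect_length(sp$train$B, 80)
  sp2 <- split_by_smallest_class(list(A = 1:10, B = 11:20), 0.8, seed = 2)
  expect_length(sp2$val$A, 2)
  expect_length(sp2$train$B, 8)
})

test_that("split is deterministic under the seed and disjoint per class", {
  cls <- list(x = 1:50, y = 51:120, z = 121:160)
  a <- split_by_smallest_class(cls, 0.8, seed = 99)
  b <- split_by_smallest_class(cls, 0.8, seed = 99)
  expect_identical(a, b)
  d <- split_by_smallest_class(cls, 0.8, seed = 100)
  expect_false(identical(a$val, d$val))
})

test_that("split property: 50 random class-size configurations", {
  set.seed(123)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    sizes <- sample(5:400, k)
    cls <- lapply(seq_len(k), function(i) sprintf("c%d_%d", i, seq_len(sizes[i])))
    names(cls) <- paste0("class", seq_len(k))
    ratio <- runif(1, 0.6, 0.9)
    sp <- split_by_smallest_class(cls, ratio, seed = rep)
    v <- round((1 - ratio) * min(sizes))
    for (nm in names(cls)) {
      expect_length(sp$val[[nm]], v)
      expect_length(intersect(sp$train[[nm]], sp$val[[nm]]), 0)
      expect_setequal(c(sp$train[[nm]], sp$val[[nm]]), cls[[nm]])
    }
  }
})

test_that("every augmentation operator preserves shape and the [0,1] range", {
  img <- generate_image("ulcer", c(32, 32), seed = 5)$image
  for (op in ratcapsnet:::AUG_OPS) {
    out <- augment_once(img, op, seed = 3)
    expect_equal(dim(out), dim(img), label = op)
    expect_true(all(out >= 0 & out <= 1), label = op)
    # deterministic under (params, seed)
    expect_identical(out, augment_once(img, op, seed = 3), label = op)
  }
  expect_error(augment_once(img, "sharpen"), "unknown")
})

test_that("rotation by 0 is the identity and flips are involutions", {
  img <- generate_image("blood", c(24, 24), seed = 2)$image
  expect_identical(augment_once(img, "rotate", list(degrees = 0)), img)
  h2 <- augment_once(augment_once(img, "flip", list(axis = "horizontal")),
                     "flip", list(axis = "horizontal"))
  expect_identical(h2, img)
  v2 <- augment_once(augment_once(img, "flip", list(axis = "vertical")),
                     "flip", list(axis = "vertical"))
  expect_identical(v2, img)
})

test_that("erase changes an area fraction within the requested range", {
  img <- array(0.5, c(40, 40, 3))
  for (seed in 1:10) {
    out <- augment_once(img, "erase", list(fraction = c(0.05, 0.10)), seed)
    frac <- mean(apply(out != img, c(1, 2), any))
    expect_gte(frac, 0.04)  # rectangle quantization: allow one-pixel rounding
    expect_lte(frac, 0.11)
  }
})

test_that("balance_upsample hits the target exactly with every original used", {
  cfg <- augmentation_config(seed = 21)
  pool <- sprintf("img%03d", 1:80)
  ent <- balance_upsample(pool, 3000, cfg)
  expect_length(ent, 3000)
  ids <- vapply(ent, `[[`, "", "id")
  expect_setequal(unique(ids), pool)       # every original at least once
  expect_true(all(table(ids) >= 1))
  recipes <- lapply(ent, `[[`, "recipe")
  expect_true(all(vapply(recipes[1:80], is.null, TRUE)))    # originals first
  expect_false(any(vapply(recipes[81:3000], is.null, TRUE)))
  # deterministic under the config seed
  ent2 <- balance_upsample(pool, 3000, cfg)
  expect_identical(ent, ent2)
  # pool already at target: originals only
  same <- balance_upsample(pool, 80, cfg)
  expect_length(same, 80)
  expect_true(all(vapply(same, function(e) is.null(e$recipe), TRUE)))
  expect_error(balance_upsample(character(), 10, cfg), "non-empty")
  expect_error(balance_upsample(pool, 10, cfg), ">=")
})

test_that("recipes serialize to JSON and back", {
  cfg <- augmentation_config(seed = 5)
  ent <- balance_upsample(letters[1:3], 10, cfg)
  r <- ent[[5]]$recipe
  s <- ratcapsnet:::recipe_to_json(r)
  r2 <- ratcapsnet:::recipe_from_json(s)
  img <- generate_image("normal", c(16, 16), 1)$image
  expect_equal(apply_recipe(img, r), apply_recipe(img, r2), tolerance = 1e-9)
  expect_null(ratcapsnet:::recipe_from_json(""))
})
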