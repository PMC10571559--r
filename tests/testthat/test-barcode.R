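test_that("color features encode channel fractions and scale invariance", {
  r <- data.frame(area = 50, circularity = 1,
                  total_r = 1000, total_g = 0, total_b = 0)
  f <- extract_color_features(r)
  expect_equal(unname(f[1, c("frac_r", "frac_g", "frac_b")]), c(1, 0, 0))

  rg <- data.frame(area = 50, circularity = 1,
                   total_r = 500, total_g = 500, total_b = 0)
  f2 <- extract_color_features(rg)
  expect_equal(unname(f2[1, c("frac_r", "frac_g", "frac_b")]), c(0.5, 0.5, 0))

  # multiplying all channels leaves the fractions unchanged
  rg10 <- transform(rg, total_r = total_r * 10, total_g = total_g * 10,
                    total_b = total_b * 10)
  f3 <- extract_color_features(rg10)
  expect_equal(f3[1, c("frac_r", "frac_g", "frac_b")],
               f2[1, c("frac_r", "frac_g", "frac_b")])

  # zero-intensity degenerate record: fractions 1/3, flagged
  z <- data.frame(area = 50, circularity = 1,
                  total_r = 0, total_g = 0, total_b = 0)
  fz <- extract_color_features(z)
  expect_equal(unname(fz[1, c("frac_r", "frac_g", "frac_b")]), rep(1 / 3, 3))
  expect_equal(attr(fz, "zero_intensity"), 1L)
})

test_that("the tree separates the six color classes almost perfectly", {
  tr <- simulate_color_training(120, crosstalk = 0.05, seed = 9)
  set.seed(9)
  hold <- sample.int(nrow(tr$features), round(0.3 * nrow(tr$features)))
  m <- train_color_model(tr$features[-hold, ], tr$class[-hold])
  rec <- tr$records[hold, ]
  rec$color_class <- NULL
  pred <- classify_nuclei(rec, m)$color_class
  expect_gte(mean(pred == as.character(tr$class[hold])), 0.99)
  expect_gte(m$training_accuracy, 0.999)
})

test_that("training is deterministic and a fixed point of its labels", {
  tr <- simulate_color_training(60, crosstalk = 0.05, seed = 4)
  m1 <- train_color_model(tr$features, tr$class)
  m2 <- train_color_model(tr$features, tr$class)
  expect_identical(m1$nodes, m2$nodes)

  # refit on the model's own predictions reproduces the predictions
  rec <- tr$records
  rec$color_class <- NULL
  pred <- classify_nuclei(rec, m1)$color_class
  m3 <- train_color_model(tr$features, pred)
  pred3 <- classify_nuclei(rec, m3)$color_class
  expect_identical(pred3, pred)
})

test_that("single-class input errors and tiny classes warn", {
  tr <- simulate_color_training(30, classes = "R", seed = 1)
  expect_error(train_color_model(tr$features, tr$class), "2 classes")
  tr2 <- simulate_color_training(5, classes = c("R", "G"), seed = 1)
  expect_warning(train_color_model(tr2$features, tr2$class), "fewer than")
})

test_that("feature order follows the model's feature_spec", {
  tr <- simulate_color_training(60, crosstalk = 0.05, seed = 6)
  m <- train_color_model(tr$features, tr$class)
  rec <- tr$records
  rec$color_class <- NULL
  base <- classify_nuclei(rec, m)$color_class
  # permute the stored spec together with the node feature indices: the
  # predictions must be unchanged (ordering is spec-driven, not positional)
  perm <- rev(seq_along(m$feature_spec))
  m2 <- m
  m2$feature_spec <- m$feature_spec[perm]
  m2$nodes$feature <- match(m$feature_spec[m$nodes$feature], m2$feature_spec)
  expect_identical(classify_nuclei(rec, m2)$color_class, base)
  # a model asking for unknown features errors
  m3 <- m
  m3$feature_spec <- c("not_a_feature", m$feature_spec[-1])
  expect_error(classify_nuclei(rec, m3), "feature spec")
})

test_that("classification empties, fragments and rules behave", {
  tr <- simulate_color_training(40, seed = 2)
  m <- train_color_model(tr$features, tr$class)
  empty <- tr$records[0, ]
  expect_equal(nrow(classify_nuclei(empty, m)), 0)

  # noise-free classes -> perfect recall with the rule-based classifier
  tr0 <- simulate_color_training(50, crosstalk = 0, seed = 3)
  rec <- tr0$records
  rec$color_class <- NULL
  pred <- classify_nuclei_rules(rec)$color_class
  expect_equal(mean(pred == as.character(tr0$class)), 1)

  # fragments trained as TRASH are recalled as TRASH on a held-out well
  train <- truth_labeled_training(seeds = c(41, 42))
  ftr <- extract_color_features(train)
  m2 <- train_color_model(ftr, train$class)
  held <- truth_labeled_training(seeds = 43)
  pred2 <- classify_nuclei(held, m2)$color_class
  frag <- held$class == "TRASH"
  expect_gte(mean(pred2[frag] == "TRASH"), 0.95)
})

test_that("models survive a JSON round trip verbatim", {
  tr <- simulate_color_training(40, seed = 8)
  m <- train_color_model(tr$features, tr$class)
  path <- tempfile(fileext = ".json")
  write_color_model(m, path)
  m2 <- read_color_model(path)
  rec <- tr$records
  rec$color_class <- NULL
  expect_identical(classify_nuclei(rec, m2)$color_class,
                   classify_nuclei(rec, m)$color_class)
})
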