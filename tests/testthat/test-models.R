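# Random-forest model families, design matrices, LOSO evaluation.

toy_samples <- function(n_scans = 3) {
  do.call(rbind, lapply(seq_len(n_scans), function(s) {
    df <- data.frame(scan_id = paste0("scan", s),
                     eccentricity = seq(-0.75, 0.75, 0.25),
                     onl = 100, is_len = 25, cos_len = 25, rpe = 18,
                     n_extrema = 4)
    refl <- matrix(runif(7 * 61), 7, 61,
                   dimnames = list(NULL, sprintf("refl_%02d", 1:61)))
    cbind(df, refl)
  }))
}

test_that("design_matrix_I builds thickness features with interaction terms", {
  s <- data.frame(scan_id = "a", eccentricity = 0, onl = 100, is_len = 25,
                  cos_len = 25, rpe = 18, n_extrema = 4)
  X <- design_matrix_I(s)
  expect_equal(unname(X[1, c("onl_x_cos", "onl_x_ecc", "cos_x_ecc")]),
               c(2500, 0, 0))

  # nasal/temporal folding: mirrored eccentricities give identical rows
  s2 <- s[c(1, 1), ]; s2$eccentricity <- c(-0.5, 0.5)
  X2 <- design_matrix_I(s2)
  expect_equal(X2[1, ], X2[2, ])

  # zero ONL zeroes all ONL-bearing columns
  s3 <- s; s3$onl <- 0
  X3 <- design_matrix_I(s3)
  expect_true(all(X3[1, c("onl", "onl_x_cos", "onl_x_ecc")] == 0))

  # flagged thickness -> imputed 0 + indicator
  s4 <- s; s4$cos_len <- NA
  X4 <- design_matrix_I(s4)
  expect_equal(unname(X4[1, c("cos_len", "miss_cos", "onl_x_cos")]),
               c(0, 1, 0))
})

test_that("design_matrix_II is reflectivity-only with a position tag", {
  set.seed(41)
  s <- toy_samples()
  X <- design_matrix_II(s)
  expect_equal(dim(X), c(21, 62)) # 61 depths + |ecc| tag
  expect_equal(dim(design_matrix_II(s, ecc_tag = FALSE)), c(21, 61))

  # identical scans give identical rows
  s$scan_id <- "same"
  srep <- s[c(1, 1), ]
  expect_equal(design_matrix_II(srep)[1, ], design_matrix_II(srep)[2, ])

  # ragged/incomplete vectors rejected
  sbad <- s; sbad$refl_10[3] <- NA
  expect_error(design_matrix_II(sbad), "ragged")
  expect_error(design_matrix_II(s[1:2, 1:7]), "no reflectivity")
})

test_that("rmse follows the squared-averaged-rooted definition", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(5, 2), 3)
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "at least one")
})

test_that("subject_record validates its 3x7 design", {
  s <- toy_samples()
  r <- subject_record("X", "IRD", 20, 0.5, s)
  expect_s3_class(r, "subject_record")
  expect_error(subject_record("X", "IRD", 20, 0.5, s[1:20, ]), "expected 21")
  expect_error(subject_record("X", "IRD", 20, -0.5, s), "positive")
  s2 <- s; s2$scan_id <- "one"
  expect_error(subject_record("X", "IRD", 20, 0.5, s2), "distinct scans")
})

test_that("model_spec covers exactly the four model families", {
  expect_error(model_spec("III", "FS"))
  expect_error(model_spec("I", "acuity"))
  sp <- model_spec("II", "VA", n_trees = 10)
  expect_equal(sp$family, "II")
  expect_error(model_spec("I", "FS", n_trees = 0))
})

test_that("LOSO: one fold per subject, constant targets give zero rmse", {
  co <- generate_training_cohort(8, 2, seed = 51)
  recs <- samples_from_cohort(co, seed = 52)
  # constant target
  recs_c <- lapply(recs, function(r) { r$fs_measured <- 7; r })
  ev <- loso_evaluate(recs_c, model_spec("I", "FS", n_trees = 30, seed = 53))
  expect_equal(ev$n_folds, 10)
  expect_equal(ev$per_subject$predicted, rep(7, 10))
  expect_equal(ev$rmse, 0)
})

test_that("LOSO excludes subjects without targets, never leaks held-out rows", {
  co <- generate_training_cohort(8, 2, seed = 61)
  recs <- samples_from_cohort(co, seed = 62)
  recs[[1]]$fs_measured <- NA
  expect_warning(ev <- loso_evaluate(recs,
                                     model_spec("I", "FS", n_trees = 30,
                                                seed = 63)),
                 "excluded")
  expect_equal(ev$n_folds, 9)

  # leak test: perturbing a subject's own target must not move its own
  # prediction (its rows never enter its fold's training set)
  recs2 <- samples_from_cohort(co, seed = 62)
  sp <- model_spec("I", "FS", n_trees = 30, seed = 64)
  ev_a <- loso_evaluate(recs2, sp)
  recs3 <- recs2
  recs3[[4]]$fs_measured <- recs3[[4]]$fs_measured + 1000
  ev_b <- loso_evaluate(recs3, sp)
  expect_equal(ev_a$per_subject$predicted[4], ev_b$per_subject$predicted[4])
})

test_that("LOSO recovers a pure function of ONL at zero noise (n = 60)", {
  co <- generate_training_cohort(56, 4, noise_fs_sd = 0, noise_va_sd = 0,
                                 seed = 71)
  recs <- samples_from_cohort(co, thickness_noise_sd = 1, seed = 72)
  ev <- loso_evaluate(recs, model_spec("I", "FS", n_trees = 150, seed = 73))
  expect_equal(ev$n_folds, 60)
  expect_lte(ev$rmse, 0.2 * sd(ev$per_subject$measured))
})

test_that("train_final + predict_subject: determinism, range property, contracts", {
  co <- generate_training_cohort(8, 2, seed = 81)
  recs <- samples_from_cohort(co, seed = 82)
  sp <- model_spec("I", "FS", n_trees = 50, seed = 83)
  ev <- loso_evaluate(recs, sp)
  m1 <- train_final(recs, sp, ev)
  m2 <- train_final(recs, sp, ev)
  p1 <- predict_subject(m1, recs[[2]]$samples)
  expect_identical(p1$value, predict_subject(m2, recs[[2]]$samples)$value)
  expect_equal(p1$half_width, 1.96 * ev$rmse)

  # forest predictions bounded by the training-target range
  set.seed(84)
  for (k in 1:20) {
    s <- recs[[sample(10, 1)]]$samples
    s$onl <- s$onl * runif(1, 0, 3)
    s$cos_len <- s$cos_len * runif(1, 0, 3)
    v <- predict_subject(m1, s)$value
    expect_gte(v, m1$target_range[1])
    expect_lte(v, m1$target_range[2])
  }

  expect_error(predict_subject(m1, recs[[1]]$samples[1:14, ]), "21")
  expect_error(train_final(recs[1], sp), "fewer than 2")
  recs_na <- recs; recs_na[[2]]$fs_measured <- NA
  expect_error(train_final(recs_na, sp), "rejected")

  # rmse-free training for replicate studies
  m3 <- train_final(recs, sp, evaluation = NA)
  expect_true(is.na(m3$rmse))
  expect_true(is.finite(predict_subject(m3, recs[[1]]$samples)$value))
})
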