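test_that("curation levels map to data-quality probabilities", {
  expect_equal(curation_probability(c("expert", "intermediate",
                                      "autocuration")),
               c(1, 0.75, 0.5))
  expect_error(curation_probability("manual"), "manual",
               class = "alma_data_error")
})

test_that("condition statistics average theta5 over active records only", {
  st <- condition_stats(toy_records(), toy_descriptors())
  sx <- st[st$condition_class == "sx", ]
  expect_equal(sx$n, 4L)
  expect_equal(sx$n1, 2L)
  expect_equal(sx$p1, 0.5)
  expect_equal(sx$mean_theta5, 2)   # mean of active theta5 = (1 + 3) / 2
  expect_equal(sx$ma_value, 1)      # 0.5 * 2

  # single active record
  rec1 <- toy_records()[2, ]
  st1 <- condition_stats(rec1, toy_descriptors())
  expect_true(all(st1$n == 1L & st1$n1 == 1L & st1$p1 == 1))
  expect_true(all(st1$ma_value == 3))

  # no active records in a condition: zeroed statistics
  rec0 <- toy_records()
  rec0$label <- 0L
  st0 <- condition_stats(rec0, toy_descriptors())
  expect_true(all(st0$p1 == 0 & st0$mean_theta5 == 0 & st0$ma_value == 0))
})

test_that("missing descriptors raise a keyed error", {
  expect_error(
    condition_stats(toy_records(), toy_descriptors()[-2, ]),
    "c2", class = "alma_data_error")
})

test_that("statistics satisfy the exact decomposition identities", {
  cfg <- small_config(seed = 11L)
  sim <- generate_endpoints(cfg)
  st <- condition_stats(sim$records, sim$descriptors)
  expect_equal(st$p1, st$n1 / st$n, tolerance = 0)
  expect_equal(st$ma_value, st$p1 * st$mean_theta5, tolerance = 0)
  expect_true(all(st$n1 <= st$n))
  expect_true(all(st$mean_theta5 >= 0))
})

test_that("published condition priors are reproduced from their counts", {
  pub <- utils::read.csv(extdata("published_condition_priors.csv"),
                         colClasses = "character")
  p1 <- as.integer(pub$n1) / as.integer(pub$n)
  expect_equal(round(p1, 2), as.numeric(pub$p1_printed))
})

test_that("moving-average features are quality term plus deviations", {
  rec <- toy_records()[1, ]
  desc <- data.frame(compound_id = "c1", theta5 = 1)
  f <- ma_features(rec, desc, toy_stats())
  expect_equal(unlist(f, use.names = FALSE), c(1, 0, 0, 0, 0))

  desc0 <- data.frame(compound_id = "c1", theta5 = 0)
  f0 <- ma_features(rec, desc0, toy_stats(c(sx = 2.03, au = 1.88,
                                            ot = 1.82, te = 1.30)))
  expect_equal(unlist(f0, use.names = FALSE),
               c(0, -2.03, -1.88, -1.82, -1.30))

  rec75 <- rec
  rec75$curation_level <- "intermediate"
  desc25 <- data.frame(compound_id = "c1", theta5 = 2.5)
  f25 <- ma_features(rec75, desc25, toy_stats(c(sx = 2.03, au = 1.88,
                                                ot = 1.82, te = 1.30)))
  expect_equal(unlist(f25, use.names = FALSE),
               c(1.875, 0.47, 0.62, 0.68, 1.20))
})

test_that("unseen conditions error in strict mode, fall back in lenient", {
  rec <- toy_records()[1, ]
  rec$assay_id <- "A999"
  desc <- data.frame(compound_id = "c1", theta5 = 2)
  st <- toy_stats(c(sx = 1, au = 1.5, ot = 1, te = 1))
  expect_error(ma_features(rec, desc, st), "A999",
               class = "alma_data_error")
  f <- ma_features(rec, desc, st, strict = FALSE)
  # the global active-set value of the au class equals its only entry
  expect_equal(f$dev_au, 2 - 1.5)
})

test_that("the reference scorer is the printed affine function", {
  m <- reference_model()
  zero <- data.frame(quality = 0, dev_sx = 0, dev_au = 0, dev_ot = 0,
                     dev_te = 0)
  expect_identical(alma_score(m, zero), 1.139556)
  one_q <- zero; one_q$quality <- 1
  expect_equal(alma_score(m, one_q), 1.139556 - 0.403994,
               tolerance = 1e-15)
  flat <- alma_model(2.5, c(quality = 0, sx = 0, au = 0, ot = 0, te = 0))
  rand <- data.frame(quality = rnorm(3), dev_sx = rnorm(3),
                     dev_au = rnorm(3), dev_ot = rnorm(3),
                     dev_te = rnorm(3))
  expect_equal(alma_score(flat, rand), rep(2.5, 3))
})

test_that("score is affine in the features", {
  set.seed(4)
  m <- reference_model()
  mk <- function(x) as.data.frame(as.list(stats::setNames(
    x, c("quality", "dev_sx", "dev_au", "dev_ot", "dev_te"))))
  for (i in 1:5) {
    f <- rnorm(5); g <- rnorm(5); a <- runif(1)
    expect_equal(alma_score(m, mk(a * f + (1 - a) * g)),
                 a * alma_score(m, mk(f)) + (1 - a) * alma_score(m, mk(g)),
                 tolerance = 1e-12)
  }
})

test_that("the probability link is monotone, symmetric and saturating", {
  m <- reference_model()
  s <- seq(-4, 4, by = 0.5)
  p <- alma_probability(m, s)
  expect_true(all(diff(p) > 0))
  expect_equal(p + rev(p), rep(1, length(p)), tolerance = 1e-12)
  expect_gt(alma_probability(m, 40), 1 - 1e-12)
  expect_lt(alma_probability(m, -40), 1e-12)
})

test_that("classification uses a strict cutoff", {
  m <- reference_model()
  expect_equal(alma_classify(m, c(0.49, 0.5, 0.51)), c(0L, 0L, 1L))
})

test_that("the fitted discriminant separates planted classes", {
  set.seed(42)
  n <- 400
  X <- data.frame(quality = rnorm(n), dev_sx = rnorm(n),
                  dev_au = rnorm(n), dev_ot = rnorm(n),
                  dev_te = rnorm(n))
  y <- as.integer(X$dev_au + rnorm(n, sd = 0.3) > 0)
  fit <- fit_alma_lda(X, y)
  expect_gt(fit$coef["au"], 0)
  expect_gt(abs(fit$coef["au"]), max(abs(fit$coef[c("sx", "ot", "te")])))
  # decision boundary sits at posterior one half
  expect_equal(alma_probability(fit, 0), 0.5)
  # training accuracy is high on this easy problem
  p <- alma_probability(fit, alma_score(fit, X))
  expect_gt(mean((p > 0.5) == (y == 1)), 0.85)
})

test_that("null features yield a near-zero canonical correlation", {
  set.seed(7)
  n <- 2000
  X <- data.frame(quality = rnorm(n), dev_sx = rnorm(n),
                  dev_au = rnorm(n), dev_ot = rnorm(n),
                  dev_te = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_alma_lda(X, y)
  expect_lt(abs(fit$meta$Rc), 0.1)
})

test_that("the closed-form discriminant direction matches MASS::lda", {
  set.seed(9)
  n <- 300
  X <- data.frame(quality = rnorm(n), dev_sx = rnorm(n),
                  dev_au = rnorm(n), dev_ot = rnorm(n),
                  dev_te = rnorm(n))
  y <- as.integer(0.8 * X$quality - 0.5 * X$dev_sx + rnorm(n) > 0)
  fit <- fit_alma_lda(X, y)
  ref <- MASS::lda(as.matrix(X), grouping = y)
  expect_equal(abs(cosine_sim(fit$coef, ref$scaling[, 1])), 1,
               tolerance = 1e-8)
})

test_that("degenerate fits are rejected with clear errors", {
  X <- data.frame(quality = rnorm(10), dev_sx = rnorm(10),
                  dev_au = rnorm(10), dev_ot = rnorm(10),
                  dev_te = rnorm(10))
  expect_error(fit_alma_lda(X, rep(1L, 10)), class = "alma_domain_error")
  expect_error(fit_alma_lda(X[1:4, ], c(0L, 1L, 0L, 1L)),
               class = "alma_domain_error")
  # perfectly collinear features give a singular pooled covariance
  Xs <- X; Xs$dev_te <- Xs$dev_ot
  y <- rep(c(0L, 1L), 5)
  expect_error(fit_alma_lda(Xs, y), class = "alma_numerical_error")
  expect_s3_class(fit_alma_lda(Xs, y, ridge = 1e-6), "alma_model")
})

test_that("predictions depend on the condition set, not just the compound", {
  desc <- data.frame(compound_id = "c1", theta5 = 2)
  rec <- toy_records()[c(1, 1), ]
  rec$target_id <- c("T1", "T2")
  rec$label <- NA_integer_
  st <- rbind(toy_stats(c(sx = 1, au = 1, ot = 1, te = 0.5)),
              toy_stats(c(te = 1.9), values = c(te = "T2")))
  pred <- predict_table(reference_model(), rec, desc, st)
  expect_equal(nrow(pred), 2L)
  expect_false(pred$score[1] == pred$score[2])
  # all-zero features map above the midpoint under the reference model
  zero_rec <- toy_records()[1, ]
  zdesc <- data.frame(compound_id = "c1", theta5 = 0)
  zstat <- toy_stats(c(sx = 0, au = 0, ot = 0, te = 0))
  zstat$p1 <- 0; zstat$mean_theta5 <- 0
  zp <- predict_table(reference_model(), zero_rec, zdesc, zstat)
  expect_gt(zp$prob, 0.5)
  expect_equal(zp$label_pred, 1L)
})

test_that("predicting an empty record table returns an empty table", {
  pred <- predict_table(reference_model(), toy_records()[0, ],
                        toy_descriptors(), toy_stats())
  expect_equal(nrow(pred), 0L)
  expect_true(all(c("score", "prob", "label_pred") %in% names(pred)))
})

test_that("fit then predict on the training table keeps every record", {
  cfg <- small_config(seed = 5L)
  sim <- generate_endpoints(cfg)
  st <- condition_stats(sim$records, sim$descriptors)
  feats <- ma_features(sim$records, sim$descriptors, st)
  fit <- fit_alma_lda(feats, sim$records$label)
  pred <- predict_table(fit, sim$records, sim$descriptors, st)
  cs <- confusion_summary(pred$label, pred$label_pred)
  expect_equal(cs$n, nrow(sim$records))
  expect_equal(sum(cs$counts), nrow(sim$records))
})
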