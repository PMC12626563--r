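test_that("deformation score matches the published logistic form", {
  # all standardized inputs at the reference mean
  p0 <- predict_risk(builtin_model("rs_deform"),
                     data.frame(R_std = 0, D_max = 0, D_std = 0, D_ratio = 0))
  expect_equal(as.numeric(p0), 1 / (1 + exp(1.098)), tolerance = 1e-12)
  expect_equal(round(as.numeric(p0), 4), 0.2501)

  # the product-ratio coefficient is positive: score increases with Dratio
  ds <- rs_deform(0, 0, 0, c(0.5, 1, 2, 4))
  expect_true(all(diff(ds) > 0))

  # logistic limits
  expect_lt(rs_deform(-40, 40, 40, -40), 1e-10)

  # missing ratio imputed as the neutral value with a warning
  expect_warning(pim <- rs_deform(0, 0, 0, NA), "imputed")
  expect_equal(as.numeric(pim), as.numeric(rs_deform(0, 0, 0, 1)))
  expect_error(rs_deform(Inf, 0, 0, 1), "finite")
})

test_that("tumor morphology score matches the published logistic form", {
  p <- rs_tumor(1, 1)
  expect_equal(as.numeric(p), 1 / (1 + exp(1.207)), tolerance = 1e-12)
  expect_equal(round(as.numeric(p), 4), 0.2302)
  # less spherical -> higher risk; flatter -> risk approaches 1
  ps <- rs_tumor(1.2, c(0.9, 0.7, 0.5))
  expect_true(all(diff(ps) > 0))
  expect_gt(rs_tumor(10, 1), 1 - 1e-10)
  expect_error(rs_tumor(0.8, 0.5), "T_flat")
  expect_error(rs_tumor(1.2, 1.5), "T_sphere")
})

test_that("model specs round-trip through JSON", {
  m <- risk_score_model("demo", c("a", "b"), 0.5, c(1.25, -2),
                        standardization = list(a = list(mean = 3, sd = 2)),
                        vessel_class = "vein")
  path <- file.path(tempdir(), "m.json")
  write_model_spec(m, path)
  m2 <- read_model_spec(path)
  expect_equal(m2$betas, m$betas)
  expect_equal(m2$beta0, m$beta0)
  expect_equal(m2$standardization$a$sd, 2)
  x <- data.frame(a = c(3, 5), b = c(0, 1))
  expect_equal(predict_risk(m2, x), predict_risk(m, x))
})

test_that("the Fisher score follows its closed form and invariances", {
  expect_equal(fisher_score(c(0, 1, 2, 3), c(0, 0, 1, 1)), 8)
  expect_equal(fisher_score(c(1, 3, 1, 3), c(0, 0, 1, 1)), 0)
  x <- rnorm(40); y <- rep(c(0, 1), 20)
  expect_equal(fisher_score(5 * x - 2, y), fisher_score(x, y),
               tolerance = 1e-9)
  expect_identical(fisher_score(c(1, 1, 2, 2), c(0, 0, 1, 1)), Inf)
  expect_identical(fisher_score(c(1, 1, 1, 1), c(0, 0, 1, 1)), 0)
  expect_error(fisher_score(1:4, c(1, 1, 1, 1)), "class")
})

test_that("logistic fits reproduce the closed-form 2x2 solution", {
  x <- c(rep(1, 30), rep(0, 45))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 5), rep(0, 40))
  f <- fit_logistic_wald(data.frame(x = x), y)
  expect_equal(f$stats$estimate[2], log(16), tolerance = 1e-6)
  expect_equal(f$stats$estimate[1], log(5 / 40), tolerance = 1e-6)
  expect_equal(f$stats$or[2], 16, tolerance = 1e-5)
  expect_error(fit_logistic_wald(data.frame(x = x), rep(1, 75)), "class")
  # perfectly separable data raise a flagged, non-fatal warning
  xs <- rep(c(0, 1), each = 15)
  ys <- xs
  expect_warning(fs <- fit_logistic_wald(data.frame(x = xs), ys),
                 "separation")
  expect_true(is.finite(fs$stats$estimate[2]))
})

test_that("Wald p-values are calibrated under the null", {
  set.seed(101)
  rej <- 0
  for (r in 1:500) {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, 0.3)
    f <- suppressWarnings(fit_logistic_wald(data.frame(x = x), y))
    if (f$stats$p[2] < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 500, 0.03)
  expect_lte(rej / 500, 0.07)
})

test_that("AUC equals exhaustive pair counting and handles ties", {
  ev <- evaluate_classifier(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(ev$auc["est"]), 1)
  expect_equal(unname(ev$sensitivity["est"]), 1)
  expect_equal(unname(ev$specificity["est"]), 1)

  expect_equal(unname(
    evaluate_classifier(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc["est"]),
    0.75)
  expect_equal(unname(
    evaluate_classifier(rep(0.4, 10), rep(c(0, 1), 5))$auc["est"]), 0.5)

  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:200, 1)
    s <- round(runif(n), 2)            # coarse scores force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(unname(evaluate_classifier(s, y)$auc["est"]),
                 pair_auc(s, y), tolerance = 1e-12)
  }
})

test_that("Youden cutoff ties resolve toward the lower threshold", {
  s <- c(0.1, 0.4, 0.6, 0.9)
  y <- c(0, 1, 0, 1)
  # J is maximal (0.5) at cutoffs 0.4 and 0.9 -> pick 0.4 (sensitivity first)
  ev <- evaluate_classifier(s, y)
  expect_equal(ev$cutoff, 0.4)
  expect_equal(unname(ev$sensitivity["est"]), 1)
})

test_that("AUC confidence intervals agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- runif(120); y <- rbinom(120, 1, plogis(3 * s - 1.5))
  ev <- evaluate_classifier(s, y)
  ref <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE), method = "delong")
  expect_equal(unname(ev$auc["est"]), as.numeric(ref[2]), tolerance = 1e-9)
  expect_equal(unname(ev$auc["lo"]), as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(unname(ev$auc["hi"]), as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("paired comparisons: DeLong, McNemar and kappa", {
  set.seed(9)
  y <- rbinom(80, 1, 0.4)
  s <- runif(80)
  idd <- compare_classifiers(s, s, y, predsA = s > 0.5, predsB = s > 0.5)
  expect_equal(idd$delong$z, 0)
  expect_equal(idd$delong$p, 1)
  expect_equal(idd$mcnemar$p, 1)
  expect_equal(idd$kappa, 1)

  # continuity-corrected chi-square at b=10, c=2 ... requires b+c >= 25,
  # so check the printed formula directly at b=30, c=12 and the b=10, c=2
  # exact variant against binomial tails
  mc <- mcnemar_test(30, 12)
  expect_equal(mc$statistic, (abs(30 - 12) - 1)^2 / 42, tolerance = 1e-12)
  for (b in c(0, 2, 5, 10)) {
    for (cc in c(1, 3, 10)) {
      if (b + cc > 20) next
      got <- mcnemar_test(b, cc)$p
      expect_equal(got, min(1, 2 * pbinom(min(b, cc), b + cc, 0.5)),
                   tolerance = 1e-12)
    }
  }

  # agreement table a=40 b=5 c=10 d=45 -> kappa 0.70
  a1 <- c(rep(1, 45), rep(0, 55))
  a2 <- c(rep(1, 40), rep(0, 5), rep(1, 10), rep(0, 45))
  expect_equal(cohens_kappa(a1, a2), 0.7, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  s2 <- pmin(1, pmax(0, s + rnorm(80, 0, 0.2)))
  dl <- delong_test(s, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(dl$p, as.numeric(ref$p.value), tolerance = 1e-6)
})

test_that("continuity-corrected McNemar matches the 12-pair worked example", {
  # (|10-2|-1)^2/12 printed form of the corrected statistic
  expect_equal((abs(10 - 2) - 1)^2 / 12, 4.0833, tolerance = 1e-4)
  # our implementation switches to the exact test below 25 discordant pairs
  expect_identical(mcnemar_test(10, 2)$method, "exact")
})

test_that("calibration and decision curves follow their closed forms", {
  # group-exact calibration -> zero statistic
  probs <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  y <- as.vector(vapply(seq(0.05, 0.95, by = 0.1),
                        function(p) rep(c(1, 0), c(round(20 * p),
                                                   20 - round(20 * p))),
                        numeric(20)))
  # make predicted group means equal observed rates exactly
  probs <- rep(vapply(split(y, rep(1:10, each = 20)), mean, numeric(1)),
               each = 20)
  probs <- pmin(0.99, pmax(0.01, probs + rep(seq(-1e-6, 1e-6,
                                                 length.out = 20), 10)))
  cd <- calibration_and_dca(probs, y)
  expect_lt(cd$hosmer_lemeshow$statistic, 1e-3)
  expect_equal(cd$hosmer_lemeshow$df, 8)

  # treat-all net benefit: pi - (1-pi) t/(1-t); pi = 0.25, t = 0.5 -> -0.5
  set.seed(3)
  p2 <- runif(400, 0.01, 0.99)
  y2 <- rep(c(1, 0), c(100, 300))
  cd2 <- calibration_and_dca(p2, y2, thresholds = 0.5)
  expect_equal(cd2$dca$treat_all, -0.5)
  expect_equal(cd2$dca$treat_none, 0)
  tp <- sum(p2 >= 0.5 & y2 == 1); fp <- sum(p2 >= 0.5 & y2 == 0)
  expect_equal(cd2$dca$net_benefit, tp / 400 - fp / 400)

  expect_error(calibration_and_dca(rep(0.5, 50), rbinom(50, 1, 0.5)),
               "distinct")
})

test_that("well-calibrated fitted models pass Hosmer-Lemeshow", {
  ok <- 0
  for (r in 1:200) {
    set.seed(r)
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-0.5 + 0.8 * x))
    fit <- glm(y ~ x, family = binomial())
    cd <- calibration_and_dca(fitted(fit), y)
    if (cd$hosmer_lemeshow$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok / 200, 0.9)
})

test_that("nomograms span 100 points and invert exactly", {
  m <- risk_score_model("demo", c("a", "b", "c"), -1, c(2, -0.5, 0))
  ranges <- list(a = c(0, 10), b = c(-5, 5), c = c(0, 100))
  nomo <- nomogram_points(m, ranges)
  expect_equal(max(nomo$tables$a$points), 100)     # largest |beta * range|
  expect_true(all(nomo$tables$c$points == 0))      # zero coefficient
  expect_true(all(diff(nomo$tables$a$points) > 0))
  set.seed(21)
  for (i in 1:100) {
    v <- list(a = runif(1, 0, 10), b = runif(1, -5, 5), c = runif(1, 0, 100))
    np <- nomogram_predict(nomo, v)
    direct <- predict_risk(m, as.data.frame(v))
    expect_equal(np$probability, as.numeric(direct), tolerance = 1e-6)
  }
  expect_error(nomogram_points(m, list(a = c(1, 1), b = c(2, 2),
                                       c = c(3, 3))), "zero")
})

test_that("vein models carry the deformation score; artery models do not", {
  expect_identical(vessel_model_features("SMA"),
                   c("theta_encase_deg", "RStumor"))
  expect_identical(vessel_model_features("PV"),
                   c("theta_encase_deg", "RStumor", "RSdeform"))
  set.seed(31)
  n <- 120
  tbl <- do.call(rbind, lapply(VESSEL_NAMES, function(vn) {
    data.frame(vessel = vn, theta_encase_deg = runif(n, 0, 360),
               RStumor = runif(n), RSdeform = runif(n))
  }))
  tbl$involved <- rbinom(nrow(tbl), 1,
                         plogis(0.01 * tbl$theta_encase_deg - 2))
  fits <- fit_vessel_models(tbl)
  expect_identical(sort(names(fits)), sort(VESSEL_NAMES))
  for (vn in VESSEL_NAMES) {
    expect_identical(fits[[vn]]$model$feature_names,
                     vessel_model_features(vn))
  }
  tbl2 <- tbl
  tbl2$involved[tbl2$vessel == "CA"] <- 0
  expect_warning(f2 <- fit_vessel_models(tbl2), "single-class")
  expect_false("CA" %in% names(f2))
})

test_that("feature selection ranks informative features first", {
  set.seed(12)
  n <- 400
  X <- data.frame(good = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$good))
  sel <- select_features(X, y, top_k = 2)
  expect_identical(sel$ranking$feature[1], "good")
  expect_true("good" %in% sel$selected)
})
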