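#' Logistic risk score model
#'
#' A named logistic model: intercept, coefficients aligned to feature names,
#' and optional per-feature standardization (reference mean and sd applied to
#' inputs before the linear predictor).
#'
#' @param name model name (e.g. `"RSdeform"`, `"RStumor"`).
#' @param feature_names ordered character vector of features.
#' @param beta0 intercept.
#' @param betas coefficients, same length/order as `feature_names`.
#' @param standardization optional named list `feature -> list(mean, sd)`;
#'   sds must be positive.
#' @param vessel_class optional `"artery"` or `"vein"` tag.
#' @return object of class `risk_score_model`.
#' @export
risk_score_model <- function(name, feature_names, beta0, betas,
                             standardization = NULL, vessel_class = NULL) {
  stopifnot(length(betas) == length(feature_names),
            is.finite(beta0), all(is.finite(betas)))
  if (!is.null(standardization)) {
    stopifnot(all(names(standardization) %in% feature_names))
    for (st in standardization) stopifnot(st$sd > 0)
  }
  m <- list(name = name, feature_names = feature_names,
            beta0 = as.numeric(beta0),
            betas = setNames(as.numeric(betas), feature_names),
            standardization = standardization,
            vessel_class = vessel_class)
  class(m) <- "risk_score_model"
  m
}

#' @export
print.risk_score_model <- function(x, ...) {
  cat("risk_score_model", x$name, "\n  logit(p) =", signif(x$beta0, 5))
  for (f in x$feature_names)
    cat(sprintf(" %+g*%s", signif(x$betas[[f]], 5), f))
  cat("\n")
  if (!is.null(x$standardization)) cat("  (standardized inputs)\n")
  invisible(x)
}

#' Read / write a model specification JSON
#' @param path JSON file path.
#' @return a [risk_score_model()] (for `read_model_spec`).
#' @export
read_model_spec <- function(path) {
  j <- jsonlite::read_json(path)
  std <- NULL
  if (!is.null(j$standardization)) {
    std <- lapply(j$standardization, function(s)
      list(mean = s$mean, sd = s$sd))
  }
  risk_score_model(j$name, unlist(j$feature_names), j$beta0,
                   unlist(j$betas), std, j$vessel_class)
}

#' @rdname read_model_spec
#' @param model a [risk_score_model()].
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "risk_score_model"))
  jsonlite::write_json(
    list(name = model$name, feature_names = model$feature_names,
         beta0 = model$beta0, betas = unname(model$betas),
         standardization = model$standardization,
         vessel_class = model$vessel_class),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Built-in published risk score models
#'
#' `"rs_deform"`: vascular deformation score over standardized `R_std`,
#' `D_max`, `D_std`, `D_ratio` (intercept -1.098; coefficients 0.663, -1.086,
#' -0.745, 2.395).  `"rs_tumor"`: tumor morphology score over raw `T_flat`,
#' `T_sphere` (intercept 1.526; coefficients 7.093, -9.826).
#'
#' @param which `"rs_deform"` or `"rs_tumor"`.
#' @return a [risk_score_model()].
#' @export
builtin_model <- function(which = c("rs_deform", "rs_tumor")) {
  which <- match.arg(which)
  path <- system.file("extdata", "models", paste0(which, ".json"),
                      package = "pancvas")
  if (!nzchar(path)) stop("built-in model file not found")
  read_model_spec(path)
}

#' Evaluate a risk score model
#'
#' Applies per-feature standardization (when the model carries it), then the
#' logistic of the linear predictor.  A missing `D_ratio` (undefined ratio,
#' e.g. when the whole skeleton is tumor-proximal) is imputed as the neutral
#' ratio 1.0 before standardization; the result then carries an `imputed`
#' attribute and a warning is raised.
#'
#' @param model a [risk_score_model()].
#' @param newdata data.frame (or named list) holding the model features;
#'   vectors are recycled to equal length.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "risk_score_model"))
  newdata <- as.data.frame(as.list(newdata)[model$feature_names])
  miss <- setdiff(model$feature_names, names(newdata))
  if (length(miss)) stop("missing model feature(s): ",
                         paste(miss, collapse = ", "))
  imputed <- FALSE
  lp <- rep(model$beta0, nrow(newdata))
  for (f in model$feature_names) {
    x <- as.numeric(newdata[[f]])
    if (f == "D_ratio" && anyNA(x)) {
      x[is.na(x)] <- 1.0
      imputed <- TRUE
      warning("missing D_ratio imputed as 1.0")
    }
    if (any(!is.finite(x))) stop("non-finite value for feature ", f)
    st <- model$standardization[[f]]
    if (!is.null(st)) x <- (x - st$mean) / st$sd
    lp <- lp + model$betas[[f]] * x
  }
  p <- stats::plogis(lp)
  if (imputed) attr(p, "imputed") <- TRUE
  p
}

#' Vascular deformation risk score
#'
#' Logistic score over the four deformation features (radius standard
#' deviation, maximum and standard deviation of the radius-distance product,
#' and the radius-distance product ratio).  With the built-in published
#' model, inputs are standardized against the model's reference scale.
#'
#' @param Rstd,Dmax,Dstd,Dratio feature values (vectors recycle); `Dratio`
#'   may be `NA` (imputed as 1.0 with a warning).
#' @param model scoring model (default: built-in published coefficients).
#' @return probabilities in (0, 1).
#' @export
rs_deform <- function(Rstd, Dmax, Dstd, Dratio,
                      model = builtin_model("rs_deform")) {
  predict_risk(model, data.frame(R_std = Rstd, D_max = Dmax,
                                 D_std = Dstd, D_ratio = Dratio))
}

#' Tumor morphology risk score
#'
#' Logistic score over tumor flatness (major/medium axis ratio, >= 1) and
#' sphericity, on their natural scales.  Flatter, less spherical tumors score
#' higher.  Sphericity slightly above 1 (up to the mesh tolerance 1.02 that
#' discrete surface estimation can produce) is accepted.
#'
#' @param Tflat flatness values, >= 1.
#' @param Tsphere sphericity values in (0, 1.02].
#' @param model scoring model (default: built-in published coefficients).
#' @return probabilities in (0, 1).
#' @export
rs_tumor <- function(Tflat, Tsphere, model = builtin_model("rs_tumor")) {
  if (any(!is.finite(Tflat)) || any(Tflat < 1))
    stop("T_flat must be finite and >= 1")
  if (any(!is.finite(Tsphere)) || any(Tsphere <= 0) || any(Tsphere > 1.02))
    stop("T_sphere must lie in (0, 1.02]")
  predict_risk(model, data.frame(T_flat = Tflat, T_sphere = Tsphere))
}

#' Fisher score of a feature against a binary label
#'
#' `(mu1 - mu0)^2 / (sigma1^2 + sigma0^2)` with population variances.  Equal
#' degenerate classes give 0; degenerate classes with different means give
#' `Inf`.
#'
#' @param values numeric vector.
#' @param labels binary vector (0/1 or logical), both classes present.
#' @return non-negative score (possibly `Inf`).
#' @export
fisher_score <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  x0 <- values[labels == 0]; x1 <- values[labels == 1]
  v0 <- mean((x0 - mean(x0))^2); v1 <- mean((x1 - mean(x1))^2)
  num <- (mean(x1) - mean(x0))^2
  if (v0 + v1 == 0) return(if (num == 0) 0 else Inf)
  num / (v0 + v1)
}

#' Fit a logistic model with Wald statistics
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], tight convergence tolerance, at most 100
#' iterations) with per-coefficient Wald z, p-values, odds ratios and 95%
#' Wald confidence intervals.  Coefficients larger than 15 in absolute value
#' trigger a (non-fatal) complete-separation warning.
#'
#' @param X numeric matrix or data.frame of predictors.
#' @param y binary outcome vector, both classes present.
#' @param name model name stored on the result.
#' @return list with `model` (a [risk_score_model()]) and `stats`
#'   (data.frame: term, estimate, se, z, p, or, or_lo, or_hi).
#' @export
fit_logistic_wald <- function(X, y, name = "fit") {
  X <- as.data.frame(X)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (nrow(X) <= ncol(X) + 1) stop("need n > number of features + 1")
  dat <- cbind(X, .y = y)
  # glm's own saturation warning is folded into the separation check below
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  separated <- any(abs(b) > 15)
  if (!fit$converged && !separated)
    stop("IRLS did not converge in ", fit$iter, " iterations")
  se <- sqrt(diag(vcov(fit)))
  if (separated)
    warning("possible complete separation: |coefficient| > 15")
  z <- b / se
  stats <- data.frame(term = names(b), estimate = unname(b),
                      se = unname(se), z = unname(z),
                      p = unname(2 * pnorm(-abs(z))),
                      or = unname(exp(b)),
                      or_lo = unname(exp(b - 1.96 * se)),
                      or_hi = unname(exp(b + 1.96 * se)),
                      row.names = NULL)
  model <- risk_score_model(name, names(b)[-1], b[[1]], b[-1])
  list(model = model, stats = stats, glm = fit)
}

#' Rank features by Fisher score and filter by univariable Wald tests
#'
#' The selection pipeline: rank candidate features by Fisher score, keep the
#' top `top_k`, then retain those with univariable Wald p < `alpha`; features
#' in `always_keep` are retained regardless.
#'
#' @param X data.frame of candidate features.
#' @param y binary outcome.
#' @param top_k number of top-ranked features to carry forward.
#' @param alpha Wald significance threshold (default 0.05).
#' @param always_keep features exempt from the p-value filter.
#' @return list with `selected` (character), and a `ranking` data.frame.
#' @export
select_features <- function(X, y, top_k = 4, alpha = 0.05,
                            always_keep = character()) {
  X <- as.data.frame(X)
  fs <- vapply(X, fisher_score, numeric(1), labels = y)
  ranking <- data.frame(feature = names(fs), fisher = unname(fs))
  ranking <- ranking[order(-ranking$fisher), ]
  top <- utils::head(ranking$feature, top_k)
  pvals <- vapply(top, function(f) {
    fit <- fit_logistic_wald(X[, f, drop = FALSE], y)
    fit$stats$p[2]
  }, numeric(1))
  ranking$wald_p <- NA_real_
  ranking$wald_p[match(top, ranking$feature)] <- pvals
  selected <- union(top[pvals < alpha], intersect(always_keep, names(X)))
  rownames(ranking) <- NULL
  list(selected = selected, ranking = ranking)
}

# --- ROC machinery ---------------------------------------------------------

# Mann-Whitney AUC with ties counted 1/2, via midranks.
auc_mw <- function(scores, y) {
  y <- as.logical(y)
  r <- rank(scores)
  m <- sum(y); n <- sum(!y)
  (sum(r[y]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement values: V10 (per positive), V01 (per negative).
delong_placements <- function(scores, y) {
  y <- as.logical(y)
  x <- scores[y]; z <- scores[!y]
  m <- length(x); n <- length(z)
  r_all <- rank(c(x, z))
  r_x <- rank(x); r_z <- rank(z)
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_z) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Evaluate a probabilistic classifier against binary outcomes
#'
#' AUC is the Mann-Whitney pair statistic (ties count 1/2) with a DeLong
#' 95% confidence interval.  The operating cutoff defaults to the
#' Youden-optimal threshold (positive when score >= cutoff; ties broken
#' toward the lower cutoff, favouring sensitivity).  Sensitivity,
#' specificity, PPV and NPV carry exact Clopper-Pearson 95% intervals.
#'
#' @param scores numeric prediction scores or probabilities.
#' @param y binary outcomes, both classes present.
#' @param cutoff optional fixed probability cutoff.
#' @return object of class `evaluation_report`: cutoff, 2x2 `confusion`
#'   matrix, per-metric estimates with CIs and counts, and `auc` with CI.
#' @export
evaluate_classifier <- function(scores, y, cutoff = NULL) {
  y <- as.logical(y)
  if (length(scores) != length(y)) stop("length mismatch")
  if (length(unique(y)) < 2) stop("outcomes have a single class")
  if (is.null(cutoff)) {
    cand <- sort(unique(scores))
    j <- vapply(cand, function(cc) {
      pred <- scores >= cc
      sum(pred & y) / sum(y) + sum(!pred & !y) / sum(!y) - 1
    }, numeric(1))
    cutoff <- cand[which(j >= max(j) - 1e-12)[1]]  # ties -> lower cutoff
  }
  pred <- scores >= cutoff
  tp <- sum(pred & y); fn <- sum(!pred & y)
  fp <- sum(pred & !y); tn <- sum(!pred & !y)
  prop <- function(k, n) {
    if (n == 0) return(c(est = NA, lo = NA, hi = NA, num = k, den = n))
    ci <- stats::binom.test(k, n)$conf.int
    c(est = k / n, lo = ci[1], hi = ci[2], num = k, den = n)
  }
  pl <- delong_placements(scores, y)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  auc <- pl$auc
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * sqrt(v)))
  out <- list(cutoff = cutoff,
              confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                                 dimnames = list(pred = c("pos", "neg"),
                                                 truth = c("pos", "neg"))),
              sensitivity = prop(tp, tp + fn),
              specificity = prop(tn, tn + fp),
              ppv = prop(tp, tp + fp),
              npv = prop(tn, tn + fn),
              auc = c(est = auc, lo = ci[1], hi = ci[2]),
              n = length(y))
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (n = %d, cutoff = %.4g)\n", x$n, x$cutoff))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %.2f (%d/%d) [%.2f, %.2f]\n", m, v["est"],
                v["num"], v["den"], v["lo"], v["hi"]))
  }
  cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", "auc", x$auc["est"],
              x$auc["lo"], x$auc["hi"]))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' @param scoresA,scoresB paired score vectors.
#' @param y shared binary outcomes.
#' @return list: `aucA`, `aucB`, `z`, `p`.
#' @export
delong_test <- function(scoresA, scoresB, y) {
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(y))
    stop("length mismatch")
  pa <- delong_placements(scoresA, y)
  pb <- delong_placements(scoresB, y)
  m <- length(pa$v10); n <- length(pa$v01)
  v <- (var(pa$v10) + var(pb$v10) - 2 * stats::cov(pa$v10, pb$v10)) / m +
       (var(pa$v01) + var(pb$v01) - 2 * stats::cov(pa$v01, pb$v01)) / n
  d <- pa$auc - pb$auc
  z <- if (v <= 1e-16) 0 else d / sqrt(v)
  list(aucA = pa$auc, aucB = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' McNemar test on discordant counts
#'
#' Exact binomial version when `b + c < 25`, otherwise the
#' continuity-corrected chi-square `(|b-c|-1)^2 / (b+c)`.
#'
#' @param b,c discordant pair counts.
#' @return list: `statistic` (`NA` for the exact test), `p`, `method`.
#' @export
mcnemar_test <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  nd <- b + c
  if (nd == 0) return(list(statistic = NA_real_, p = 1, method = "exact"))
  if (nd < 25) {
    p <- min(1, 2 * pbinom(min(b, c), nd, 0.5))
    list(statistic = NA_real_, p = p, method = "exact")
  } else {
    stat <- (abs(b - c) - 1)^2 / nd
    list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chi-squared with continuity correction")
  }
}

#' Cohen's kappa between two binary raters
#' @param a,b binary vectors of equal length.
#' @return kappa in [-1, 1].
#' @export
cohens_kappa <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Compare two paired classifiers
#'
#' DeLong test on the two score vectors against the shared outcomes, McNemar
#' test on the discordant predictions, and Cohen's kappa between the two
#' prediction vectors.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param y shared binary outcomes.
#' @param predsA,predsB binary predictions (default: scores dichotomized at
#'   each classifier's Youden cutoff).
#' @return list: `delong`, `mcnemar`, `kappa`.
#' @export
compare_classifiers <- function(scoresA, scoresB, y,
                                predsA = NULL, predsB = NULL) {
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(y))
    stop("length mismatch")
  if (is.null(predsA)) predsA <- scoresA >= evaluate_classifier(scoresA, y)$cutoff
  if (is.null(predsB)) predsB <- scoresB >= evaluate_classifier(scoresB, y)$cutoff
  predsA <- as.logical(predsA); predsB <- as.logical(predsB)
  b <- sum(predsA & !predsB)
  c <- sum(!predsA & predsB)
  list(delong = delong_test(scoresA, scoresB, y),
       mcnemar = mcnemar_test(b, c),
       kappa = cohens_kappa(predsA, predsB))
}

#' Calibration (Hosmer-Lemeshow) and decision-curve analysis
#'
#' Hosmer-Lemeshow chi-square over `n_groups` equal-count risk groups
#' (df = n_groups - 2), the calibration curve (mean predicted vs observed
#' rate per group), and the net-benefit curve
#' `NB(t) = TP/n - (FP/n) * t/(1-t)` with treat-all and treat-none
#' references.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param y binary outcomes.
#' @param n_groups number of risk groups (default 10).
#' @param thresholds threshold probabilities for the net-benefit curve.
#' @return list: `hosmer_lemeshow` (statistic, df, p), `calibration`
#'   (data.frame), `dca` (data.frame with model / treat-all / treat-none net
#'   benefit).
#' @export
calibration_and_dca <- function(probs, y, n_groups = 10,
                                thresholds = seq(0.05, 0.95, by = 0.05)) {
  y <- as.integer(as.logical(y))
  if (any(probs <= 0 | probs >= 1)) stop("probabilities must lie in (0, 1)")
  if (length(unique(probs)) < n_groups)
    stop("fewer distinct observations than groups")
  ord <- order(probs)
  gid <- integer(length(probs))
  gid[ord] <- ceiling(seq_along(ord) * n_groups / length(ord))
  obs <- tapply(y, gid, sum)
  expd <- tapply(probs, gid, sum)
  ng <- tapply(y, gid, length)
  stat <- sum((obs - expd)^2 / expd + ((ng - obs) - (ng - expd))^2 /
                pmax(ng - expd, .Machine$double.eps))
  df <- n_groups - 2
  calib <- data.frame(group = as.integer(names(obs)),
                      mean_predicted = as.numeric(expd / ng),
                      observed_rate = as.numeric(obs / ng),
                      n = as.integer(ng))
  nn <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(t) {
    pos <- probs >= t
    sum(pos & y == 1) / nn - sum(pos & y == 0) / nn * t / (1 - t)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  dca <- data.frame(threshold = thresholds, net_benefit = nb,
                    treat_all = nb_all, treat_none = 0)
  list(hosmer_lemeshow = list(statistic = stat, df = df,
                              p = pchisq(stat, df, lower.tail = FALSE)),
       calibration = calib, dca = dca)
}

#' Nomogram point table for a logistic model
#'
#' Maps each feature's value range onto a 0-100 point scale: the feature with
#' the largest absolute coefficient-times-range spans exactly 100 points, and
#' each feature's reference value is the range endpoint minimizing the linear
#' predictor.  The total-points axis maps back to predicted probability.
#'
#' @param model a [risk_score_model()] (standardization, if any, applies to
#'   the supplied ranges' scale).
#' @param feature_ranges named list of `c(lo, hi)` per model feature.
#' @param grid_n number of tabulated values per feature (default 11).
#' @return object of class `nomogram_table`: per-feature point tables,
#'   `points_per_unit`, reference values, and a total-points-to-probability
#'   map.
#' @export
nomogram_points <- function(model, feature_ranges, grid_n = 11) {
  stopifnot(inherits(model, "risk_score_model"))
  feats <- model$feature_names
  if (!all(feats %in% names(feature_ranges)))
    stop("feature_ranges must cover all model features")
  std <- function(f, v) {
    st <- model$standardization[[f]]
    if (is.null(st)) v else (v - st$mean) / st$sd
  }
  contrib <- vapply(feats, function(f) {
    r <- std(f, sort(as.numeric(feature_ranges[[f]])))
    abs(model$betas[[f]]) * (r[2] - r[1])
  }, numeric(1))
  if (all(contrib == 0)) stop("all features have zero point range")
  scale <- 100 / max(contrib)
  tabs <- list(); refs <- numeric(length(feats)); names(refs) <- feats
  lp_min <- model$beta0
  for (f in feats) {
    r <- sort(as.numeric(feature_ranges[[f]]))
    zr <- std(f, r)
    b <- model$betas[[f]]
    ref <- if (b >= 0) r[1] else r[2]
    refs[f] <- ref
    lp_min <- lp_min + b * std(f, ref)
    vals <- seq(r[1], r[2], length.out = grid_n)
    pts <- scale * abs(b) * abs(std(f, vals) - std(f, ref))
    tabs[[f]] <- data.frame(value = vals, points = pts)
  }
  total_max <- sum(vapply(tabs, function(t) max(t$points), numeric(1)))
  totals <- seq(0, max(total_max, 1e-12), length.out = 101)
  prob_map <- data.frame(total_points = totals,
                         probability = stats::plogis(lp_min + totals / scale))
  out <- list(tables = tabs, points_per_unit_lp = scale, reference = refs,
              lp_at_reference = lp_min, probability_map = prob_map,
              model = model)
  class(out) <- "nomogram_table"
  out
}

#' Points and probability for feature values under a nomogram
#' @param nomo a [nomogram_points()] table.
#' @param values named list/data.frame of feature values.
#' @return list: per-feature `points`, `total`, `probability`.
#' @export
nomogram_predict <- function(nomo, values) {
  stopifnot(inherits(nomo, "nomogram_table"))
  model <- nomo$model
  std <- function(f, v) {
    st <- model$standardization[[f]]
    if (is.null(st)) v else (v - st$mean) / st$sd
  }
  pts <- vapply(model$feature_names, function(f) {
    v <- as.numeric(values[[f]])
    nomo$points_per_unit_lp * abs(model$betas[[f]]) *
      abs(std(f, v) - std(f, nomo$reference[[f]]))
  }, numeric(1))
  total <- sum(pts)
  prob <- stats::plogis(nomo$lp_at_reference + total / nomo$points_per_unit_lp)
  list(points = pts, total = total, probability = prob)
}

#' Feature composition of a per-vessel involvement model
#'
#' Artery models use the encasement angle and the tumor morphology score;
#' vein models additionally include the vascular deformation score.
#'
#' @param vessel one of [VESSEL_NAMES].
#' @return character vector of feature column names.
#' @export
vessel_model_features <- function(vessel) {
  vessel <- match.arg(vessel, VESSEL_NAMES)
  if (VESSEL_CLASS[[vessel]] == "vein")
    c("theta_encase_deg", "RStumor", "RSdeform")
  else
    c("theta_encase_deg", "RStumor")
}

#' Fit per-vessel involvement models
#'
#' Fits one logistic model per vessel over [vessel_model_features()] (the
#' deformation score enters vein models only; the tumor morphology score is
#' always retained regardless of significance).  Vessels whose outcomes are
#' single-class are skipped with a warning.
#'
#' @param tbl data.frame with `vessel`, the feature columns, and the outcome.
#' @param outcome_col name of the binary outcome column.
#' @return named list of [fit_logistic_wald()] results.
#' @export
fit_vessel_models <- function(tbl, outcome_col = "involved") {
  stopifnot(all(c("vessel", outcome_col) %in% names(tbl)))
  out <- list()
  for (vn in intersect(VESSEL_NAMES, unique(tbl$vessel))) {
    sub <- tbl[tbl$vessel == vn, , drop = FALSE]
    feats <- vessel_model_features(vn)
    if (!all(feats %in% names(sub)))
      stop("missing feature column(s) for ", vn, ": ",
           paste(setdiff(feats, names(sub)), collapse = ", "))
    yy <- sub[[outcome_col]]
    if (length(unique(yy)) < 2) {
      warning("skipping ", vn, ": single-class outcomes")
      next
    }
    fit <- fit_logistic_wald(sub[, feats, drop = FALSE], yy,
                             name = paste0("involvement:", vn))
    stopifnot(identical(fit$model$feature_names, feats))
    out[[vn]] <- fit
  }
  out
}
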