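test_that("AUC matches brute-force pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 8), rep(c("R", "NR"), 4)), 0.5)
  scores <- c(0.9, 0.7, 0.5, 0.5, 0.3, 0.1) # one tie across classes
  labels <- c("R", "R", "R", "NR", "NR", "NR")
  expect_equal(roc_auc(scores, labels),
               auc_pair_counting(scores, labels == "R"))
  set.seed(2)
  for (i in 1:5) {
    s <- sample(1:6, 10, replace = TRUE) # heavy ties
    l <- rep(c("R", "NR"), 5)
    expect_equal(roc_auc(s, l), auc_pair_counting(s, l == "R"))
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1) # complement identity
  }
  expect_error(roc_auc(1:3, c("R", "R", "R")), "single class")
})

test_that("ROC curves average vertically on an FPR grid", {
  c1 <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("R", "R", "NR", "NR"))
  expect_equal(max(c1$tpr[c1$fpr == 0]), 1) # perfect curve hits (0, 1)
  c2 <- roc_curve(c(0.1, 0.2, 0.8, 0.9), c("R", "R", "NR", "NR"))
  avg <- average_roc(list(c1, c2), grid = c(0, 0.5, 1))
  expect_equal(avg$tpr, c((1 + 0) / 2, (1 + 0) / 2, 1))
})

test_that("group comparisons reproduce exact Wilcoxon results", {
  # completely separated groups of 5 vs 5: the minimal two-sided p
  out <- compare_groups(c(1:5, 11:15), rep(c("a", "b"), each = 5))
  expect_equal(out$p_value, 2 / choose(10, 5)) # 0.00793650...
  expect_equal(out$method, "wilcoxon_rank_sum")
  # identical groups: p = 1, effect ~ 0
  expect_warning(tied <- compare_groups(rep(2, 10), rep(c("a", "b"), 5)),
                 "tied")
  expect_equal(tied$p_value, 1)
  expect_equal(tied$effect_size, 0)
  # effect size r = Z / sqrt(n)
  expect_equal(tmemark:::effect_size_r(2.0, 25), 0.4)
  # paired one-sided signed-rank
  x <- c(5, 6, 7, 8, 9, 10); y <- x - 1
  pr <- compare_groups(x, y, paired = TRUE)
  expect_lt(pr$p_value, 0.05)
  expect_gt(pr$effect_size, 0.5)
  expect_error(compare_groups(1:3, c("a", "b", "c")), "2 levels")
})

test_that("rank-sum z agrees with the normal approximation of wilcox.test", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(35, mean = 0.8)
  z <- tmemark:::rank_sum_z(x, y)
  p_normal <- 2 * pnorm(-abs(z))
  p_wilcox <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_normal, p_wilcox, tolerance = 1e-10)
})

test_that("TMB tertiles split values into thirds with stable ties", {
  expect_equal(tmb_classify(1:9), rep(c("L", "M", "H"), each = 3))
  expect_equal(tmb_classify(9:1), rep(c("H", "M", "L"), each = 3))
  expect_equal(tmb_classify(c("H", "L", "M")), c("H", "L", "M")) # pass-through
  expect_error(tmb_classify(c("H", "X")), "L, M, or H")
  expect_warning(cls <- tmb_classify(rep(5, 9)), "stable")
  expect_equal(cls, rep(c("L", "M", "H"), each = 3))
  expect_error(tmb_classify(c(1, 2)), ">= 3")
})

test_that("penalty integration shifts scores by class", {
  p <- c(0.6, 0.6, 0.6)
  cls <- c("L", "M", "H")
  expect_equal(integrate_tmb_penalty(p, cls, gamma = 0), p) # gamma 0: no-op
  expect_equal(integrate_tmb_penalty(p, cls, gamma = 0.2),
               c(0.4, 0.6, 0.8)) # M unchanged, L down, H up
  expect_error(integrate_tmb_penalty(p, cls, gamma = -1), ">= 0")
  # monotone in TMB class for fixed P
  out <- integrate_tmb_penalty(rep(0.5, 3), c("L", "M", "H"), 0.1)
  expect_true(all(diff(out) > 0))
})

test_that("weighted integration blends scaled scores with class values", {
  p <- c(0, 0.4, 1) # already spanning [0, 1]: min-max scaling is identity
  expect_equal(integrate_tmb_weighted(p, c("M", "M", "M"), eta = 0.5),
               c(0.25, 0.45, 0.75)) # 0.5*0.4 + 0.5*0.5 = 0.45
  expect_equal(integrate_tmb_weighted(p, c("L", "M", "H"), eta = 0), p)
  expect_equal(integrate_tmb_weighted(p, c("L", "M", "H"), eta = 1),
               c(0, 0.5, 1))
  expect_warning(cst <- integrate_tmb_weighted(rep(2, 3), c("L", "M", "H"),
                                               eta = 1),
                 "constant")
  expect_equal(cst, c(0, 0.5, 1))
  expect_error(integrate_tmb_weighted(p, c("L", "M", "H"), eta = 2), "0, 1")
  # eta = 0 preserves the pure model ranking; eta = 1 the pure TMB ranking
  set.seed(5)
  pp <- runif(9); cls <- tmb_classify(runif(9))
  expect_equal(order(integrate_tmb_weighted(pp, cls, 0)), order(pp))
  r1 <- rank(integrate_tmb_weighted(pp, cls, 1))
  expect_equal(order(rank(c(L = 0, M = 0.5, H = 1)[cls])), order(r1))
})

test_that("response label mapping follows the configured convention", {
  clin <- data.frame(sample_id = paste0("P", 1:4),
                     response = c("CR", "PR", "SD", "PD"))
  lab <- map_response_labels(clin)
  expect_equal(lab$label, c("R", "R", "NR", "NR"))
  expect_error(map_response_labels(
    data.frame(sample_id = "P1", response = "MR")), "unmapped")
  lab2 <- map_response_labels(clin, mapping = c(CR = "R", PR = "NR",
                                                SD = "NR", PD = "NR"))
  expect_equal(lab2$label, c("R", "NR", "NR", "NR"))
})

test_that("cohort predictions average runs, tasks, and views as stated", {
  w_seed <- 31
  set.seed(w_seed)
  N <- 40
  X1 <- matrix(rnorm(N * 5), N, 5,
               dimnames = list(sprintf("S%03d", 1:N), paste0("a", 1:5)))
  X2 <- matrix(rnorm(N * 4), N, 4,
               dimnames = list(rownames(X1), paste0("b", 1:4)))
  Y <- cbind(t1 = X1[, 1] + 0.1 * rnorm(N), t2 = X2[, 1] + 0.1 * rnorm(N))
  rownames(Y) <- rownames(X1)
  e1 <- run_randomized_cv(list(v1 = X1), Y, "rmtlr", n_runs = 4, seed = 1,
                          n_lambda = 4)
  e2 <- run_randomized_cv(list(v2 = X2), Y, "rmtlr", n_runs = 4, seed = 1,
                          n_lambda = 4)
  newX1 <- matrix(rnorm(10 * 5), 10, 5,
                  dimnames = list(sprintf("N%02d", 1:10), paste0("a", 1:5)))
  newX2 <- matrix(rnorm(10 * 4), 10, 4,
                  dimnames = list(rownames(newX1), paste0("b", 1:4)))
  views_new <- list(v1 = newX1, v2 = newX2)
  pred <- predict_cohort(list(v1 = e1, v2 = e2), views_new)
  # the ensemble score is exactly the mean of the single-view scores
  expect_equal(pred$ensemble_score,
               rowMeans(cbind(rowMeans(pred$per_view_task$v1),
                              rowMeans(pred$per_view_task$v2))))
  expect_equal(pred$ensemble_task,
               (pred$per_view_task$v1 + pred$per_view_task$v2) / 2)
  # per-view per-task prediction is the average over the run models
  newX1p <- newX1
  colnames(newX1p) <- paste0("v1.", colnames(newX1)) # merged-view naming
  manual <- Reduce(`+`, lapply(e1$runs, function(r)
    rmtlr_predict(r$model, apply_standardizer(r$standardizer_x, newX1p)))) / 4
  expect_equal(pred$per_view_task$v1, manual)
})

test_that("identical runs make the cohort prediction equal a single model", {
  set.seed(33)
  N <- 30
  X <- matrix(rnorm(N * 4), N, 4,
              dimnames = list(sprintf("S%03d", 1:N), paste0("f", 1:4)))
  Y <- cbind(t1 = X[, 1], t2 = X[, 2])
  rownames(Y) <- rownames(X)
  ens <- run_randomized_cv(list(v = X), Y, "rmtlr", n_runs = 3, seed = 9,
                           n_lambda = 3)
  ens$runs <- rep(ens$runs[1], 3) # force identical run models
  newX <- matrix(rnorm(8 * 4), 8, 4,
                 dimnames = list(paste0("N", 1:8), paste0("f", 1:4)))
  pred <- predict_cohort(ens, list(v = newX))
  newXp <- newX
  colnames(newXp) <- paste0("v.", colnames(newX))
  single <- rmtlr_predict(ens$runs[[1]]$model,
                          apply_standardizer(ens$runs[[1]]$standardizer_x, newXp))
  expect_equal(pred$per_view_task[[1]], single)
})

test_that("evaluation reports task, view, and ensemble AUCs", {
  set.seed(35)
  res <- structure(list(
    per_view_task = list(v1 = cbind(t1 = 1:10, t2 = 10:1)),
    per_view_score = matrix(1:10, 10, 1,
                            dimnames = list(paste0("S", 1:10), "v1")),
    ensemble_task = cbind(t1 = 1:10, t2 = 10:1),
    ensemble_score = setNames(as.numeric(1:10), paste0("S", 1:10)),
    views = "v1", task_names = c("t1", "t2")), class = "prediction_result")
  labels <- rep(c("NR", "R"), each = 5)
  ev <- evaluate_predictions(res, labels)
  expect_equal(unname(ev$task_auc), c(1, 0))
  expect_equal(ev$task_auc_mean, 0.5)
  expect_equal(ev$ensemble_auc, 1)
  expect_equal(nrow(ev$mean_roc), 101L)
})
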