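test_that("deconvolution recovers noiseless mixtures exactly", {
  set.seed(5)
  sig <- matrix(runif(40, 1, 100), 20, 2,
                dimnames = list(sprintf("G%02d", 1:20), c("A", "B")))
  mix <- 0.3 * sig[, "A"] + 0.7 * sig[, "B"]
  expr <- tiny_expr(cbind(S1 = mix))
  cf <- deconvolve_cell_fractions(expr, sig)
  expect_equal(unname(cf$values[1, c("A", "B")]), c(0.3, 0.7), tolerance = 1e-8)
  expect_equal(unname(cf$values[1, "Other"]), 0, tolerance = 1e-8)
})

test_that("a sample orthogonal to the signature is all 'other'", {
  sig <- matrix(c(10, 0, 0, 0, 10, 0), 3, 2,
                dimnames = list(c("G1", "G2", "G3"), c("A", "B")))
  expr <- tiny_expr(cbind(S1 = c(0, 0, 50)), genes = c("G1", "G2", "G3"))
  cf <- deconvolve_cell_fractions(expr, sig)
  expect_equal(unname(cf$values[1, c("A", "B")]), c(0, 0))
  expect_equal(unname(cf$values[1, "Other"]), 1)
})

test_that("cell fractions satisfy the simplex invariants and CD4 aggregation", {
  pr <- make_priors(seed = 11)
  co <- make_cohort(pr, n_samples = 25, noise_sd = 0.1, seed = 12)
  cf <- deconvolve_cell_fractions(co$expr, pr$cell_signature)
  V <- cf$values
  expect_equal(ncol(V), 11L) # 10 immune cell types + other
  expect_true(all(V >= 0 & V <= 1 + 1e-12))
  immune_raw <- rowSums(V[, setdiff(colnames(V), c("Other"))]) -
    V[, "Treg"] # CD4 column already contains Treg
  expect_equal(unname(immune_raw + V[, "Other"]), rep(1, nrow(V)),
               tolerance = 1e-12)
  # CD4 column equals non-regulatory CD4 plus Treg, Treg kept separately
  raw <- t(apply(co$expr$tpm[intersect(rownames(co$expr$tpm),
                                       rownames(pr$cell_signature)), ], 2,
                 function(b) tmemark:::nnls_solve(
                   pr$cell_signature[intersect(rownames(co$expr$tpm),
                                               rownames(pr$cell_signature)), ], b)))
  colnames(raw) <- colnames(pr$cell_signature)
  expect_equal(unname(V[, "CD4"]), unname(raw[, "CD4"] + raw[, "Treg"]),
               tolerance = 1e-8)
})

test_that("deconvolution on a noisy Dirichlet cohort stays below RMSE 0.05", {
  pr <- make_priors(seed = 21)
  co <- make_cohort(pr, n_samples = 50, noise_sd = 0.01, seed = 22)
  cf <- deconvolve_cell_fractions(co$expr, pr$cell_signature)
  truth <- co$truth$fractions
  est <- cf$values
  est[, "CD4"] <- est[, "CD4"] - est[, "Treg"] # undo reporting aggregation
  for (ct in colnames(pr$cell_signature)) {
    rmse <- sqrt(mean((est[, ct] - truth[, ct])^2))
    expect_lt(rmse, 0.05)
  }
})

test_that("deconvolution errors on degenerate input", {
  sig <- matrix(1:4, 2, dimnames = list(c("G1", "G2"), c("A", "B")))
  expr <- tiny_expr(cbind(S1 = c(1, 2)), genes = c("H1", "H2"))
  expect_error(deconvolve_cell_fractions(expr, sig), "no overlap")
  expr0 <- tiny_expr(cbind(S1 = c(0, 0)), genes = c("G1", "G2"))
  expect_error(deconvolve_cell_fractions(expr0, sig), "all-zero")
})

test_that("pathway scores follow the weighted z-score formula", {
  # single pathway, single gene with weight 2; engineer z = 1.5 for S4
  x <- c(1, 1, 1, 7) # log2(tpm+1) values via tpm = 2^x - 1
  expr <- tiny_expr(matrix(2^c(x, 0, 3, 1, 2) - 1, 2, 4, byrow = TRUE),
                    genes = c("GA", "GB"))
  W <- matrix(2, 1, 1, dimnames = list("GA", "P1"))
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  v <- compute_pathway_activity(expr, W)
  expect_equal(unname(v$values[, "P1"]), 2 * z) # score = weight * z-score
  # a sample sitting at the gene-wise mean scores 0 on every pathway
  W2 <- matrix(c(2, -1), 2, 1, dimnames = list(c("GA", "GB"), "P1"))
  m <- rowMeans(log2(expr$tpm + 1))
  expr2 <- tiny_expr(cbind(expr$tpm, SM = 2^m - 1), genes = c("GA", "GB"))
  v2 <- compute_pathway_activity(expr2, W2)
  expect_equal(unname(v2$values["SM", "P1"]), 0)
})

test_that("pathway exclusion list removes genes and can empty the view", {
  expr <- tiny_expr(matrix(runif(12, 1, 50), 3, 4),
                    genes = c("GA", "GB", "GC"))
  W <- matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
              dimnames = list(c("GA", "GB", "GC"), c("P1", "P2")))
  expect_warning(v <- compute_pathway_activity(expr, W,
                                               exclude_genes = c("GC")),
                 "P2")
  expect_equal(colnames(v$values), "P1")
  expect_warning(v0 <- compute_pathway_activity(expr, W,
                                                exclude_genes = c("GA", "GB", "GC")),
                 "dropped")
  expect_equal(ncol(v0$values), 0L)
})

test_that("pathway scoring is linear: an averaged sample scores the average", {
  set.seed(9)
  E <- matrix(runif(20, 0, 6), 5, 4)
  E <- cbind(E, (E[, 1] + E[, 2]) / 2) # sample 5 is the log-space average
  expr <- tiny_expr(2^E - 1)
  W <- matrix(rnorm(10), 5, 2,
              dimnames = list(rownames(expr$tpm), c("P1", "P2")))
  v <- compute_pathway_activity(expr, W)$values
  expect_equal(unname(v[5, ]), unname((v[1, ] + v[2, ]) / 2), tolerance = 1e-10)
})

test_that("TF activity matches a brute-force evaluation of the rank formula", {
  set.seed(14)
  expr <- tiny_expr(matrix(runif(30, 0, 100), 10, 3))
  reg <- data.frame(tf = "TFX", target = c("G01", "G04", "G07"),
                    mor = c(1, -1, 1), confidence = "A")
  v <- compute_tf_activity(expr, reg, min_targets = 3)
  for (s in 1:3) {
    x <- expr$tpm[, s]
    z <- qnorm((rank(x) - 0.5) / length(x))
    nes <- sum(c(1, -1, 1) * z[c("G01", "G04", "G07")]) / sqrt(3)
    expect_equal(unname(v$values[s, "TFX"]), nes)
  }
})

test_that("TF activity is rank-based, odd in mor, and maximal for top targets", {
  set.seed(15)
  expr <- tiny_expr(matrix(runif(60, 0, 100), 20, 3))
  reg <- data.frame(tf = rep(c("T1", "T2"), each = 5),
                    target = rownames(expr$tpm)[1:10],
                    mor = 1, confidence = c("A", "B"))
  v1 <- compute_tf_activity(expr, reg)
  # invariance under strictly monotone per-sample transforms
  expr2 <- tiny_expr(expr$tpm^2 + 3 * expr$tpm)
  v2 <- compute_tf_activity(expr2, reg)
  expect_equal(v1$values, v2$values)
  # flipping every mor sign negates the score exactly
  reg_neg <- transform(reg, mor = -mor)
  v3 <- compute_tf_activity(expr, reg_neg)
  expect_equal(v3$values, -v1$values)
  # a regulon sitting on the top ranks dominates all other TFs
  x <- sort(runif(20, 0, 10))
  expr_top <- tiny_expr(cbind(S1 = x, S2 = rev(x)),
                        genes = rownames(expr$tpm))
  reg_top <- data.frame(tf = rep(c("TOP", "MID"), each = 5),
                        target = rownames(expr_top$tpm)[c(16:20, 8:12)],
                        mor = 1, confidence = "A")
  vt <- compute_tf_activity(expr_top, reg_top)
  expect_gt(vt$values["S1", "TOP"], vt$values["S1", "MID"])
  expect_equal(unname(which.max(vt$values["S1", ])),
               unname(which(colnames(vt$values) == "TOP")))
})

test_that("TFs with too few present targets are dropped, grades filtered", {
  expr <- tiny_expr(matrix(runif(30, 0, 10), 10, 3))
  reg <- data.frame(tf = c(rep("T1", 6), rep("T2", 2)),
                    target = rownames(expr$tpm)[1:8],
                    mor = 1,
                    confidence = c(rep("A", 6), "A", "C"))
  expect_warning(v <- compute_tf_activity(expr, reg, min_targets = 5),
                 "T2")
  expect_equal(colnames(v$values), "T1")
  reg_c <- transform(reg, confidence = "C")
  expect_error(compute_tf_activity(expr, reg_c), "confidence filter")
})

test_that("TME LR filter applies the expression and pairing rules", {
  db <- toy_lr_db()
  kept <- derive_tme_lr_pairs(db, tpm_threshold = 10)
  expect_setequal(kept$pairs$pair_id, c("P1", "P2", "P3")) # P3 is autocrine
  # a ligand below threshold everywhere kills its pair
  db2 <- db
  db2$celltype_expression[, "L1"] <- 5
  expect_setequal(derive_tme_lr_pairs(db2, 10)$pairs$pair_id, c("P2", "P3"))
  # threshold 0 keeps every pair whose genes are present
  expect_equal(nrow(derive_tme_lr_pairs(db, 0)$pairs), 3L)
  # sender/receiver must co-express within single cell types
  db3 <- db
  db3$celltype_expression["Tc_2", "L3B"] <- 0
  db3$celltype_expression["Fib_2", "L3B"] <- 50 # expressed, but not with L3A
  expect_setequal(derive_tme_lr_pairs(db3, 10)$pairs$pair_id, c("P1", "P2"))
})

test_that("LR weights are the min of log2(TPM+1) over all constituent genes", {
  db <- toy_lr_db()
  tpm <- matrix(0, 7, 2, dimnames = list(c("L1", "R1", "L2", "R2",
                                           "L3A", "L3B", "R3"),
                                         c("S1", "S2")))
  tpm[, "S1"] <- c(3, 1, 0, 8, 7, 3, 15)
  tpm[, "S2"] <- c(10, 10, 5, 0, 1, 1, 1)
  v <- compute_lr_view(gene_expr(tpm), db)
  expect_equal(unname(v$values["S1", "P1"]), 1.0)  # min(log2 4, log2 2)
  expect_equal(unname(v$values["S1", "P2"]), 0.0)  # one gene at TPM 0
  expect_equal(unname(v$values["S1", "P3"]), 2.0)  # complex: min over 3 genes
  # monotone non-decreasing in every constituent gene
  tpm2 <- tpm; tpm2["R1", "S1"] <- 2
  v2 <- compute_lr_view(gene_expr(tpm2), db)
  expect_gte(v2$values["S1", "P1"], v$values["S1", "P1"])
  # absent genes behave as unexpressed with a warning
  expr_missing <- tiny_expr(tpm[1:2, , drop = FALSE], genes = c("L1", "R1"))
  expect_warning(v3 <- compute_lr_view(expr_missing, db), "unexpressed")
  expect_equal(unname(v3$values[, "P2"]), c(0, 0))
})

test_that("identical LR feature columns are grouped", {
  vals <- matrix(c(1, 2, 3,
                   1, 2, 3,
                   4, 5, 6,
                   1, 2, 3), 3, 4,
                 dimnames = list(paste0("S", 1:3), c("PB", "PA", "PC", "PD")))
  v <- view_matrix(vals, "lrpairs")
  g <- group_lr_features(v)
  expect_equal(ncol(g$values), 2L) # three identical columns collapse to one
  expect_true("PA_PB_PD" %in% colnames(g$values))
  expect_equal(unname(g$values[, "PA_PB_PD"]), c(1, 2, 3))
  # no identical columns -> unchanged
  v2 <- view_matrix(vals[, c("PA", "PC")], "lrpairs")
  expect_equal(group_lr_features(v2)$values, v2$values)
})

test_that("CC scores sum inverse reference frequencies of active pairs", {
  db <- toy_lr_db()
  genes <- c("L1", "R1", "L2", "R2", "L3A", "L3B", "R3")
  tpm <- matrix(c(20, 20, 20, 20, 1, 1, 1,   # S1: P1, P2 active
                  1, 1, 1, 1, 1, 1, 1),      # S2: nothing active
                7, 2, dimnames = list(genes, c("S1", "S2")))
  v <- compute_cc_view(gene_expr(tpm), db,
                       reference_frequencies = c(P1 = 0.5, P2 = 0.25, P3 = 0.1))
  expect_equal(ncol(v$values), 9L) # all ordered pairs of 3 aggregated types
  expect_equal(unname(v$values["S1", "Tcell->Fibroblast"]), 1 / 0.5 + 1 / 0.25)
  expect_equal(unname(sum(v$values["S2", ])), 0)
  # frequency-1 world reduces to a plain count of active assigned pairs
  v1 <- compute_cc_view(gene_expr(tpm), db,
                        reference_frequencies = c(P1 = 1, P2 = 1, P3 = 1))
  expect_equal(unname(v1$values["S1", "Tcell->Fibroblast"]), 2)
  # zero-frequency pairs are excluded rather than giving infinite scores
  v0 <- compute_cc_view(gene_expr(tpm), db,
                        reference_frequencies = c(P1 = 0, P2 = 0.25, P3 = 0))
  expect_equal(unname(v0$values["S1", "Tcell->Fibroblast"]), 4)
  expect_true(all(is.finite(v0$values)))
})

test_that("CC frequencies can be computed from a reference cohort", {
  db <- toy_lr_db()
  genes <- c("L1", "R1", "L2", "R2", "L3A", "L3B", "R3")
  ref <- matrix(1, 7, 4, dimnames = list(genes, paste0("S", 1:4)))
  ref[c("L1", "R1"), 1:2] <- 50 # P1 active in half the reference
  f <- lr_pair_frequencies(gene_expr(ref), db)
  expect_equal(unname(f["P1"]), 0.5)
  expect_equal(unname(f["P2"]), 0)
  expect_error(compute_cc_view(gene_expr(ref), db), "reference")
})

test_that("the canonical aggregated cell-type list yields 169 CC features", {
  pr <- make_priors(seed = 2)
  co <- make_cohort(pr, n_samples = 10, seed = 3)
  db <- derive_tme_lr_pairs(pr$lr_database)
  v <- compute_cc_view(co$expr, db, reference_expr = co$expr)
  expect_equal(length(pr$lr_database$aggregated_types), 13L)
  expect_equal(ncol(v$values), 169L)
  expect_true(all(v$values >= 0))
})

test_that("view_matrix drops features with missing values, logged", {
  vals <- matrix(c(1, 2, NA, 4, 5, 6), 3, 2,
                 dimnames = list(paste0("S", 1:3), c("F1", "F2")))
  expect_message(v <- view_matrix(vals, "external"), "dropped 1 feature")
  expect_equal(colnames(v$values), "F2")
  expect_equal(v$dropped, "F1")
})
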