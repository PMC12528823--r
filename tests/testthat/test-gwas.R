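sim_gy <- function(n = 80, m = 300, seed = 1, fst = 0.05, K = 2) {
  cfg <- sim_config(n_genotypes = n, n_markers = m, n_subpops = K, fst = fst,
                    qtl = NULL, seed = seed)
  simulate_genotypes(cfg)
}

test_that("VanRaden kinship matches a hand calculation on a toy matrix", {
  calls <- rbind(c(0L, 1L, 2L, 1L),
                 c(2L, 1L, 0L, 0L),
                 c(1L, 2L, 1L, 1L))
  g <- toy_geno(calls)
  K <- vanraden_kinship(g)
  p <- colMeans(calls) / 2
  Z <- sweep(calls, 2, 2 * p)
  K_hand <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  expect_equal(unname(K$K), unname(K_hand), tolerance = 1e-12)
  expect_equal(K$n_markers_used, 4L)
})

test_that("duplicated individuals have off-diagonal equal to the diagonals", {
  set.seed(21)
  base <- sample(0:2, 50, TRUE)
  calls <- rbind(base, base, sample(0:2, 50, TRUE))
  g <- toy_geno(matrix(as.integer(calls), 3))
  K <- vanraden_kinship(g)$K
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
  expect_equal(K[1, 2], K[2, 2], tolerance = 1e-12)
})

test_that("kinship diagonal averages near one under Hardy-Weinberg", {
  g <- sim_gy(n = 100, m = 5000, seed = 31, fst = 0, K = 1)
  K <- vanraden_kinship(g)$K
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
  # monomorphic markers are skipped
  g2 <- toy_geno(cbind(c(1L, 0L, 2L), c(1L, 1L, 1L)))
  expect_equal(vanraden_kinship(g2)$n_markers_used, 1L)
  expect_error(vanraden_kinship(toy_geno(matrix(2L, 3, 2))), "polymorphic")
})

test_that("PCA covariates separate structure and behave like an SVD", {
  cfg <- sim_config(n_genotypes = 100, n_markers = 1000, n_subpops = 2,
                    fst = 0.2, qtl = NULL, seed = 41)
  g <- simulate_genotypes(cfg)
  pcs <- pca_covariates(g, 3)
  sub <- attr(g, "subpop")
  # PC1 separates the two subpopulations: mean silhouette-like separation
  m1 <- mean(pcs[sub == 1, 1]); m2 <- mean(pcs[sub == 2, 1])
  s <- sd(pcs[, 1])
  expect_gt(abs(m1 - m2) / s, 1)
  # score columns are orthogonal
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  # duplicated samples project identically
  calls2 <- g$calls[c(1, 1, 2:20), ]
  g2 <- genotype_matrix(calls2, g$map)
  pcs2 <- pca_covariates(g2, 2)
  expect_equal(pcs2[1, ], pcs2[2, ], tolerance = 1e-8)
  expect_error(pca_covariates(g2, 25), "smaller")
})

test_that("GLM marker tests match a brute-force regression oracle", {
  set.seed(51)
  g <- sim_gy(n = 20, m = 30, seed = 51)
  cov1 <- matrix(rnorm(20), 20, 1)
  y <- rnorm(20, 10, 2)
  res <- glm_scan(g, y, cov1)
  M <- impute_dosage(g)
  for (j in c(1, 7, 30)) {
    fit <- summary(lm(y ~ cov1 + M[, j]))
    expect_equal(res$effect[j], unname(coef(fit)[3, 1]), tolerance = 1e-10)
    expect_equal(res$p[j], unname(coef(fit)[3, 4]), tolerance = 1e-10)
    # partial R2 given covariates
    sse0 <- sum(resid(lm(y ~ cov1))^2)
    sse1 <- sum(resid(lm(y ~ cov1 + M[, j]))^2)
    expect_equal(res$r2_pct[j], 100 * (sse0 - sse1) / sse0, tolerance = 1e-8)
  }
})

test_that("a perfectly associated marker gives R2 = 100 and a floored p", {
  g <- toy_geno(matrix(as.integer(c(0, 1, 2, 1, 0, 2, 1, 1,
                                    0, 2, 1, 0, 1, 2, 0, 1)), 8, 2))
  y <- as.numeric(g$calls[, 1]) * 3 + 2
  res <- glm_scan(g, y)
  expect_equal(res$r2_pct[1], 100, tolerance = 1e-10)
  expect_equal(res$p[1], 1e-300)
  expect_equal(res$neglog10p[1], 300)
  # zero-variance marker yields missing p
  g2 <- toy_geno(cbind(c(0L, 1L, 2L, 1L, 0L, 1L), rep(1L, 6)))
  res2 <- glm_scan(g2, rnorm(6))
  expect_true(is.na(res2$p[2]))
})

test_that("GLM null p-values are calibrated", {
  g <- sim_gy(n = 150, m = 2000, seed = 61, fst = 0, K = 1)
  set.seed(62)
  y <- rnorm(150)
  res <- glm_scan(g, y)
  # empirical type-I error at alpha = 0.05 within a binomial tolerance
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_gt(suppressWarnings(ks.test(res$p, "punif")$p.value), 0.01)
})

test_that("MLM with identity kinship collapses to the GLM", {
  g <- sim_gy(n = 50, m = 200, seed = 71)
  set.seed(72)
  y <- rnorm(50, 5, 1)
  KI <- diag(50)
  res_mlm <- mlm_scan(g, y, KI)
  res_glm <- glm_scan(g, y)
  expect_equal(res_mlm$p, res_glm$p, tolerance = 1e-6)
  expect_equal(res_mlm$effect, res_glm$effect, tolerance = 1e-6)
})

test_that("REML delta matches a fine grid search", {
  cfg <- sim_config(n_genotypes = 80, n_markers = 600, n_subpops = 2,
                    fst = 0.15, qtl = NULL, seed = 81)
  g <- simulate_genotypes(cfg)
  K <- vanraden_kinship(g)$K
  set.seed(82)
  # phenotype with a genuine polygenic component tied to K
  u <- drop(t(chol(K + 1e-4 * diag(80))) %*% rnorm(80))
  y <- 10 + u * 2 + rnorm(80, 0, 1)
  eig <- eigen(K + 1e-6 * diag(80), symmetric = TRUE)
  d <- pmax(eig$values, 0); U <- eig$vectors
  ys <- drop(crossprod(U, y)); Xs <- crossprod(U, matrix(1, 80, 1))
  est <- metsel:::reml_delta(ys, Xs, d)
  xtx <- as.numeric(determinant(crossprod(Xs))$modulus)
  llf <- function(grid) vapply(grid, metsel:::reml_ll_delta, numeric(1),
                               ys = ys, Xs = Xs, d = d, xtx_logdet = xtx)
  coarse <- seq(log(1e-4), log(1e4), by = 0.01)
  c0 <- coarse[which.max(llf(coarse))]
  fine <- seq(c0 - 0.02, c0 + 0.02, by = 1e-4)
  best <- fine[which.max(llf(fine))]
  expect_equal(log(est$delta), best, tolerance = 1e-3)
})

test_that("MLM controls structure-driven inflation better than GLM", {
  better <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genotypes = 120, n_markers = 800, n_subpops = 4,
                      fst = 0.3, qtl = NULL, seed = 900 + s)
    g <- simulate_genotypes(cfg)
    K <- vanraden_kinship(g)
    set.seed(950 + s)
    sub <- attr(g, "subpop")
    y <- as.numeric(sub) * 2 + rnorm(120)  # confounded with structure
    lam <- function(p) median(qchisq(p[!is.na(p)], 1, lower.tail = FALSE)) /
      qchisq(0.5, 1)
    l_glm <- lam(glm_scan(g, y)$p)
    l_mlm <- lam(mlm_scan(g, y, K)$p)
    abs(l_mlm - 1) < abs(l_glm - 1)
  }, logical(1))
  expect_gte(sum(better), 4)
})

test_that("FarmCPU with no qualifying markers equals the plain GLM", {
  g <- sim_gy(n = 60, m = 200, seed = 91)
  set.seed(92)
  y <- rnorm(60)
  res_f <- farmcpu_scan(g, y, inclusion_p = 1e-12)
  res_g <- glm_scan(g, y)
  expect_equal(res_f$p, res_g$p, tolerance = 1e-12)
  expect_length(attr(res_f, "pseudo_qtns"), 0)
  expect_true(attr(res_f, "converged"))
})

test_that("FarmCPU recovers a planted QTL as pseudo-QTN and converges", {
  hits <- vapply(1:5, function(s) {
    tr <- data.frame(trait = "T1", mean = 50, sigma2_G = 15, sigma2_GL = 5,
                     sigma2_L = 1, sigma2_R = 1, sigma2_E = 5)
    cfg <- sim_config(n_genotypes = 150, n_markers = 500, traits = tr,
                      genetic_cor = diag(1),
                      qtl = data.frame(trait = "T1", marker = 77L, effect = 1,
                                       location = NA),
                      seed = 1000 + s)
    g <- simulate_genotypes(cfg)
    # effect sized from the realized dosage variance: QTL explains about a
    # third of the genotype-mean phenotypic variance
    bg_var <- 15 + 5 / 2 + 5 / 6
    cfg$qtl$effect <- sqrt(bg_var / 2 / var(as.numeric(g$calls[, 77])))
    p <- simulate_phenotypes(cfg, g)
    y <- rowMeans(genotype_means(p, "T1"))
    res <- farmcpu_scan(g, y)
    ok_conv <- isTRUE(attr(res, "converged"))
    ok_qtn <- 77L %in% attr(res, "pseudo_qtns") || which.min(res$p) == 77L
    ok_sig <- res$p[77] <= attr(res, "thresholds")$suggestive
    ok_conv && ok_qtn && ok_sig
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("model choice prefers calibrated p-values and breaks ties by name", {
  mk <- function(p, model) {
    map <- data.frame(marker = paste0("m", seq_along(p)), chrom = "1",
                      pos = seq_along(p))
    metsel:::build_assoc(map, model, rep(0, length(p)), p, rep(1, length(p)))
  }
  m <- 2000
  p_unif <- (seq_len(m) - 0.5) / m
  p_infl <- p_unif^3  # heavy inflation
  pick <- choose_model(list(good = mk(p_unif, "GLM"), bad = mk(p_infl, "MLM")))
  expect_equal(pick$chosen, "good")
  expect_lt(pick$metrics$qq_msd[pick$metrics$model == "good"],
            pick$metrics$qq_msd[pick$metrics$model == "bad"])
  # identical results: first model name in sorted order wins
  tie <- choose_model(list(zeta = mk(p_unif, "A"), alpha = mk(p_unif, "B")))
  expect_equal(tie$chosen, "alpha")
  # genomic inflation of exactly uniform p at n = 10001 is 1.00
  lam <- choose_model(list(u = mk((seq_len(10001) - 0.5) / 10001, "GLM")))
  expect_equal(lam$metrics$lambda, 1, tolerance = 0.02)
})

test_that("threshold tiers follow SP = 1/N and p < 0.001", {
  ts <- thresholds(33165)
  expect_equal(ts$suggestive, 1 / 33165)
  expect_equal(ts$neglog10_suggestive, 4.52)
  expect_equal(thresholds(1000)$suggestive, 1e-3)
  expect_equal(thresholds(1)$suggestive, 1)
  # tier assignment is a pure function of the thresholds
  p <- c(1e-6, 5e-4, 0.01, NA)
  tiers <- metsel:::assign_tiers(p, thresholds(10000))
  expect_equal(tiers, c("suggestive", "p<0.001", "none", "none"))
  # suggestive tier count equals |{p <= 1/N}| on a random scan
  g <- sim_gy(n = 40, m = 150, seed = 93)
  set.seed(94)
  res <- glm_scan(g, rnorm(40))
  expect_equal(sum(res$tier == "suggestive"),
               sum(res$p <= 1 / 150, na.rm = TRUE))
})

test_that("effect classes split strictly at 10% explained variance", {
  r <- data.frame(r2_pct = c(28.317, 10.0, 4.454, 10.0001, NA))
  out <- classify_effects(r)
  expect_equal(out$effect_class,
               c("major", "minor", "minor", "major", NA))
})

test_that("LD r2 matches the correlation oracle and flags degenerate pairs", {
  # identical dosage columns: complete LD
  x <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  g <- toy_geno(cbind(x, x, 2L - x, c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)),
                chrom = c("2", "2", "2", "3"))
  expect_equal(ld_r2(g, cbind("m1", "m2"))$r2, 1, tolerance = 1e-12)
  # a marker and its 2-dosage complement are also in complete LD
  expect_equal(ld_r2(g, cbind("m1", "m3"))$r2, 1, tolerance = 1e-12)
  # brute-force correlation on a toy pair
  set.seed(95)
  a <- sample(0:2, 8, TRUE); b <- sample(0:2, 8, TRUE)
  g2 <- toy_geno(cbind(as.integer(a), as.integer(b)))
  expect_equal(ld_r2(g2, cbind(1, 2))$r2, cor(a, b)^2, tolerance = 1e-12)
  # cross-chromosome pairs are refused; few complete samples are flagged
  expect_error(ld_r2(g, cbind("m1", "m4")), "chromosome")
  g3 <- toy_geno(cbind(c(0L, 1L, NA, NA, NA, NA, NA, NA),
                       c(1L, 0L, NA, NA, NA, NA, NA, NA)))
  out <- ld_r2(g3, cbind(1, 2))
  expect_true(is.na(out$r2))
  expect_equal(out$flag, "too_few_complete")
})
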