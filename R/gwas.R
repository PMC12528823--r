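#' Significance thresholds for an association scan
#'
#' Two fixed tiers: the suggestive per-study threshold \eqn{SP = 1/N} for
#' \eqn{N} tested markers, and the fixed \eqn{p = 0.001} tier.  No
#' FDR/Bonferroni correction is applied; tiers are the only
#' multiple-testing control.
#'
#' @param n_markers number of markers tested, `>= 1`.
#' @return object of class `"threshold_spec"` with `suggestive`, `fixed`,
#'   and their `-log10` values rounded to 2 decimals.
#' @export
thresholds <- function(n_markers) {
  stopifnot(n_markers >= 1)
  sp <- 1 / n_markers
  structure(list(n_markers = as.integer(n_markers),
                 suggestive = sp, fixed = 1e-3,
                 neglog10_suggestive = round(-log10(sp), 2),
                 neglog10_fixed = 3),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("thresholds for N = %d markers: suggestive p = %.3g (-log10 = %.2f), fixed p = %.3g\n",
              x$n_markers, x$suggestive, x$neglog10_suggestive, x$fixed))
  invisible(x)
}

assign_tiers <- function(p, ts) {
  tier <- rep("none", length(p))
  tier[!is.na(p) & p <= ts$fixed] <- "p<0.001"
  tier[!is.na(p) & p <= ts$suggestive] <- "suggestive"
  tier
}

#' Classify marker effects as major or minor by explained variance
#'
#' A marker is major when it explains strictly more than 10\% of the
#' phenotypic variance (R² > 10), minor otherwise (the boundary value 10
#' is minor under the strict reading of "more than").
#'
#' @param r an `assoc_result` data.frame (or anything with an `r2_pct`
#'   column).
#' @return `r` with an `effect_class` column of `"major"` / `"minor"`.
#' @export
classify_effects <- function(r) {
  stopifnot("r2_pct" %in% names(r))
  r$effect_class <- ifelse(is.na(r$r2_pct), NA_character_,
                           ifelse(r$r2_pct > 10, "major", "minor"))
  r
}

# assemble a per-marker association result table
build_assoc <- function(map, model, effect, p, r2) {
  p <- pmax(p, 1e-300)  # display floor against underflow
  res <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    model = model, effect = effect, p = p,
                    neglog10p = -log10(p), r2_pct = r2,
                    stringsAsFactors = FALSE)
  ts <- thresholds(nrow(map))
  res$tier <- assign_tiers(res$p, ts)
  res <- classify_effects(res)
  attr(res, "thresholds") <- ts
  class(res) <- c("assoc_result", "data.frame")
  res
}

# residualize y and the marker matrix against X0, then per-marker OLS t-tests
ols_scan_core <- function(M, y, X0) {
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) stop("covariates are rank-deficient")
  yr <- qr.resid(qrX, y)
  Mres <- M - qr.fitted(qrX, M)
  sxx <- colSums(Mres^2)
  sxy <- drop(crossprod(Mres, yr))
  ok <- sxx > 1e-12 * nrow(M)
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  sse0 <- sum(yr^2)
  sse <- sse0 - ifelse(ok, beta * sxy, 0)
  dfres <- length(y) - qrX$rank - 1
  if (dfres < 1) stop("not enough residual degrees of freedom")
  se <- sqrt(pmax(sse, 0) / dfres / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE)
  p[ok & se == 0] <- 0   # perfect fit; floored later
  r2 <- ifelse(ok, 100 * (sse0 - sse) / sse0, NA_real_)
  list(effect = beta, p = ifelse(ok, p, NA_real_), r2 = r2, dfres = dfres)
}

check_y <- function(g, y) {
  if (length(y) != n_samples(g))
    stop("phenotype length (", length(y), ") does not match sample count (",
         n_samples(g), "); supply one genotype mean per sample ",
         "(raw replicate data must be averaged per genotype first)")
  if (!is.null(names(y)) && !is.null(rownames(g$calls))) {
    if (!all(rownames(g$calls) %in% names(y)))
      stop("phenotype names do not cover the genotyped samples")
    y <- y[rownames(g$calls)]
  }
  as.numeric(y)
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  C <- as.matrix(covariates)
  stopifnot(nrow(C) == n)
  cbind("(Intercept)" = 1, C)
}

#' General linear model association scan
#'
#' Per marker, ordinary least squares of the phenotype (genotype means per
#' location) on an intercept, optional covariates, and the mean-imputed
#' allele dosage; two-sided t-test on the dosage coefficient.  The marker
#' effect is the fitted dosage coefficient (trait units per alternate
#' allele), and R² is 100 times the partial R² of the marker given the
#' covariates.
#'
#' @param g a [genotype_matrix()].
#' @param y numeric phenotype, one value per sample (named vectors are
#'   aligned by sample name).
#' @param covariates optional numeric matrix of covariates (e.g. principal
#'   components), samples in rows; an intercept is always added.
#' @return an `assoc_result` data.frame: marker, chrom, pos, model, effect,
#'   p, neglog10p, r2_pct, tier, effect_class.
#' @export
glm_scan <- function(g, y, covariates = NULL) {
  y <- check_y(g, y)
  M <- impute_dosage(g)
  X0 <- as_covariate_matrix(covariates, length(y))
  sc <- ols_scan_core(M, y, X0)
  build_assoc(g$map, "GLM", sc$effect, sc$p, sc$r2)
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 estimator: markers are mean-imputed, centered by twice the
#' allele frequency, and \eqn{K = ZZ^\top / (2\sum_j \hat p_j(1-\hat p_j))}.
#' Monomorphic markers carry no information and are skipped.
#'
#' @param g a [genotype_matrix()].
#' @return object of class `"kinship"`: list with the n x n matrix `K`,
#'   `method`, and `n_markers_used`.
#' @export
vanraden_kinship <- function(g) {
  if (n_samples(g) < 2) stop("need at least 2 samples for kinship")
  M <- impute_dosage(g)
  p <- colMeans(M) / 2
  v <- apply(M, 2, stats::var)
  poly <- p > 0 & p < 1 & v > 0
  if (!any(poly)) stop("no polymorphic markers; kinship undefined")
  Z <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly])
  K <- tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(K) <- list(rownames(g$calls), rownames(g$calls))
  structure(list(K = K, method = "vanraden1", n_markers_used = sum(poly)),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat("kinship (", x$method, "), ", nrow(x$K), " samples, ",
      x$n_markers_used, " markers; mean diagonal ",
      round(mean(diag(x$K)), 3), "\n", sep = "")
  invisible(x)
}

#' Principal components of the dosage matrix as structure covariates
#'
#' SVD of the column-centered, mean-imputed dosage matrix; scores
#' \eqn{U_k d_k} for the leading components.
#'
#' @param g a [genotype_matrix()].
#' @param n_pcs number of components, `< n_samples`.
#' @param scale_markers divide centered dosages by marker standard
#'   deviation first (default `FALSE`).
#' @return samples x PCs score matrix with attribute `"var_explained"`
#'   (fraction of total variance per PC).
#' @export
pca_covariates <- function(g, n_pcs = 3, scale_markers = FALSE) {
  if (n_pcs >= n_samples(g))
    stop("n_pcs must be smaller than the number of samples")
  M <- impute_dosage(g)
  Mc <- sweep(M, 2, colMeans(M))
  if (scale_markers) {
    sds <- apply(Mc, 2, stats::sd)
    keep <- sds > 0
    Mc <- sweep(Mc[, keep, drop = FALSE], 2, sds[keep], "/")
  }
  sv <- svd(Mc)
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(scores) <- list(rownames(g$calls), paste0("PC", seq_len(n_pcs)))
  attr(scores, "var_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(n_pcs)]
  scores
}

# restricted log-likelihood of the null mixed model on the eigenbasis of K;
# delta = sigma2_e / sigma2_g
reml_ll_delta <- function(log_delta, ys, Xs, d, xtx_logdet) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xs * sw, ys * sw)
  R <- sum(fit$residuals^2)
  nq <- length(ys) - ncol(Xs)
  s2 <- R / nq
  xwx_logdet <- as.numeric(determinant(crossprod(Xs * sw), logarithm = TRUE)$modulus)
  -0.5 * (nq * log(2 * pi * s2) + nq + sum(log(d + delta)) +
            xwx_logdet - xtx_logdet)
}

# REML estimate of delta by coarse grid + local refinement
reml_delta <- function(ys, Xs, d, grid = seq(-10, 10, length.out = 81)) {
  xtx_logdet <- as.numeric(determinant(crossprod(Xs), logarithm = TRUE)$modulus)
  ll <- vapply(grid, reml_ll_delta, numeric(1), ys = ys, Xs = Xs, d = d,
               xtx_logdet = xtx_logdet)
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(reml_ll_delta, c(lo, hi), maximum = TRUE,
                         ys = ys, Xs = Xs, d = d, xtx_logdet = xtx_logdet,
                         tol = 1e-6)
  list(delta = exp(opt$maximum), ll = opt$objective)
}

# restricted log-likelihood of the OLS null model (no random effect),
# comparable with reml_ll_delta values
reml_ll_ols <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  nq <- length(y) - ncol(X)
  s2 <- sum(fit$residuals^2) / nq
  -0.5 * (nq * log(2 * pi * s2) + nq)
}

#' Mixed linear model association scan (P3D)
#'
#' EMMA-style mixed model with a polygenic random effect of covariance
#' \eqn{\sigma^2_g K}.  The variance ratio \eqn{\delta = \sigma^2_e /
#' \sigma^2_g} is estimated once by REML on the null model (P3D:
#' population parameters previously determined) via the spectral
#' decomposition of `K`, then each marker is tested by generalized least
#' squares in the rotated space with a Wald t-test.  Effect and R² are
#' computed as in [glm_scan()] on the whitened data.
#'
#' @inheritParams glm_scan
#' @param K a [vanraden_kinship()] result (or bare symmetric matrix).
#' @return an `assoc_result` data.frame; attribute `"delta"` carries the
#'   REML variance ratio.
#' @export
mlm_scan <- function(g, y, K, covariates = NULL) {
  y <- check_y(g, y)
  M <- impute_dosage(g)
  Kmat <- if (inherits(K, "kinship")) K$K else as.matrix(K)
  n <- length(y)
  stopifnot(nrow(Kmat) == n)
  Kmat <- Kmat + 1e-6 * diag(n)
  eig <- eigen(Kmat, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop("kinship matrix is not positive semi-definite after regularization")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  X0 <- as_covariate_matrix(covariates, n)
  ys <- drop(crossprod(U, y))
  X0s <- crossprod(U, X0)
  est <- reml_delta(ys, X0s, d)
  sw <- sqrt(1 / (d + est$delta))
  sc <- ols_scan_core(crossprod(U, M) * sw, ys * sw, X0s * sw)
  res <- build_assoc(g$map, "MLM", sc$effect, sc$p, sc$r2)
  attr(res, "delta") <- est$delta
  res
}

# best marker per physical bin among those below the inclusion threshold,
# ordered by p-value
bin_candidates <- function(map, p, bin_size, inclusion_p, max_qtn) {
  cand <- which(!is.na(p) & p <= inclusion_p)
  if (!length(cand)) return(integer(0))
  cand <- cand[order(p[cand])]
  bin <- paste0(map$chrom[cand], ":", map$pos[cand] %/% bin_size)
  cand <- cand[!duplicated(bin)]
  utils::head(cand, max_qtn)
}

#' FarmCPU-style iterative association scan
#'
#' Alternates (1) a fixed-effect GLM scan conditioned on the current set of
#' pseudo-QTNs as covariates with (2) a random-effect step that re-selects
#' the pseudo-QTN set: significant markers are binned by physical window
#' (the window starts at `bin_size` and halves each iteration, floored at
#' 1 Mb), the best marker per bin is taken as a candidate, and the number
#' of pseudo-QTNs kept is the prefix (in p-value order) that maximizes the
#' REML likelihood of a kinship built from the candidate markers.  The
#' loop stops when the pseudo-QTN set is unchanged or after `max_iter`
#' iterations; p-values come from the fixed-effect scan of the final
#' iteration.  A pseudo-QTN's own p-value is computed with that marker
#' removed from the conditioning set.  This is a faithful-in-structure
#' re-implementation of the method, not a bit-compatible port of any
#' particular package.
#'
#' @inheritParams glm_scan
#' @param max_iter maximum number of outer iterations.
#' @param bin_size initial binning window in bp (default 10 Mb).
#' @param inclusion_p p-value threshold for pseudo-QTN candidacy (default:
#'   the suggestive threshold `1/N`).
#' @param max_qtn maximum pseudo-QTN set size considered.
#' @return an `assoc_result` data.frame; attributes `"pseudo_qtns"`
#'   (marker indices), `"trajectory"` (set per iteration) and
#'   `"converged"`.
#' @export
farmcpu_scan <- function(g, y, covariates = NULL, max_iter = 10,
                         bin_size = 1e7, inclusion_p = NULL, max_qtn = 20) {
  y <- check_y(g, y)
  if (anyNA(g$map$pos)) stop("marker map with positions required for binning")
  M <- impute_dosage(g)
  m <- ncol(M); n <- length(y)
  if (is.null(inclusion_p)) inclusion_p <- 1 / m
  X0 <- as_covariate_matrix(covariates, n)
  qtn <- integer(0)
  trajectory <- list()
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # (1) fixed-effect scan conditioned on current pseudo-QTNs
    sc <- ols_scan_core(M, y, cbind(X0, M[, qtn, drop = FALSE]))
    for (j in qtn) {  # a pseudo-QTN is tested without conditioning on itself
      others <- setdiff(qtn, j)
      scj <- ols_scan_core(M[, j, drop = FALSE], y,
                           cbind(X0, M[, others, drop = FALSE]))
      sc$effect[j] <- scj$effect; sc$p[j] <- scj$p; sc$r2[j] <- scj$r2
    }
    # (2) candidate binning and REML-based set-size selection
    bs <- max(bin_size / 2^(iter - 1), 1e6)
    cand <- bin_candidates(g$map, sc$p, bs, inclusion_p, max_qtn)
    if (length(cand) == 0) {
      qtn_new <- integer(0)
    } else {
      ll0 <- reml_ll_ols(y, X0)
      lls <- vapply(seq_along(cand), function(s) {
        Ks <- vanraden_kinship(subset_genotypes(g, markers = cand[seq_len(s)]))
        eig <- eigen(Ks$K + 1e-6 * diag(n), symmetric = TRUE)
        d <- pmax(eig$values, 0)
        reml_delta(drop(crossprod(eig$vectors, y)),
                   crossprod(eig$vectors, X0), d)$ll
      }, numeric(1))
      s_best <- which.max(c(ll0, lls)) - 1L
      qtn_new <- sort(cand[seq_len(s_best)])
    }
    trajectory[[iter]] <- qtn_new
    if (identical(qtn_new, sort(qtn))) { converged <- TRUE; break }
    # a revisited set means the loop has entered a cycle; the scan above is
    # already conditioned on a member of that cycle, so stop here
    if (iter > 1 &&
        any(vapply(trajectory[seq_len(iter - 1)], identical, logical(1),
                   qtn_new))) {
      qtn <- qtn_new
      converged <- TRUE
      break
    }
    qtn <- qtn_new
  }
  res <- build_assoc(g$map, "FarmCPU", sc$effect, sc$p, sc$r2)
  attr(res, "pseudo_qtns") <- sort(qtn)
  attr(res, "trajectory") <- trajectory
  attr(res, "converged") <- converged
  if (!converged)
    warning("farmcpu_scan: pseudo-QTN set did not stabilize within ",
            max_iter, " iterations; returning the last iteration")
  res
}

#' Choose an association model by Q-Q calibration
#'
#' For each candidate result, compares observed and expected
#' \eqn{-\log_{10} p} quantiles over the least significant 90\% of markers
#' (the bulk, where p-values should be uniform; the strongest 10\% are
#' excluded so true signal does not penalize a model) and computes the
#' genomic inflation factor \eqn{\lambda =
#' \mathrm{median}(\chi^2_1)/0.4549}.  The model with the smallest mean
#' squared Q-Q deviation wins; ties go to the first model name in sorted
#' order.
#'
#' @param results named list of `assoc_result` objects on the same
#'   markers.
#' @return list with `chosen` (name), `result` (the winning
#'   `assoc_result`), and `metrics` (data.frame of model, qq_msd, lambda).
#' @export
choose_model <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("model", seq_along(results))
  met <- do.call(rbind, lapply(names(results), function(nm) {
    p <- results[[nm]]$p
    p <- sort(p[!is.na(p)])
    m <- length(p)
    expd <- (seq_len(m) - 0.5) / m
    keep <- seq_len(m) > ceiling(0.1 * m)   # drop the 10% smallest p
    msd <- mean((-log10(p[keep]) + log10(expd[keep]))^2)
    lam <- stats::median(stats::qchisq(p, 1, lower.tail = FALSE)) /
      stats::qchisq(0.5, 1)
    data.frame(model = nm, qq_msd = msd, lambda = lam,
               stringsAsFactors = FALSE)
  }))
  ord <- order(met$qq_msd, met$model)
  chosen <- met$model[ord[1]]
  list(chosen = chosen, result = results[[chosen]], metrics = met)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Composite genotypic \eqn{r^2}: the squared Pearson correlation of the
#' two markers' dosage vectors over samples complete for both markers.
#' Pairs must lie on the same chromosome (the follow-up is among
#' significant markers per chromosome); pairs with fewer than 3 complete
#' samples or a monomorphic member give `NA` with a flag.
#'
#' @param g a [genotype_matrix()].
#' @param marker_pairs two-column matrix or data.frame of marker
#'   identifiers (or indices).
#' @return data.frame: marker1, marker2, chrom, n_complete, r2, flag.
#' @export
ld_r2 <- function(g, marker_pairs) {
  mp <- as.matrix(marker_pairs)
  stopifnot(ncol(mp) == 2)
  idx <- function(x) if (is.character(x)) match(x, g$map$marker) else as.integer(x)
  i1 <- idx(mp[, 1]); i2 <- idx(mp[, 2])
  if (anyNA(i1) || anyNA(i2)) stop("unknown marker identifier in pairs")
  out <- data.frame(marker1 = g$map$marker[i1], marker2 = g$map$marker[i2],
                    chrom = g$map$chrom[i1], n_complete = NA_integer_,
                    r2 = NA_real_, flag = "", stringsAsFactors = FALSE)
  for (k in seq_along(i1)) {
    if (g$map$chrom[i1[k]] != g$map$chrom[i2[k]])
      stop("pair (", out$marker1[k], ", ", out$marker2[k],
           ") spans chromosomes; LD follow-up is within-chromosome only")
    x <- g$calls[, i1[k]]; ycol <- g$calls[, i2[k]]
    ok <- !is.na(x) & !is.na(ycol)
    out$n_complete[k] <- sum(ok)
    if (sum(ok) < 3) { out$flag[k] <- "too_few_complete"; next }
    if (stats::sd(x[ok]) == 0 || stats::sd(ycol[ok]) == 0) {
      out$flag[k] <- "monomorphic"; next
    }
    out$r2[k] <- stats::cor(x[ok], ycol[ok])^2
  }
  out
}
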