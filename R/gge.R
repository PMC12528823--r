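#' GGE biplot model from a genotype x environment table
#'
#' Singular value decomposition of a (possibly centered and scaled)
#' genotype x environment two-way table.  Tester-centering
#' (`centering = 2`) subtracts each environment's mean so that the
#' decomposition retains the genotype main effect plus the
#' genotype-by-environment interaction — the "GGE" of the biplot.  With
#' `scaling = 0` the table is not rescaled; `scaling = 1` divides each
#' environment column by its standard deviation.  Percent variance of PC
#' \eqn{k} is \eqn{100\,\lambda_k^2 / \sum_m \lambda_m^2}.
#'
#' Scores and loadings use symmetric singular-value partitioning
#' (\eqn{f = 0.5}): genotype scores \eqn{U \Lambda^{1/2}}, environment
#' loadings \eqn{V \Lambda^{1/2}}, so their cross-products reconstruct the
#' processed table.  PC signs are fixed so the first environment's loading
#' on each PC is non-negative.
#'
#' @param table numeric matrix (or data.frame), genotypes in rows,
#'   environments in columns, no missing cells.
#' @param centering 0 (none), 1 (grand-mean), or 2 (environment/tester
#'   centered; default).
#' @param scaling 0 (none; default) or 1 (per-environment standard
#'   deviation).
#' @param svp singular-value partitioning exponent in `[0, 1]` applied to
#'   scores (loadings get `1 - svp`); affects display only.
#' @return object of class `"gge_model"`: `scores`, `loadings` (all PCs),
#'   `d` (singular values), `percent_var`, `centering`, `scaling`,
#'   `processed` (the decomposed matrix).
#' @export
gge_fit <- function(table, centering = 2, scaling = 0, svp = 0.5) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("table must be numeric")
  if (anyNA(X)) stop("missing cells in the genotype x environment table")
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("need at least 2 genotypes and 2 environments")
  if (!centering %in% 0:2 || !scaling %in% 0:1)
    stop("centering must be 0, 1 or 2 and scaling 0 or 1")
  if (is.null(rownames(X))) rownames(X) <- paste0("G", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("E", seq_len(ncol(X)))
  if (centering == 1) X <- X - mean(X)
  if (centering == 2) X <- sweep(X, 2, colMeans(X))
  if (scaling == 1) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("constant environment column; cannot scale by zero sd")
    X <- sweep(X, 2, sds, "/")
  }
  sv <- svd(X)
  d <- sv$d
  # sign convention: first environment's loading non-negative on each PC
  sgn <- ifelse(sv$v[1, ] < 0, -1, 1)
  U <- sweep(sv$u, 2, sgn, "*")
  V <- sweep(sv$v, 2, sgn, "*")
  k <- length(d)
  pcs <- paste0("PC", seq_len(k))
  scores <- U %*% diag(d^svp, k)
  loadings <- V %*% diag(d^(1 - svp), k)
  dimnames(scores) <- list(rownames(X), pcs)
  dimnames(loadings) <- list(colnames(X), pcs)
  pv <- if (sum(d^2) > 0) 100 * d^2 / sum(d^2) else rep(0, k)
  rownames(U) <- rownames(X); rownames(V) <- colnames(X)
  colnames(U) <- colnames(V) <- pcs
  structure(list(scores = scores, loadings = loadings, d = d,
                 u = U, v = V,
                 percent_var = stats::setNames(pv, pcs),
                 centering = centering, scaling = scaling, svp = svp,
                 processed = X),
            class = "gge_model")
}

#' @export
print.gge_model <- function(x, ...) {
  cat("GGE biplot model (centering =", x$centering,
      ", scaling =", x$scaling, ")\n")
  cat(sprintf("  %d genotypes x %d environments\n",
              nrow(x$scores), nrow(x$loadings)))
  pv <- round(x$percent_var, 2)
  cat("  percent variance:", paste(names(pv), pv, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Environment-vector geometry of a GGE biplot
#'
#' Angles between environment vectors and the average-environment axis.
#' For this view the environment vectors carry the full singular values
#' (environment-focused partitioning, \eqn{V \Lambda}), so inner products
#' reproduce the processed table's column cross-products: an obtuse angle
#' between two environments corresponds to a negative correlation of their
#' centered columns, and the cosine of the angle equals that correlation
#' exactly.
#'
#' @param m a [gge_fit()] model.
#' @return list with `angles_deg` (environment x environment matrix of
#'   angles in degrees), `cosines`, `mean_environment` (average of the
#'   environment loadings, the tip of the average-environment axis), and
#'   `degenerate` (environments with zero-length loading vectors).
#' @export
env_geometry <- function(m) {
  stopifnot(inherits(m, "gge_model"))
  L <- m$v %*% diag(m$d, length(m$d))
  dimnames(L) <- dimnames(m$v)
  nrm <- sqrt(rowSums(L^2))
  degen <- rownames(L)[nrm == 0]
  cosm <- matrix(NA_real_, nrow(L), nrow(L), dimnames = list(rownames(L), rownames(L)))
  for (i in seq_len(nrow(L))) for (j in seq_len(nrow(L))) {
    if (nrm[i] > 0 && nrm[j] > 0)
      cosm[i, j] <- sum(L[i, ] * L[j, ]) / (nrm[i] * nrm[j])
  }
  cosm <- pmin(pmax(cosm, -1), 1)
  list(angles_deg = acos(cosm) * 180 / pi,
       cosines = cosm,
       mean_environment = colMeans(L),
       degenerate = degen)
}
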