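#' Phenotypic and genotypic covariance matrices at one location
#'
#' From the balanced genotype x replication layout at a single location,
#' estimates for each trait pair the between-genotype and error mean
#' cross-products by the multivariate analogue of the two-way ANOVA, and
#' converts them to genotypic and phenotypic covariances:
#' \deqn{G_{uv} = (MCP_{G,uv} - MCP_{E,uv}) / r}
#' with the phenotypic covariance on the genotype-mean basis
#' \deqn{P_{uv} = G_{uv} + MCP_{E,uv} / r = MCP_{G,uv} / r,}
#' because selection indices here are computed on genotype means.  The
#' plot-basis alternative \eqn{P = G + MCP_E} is available via `basis`.
#' Diagonals reduce to the univariate method-of-moments components.
#'
#' @param p a [phenotype_table()].
#' @param location location identifier present in `p`.
#' @param trait_order character vector fixing the trait order of the
#'   matrices (default: all traits in table order).
#' @param basis `"mean"` (genotype-mean phenotypic covariance, default) or
#'   `"plot"`.
#' @param check_pd error when `P` is singular or near-singular (default).
#'   Disable to inspect `G` (e.g. genetic correlations) for degenerate
#'   trait sets that could not feed an index anyway.
#' @return list with matrices `P` and `G`, plus `MCP_G`, `MCP_E`, `r`
#'   (replication count) and `basis`.
#' @export
genetic_covariances <- function(p, location, trait_order = NULL,
                                basis = c("mean", "plot"), check_pd = TRUE) {
  basis <- match.arg(basis)
  if (is.null(trait_order)) trait_order <- traits(p)
  d <- p[p$location == location & p$trait %in% trait_order, , drop = FALSE]
  if (nrow(d) == 0) stop("no data at location '", location, "'")
  if (length(trait_order) < 2) stop("need at least 2 traits")
  gs <- sort(unique(d$genotype)); rs <- sort(unique(d$rep))
  g <- length(gs); r <- length(rs)
  if (r < 2) stop("need at least 2 replications at location '", location, "'")
  # trait-wise g x r response matrices, balanced required
  Y <- lapply(trait_order, function(tr) {
    di <- d[d$trait == tr, , drop = FALSE]
    m <- tapply(di$value, list(factor(di$genotype, gs), factor(di$rep, rs)), mean)
    if (anyNA(m)) stop("unbalanced data for trait '", tr, "' at '", location, "'")
    m
  })
  names(Y) <- trait_order
  nt <- length(trait_order)
  MCP_G <- MCP_E <- matrix(0, nt, nt, dimnames = list(trait_order, trait_order))
  dev_g <- lapply(Y, function(m) rowMeans(m) - mean(m))
  dev_e <- lapply(Y, function(m) {
    sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  })
  for (u in 1:nt) for (v in u:nt) {
    cp_g <- r * sum(dev_g[[u]] * dev_g[[v]])
    cp_e <- sum(dev_e[[u]] * dev_e[[v]])
    MCP_G[u, v] <- MCP_G[v, u] <- cp_g / (g - 1)
    MCP_E[u, v] <- MCP_E[v, u] <- cp_e / ((g - 1) * (r - 1))
  }
  Gm <- (MCP_G - MCP_E) / r
  Pm <- if (basis == "mean") MCP_G / r else Gm + MCP_E
  ev <- eigen(Pm, symmetric = TRUE, only.values = TRUE)$values
  if (check_pd && (min(ev) <= 0 || max(ev) / min(ev) > 1e10))
    stop("phenotypic covariance matrix is singular or near-singular; ",
         "consider removing a redundant trait")
  list(P = Pm, G = Gm, MCP_G = MCP_G, MCP_E = MCP_E, r = r, basis = basis)
}

#' Smith-Hazel index coefficients
#'
#' Solves \eqn{P b = G a} for the optimum-index coefficient vector `b`,
#' where `P` and `G` are the phenotypic and genotypic variance-covariance
#' matrices and `a` the economic-weight vector.  The linear system is
#' solved directly (no explicit inversion).
#'
#' @param P phenotypic covariance matrix (symmetric positive definite).
#' @param G genotypic covariance matrix (symmetric), same dimension.
#' @param a economic weights, one per trait.  The default puts all weight
#'   on the first trait: improve the target trait through the auxiliary
#'   traits.
#' @return coefficient vector `b` in trait order.
#' @export
smith_hazel_b <- function(P, G, a = c(1, rep(0, ncol(P) - 1))) {
  stopifnot(is.matrix(P), is.matrix(G),
            nrow(P) == ncol(P), all(dim(P) == dim(G)), length(a) == ncol(P))
  if (max(abs(P - t(P))) > 1e-8 * max(1, max(abs(P))))
    stop("P must be symmetric")
  if (kappa(P, exact = TRUE) > 1e10)
    stop("P is ill-conditioned (condition number > 1e10)")
  b <- drop(solve(P, G %*% a))
  names(b) <- colnames(P)
  b
}

#' Selection-index scores per genotype
#'
#' Computes \eqn{SI = \sum_i b_i X_i} on genotype means at one location,
#' with `X` in the order of `trait_order`.  Genotypes missing any trait
#' mean are excluded and reported in the `"excluded"` attribute.
#'
#' @param b index coefficients, one per trait.
#' @param p a [phenotype_table()].
#' @param location location identifier.
#' @param trait_order traits in the order matching `b` (default: names of
#'   `b`, else all traits in table order).
#' @return named numeric vector of SI scores by genotype.
#' @export
index_scores <- function(b, p, location, trait_order = NULL) {
  if (is.null(trait_order))
    trait_order <- if (!is.null(names(b))) names(b) else traits(p)
  if (length(b) != length(trait_order))
    stop("length of b (", length(b), ") must match trait count (",
         length(trait_order), ")")
  gens <- sort(unique(p$genotype))
  X <- vapply(trait_order, function(tr) {
    gm <- genotype_means(p, tr)
    if (!(location %in% colnames(gm)))
      stop("no data at location '", location, "' for trait '", tr, "'")
    gm[match(gens, rownames(gm)), location]
  }, numeric(length(gens)))
  rownames(X) <- gens
  ok <- stats::complete.cases(X)
  si <- drop(X[ok, , drop = FALSE] %*% b)
  names(si) <- rownames(X)[ok]
  attr(si, "excluded") <- rownames(X)[!ok]
  si
}

#' Top-k / bottom-k selection per location and cross-location intersection
#'
#' Ranks genotypes by score within each location (descending; ties broken
#' by genotype identifier, ascending — a deterministic, documented rule),
#' takes the `k` highest and `k` lowest per location, and intersects the
#' top sets and the bottom sets across all locations.
#'
#' @param scores named list (one element per location) of named numeric
#'   score vectors over the same genotype universe.
#' @param k selection size, `k <=` number of genotypes.
#' @return object of class `"selection_outcome"`: per-location rankings and
#'   top/bottom sets, plus `top_common` and `bottom_common`.
#' @export
select_and_intersect <- function(scores, k) {
  stopifnot(is.list(scores), length(scores) >= 1)
  universe <- sort(names(scores[[1]]))
  for (s in scores)
    if (!identical(sort(names(s)), universe))
      stop("all locations must score the same genotype universe")
  n <- length(universe)
  if (k > n) stop("k (", k, ") exceeds the number of genotypes (", n, ")")
  per_loc <- lapply(scores, function(s) {
    ord <- order(-s, names(s))      # descending score, id tie-break
    ranked <- names(s)[ord]
    list(ranked = ranked,
         top = ranked[seq_len(k)],
         bottom = rev(ranked)[seq_len(k)])
  })
  tops <- lapply(per_loc, `[[`, "top")
  bots <- lapply(per_loc, `[[`, "bottom")
  structure(list(per_location = per_loc,
                 top_common = sort(Reduce(intersect, tops)),
                 bottom_common = sort(Reduce(intersect, bots)),
                 k = k),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("Selection outcome (k =", x$k, ") across",
      length(x$per_location), "location(s)\n")
  for (loc in names(x$per_location)) {
    cat("  ", loc, "top:", paste(x$per_location[[loc]]$top, collapse = " "), "\n")
  }
  cat("  common top:", length(x$top_common), "genotype(s):",
      paste(x$top_common, collapse = " "), "\n")
  cat("  common bottom:", length(x$bottom_common), "genotype(s):",
      paste(x$bottom_common, collapse = " "), "\n")
  invisible(x)
}
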