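#' Thousand-seed weight from a 50-seed sample
#'
#' TSW is scored by weighing 50 seeds and multiplying by 20.
#'
#' @param weight_50_seeds weight of 50 seeds in grams, strictly positive.
#' @return thousand-seed weight in grams.
#' @export
score_tsw <- function(weight_50_seeds) {
  if (any(!is.finite(weight_50_seeds)) || any(weight_50_seeds <= 0))
    stop("50-seed weight must be positive and finite")
  weight_50_seeds * 20
}

#' F statistic from mean squares
#'
#' Ratio of a source mean square to the error mean square, rounded to two
#' decimals for display alongside published ANOVA tables.
#'
#' @param ms_source mean square of the tested source.
#' @param ms_error error mean square, strictly positive.
#' @return F = ms_source / ms_error, rounded to 2 decimals.
#' @export
f_from_ms <- function(ms_source, ms_error) {
  if (any(ms_error <= 0)) stop("ms_error must be > 0")
  round(ms_source / ms_error, 2)
}

sig_code <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ifelse(p <= 0.1, "+", ""))))
}

#' Genotype-by-location analysis of variance
#'
#' Fits the balanced multi-environment model
#' \deqn{Y_{ijk} = \mu + g_i + r_j + l_k + (lg)_{ki} + e_{ijk}}
#' for one trait: genotype main effect, replication, location, and the
#' genotype-by-location interaction, with the residual as error term.  Sums
#' of squares are computed from marginal means (balanced data only) and each
#' F statistic is the source mean square over the error mean square.
#' Replication is treated as crossed with location by default, matching the
#' model as written; `nested_reps = TRUE` nests replications within
#' locations instead (the physical field layout).
#'
#' The returned object also carries method-of-moments variance components
#' (all-random expected-mean-squares scheme), their percentages of the
#' component sum (V.cp\%), and broad-sense heritability.
#'
#' @param p a [phenotype_table()].
#' @param trait trait name present in `p`.
#' @param nested_reps logical; nest replications within locations.
#' @return object of class `"anova_gxl"`: list with `table` (source, df, ss,
#'   ms, f, p, sig), `dims`, `trait`, `components`, `vcp_percent`, `h2`.
#' @seealso [variance_components()], [vcp_percent()], [heritability()]
#' @export
anova_gxl <- function(p, trait, nested_reps = FALSE) {
  bal <- check_balance(p, trait)
  if (!bal$balanced)
    stop("unbalanced or incomplete data for trait '", trait,
         "': ", nrow(bal$missing_cells), " missing cell(s); ",
         "see check_balance() for the unbalance report")
  g <- unname(bal$dims["g"]); l <- unname(bal$dims["l"]); r <- unname(bal$dims["r"])
  if (g < 2 || l < 2 || r < 2)
    stop("need at least 2 genotypes, 2 locations and 2 reps (zero df otherwise)")
  d <- p[p$trait == trait, , drop = FALSE]
  y <- d$value
  G <- factor(d$genotype); L <- factor(d$location); R <- factor(d$rep)
  grand <- mean(y)
  m_g <- tapply(y, G, mean); m_l <- tapply(y, L, mean)
  m_gl <- tapply(y, list(G, L), mean)
  ss_g <- l * r * sum((m_g - grand)^2)
  ss_l <- g * r * sum((m_l - grand)^2)
  ss_gl <- r * sum((m_gl - outer(m_g, rep(1, l)) -
                      outer(rep(1, g), m_l) + grand)^2)
  if (nested_reps) {
    m_rl <- tapply(y, list(R, L), mean)
    ss_r <- g * sum((sweep(m_rl, 2, m_l))^2)
    df_r <- l * (r - 1)
  } else {
    m_r <- tapply(y, R, mean)
    ss_r <- g * l * sum((m_r - grand)^2)
    df_r <- r - 1
  }
  ss_tot <- sum((y - grand)^2)
  ss_e <- ss_tot - ss_g - ss_l - ss_gl - ss_r
  ss_e <- max(ss_e, 0)
  df <- c(L = l - 1, R = df_r, G = g - 1, GxL = (g - 1) * (l - 1))
  df <- c(df, Error = (g * l * r - 1) - sum(df))
  ss <- c(L = ss_l, R = ss_r, G = ss_g, GxL = ss_gl, Error = ss_e)
  ms <- ss / df
  fstat <- if (ms["Error"] > 0) ms[1:4] / ms["Error"] else rep(NA_real_, 4)
  pval <- stats::pf(fstat, df[1:4], df["Error"], lower.tail = FALSE)
  tab <- data.frame(source = names(df), df = as.integer(df), ss = ss, ms = ms,
                    f = c(fstat, NA), p = c(pval, NA),
                    sig = c(sig_code(pval), ""), row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- structure(list(table = tab, dims = c(g = g, l = l, r = r),
                        trait = trait, nested_reps = nested_reps),
                   class = "anova_gxl")
  vc <- variance_components(out)
  out$components <- vc
  out$vcp_percent <- if (sum(vc$components) > 0) vcp_percent(vc$components) else
    stats::setNames(rep(NA_real_, length(vc$components)), names(vc$components))
  out$h2 <- heritability(out)
  out
}

#' @export
print.anova_gxl <- function(x, ...) {
  cat("G x L ANOVA for trait", x$trait,
      sprintf("(%d genotypes x %d locations x %d reps)\n",
              x$dims["g"], x$dims["l"], x$dims["r"]))
  tab <- x$table
  tab$vcp_pct <- round(x$vcp_percent[match(tab$source, names(x$vcp_percent))], 2)
  tab$ss <- signif(tab$ss, 6); tab$ms <- signif(tab$ms, 6)
  tab$f <- round(tab$f, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("H^2 = %.2f\n", x$h2))
  invisible(x)
}

ms_of <- function(a, source) {
  a$table$ms[match(source, a$table$source)]
}

#' Method-of-moments variance components for the G x L model
#'
#' Solves the all-random expected-mean-squares equations of the balanced
#' genotype x location x replication layout:
#' \deqn{\hat\sigma^2_e = MS_E,\quad
#'       \hat\sigma^2_{GL} = (MS_{GL} - MS_E)/r,\quad
#'       \hat\sigma^2_{G} = (MS_G - MS_{GL})/(rl),}
#' \deqn{\hat\sigma^2_{L} = (MS_L - MS_{GL})/(gr),\quad
#'       \hat\sigma^2_{R} = (MS_R - MS_E)/(gl).}
#' Genotype and location are declared fixed in the testing model, but
#' components are only meaningful under an all-random scheme, so that scheme
#' is used here for estimation.  Negative estimates are truncated to zero;
#' the untruncated values are kept for audit.
#'
#' @param a an [anova_gxl()] result, or a named numeric vector of mean
#'   squares `c(L=, R=, G=, GxL=, Error=)`.
#' @param g,l,r design dimensions (taken from `a` when it is an
#'   `anova_gxl`).
#' @param nested_reps logical; use the nested-replication divisor
#'   `(MS_R - MS_E)/g` for the replication component.
#' @return list with `components` (truncated, named G, GxL, L, R, Error),
#'   `raw` (untruncated) and `truncated` (logical flags).
#' @export
variance_components <- function(a, g = NULL, l = NULL, r = NULL,
                                nested_reps = FALSE) {
  if (inherits(a, "anova_gxl")) {
    g <- unname(a$dims["g"]); l <- unname(a$dims["l"]); r <- unname(a$dims["r"])
    nested_reps <- a$nested_reps
    ms <- stats::setNames(a$table$ms, a$table$source)
  } else {
    ms <- a
    if (is.null(g) || is.null(l) || is.null(r))
      stop("supply design dimensions g, l, r with a mean-square vector")
  }
  need <- c("L", "R", "G", "GxL", "Error")
  if (!all(need %in% names(ms)))
    stop("mean squares must be named ", paste(need, collapse = ", "))
  raw <- c(
    G = (ms[["G"]] - ms[["GxL"]]) / (r * l),
    GxL = (ms[["GxL"]] - ms[["Error"]]) / r,
    L = (ms[["L"]] - ms[["GxL"]]) / (g * r),
    R = if (nested_reps) (ms[["R"]] - ms[["Error"]]) / g
        else (ms[["R"]] - ms[["Error"]]) / (g * l),
    Error = ms[["Error"]])
  comp <- pmax(raw, 0)
  list(components = comp, raw = raw, truncated = raw < 0)
}

#' Variance components as percentages (V.cp\%)
#'
#' Each (non-negative) component divided by the sum of all components,
#' times 100.
#'
#' @param components non-negative named numeric vector of variance
#'   components.
#' @return named numeric vector summing to 100.
#' @export
vcp_percent <- function(components) {
  if (is.list(components)) components <- components$components
  stopifnot(all(components >= 0))
  s <- sum(components)
  if (s == 0) stop("all variance components are zero; V.cp% undefined")
  100 * components / s
}

#' Broad-sense heritability from mean squares
#'
#' Entry-mean broad-sense heritability under the balanced G x L model,
#' computed as \eqn{H^2 = 1 - MS_E / MS_G} (equivalently \eqn{1 - 1/F_G}),
#' clamped to \eqn{[0, 1]}.
#'
#' @param ms_g genotype mean square, or an [anova_gxl()] result.
#' @param ms_e error mean square (ignored when `ms_g` is an `anova_gxl`).
#' @return heritability in `[0, 1]`; 0 with a warning when `ms_g` is 0.
#' @export
heritability <- function(ms_g, ms_e = NULL) {
  if (inherits(ms_g, "anova_gxl")) {
    a <- ms_g
    ms_e <- ms_of(a, "Error")
    ms_g <- ms_of(a, "G")
  }
  if (ms_g == 0) {
    warning("MS_G is zero; heritability reported as 0")
    return(0)
  }
  min(max(1 - ms_e / ms_g, 0), 1)
}

#' Per-trait, per-location summaries of genotype means
#'
#' Minimum, maximum, mean and standard deviation of the genotype means
#' within each location, for every trait in the table.
#'
#' @param p a [phenotype_table()].
#' @return data.frame with columns trait, location, n, min, max, mean, sd.
#' @export
trait_summaries <- function(p) {
  out <- do.call(rbind, lapply(traits(p), function(tr) {
    gm <- genotype_means(p, tr)
    do.call(rbind, lapply(colnames(gm), function(loc) {
      v <- gm[, loc]
      v <- v[!is.na(v)]
      data.frame(trait = tr, location = loc, n = length(v),
                 min = min(v), max = max(v), mean = mean(v),
                 sd = stats::sd(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Trait correlation matrix on genotype means, within and across locations
#'
#' Each variable is one trait at one location (labelled `trait@location`),
#' valued at the genotype mean over replications; correlations are computed
#' across genotypes.  The matrix therefore contains the within-location
#' blocks and the cross-location block (same or different trait at the two
#' locations) in one symmetric matrix.  Spearman rank correlation is the
#' default.  Zero-variance variables give missing entries and are flagged.
#'
#' @param p a [phenotype_table()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `"zero_variance"` lists degenerate variables, if any.
#' @export
correlation_matrix <- function(p, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  vars <- list()
  for (tr in traits(p)) {
    gm <- genotype_means(p, tr)
    for (loc in colnames(gm))
      vars[[paste0(tr, "@", loc)]] <- gm[, loc]
  }
  gens <- sort(unique(unlist(lapply(vars, names))))
  X <- vapply(vars, function(v) v[match(gens, names(v))], numeric(length(gens)))
  if (nrow(X) < 3) stop("need at least 3 genotypes for correlations")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  flat <- names(sds)[!is.na(sds) & sds == 0]
  cm <- suppressWarnings(stats::cor(X, method = method,
                                    use = "pairwise.complete.obs"))
  if (length(flat)) cm[flat, ] <- cm[, flat] <- NA_real_
  diag(cm) <- 1
  attr(cm, "zero_variance") <- flat
  cm
}
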