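#' Default trait specification for the simulator
#'
#' Four seed traits on the scale of a faba bean multi-environment trial:
#' thousand-seed weight (TSW, g), seed length (SL, cm), seed width (SW,
#' cm) and seed area (SA, cm²).  Variance components (polygenic genotype,
#' genotype x location, location, replication, plot error) for TSW, SL and
#' SW follow the method-of-moments solution of published mean squares for
#' such a trial (G and G x L dominate, small error); SA uses values on the
#' same pattern at its own scale.
#'
#' @return data.frame with columns trait, mean, sigma2_G, sigma2_GL,
#'   sigma2_L, sigma2_R, sigma2_E.
#' @export
default_trait_spec <- function() {
  data.frame(
    trait = c("TSW", "SL", "SW", "SA"),
    mean = c(700, 2.2, 1.6, 2.9),
    sigma2_G = c(237.4, 0.478, 0.280, 0.30),
    sigma2_GL = c(772.9, 1.803, 0.901, 0.90),
    sigma2_L = c(41.4, 0.601, 0, 0.30),
    sigma2_R = c(9.0, 0.046, 0.018, 0.02),
    sigma2_E = c(197.3, 0.71, 0.376, 0.40),
    stringsAsFactors = FALSE)
}

#' Default planted-QTL specification
#'
#' One major-effect QTL (explaining well over 10\% of phenotypic variance
#' in TSW) and two minor QTLs.  `location = NA` means the allele acts in
#' every location; a location identifier restricts it.
#'
#' @return data.frame with columns trait, marker (column index), effect
#'   (trait units per alternate-allele dosage), location.
#' @export
default_qtl_spec <- function() {
  data.frame(trait = c("TSW", "TSW", "SL"),
             marker = c(101L, 1001L, 2001L),
             effect = c(28, 6, 0.35),
             location = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulation configuration for a structured multi-environment trial
#'
#' Defaults describe the emulated study: 110 genotypes grown at 2
#' locations with 3 replications; 33,165 SNPs on six chromosomes with
#' chromosome 1 split into arms 1S and 1L; four subpopulations of
#' Balding-Nichols divergence `fst`; seed traits with genotype- and
#' G x L-dominated variance; planted major and minor QTLs.
#'
#' @param n_genotypes,n_locations,n_reps trial dimensions.
#' @param n_markers number of biallelic SNPs.
#' @param chromosomes character vector of chromosome labels; markers are
#'   assigned evenly in this order.
#' @param n_subpops number of subpopulations K.
#' @param fst Balding-Nichols divergence F in `[0, 1)`.
#' @param traits trait specification as in [default_trait_spec()].
#' @param genetic_cor genetic correlation matrix among traits (symmetric,
#'   unit diagonal, positive semi-definite); default 0.8 off-diagonal,
#'   reflecting the strong positive correlations typical of seed
#'   dimensions.
#' @param qtl planted-QTL table as in [default_qtl_spec()], or `NULL`.
#' @param nested_reps logical; if `TRUE` replication effects are drawn per
#'   (location, rep) — the physical field layout — instead of per rep
#'   shared across locations as the analysis model writes them.
#' @param chrom_length chromosome length in bp for position sampling.
#' @param seed default random seed used when the simulation functions are
#'   called without one.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_genotypes = 110, n_locations = 2, n_reps = 3,
                       n_markers = 33165,
                       chromosomes = c("1S", "1L", "2", "3", "4", "5", "6"),
                       n_subpops = 4, fst = 0.15,
                       traits = default_trait_spec(),
                       genetic_cor = NULL,
                       qtl = default_qtl_spec(),
                       nested_reps = FALSE,
                       chrom_length = 1e9,
                       seed = 1L) {
  nt <- nrow(traits)
  if (is.null(genetic_cor)) {
    genetic_cor <- matrix(0.8, nt, nt); diag(genetic_cor) <- 1
  }
  stopifnot(n_genotypes >= 2, n_locations >= 1, n_reps >= 1, n_markers >= 1,
            n_subpops >= 1, fst >= 0, fst < 1)
  vc_cols <- c("sigma2_G", "sigma2_GL", "sigma2_L", "sigma2_R", "sigma2_E")
  stopifnot(all(vc_cols %in% names(traits)))
  if (any(as.matrix(traits[, vc_cols]) < 0))
    stop("variance components must be non-negative")
  stopifnot(nrow(genetic_cor) == nt, ncol(genetic_cor) == nt)
  if (max(abs(genetic_cor - t(genetic_cor))) > 1e-10 ||
      any(abs(diag(genetic_cor) - 1) > 1e-10))
    stop("genetic correlation matrix must be symmetric with unit diagonal")
  if (min(eigen(genetic_cor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("genetic correlation matrix must be positive semi-definite")
  if (!is.null(qtl)) {
    stopifnot(all(c("trait", "marker", "effect") %in% names(qtl)))
    if (!all(qtl$trait %in% traits$trait))
      stop("QTL trait not in trait specification")
    if (is.null(qtl$location)) qtl$location <- NA_character_
  }
  structure(list(n_genotypes = n_genotypes, n_locations = n_locations,
                 n_reps = n_reps, n_markers = n_markers,
                 chromosomes = chromosomes, n_subpops = n_subpops,
                 fst = fst, traits = traits, genetic_cor = genetic_cor,
                 qtl = qtl, nested_reps = nested_reps,
                 chrom_length = chrom_length, seed = seed),
            class = "sim_config")
}

#' Simulate genotypes with subpopulation structure
#'
#' Ancestral allele frequencies are drawn from Uniform(0.05, 0.95); each
#' subpopulation's frequencies come from the Balding-Nichols distribution
#' \eqn{\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)} (at \eqn{F = 0} all
#' subpopulations share the ancestral frequency), and dosages are
#' Hardy-Weinberg binomial draws within subpopulation.  Markers are
#' assigned evenly to the configured chromosomes with sorted positions.
#' Samples are split evenly across subpopulations.
#'
#' @param cfg a [sim_config()].
#' @param seed random seed (default `cfg$seed`).
#' @return a [genotype_matrix()] with attribute `"subpop"` (integer
#'   subpopulation of each sample).
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- cfg$n_genotypes; m <- cfg$n_markers; K <- cfg$n_subpops; F <- cfg$fst
  p_anc <- stats::runif(m, 0.05, 0.95)
  sub <- sort(rep_len(seq_len(K), n))
  calls <- matrix(NA_integer_, n, m)
  for (k in seq_len(K)) {
    rows <- which(sub == k)
    p_k <- if (F > 0)
      stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    else p_anc
    calls[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2L, rep(p_k, each = length(rows))),
      length(rows), m)
  }
  rownames(calls) <- sprintf("FB-%03d", seq_len(n))
  n_chr <- length(cfg$chromosomes)
  chrom <- rep(cfg$chromosomes, each = ceiling(m / n_chr))[seq_len(m)]
  pos <- integer(m)
  for (ch in cfg$chromosomes) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(cfg$chrom_length, length(i)))
  }
  map <- data.frame(marker = sprintf("M%05d", seq_len(m)),
                    chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, map)
  attr(g, "subpop") <- sub
  g
}

#' Simulate phenotypes under the G x L trial model
#'
#' Observations follow
#' \deqn{Y_{ijk} = \mu + g_i + r_j + l_k + (lg)_{ki} + e_{ijk}:}
#' polygenic genotype effects are multivariate normal across traits with
#' the configured genetic covariance, planted QTLs add dosage x effect to
#' the carrier genotypes (per location when the QTL is
#' location-restricted), G x L deviations are independent normal per
#' (genotype, location), replication effects are shared across genotypes
#' within a replication (crossed with location by default, nested when
#' `cfg$nested_reps`), and plot errors are iid.  The returned table is
#' balanced: every (genotype, location, rep) cell is present once per
#' trait.
#'
#' @param cfg a [sim_config()].
#' @param g a [genotype_matrix()] with `cfg$n_genotypes` samples (only
#'   needed when QTLs are planted; pass `NULL` for a purely polygenic
#'   simulation).
#' @param seed random seed (default `cfg$seed + 1` so that genotype and
#'   phenotype draws are decoupled).
#' @return a [phenotype_table()].  Attribute `"true_effects"` carries the
#'   simulated genotype effects (genotype x trait, QTL contribution
#'   included, averaged over locations).
#' @export
simulate_phenotypes <- function(cfg, g = NULL, seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genotypes; nl <- cfg$n_locations; nr <- cfg$n_reps
  tr <- cfg$traits; nt <- nrow(tr)
  qtl <- cfg$qtl
  if (!is.null(qtl) && nrow(qtl) > 0) {
    if (is.null(g)) stop("planted QTLs require a genotype matrix")
    if (n_samples(g) != n)
      stop("genotype count (", n_samples(g), ") does not match cfg (", n, ")")
    if (any(qtl$marker < 1 | qtl$marker > n_markers(g)))
      stop("QTL marker index out of range (1..", n_markers(g), ")")
  }
  set.seed(seed)
  gens <- if (!is.null(g)) rownames(g$calls) else sprintf("FB-%03d", seq_len(n))
  locs <- paste0("L", seq_len(nl))
  reps <- paste0("R", seq_len(nr))
  sd_G <- sqrt(tr$sigma2_G)
  Rchol <- chol(cfg$genetic_cor + 1e-10 * diag(nt))
  geno_eff <- (matrix(stats::rnorm(n * nt), n, nt) %*% Rchol) *
    rep(sd_G, each = n)                      # n x traits, cov = D C D
  colnames(geno_eff) <- tr$trait
  loc_eff <- vapply(seq_len(nt), function(t)
    stats::rnorm(nl, 0, sqrt(tr$sigma2_L[t])), numeric(nl))
  gl_eff <- array(stats::rnorm(n * nl * nt), c(n, nl, nt)) *
    rep(sqrt(tr$sigma2_GL), each = n * nl)
  if (cfg$nested_reps) {
    rep_eff <- array(stats::rnorm(nr * nl * nt), c(nr, nl, nt)) *
      rep(sqrt(tr$sigma2_R), each = nr * nl)
  } else {
    rep_eff0 <- vapply(seq_len(nt), function(t)
      stats::rnorm(nr, 0, sqrt(tr$sigma2_R[t])), numeric(nr))
    rep_eff <- array(rep(rep_eff0, each = 1), c(nr, nl, nt))
    for (t in seq_len(nt)) rep_eff[, , t] <- rep_eff0[, t]  # shared over locations
  }
  # per-(genotype, location, trait) expected value
  mu_glt <- array(0, c(n, nl, nt))
  for (t in seq_len(nt)) {
    mu_glt[, , t] <- tr$mean[t] + geno_eff[, t] +
      rep(loc_eff[, t], each = n) + gl_eff[, , t]
  }
  if (!is.null(qtl) && nrow(qtl) > 0) {
    for (q in seq_len(nrow(qtl))) {
      t <- match(qtl$trait[q], tr$trait)
      dos <- as.numeric(g$calls[, qtl$marker[q]])
      dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      kset <- if (is.na(qtl$location[q])) seq_len(nl)
              else match(qtl$location[q], locs)
      for (k in kset) mu_glt[, k, t] <- mu_glt[, k, t] + dos * qtl$effect[q]
    }
  }
  rows <- expand.grid(genotype = seq_len(n), location = seq_len(nl),
                      rep = seq_len(nr), KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(nt), function(t) {
    e <- stats::rnorm(nrow(rows), 0, sqrt(tr$sigma2_E[t]))
    val <- mu_glt[cbind(rows$genotype, rows$location, t)] +
      rep_eff[cbind(rows$rep, rows$location, t)] + e
    data.frame(genotype = gens[rows$genotype], location = locs[rows$location],
               rep = reps[rows$rep], trait = tr$trait[t], value = val,
               stringsAsFactors = FALSE)
  }))
  p <- phenotype_table(out)
  true_gen <- geno_eff
  if (!is.null(qtl) && nrow(qtl) > 0) {
    for (q in seq_len(nrow(qtl))) {
      t <- match(qtl$trait[q], tr$trait)
      dos <- as.numeric(g$calls[, qtl$marker[q]])
      dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      w <- if (is.na(qtl$location[q])) 1 else 1 / nl
      true_gen[, t] <- true_gen[, t] + w * dos * qtl$effect[q]
    }
  }
  rownames(true_gen) <- gens
  attr(p, "true_effects") <- true_gen
  p
}
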