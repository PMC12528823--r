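# Independent oracles and fixture builders used across the suite.

# Brute-force ANOVA sums of squares by sequential mean subtraction:
# each term is the sum over *observations* of its squared marginal effect.
oracle_anova_ss <- function(d) {
  y <- d$value
  grand <- mean(y)
  eff_g <- tapply(y, d$genotype, mean) - grand
  eff_l <- tapply(y, d$location, mean) - grand
  eff_r <- tapply(y, d$rep, mean) - grand
  cell <- tapply(y, list(d$genotype, d$location), mean)
  eff_gl <- sweep(sweep(cell, 1, tapply(y, d$genotype, mean)), 2,
                  tapply(y, d$location, mean)) + grand
  fitted <- grand + eff_g[d$genotype] + eff_l[d$location] + eff_r[d$rep] +
    eff_gl[cbind(d$genotype, d$location)]
  c(L = sum(eff_l[d$location]^2),
    R = sum(eff_r[d$rep]^2),
    G = sum(eff_g[d$genotype]^2),
    GxL = sum(eff_gl[cbind(d$genotype, d$location)]^2),
    Error = sum((y - fitted)^2),
    Total = sum((y - grand)^2))
}

# random balanced g x l x r table for one trait
random_balanced_pheno <- function(g, l, r, trait = "T1", sd = 1) {
  d <- expand.grid(genotype = sprintf("g%02d", 1:g),
                   location = sprintf("loc%d", 1:l),
                   rep = sprintf("r%d", 1:r),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$trait <- trait
  d$value <- rnorm(nrow(d), 10, sd)
  phenotype_table(d)
}

# Hudson Fst estimator from per-subpopulation allele counts
hudson_fst <- function(calls, sub) {
  ks <- sort(unique(sub))
  stopifnot(length(ks) == 2)
  p1 <- colMeans(calls[sub == ks[1], , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(calls[sub == ks[2], , drop = FALSE], na.rm = TRUE) / 2
  n1 <- 2 * sum(sub == ks[1]); n2 <- 2 * sum(sub == ks[2])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

# Spearman rank correlation by the hand formula 1 - 6*sum(d^2)/(n(n^2-1))
spearman_hand <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# tiny VCF fixture text (3 samples x 2 biallelic SNPs + 1 tri-allelic)
fixture_vcf_lines <- function(with_triallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1S\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "2\t250\tsnp2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t./.")
  if (with_triallelic)
    lines <- c(lines,
      "2\t300\tsnp3\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
      "3\t400\tsnp4\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0",
      "3\t500\tsnp5\tG\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  lines
}

# small genotype matrix built directly
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  genotype_matrix(calls, data.frame(
    marker = paste0("m", seq_len(m)),
    chrom = if (is.null(chrom)) rep("1", m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 100L else pos))
}
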