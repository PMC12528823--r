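#' Long-format phenotype table
#'
#' Trait observations from a multi-environment trial, one row per
#' (genotype, location, replication, trait).  The constructor validates that
#' the key is unique and values are finite or missing.
#'
#' @param df data.frame with columns `genotype`, `location`, `rep`, `trait`,
#'   `value`.
#' @return object of class `"pheno_table"` (a data.frame).
#' @export
phenotype_table <- function(df) {
  need <- c("genotype", "location", "rep", "trait", "value")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[, need]
  df$genotype <- as.character(df$genotype)
  df$location <- as.character(df$location)
  df$rep <- as.character(df$rep)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  key <- paste(df$genotype, df$location, df$rep, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (genotype, location, rep, trait) observation(s)")
  if (any(is.infinite(df$value)))
    stop("non-finite trait values")
  rownames(df) <- NULL
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' @export
print.pheno_table <- function(x, ...) {
  cat("pheno_table:", length(unique(x$genotype)), "genotypes x",
      length(unique(x$location)), "locations x",
      length(unique(x$rep)), "reps;",
      "traits:", paste(unique(x$trait), collapse = ", "), "\n")
  NextMethod()
}

#' List trait names in a phenotype table
#' @param p a [phenotype_table()]
#' @return character vector
#' @export
traits <- function(p) unique(p$trait)

#' Check whether a trait's data form a complete balanced g x l x r design
#'
#' @param p a [phenotype_table()]
#' @param trait trait name
#' @return list with `balanced` (logical), `dims` (g, l, r) and, when
#'   unbalanced, a data.frame `missing_cells` of absent combinations.
#' @export
check_balance <- function(p, trait) {
  d <- p[p$trait == trait & !is.na(p$value), , drop = FALSE]
  gs <- sort(unique(d$genotype)); ls_ <- sort(unique(d$location))
  rs <- sort(unique(d$rep))
  full <- expand.grid(genotype = gs, location = ls_, rep = rs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(x) paste(x$genotype, x$location, x$rep, sep = "\r")
  absent <- !(key(full) %in% key(d))
  list(balanced = !any(absent) && nrow(d) == nrow(full),
       dims = c(g = length(gs), l = length(ls_), r = length(rs)),
       missing_cells = full[absent, , drop = FALSE])
}

#' Genotype means per location for one trait
#'
#' Averages replications within (genotype, location); the unit on which
#' selection indices, GGE tables and association scans operate.
#'
#' @param p a [phenotype_table()]
#' @param trait trait name
#' @return data.frame genotype x location matrix of means (genotypes in
#'   rows, locations in columns)
#' @export
genotype_means <- function(p, trait) {
  d <- p[p$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for trait '", trait, "'")
  tapply(d$value, list(d$genotype, d$location), mean, na.rm = TRUE)
}

#' Read a phenotype CSV
#'
#' Expected header: `genotype,location,rep,<trait1>,<trait2>,...` with one
#' row per plot.  Non-numeric trait cells become missing values with a
#' warning reporting how many.
#'
#' @param path CSV file path.
#' @return a [phenotype_table()] in long format.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("genotype", "location", "rep")
  if (!all(need %in% names(df)))
    stop("phenotype CSV must have columns genotype, location, rep: ", path)
  tr <- setdiff(names(df), need)
  if (length(tr) == 0) stop("phenotype CSV has no trait columns: ", path)
  key <- paste(df$genotype, df$location, df$rep, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (genotype, location, rep) row(s) in ", path)
  n_bad <- 0L
  long <- do.call(rbind, lapply(tr, function(t) {
    raw <- df[[t]]
    v <- suppressWarnings(as.numeric(raw))
    n_bad <<- n_bad + sum(is.na(v) & !is.na(raw) & raw != "" & raw != "NA")
    data.frame(genotype = df$genotype, location = df$location, rep = df$rep,
               trait = t, value = v, stringsAsFactors = FALSE)
  }))
  if (n_bad > 0)
    warning("read_phenotypes: ", n_bad, " non-numeric trait cell(s) set to NA")
  phenotype_table(long)
}

#' Write a phenotype table to CSV
#'
#' Inverse of [read_phenotypes()]: wide layout with one column per trait.
#'
#' @param p a [phenotype_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(p, path) {
  tr <- traits(p)
  base <- unique(p[, c("genotype", "location", "rep")])
  out <- base
  key <- paste(base$genotype, base$location, base$rep, sep = "\r")
  for (t in tr) {
    d <- p[p$trait == t, , drop = FALSE]
    out[[t]] <- d$value[match(key, paste(d$genotype, d$location, d$rep, sep = "\r"))]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
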