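# Fixture builders and independent oracles used across test files.

make_abund <- function(values, kingdom = NULL) {
  if (is.null(kingdom))
    kingdom <- setNames(rep("bacteria", nrow(values)), rownames(values))
  abundance_table(values, kingdom)
}

make_comp <- function(values, classes) {
  compound_table(values, setNames(classes, rownames(values)))
}

make_dm <- function(m, metric = "euclidean") {
  m <- as.matrix(m)
  if (is.null(colnames(m)))
    colnames(m) <- rownames(m) <- paste0("s", seq_len(nrow(m)))
  structure(list(values = m, metric = metric), class = "distance_matrix")
}

# a small, fully spelled-out dataset: 3 taxa x 6 samples plus compounds
tiny_dataset <- function(dir = tempfile()) {
  dir.create(dir)
  samples <- paste0("S", 1:6)
  av <- matrix(c(10, 20, 30, 40, 50, 60,
                 5, 5, 5, 5, 5, 5,
                 1, 2, 1, 2, 1, 2), 3, 6, byrow = TRUE,
               dimnames = list(c("Lacto", "Weiss", "Kaz"), samples))
  cv <- matrix(c(1.0, 2.0, 3.1, 4.2, 5.0, 6.3,
                 0.5, 0.5, 0.6, 0.4, 0.5, 0.5), 2, 6, byrow = TRUE,
               dimnames = list(c("ethyl_acetate", "alanine"), samples))
  meta <- data.frame(sample_id = samples,
                     group = rep(c("CK", "Lpscw"), each = 3),
                     day = rep(c(0, 3, 10), 2), replicate = 1L)
  a <- file.path(dir, "abundance.tsv")
  c_ <- file.path(dir, "compounds.tsv")
  m <- file.path(dir, "metadata.tsv")
  write.table(data.frame(taxon = rownames(av),
                         kingdom = c("bacteria", "bacteria", "fungi"), av,
                         check.names = FALSE),
              a, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(compound = rownames(cv),
                         compound_class = c("ester", "amino_acid"), cv,
                         check.names = FALSE),
              c_, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, m, sep = "\t", quote = FALSE, row.names = FALSE)
  list(abundance = a, compounds = c_, metadata = m, dir = dir,
       av = av, cv = cv, meta = meta)
}

# independent Spearman oracle: rank both vectors, Pearson on the ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# type-7 quantile computed from first principles
quantile_oracle <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# recursive enumeration of all permutations of 1..n (independent of the
# package's internal enumerator)
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# Bray-Curtis / Jaccard from the summation formulas
bray_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)
jaccard_oracle <- function(x, y) {
  a <- sum(x > 0 & y > 0); u <- sum(x > 0 | y > 0)
  1 - a / u
}
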