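#' Taxon-compound association screen
#'
#' Correlates every taxon's relative abundance with every compound's
#' concentration across the shared samples. P-values come from the standard
#' test of the chosen correlation; false-discovery control is
#' Benjamini-Hochberg applied separately within each compound class (esters
#' corrected together, amino acids together, ...). Constant vectors yield a
#' correlation recorded as 0 with p = 1 and `degenerate = TRUE`.
#'
#' @param abund an [abundance_table()] (relative abundances).
#' @param comp a [compound_table()] over the same samples.
#' @param method `"spearman"` (default; rank-based, robust for compositional
#'   abundances) or `"pearson"`.
#' @return data frame with columns taxon, compound, compound_class, rho, p,
#'   q, n, degenerate.
#' @export
pairwise_association <- function(abund, comp, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(samples_of(abund), samples_of(comp))
  if (length(shared) < 4)
    stop("need at least 4 shared samples, have ", length(shared))
  A <- abund$values[, shared, drop = FALSE]
  C <- comp$values[, shared, drop = FALSE]
  grid <- expand.grid(taxon = rownames(A), compound = rownames(C),
                      stringsAsFactors = FALSE)
  res <- mapply(function(tx, cm) {
    x <- A[tx, ]; y <- C[cm, ]
    if (sd(x) == 0 || sd(y) == 0) return(c(0, 1, 1))
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    c(unname(ct$estimate), ct$p.value, 0)
  }, grid$taxon, grid$compound)
  out <- data.frame(taxon = grid$taxon, compound = grid$compound,
                    compound_class = unname(comp$compound_class[grid$compound]),
                    rho = res[1, ], p = res[2, ], q = NA_real_,
                    n = length(shared), degenerate = res[3, ] == 1,
                    stringsAsFactors = FALSE)
  for (cl in unique(out$compound_class)) {
    idx <- out$compound_class == cl
    out$q[idx] <- p.adjust(out$p[idx], method = "BH")
  }
  rownames(out) <- NULL
  out
}

qualifying <- function(results, classes, alpha, rho_min) {
  results[results$compound_class %in% classes &
            !results$degenerate &
            results$rho >= rho_min & results$q < alpha, , drop = FALSE]
}

#' Flavor group: taxa tied to both ester and acid production
#'
#' A taxon joins the Flavor group when it has at least one strong positive
#' association (rho >= `rho_min`, BH q < `alpha`) with an ester-class
#' compound AND at least one with an acid-class compound (classes `acid` or
#' `organic_acid`).
#'
#' @param results output of [pairwise_association()].
#' @param alpha FDR threshold (default 0.05).
#' @param rho_min minimum positive correlation (default 0.6).
#' @return character vector of taxa.
#' @export
assign_flavor_group <- function(results, alpha = 0.05, rho_min = 0.6) {
  for (cl in list("ester", c("acid", "organic_acid"))) {
    if (!any(results$compound_class %in% cl))
      stop("no compounds of class ", paste(cl, collapse = "/"), " present")
  }
  est <- unique(qualifying(results, "ester", alpha, rho_min)$taxon)
  acd <- unique(qualifying(results, c("acid", "organic_acid"), alpha, rho_min)$taxon)
  sort(intersect(est, acd))
}

#' Amino-acid group: taxa tied to free amino acid production
#'
#' Taxa with at least `min_hits` strong positive associations
#' (rho >= `rho_min`, q < `alpha`) to amino_acid-class compounds.
#'
#' @inheritParams assign_flavor_group
#' @param min_hits minimum number of qualifying amino-acid associations.
#' @return character vector of taxa.
#' @export
assign_amino_acid_group <- function(results, alpha = 0.05, rho_min = 0.6,
                                    min_hits = 2) {
  if (!any(results$compound_class == "amino_acid"))
    stop("no compounds of class amino_acid present")
  q <- qualifying(results, "amino_acid", alpha, rho_min)
  hits <- table(q$taxon)
  sort(names(hits)[hits >= min_hits])
}

#' Major group: taxa above a mean relative-abundance threshold
#'
#' @param abund normalized [abundance_table()].
#' @param threshold mean relative abundance that must be strictly exceeded;
#'   default 0.001 (i.e. 0.1%).
#' @return character vector of taxa.
#' @export
assign_major_group <- function(abund, threshold = 0.001) {
  m <- rowMeans(abund$values)
  sort(names(m)[m > threshold])
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis on relative abundances or Jaccard on presence/absence
#' (presence = abundance > 0), via [vegan::vegdist()].
#'
#' @param abund normalized [abundance_table()].
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return a `distance_matrix`: list(values = symmetric matrix with zero
#'   diagonal, metric).
#' @export
distance_matrix <- function(abund, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  X <- t(abund$values)
  if (sum(rowSums(X) == 0) >= 2) stop("two all-zero samples")
  d <- switch(metric,
              bray_curtis = vegan::vegdist(X, method = "bray"),
              jaccard = vegan::vegdist(X > 0, method = "jaccard", binary = TRUE))
  m <- as.matrix(d)
  diag(m) <- 0
  structure(list(values = m, metric = metric), class = "distance_matrix")
}

#' Wrap a precomputed symmetric matrix as a `distance_matrix`
#'
#' @param m symmetric numeric matrix (or `dist`); the diagonal is zeroed.
#' @param metric label recorded on the object.
#' @return a `distance_matrix`.
#' @export
as_distance_matrix <- function(m, metric = "euclidean") {
  m <- as.matrix(m)
  stopifnot(isSymmetric(unname(m), tol = 1e-12))
  diag(m) <- 0
  structure(list(values = m, metric = metric), class = "distance_matrix")
}

upper_vec <- function(m) m[upper.tri(m)]

# all permutations of 1..n (n <= 7), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Mantel test between two distance matrices
#'
#' The statistic is the correlation (Spearman by default) between the two
#' upper-triangle vectors; significance comes from jointly permuting the
#' rows and columns of the second matrix. The Monte Carlo p uses the
#' add-one convention p = (1 + #\{r_perm >= r_obs\}) / (1 + permutations); with
#' `exhaustive = TRUE` (n <= 7) every relabeling is enumerated and
#' p = #\{r_perm >= r_obs\} / n! over all n! permutations, identity included.
#'
#' @param d1,d2 `distance_matrix` objects with identical sample labels.
#' @param method correlation method.
#' @param permutations Monte Carlo permutation count.
#' @param seed integer seed (Monte Carlo only).
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list(r, p, permutations, method).
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        permutations = 999, seed = 1, exhaustive = FALSE) {
  method <- match.arg(method)
  m1 <- d1$values; m2 <- d2$values
  if (!identical(colnames(m1), colnames(m2)))
    stop("distance matrices have mismatched sample labels")
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 samples")
  if (method == "spearman") {
    # ranks are permutation-invariant: rank once, correlate with pearson
    m1 <- matrix(0, n, n); m1[upper.tri(m1)] <- rank(upper_vec(d1$values))
    m1 <- m1 + t(m1)
    m2 <- matrix(0, n, n); m2[upper.tri(m2)] <- rank(upper_vec(d2$values))
    m2 <- m2 + t(m2)
  }
  v1 <- upper_vec(m1)
  stat <- function(perm) cor(v1, upper_vec(m2[perm, perm]))
  r_obs <- stat(seq_len(n))
  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration limited to n <= 7")
    P <- all_perms(n)
    rs <- apply(P, 1, stat)
    p <- sum(rs >= r_obs - 1e-12) / nrow(P)
    permutations <- nrow(P)
  } else {
    set.seed(seed)
    rs <- replicate(permutations, stat(sample(n)))
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (1 + permutations)
  }
  list(r = r_obs, p = p, permutations = permutations, method = method)
}

anosim_R <- function(dm, g) {
  n <- nrow(dm)
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- rank(upper_vec(dm))
  r <- r + t(r)
  same <- outer(g, g, "==")
  ut <- upper.tri(dm)
  (mean(r[ut & !same]) - mean(r[ut & same])) / (n * (n - 1) / 4)
}

#' ANOSIM: rank-based group separation on a distance matrix
#'
#' All pairwise distances are ranked (average ranks on ties);
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4),
#' in \[-1, 1\]. Significance by permuting group labels, add-one Monte Carlo
#' convention, or full enumeration with `exhaustive = TRUE` (n <= 7).
#'
#' @param d a `distance_matrix`.
#' @param labels group assignment, one per sample (>= 2 groups, each with
#'   >= 2 members).
#' @param permutations,seed,exhaustive as in [mantel_test()].
#' @return list(R, p, permutations).
#' @export
anosim_test <- function(d, labels, permutations = 999, seed = 1,
                        exhaustive = FALSE) {
  dm <- d$values
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(dm))
  tb <- table(labels)
  if (length(tb) < 2) stop("need at least 2 groups")
  if (any(tb < 2)) stop("group with a single member: ", names(tb)[tb < 2][1])
  R_obs <- anosim_R(dm, labels)
  n <- nrow(dm)
  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration limited to n <= 7")
    P <- all_perms(n)
    Rs <- apply(P, 1, function(p) anosim_R(dm, labels[p]))
    p <- sum(Rs >= R_obs - 1e-12) / nrow(P)
    permutations <- nrow(P)
  } else {
    set.seed(seed)
    Rs <- replicate(permutations, anosim_R(dm, sample(labels)))
    p <- (1 + sum(Rs >= R_obs - 1e-12)) / (1 + permutations)
  }
  list(R = R_obs, p = p, permutations = permutations)
}

#' Per-sample alpha diversity
#'
#' Shannon entropy (natural log), observed richness, and Pielou's evenness
#' (Shannon / ln richness, 0 for a single-taxon sample).
#'
#' @param abund normalized [abundance_table()].
#' @return data frame with columns sample_id, shannon, pielou, observed.
#' @export
alpha_diversity <- function(abund) {
  out <- apply(abund$values, 2, function(p) {
    p <- p[p > 0]
    sh <- -sum(p * log(p))
    obs <- length(p)
    c(shannon = sh, pielou = if (obs > 1) sh / log(obs) else 0, observed = obs)
  })
  data.frame(sample_id = colnames(out), shannon = out["shannon", ],
             pielou = out["pielou", ], observed = as.integer(out["observed", ]),
             row.names = NULL)
}
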