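presence_matrix <- function(abund) {
  pres <- abund$values > 0
  rich <- colSums(pres)
  if (any(rich == 0))
    stop("sample with richness 0: ", colnames(pres)[which(rich == 0)[1]])
  pres[rowSums(pres) > 0, , drop = FALSE]
}

rc_from_null <- function(null_shared, obs) {
  p_sim <- (sum(null_shared > obs) + 0.5 * sum(null_shared == obs)) /
    length(null_shared)
  2 * (p_sim - 0.5)
}

#' Raup-Crick dissimilarity under a frequency-weighted null model
#'
#' Presence/absence null model in the style of Chase et al. (2011): for each
#' sample pair, null communities with the two observed richnesses are
#' assembled by sequentially drawing species without replacement from the
#' regional pool (all species observed in at least one sample), with
#' probability proportional to each species' occurrence frequency across
#' samples. With `obs` the observed number of shared species,
#' p_sim = (#\{null_shared > obs\} + 0.5 #\{null_shared = obs\}) / reps
#' (half-weight tie convention) and RC = 2 (p_sim - 0.5). RC near -1 means
#' the pair shares more species than the null expects (deterministic
#' assembly); RC near 0 is neutral-compatible; RC near +1 means fewer shared
#' species than chance.
#'
#' Each pair's null draws come from a sub-seed derived from the pair index,
#' so results do not depend on pair evaluation order.
#'
#' @param abund an [abundance_table()]; presence = abundance > 0.
#' @param reps null draws per pair (default 999).
#' @param seed integer seed.
#' @param pool_freq optional named vector of regional-pool weights (one per
#'   taxon of `abund`, all positive entries form the pool). Defaults to the
#'   occurrence counts observed in `abund`; supplying it allows evaluating
#'   samples against a larger or externally defined species pool.
#' @return an `rc_matrix`: list(values = symmetric matrix in \[-1, 1\] with
#'   zero diagonal, reps, seed, pool_frequencies).
#' @export
raup_crick <- function(abund, reps = 999, seed = 1, pool_freq = NULL) {
  if (is.null(pool_freq)) {
    pres <- presence_matrix(abund)
    freq <- rowSums(pres)
  } else {
    if (is.null(names(pool_freq)) ||
        !all(rownames(abund$values) %in% names(pool_freq)))
      stop("pool_freq must be named and cover every taxon")
    keep <- names(pool_freq)[pool_freq > 0]
    pres <- abund$values[intersect(rownames(abund$values), keep), ,
                         drop = FALSE] > 0
    if (any(colSums(pres) == 0)) stop("sample with richness 0")
    freq <- pool_freq[rownames(pres)]
  }
  n <- ncol(pres)
  if (n < 2) stop("need at least 2 samples")
  S <- nrow(pres)
  rc <- matrix(0, n, n, dimnames = list(colnames(pres), colnames(pres)))
  rich <- colSums(pres)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      obs <- sum(pres[, i] & pres[, j])
      sub_seed(seed, 100000L + (i - 1L) * n + j)
      null_shared <- vapply(seq_len(reps), function(r) {
        s1 <- sample.int(S, rich[i], prob = freq)
        s2 <- sample.int(S, rich[j], prob = freq)
        sum(s1 %in% s2)
      }, numeric(1))
      rc[i, j] <- rc[j, i] <- rc_from_null(null_shared, obs)
    }
  }
  structure(list(values = rc, reps = reps, seed = seed,
                 pool_frequencies = freq), class = "rc_matrix")
}

# probability of drawing exactly the species set `idx` (order ignored) by
# sequential weighted sampling without replacement with weights w
set_draw_prob <- function(idx, w) {
  total <- sum(w)
  recurse <- function(remaining, tot) {
    if (!length(remaining)) return(1)
    sum(vapply(seq_along(remaining), function(k) {
      a <- remaining[k]
      w[a] / tot * recurse(remaining[-k], tot - w[a])
    }, numeric(1)))
  }
  recurse(idx, total)
}

#' Exact Raup-Crick by enumeration of weighted draws
#'
#' Closed-form counterpart of [raup_crick()]: enumerates every possible null
#' community for each richness and sums exact draw probabilities. Only
#' feasible for small pools (cost grows combinatorially); intended for
#' validating the Monte Carlo estimator.
#'
#' @param abund an [abundance_table()].
#' @param max_pool refuse pools larger than this (default 10).
#' @return an `rc_matrix` with `reps = Inf`.
#' @export
raup_crick_exact <- function(abund, max_pool = 10) {
  pres <- presence_matrix(abund)
  S <- nrow(pres)
  if (S > max_pool)
    stop("pool of ", S, " species exceeds max_pool = ", max_pool)
  freq <- rowSums(pres)
  n <- ncol(pres)
  rich <- colSums(pres)
  # shared-species distribution for a richness pair, cached by richness
  set_probs <- function(m) {
    sets <- combn(S, m, simplify = FALSE)
    p <- vapply(sets, set_draw_prob, numeric(1), w = freq)
    list(sets = sets, p = p)
  }
  cache <- list()
  get_sp <- function(m) {
    key <- as.character(m)
    if (is.null(cache[[key]])) cache[[key]] <<- set_probs(m)
    cache[[key]]
  }
  rc <- matrix(0, n, n, dimnames = list(colnames(pres), colnames(pres)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      obs <- sum(pres[, i] & pres[, j])
      sp1 <- get_sp(rich[i]); sp2 <- get_sp(rich[j])
      p_gt <- 0; p_eq <- 0
      for (a in seq_along(sp1$sets)) for (b in seq_along(sp2$sets)) {
        sh <- length(intersect(sp1$sets[[a]], sp2$sets[[b]]))
        pr <- sp1$p[a] * sp2$p[b]
        if (sh > obs) p_gt <- p_gt + pr
        else if (sh == obs) p_eq <- p_eq + pr
      }
      rc[i, j] <- rc[j, i] <- 2 * ((p_gt + 0.5 * p_eq) - 0.5)
    }
  }
  structure(list(values = rc, reps = Inf, seed = NA_integer_,
                 pool_frequencies = freq), class = "rc_matrix")
}

rc_to_dissim <- function(x) {
  if (inherits(x, "rc_matrix")) (x$values + 1) / 2 else x$values
}

#' Non-metric multidimensional scaling with restarts
#'
#' Kruskal stress-1 NMDS via [vegan::monoMDS()] run from `restarts` random
#' initial configurations; the lowest-stress solution is returned with
#' coordinates centered at the origin. Raup-Crick matrices are mapped to
#' non-negative dissimilarities by (RC + 1) / 2 first — a monotone map, so
#' the rank-based ordination is unaffected.
#'
#' @param d a `distance_matrix` or `rc_matrix`.
#' @param k embedding dimension.
#' @param restarts random initializations.
#' @param max_iter iterations per restart.
#' @param tol stress value at which iteration stops.
#' @param seed integer seed for the random starts.
#' @return list(coordinates, stress, converged, restarts_used).
#' @export
nmds <- function(d, k = 2, restarts = 10, max_iter = 300, tol = 1e-6, seed = 1) {
  m <- rc_to_dissim(d)
  if (any(!is.finite(m))) stop("non-finite dissimilarity")
  n <- nrow(m)
  if (n < k + 1) stop("need at least k + 1 samples")
  dis <- stats::as.dist(m)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- matrix(rnorm(n * k), n, k)
    fit <- vegan::monoMDS(dis, y = init, k = k, model = "global",
                          maxit = max_iter, smin = tol, sfgrmin = 1e-9)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- scale(best$points, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  rownames(coords) <- colnames(m)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  list(coordinates = coords, stress = best$stress,
       converged = best$icause != 1L, restarts_used = restarts)
}

#' Recompute Kruskal stress-1 from coordinates by isotonic regression
#'
#' Utility for validating an NMDS solution: fits a monotone (pool-adjacent
#' violators) regression of configuration distances on the input
#' dissimilarities and evaluates
#' stress = sqrt(sum((dhat - dist)^2) / sum(dist^2)).
#'
#' @param d a `distance_matrix` or `rc_matrix` (same mapping as [nmds()]).
#' @param coordinates configuration matrix (samples x k).
#' @return stress-1 value.
#' @export
kruskal_stress <- function(d, coordinates) {
  dd <- as.vector(stats::as.dist(rc_to_dissim(d)))
  cd <- as.vector(dist(coordinates))
  o <- order(dd)
  dhat <- stats::isoreg(dd[o], cd[o])$yf
  sqrt(sum((cd[o] - dhat)^2) / sum(cd[o]^2))
}

#' Summarize within-group Raup-Crick structure
#'
#' Aggregates within-group pairwise RC values by fermentation day and
#' overall: mean RC, the fraction in the deterministic band (|RC| >
#' `deterministic_band`) and the fraction in the neutral-compatible band
#' (|RC| < `neutral_band`). Bands are reporting conventions, not tests.
#'
#' @param rc an `rc_matrix`.
#' @param meta [sample_metadata()] covering the RC labels.
#' @param deterministic_band,neutral_band |RC| thresholds (defaults 0.95,
#'   0.5).
#' @return data frame (group, day, n_pairs, mean_rc, frac_deterministic,
#'   frac_neutral); day is `NA` for the overall per-group rows.
#' @export
assembly_summary <- function(rc, meta, deterministic_band = 0.95,
                             neutral_band = 0.5) {
  labs <- colnames(rc$values)
  if (!all(labs %in% meta$sample_id))
    stop("RC labels missing from metadata")
  meta <- meta[match(labs, meta$sample_id), ]
  rows <- list()
  pair_vals <- function(idx) {
    if (length(idx) < 2) return(numeric(0))
    upper_vec(rc$values[idx, idx, drop = FALSE])
  }
  add <- function(group, day, v) {
    if (!length(v)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, day = day, n_pairs = length(v), mean_rc = mean(v),
      frac_deterministic = mean(abs(v) > deterministic_band),
      frac_neutral = mean(abs(v) < neutral_band))
  }
  for (g in unique(meta$group)) {
    for (d in sort(unique(meta$day[meta$group == g])))
      add(g, d, pair_vals(which(meta$group == g & meta$day == d)))
    add(g, NA_integer_, pair_vals(which(meta$group == g)))
  }
  do.call(rbind, rows)
}

#' Write a labeled square matrix (RC or distance) as TSV
#'
#' A comment header records the null-model parameters for `rc_matrix`
#' inputs.
#' @param x an `rc_matrix` or `distance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "rc_matrix"))
    writeLines(sprintf("# raup_crick reps=%s seed=%s", x$reps, x$seed), con)
  else writeLines(sprintf("# metric=%s", x$metric), con)
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
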