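#' Bundle the four screening groups with per-taxon evidence
#'
#' @param flavor,amino_acid,cooccurring,major character vectors of taxa.
#' @param associations output of [pairwise_association()], used to attach
#'   supporting statistics (best qualifying rho per taxon and class).
#' @param network optional `cooccurrence_network` supplying strengths.
#' @param alpha,rho_min thresholds used for the evidence records (should
#'   match the ones used to build the groups).
#' @return a `functional_groups` object: the four sets, a `syncom` slot
#'   (filled by [cross_reference()]), and `provenance`, a data frame
#'   (taxon, group, statistic, value).
#' @export
functional_groups <- function(flavor, amino_acid, cooccurring, major,
                              associations = NULL, network = NULL,
                              alpha = 0.05, rho_min = 0.6) {
  prov <- list()
  prov_df <- function(taxa, group, statistic, value) {
    data.frame(taxon = taxa, group = rep(group, length(taxa)),
               statistic = rep(statistic, length(taxa)), value = value,
               stringsAsFactors = FALSE)
  }
  best_rho <- function(taxa, classes) {
    if (is.null(associations) || !length(taxa)) return(rep(NA_real_, length(taxa)))
    q <- qualifying(associations, classes, alpha, rho_min)
    vapply(taxa, function(tx) {
      v <- q$rho[q$taxon == tx]
      if (length(v)) max(v) else NA_real_
    }, numeric(1))
  }
  prov$flavor <- prov_df(flavor, "flavor", "max_rho_ester_acid",
                         best_rho(flavor, c("ester", "acid", "organic_acid")))
  prov$amino_acid <- prov_df(amino_acid, "amino_acid", "max_rho_amino_acid",
                             best_rho(amino_acid, "amino_acid"))
  prov$cooccurring <- prov_df(
    cooccurring, "cooccurring", "strength",
    if (is.null(network)) rep(NA_real_, length(cooccurring))
    else unname(network$strengths[cooccurring]))
  prov$major <- prov_df(major, "major", "mean_relative_abundance",
                        rep(NA_real_, length(major)))
  structure(list(flavor = flavor, amino_acid = amino_acid,
                 cooccurring = cooccurring, major = major,
                 syncom = character(0),
                 provenance = do.call(rbind, unname(prov))),
            class = "functional_groups")
}

#' @export
print.functional_groups <- function(x, ...) {
  for (g in c("flavor", "amino_acid", "cooccurring", "major", "syncom"))
    cat(sprintf("%-12s (%d): %s\n", g, length(x[[g]]),
                paste(x[[g]], collapse = ", ")))
  invisible(x)
}

#' Cross-reference the screening groups into SynCom candidates
#'
#' Evaluates a set expression over the group names `flavor`, `amino_acid`,
#' `cooccurring` and `major`, where `|` is union and `&` intersection. The
#' default rule — taxa tied to flavor or amino-acid production that are also
#' network hubs and abundant — is one defensible formalization of
#' group cross-referencing; it is configurable because the cross-referencing
#' step has no canonical algebra.
#'
#' @param groups a [functional_groups()] object.
#' @param rule set expression as text.
#' @param min_size warn (not error) when the result is smaller than this.
#' @return the candidate taxon set (character vector); also recorded in the
#'   returned attribute `groups` (updated `functional_groups`) when assigned.
#' @export
cross_reference <- function(groups,
                            rule = "(flavor | amino_acid) & cooccurring & major",
                            min_size = 2) {
  known <- c("flavor", "amino_acid", "cooccurring", "major")
  toks <- regmatches(rule, gregexpr("[A-Za-z_]+", rule))[[1]]
  bad <- setdiff(toks, known)
  if (length(bad)) stop("unknown group name in rule: ", bad[1])
  if (grepl("[^A-Za-z_()|& ]", rule)) stop("rule may only use group names, (), | and &")
  env <- new.env(parent = emptyenv())
  for (g in known) assign(g, groups[[g]], envir = env)
  assign("|", function(a, b) union(a, b), envir = env)
  assign("&", function(a, b) intersect(a, b), envir = env)
  assign("(", `(`, envir = env)
  out <- sort(unique(eval(parse(text = rule)[[1]], envir = env)))
  if (length(out) < min_size)
    warning("cross-reference yielded only ", length(out),
            " candidate(s) (min_size = ", min_size, ")")
  out
}

#' Culturability substitution for SynCom candidates
#'
#' Candidates that were not obtained as culturable strains are replaced by
#' the highest-evidence culturable taxon sharing at least one functional
#' group with them (evidence = the provenance statistic recorded for that
#' taxon in the shared group, typically its best qualifying correlation).
#' Unculturable candidates with no eligible substitute are dropped with a
#' logged reason; culturable candidates pass through unchanged.
#'
#' @param candidates character vector from [cross_reference()].
#' @param culturable character vector of taxa available as isolates.
#' @param groups a [functional_groups()] object (supplies group membership
#'   and evidence).
#' @return list(final = character vector, log = data.frame(candidate,
#'   action, substitute, shared_group, evidence)).
#' @export
substitute_members <- function(candidates, culturable, groups) {
  log <- data.frame(candidate = character(0), action = character(0),
                    substitute = character(0), shared_group = character(0),
                    evidence = numeric(0), stringsAsFactors = FALSE)
  final <- character(0)
  group_names <- c("flavor", "amino_acid", "cooccurring", "major")
  prov <- groups$provenance
  for (cand in candidates) {
    if (cand %in% culturable) {
      final <- c(final, cand)
      next
    }
    shared <- group_names[vapply(group_names,
                                 function(g) cand %in% groups[[g]], logical(1))]
    # eligible: culturable, not already a candidate, in a shared group
    best <- NULL
    for (g in shared) {
      elig <- setdiff(intersect(groups[[g]], culturable), candidates)
      for (e in elig) {
        ev <- prov$value[prov$taxon == e & prov$group == g]
        ev <- if (length(ev) && !all(is.na(ev))) max(ev, na.rm = TRUE) else -Inf
        if (is.null(best) || ev > best$evidence)
          best <- list(taxon = e, group = g, evidence = ev)
      }
    }
    if (is.null(best)) {
      log <- rbind(log, data.frame(candidate = cand, action = "dropped",
                                   substitute = NA_character_,
                                   shared_group = NA_character_,
                                   evidence = NA_real_))
    } else {
      final <- c(final, best$taxon)
      log <- rbind(log, data.frame(candidate = cand, action = "substituted",
                                   substitute = best$taxon,
                                   shared_group = best$group,
                                   evidence = if (is.finite(best$evidence))
                                     best$evidence else NA_real_))
    }
  }
  list(final = sort(unique(final)), log = log)
}
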