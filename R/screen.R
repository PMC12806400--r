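#' Euclidean distance between samples in compound space
#'
#' @param comp a [compound_table()].
#' @param classes restrict to these compound classes (default: all except
#'   physicochemical).
#' @param scale standardize each compound to unit variance first (default
#'   TRUE; concentrations are on heterogeneous scales).
#' @return a `distance_matrix` with metric `"euclidean"`.
#' @export
compound_distance <- function(comp, classes = setdiff(COMPOUND_CLASSES,
                                                      "physicochemical"),
                              scale = TRUE) {
  keep <- names(comp$compound_class)[comp$compound_class %in% classes]
  if (!length(keep)) stop("no compounds in the requested classes")
  X <- t(comp$values[keep, , drop = FALSE])
  if (scale) {
    sds <- apply(X, 2, sd)
    X <- sweep(X, 2, ifelse(sds > 0, sds, 1), "/")
  }
  as_distance_matrix(as.matrix(dist(X)), "euclidean")
}

#' Run the full SynCom screening and assembly pipeline
#'
#' Orchestrates: load (or simulate) -> normalize -> taxon-compound
#' associations -> Flavor / Amino-acid / Major groups -> co-occurrence
#' network and hubs -> cross-reference -> culturability substitution ->
#' beta-diversity distances -> Mantel (per-kingdom community vs flavor
#' compounds) and ANOSIM (compound space, between arms) -> per-kingdom
#' Raup-Crick -> NMDS on RC -> assembly summaries. All result tables are
#' written under `out_dir`, together with `manifest.json` recording every
#' threshold in effect (defaults that formalize choices the screening
#' protocol leaves open are tagged `"protocol_unstated"`).
#'
#' @param out_dir results directory (created if missing).
#' @param abundance_path,compound_path,metadata_path input TSVs; either
#'   these or `simulate` must be given.
#' @param simulate a [syncom_config()]; when given, inputs are generated and
#'   the ground truth is written alongside the results.
#' @param culturable character vector of culturable taxa for the
#'   substitution step (default: all candidates treated as culturable).
#' @param method correlation method for associations and the network.
#' @param alpha,rho_min,min_hits,major_threshold,hub_quantile,rule screening
#'   thresholds; see the individual functions.
#' @param rc_reps Raup-Crick null draws per pair.
#' @param seed integer seed driving every stochastic step.
#' @param keep_partial keep partial outputs if a stage fails.
#' @return invisibly, a list with every intermediate object (dataset,
#'   associations, groups, network, syncom, stats, rc, nmds, summaries).
#' @export
run_screen <- function(out_dir,
                       abundance_path = NULL, compound_path = NULL,
                       metadata_path = NULL, simulate = NULL,
                       culturable = NULL,
                       method = "spearman", alpha = 0.05, rho_min = 0.6,
                       min_hits = 2, major_threshold = 0.001,
                       hub_quantile = 0.8,
                       rule = "(flavor | amino_acid) & cooccurring & major",
                       rc_reps = 999, seed = 1, keep_partial = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fn, name) {
    p <- file.path(out_dir, name)
    fn(p)
    written <<- c(written, p)
    p
  }
  stage <- "config"
  res <- tryCatch({
    if (is.null(simulate) &&
        (is.null(abundance_path) || is.null(compound_path) ||
         is.null(metadata_path)))
      stop("config error: provide abundance_path/compound_path/metadata_path ",
           "or a simulate config")

    stage <- "load"
    if (!is.null(simulate)) {
      ds <- generate_dataset(simulate)
      emit(function(p) jsonlite::write_json(
        ds$truth[c("producers", "hubs", "partners", "major", "shuffled_fungi")],
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE), "ground_truth.json")
    } else {
      ds <- load_dataset(abundance_path, compound_path, metadata_path)
    }

    stage <- "normalize"
    abund <- to_relative_abundance(ds$abundance)

    stage <- "associations"
    assoc <- pairwise_association(abund, ds$compounds, method = method)
    emit(function(p) utils::write.table(assoc, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE), "associations.tsv")

    stage <- "groups"
    flavor <- assign_flavor_group(assoc, alpha = alpha, rho_min = rho_min)
    amino <- assign_amino_acid_group(assoc, alpha = alpha, rho_min = rho_min,
                                     min_hits = min_hits)
    major <- assign_major_group(abund, threshold = major_threshold)

    stage <- "network"
    major_abund <- abundance_table(abund$values[major, , drop = FALSE],
                                   abund$kingdom[major])
    net <- build_network(major_abund, method = method, rho_min = rho_min,
                         alpha = alpha)
    emit(function(p) write_network(net, p,
                                   graphml = file.path(out_dir, "network.graphml")),
         "network_edges.tsv")
    hubs <- hub_taxa(net, quantile = hub_quantile)

    groups <- functional_groups(flavor, amino, hubs, major,
                                associations = assoc, network = net,
                                alpha = alpha, rho_min = rho_min)
    emit(function(p) utils::write.table(
      groups$provenance, p, sep = "\t", quote = FALSE, row.names = FALSE),
      "groups.tsv")

    stage <- "cross_reference"
    candidates <- cross_reference(groups, rule = rule)
    groups$syncom <- candidates

    stage <- "substitution"
    if (is.null(culturable)) culturable <- candidates
    sub <- substitute_members(candidates, culturable, groups)
    syncom_df <- data.frame(
      member = sub$final,
      source_groups = vapply(sub$final, function(tx) paste(
        c("flavor", "amino_acid", "cooccurring", "major")[
          c(tx %in% groups$flavor, tx %in% groups$amino_acid,
            tx %in% groups$cooccurring, tx %in% groups$major)],
        collapse = ","), character(1)),
      substitution = vapply(sub$final, function(tx) {
        i <- which(sub$log$substitute == tx)
        if (length(i)) paste0("substitute_for:", sub$log$candidate[i[1]]) else ""
      }, character(1)), row.names = NULL)
    emit(function(p) utils::write.table(syncom_df, p, sep = "\t",
                                        quote = FALSE, row.names = FALSE),
         "syncom.tsv")

    stage <- "distances"
    meta <- ds$metadata
    bact <- to_relative_abundance(subset_kingdom(abund, "bacteria"))
    fung <- to_relative_abundance(subset_kingdom(abund, "fungi"))
    d_bact <- distance_matrix(bact, "bray_curtis")
    d_fung <- distance_matrix(fung, "bray_curtis")
    d_comp <- compound_distance(ds$compounds)

    stage <- "mantel_anosim"
    mant_b <- mantel_test(d_bact, d_comp, method = method, seed = seed)
    mant_f <- mantel_test(d_fung, d_comp, method = method, seed = seed + 1)
    anos <- anosim_test(d_comp, meta$group[match(colnames(d_comp$values),
                                                 meta$sample_id)],
                        seed = seed + 2)
    stats <- list(
      mantel = list(bacteria_vs_compounds = mant_b,
                    fungi_vs_compounds = mant_f),
      anosim_compounds_between_arms = anos,
      alpha_diversity = alpha_diversity(abund),
      parameters = list(seed = seed, method = method))
    emit(function(p) jsonlite::write_json(stats, p, auto_unbox = TRUE,
                                          digits = NA, pretty = TRUE),
         "stats.json")

    stage <- "raup_crick"
    rc_b <- raup_crick(bact, reps = rc_reps, seed = seed)
    rc_f <- raup_crick(fung, reps = rc_reps, seed = seed + 1)
    emit(function(p) write_matrix_tsv(rc_b, p), "rc_bacteria.tsv")
    emit(function(p) write_matrix_tsv(rc_f, p), "rc_fungi.tsv")

    stage <- "nmds"
    nm_b <- nmds(rc_b, seed = seed)
    nm_f <- nmds(rc_f, seed = seed + 1)
    coords <- rbind(
      data.frame(kingdom = "bacteria", sample_id = rownames(nm_b$coordinates),
                 nm_b$coordinates, stress = nm_b$stress, row.names = NULL),
      data.frame(kingdom = "fungi", sample_id = rownames(nm_f$coordinates),
                 nm_f$coordinates, stress = nm_f$stress, row.names = NULL))
    emit(function(p) utils::write.table(coords, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE), "nmds_coords.tsv")

    stage <- "summaries"
    summ <- rbind(cbind(kingdom = "bacteria", assembly_summary(rc_b, meta)),
                  cbind(kingdom = "fungi", assembly_summary(rc_f, meta)))
    emit(function(p) utils::write.table(summ, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE),
         "assembly_summary.tsv")

    stage <- "manifest"
    manifest <- list(
      seed = seed,
      parameters = list(
        method = list(value = method, provenance = "protocol_unstated"),
        alpha = list(value = alpha, provenance = "protocol_unstated"),
        rho_min = list(value = rho_min, provenance = "protocol_unstated"),
        min_hits = list(value = min_hits, provenance = "protocol_unstated"),
        major_threshold = list(value = major_threshold,
                               provenance = "protocol_stated"),
        hub_quantile = list(value = hub_quantile,
                            provenance = "protocol_unstated"),
        rule = list(value = rule, provenance = "protocol_unstated"),
        rc_reps = list(value = rc_reps, provenance = "protocol_unstated"),
        bh_family = list(value = "per_compound_class",
                         provenance = "protocol_unstated"),
        replicate_handling = list(value = "per_sample",
                                  provenance = "protocol_unstated")),
      r_version = as.character(getRversion()))
    emit(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                          digits = NA, pretty = TRUE),
         "manifest.json")

    list(dataset = ds, abundance = abund, associations = assoc,
         groups = groups, network = net, candidates = candidates,
         syncom = sub, stats = stats, rc = list(bacteria = rc_b, fungi = rc_f),
         nmds = list(bacteria = nm_b, fungi = nm_f), summary = summ,
         manifest = manifest, files = written)
  }, error = function(e) {
    if (!keep_partial) unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
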