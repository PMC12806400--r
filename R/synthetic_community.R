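#' Configuration for the fermentation-community generator
#'
#' Defaults mirror a two-arm chili-fermentation design: a spontaneous control
#' arm ("CK") and an inoculated arm ("Lpscw"), sampled at days 0, 3, 10, 30
#' and 45 with three replicates per time point.
#'
#' @param n_bacteria,n_fungi number of bacterial / fungal genera.
#' @param n_compounds_per_class named integer vector: compounds emitted per
#'   chemical class. Physicochemical rows (pH, reducing_sugar, lactic_acid)
#'   are always emitted and are not counted here.
#' @param n_producers number of planted producer taxa; each drives one
#'   ester, one acid-class compound and two free amino acids.
#' @param n_hubs number of planted hub taxa; each shares a latent factor
#'   with `n_partners` partner taxa.
#' @param n_partners partners per hub (>= 4).
#' @param hub_cor log-scale correlation between a hub and each partner.
#'   Partner-partner correlation is `hub_cor^2`, so the default 0.8 puts hub
#'   edges well above a 0.6 correlation threshold while most partner-partner
#'   edges (0.64 before sampling noise) fall below it.
#' @param producer_hub_overlap number of hub centers that coincide with
#'   producer taxa (keystones that are simultaneously flavor producers and
#'   network hubs, the configuration the cross-reference screen selects
#'   for). The default 0 plants the roles disjointly, so each screening arm
#'   can be benchmarked against its own planted set without confounding:
#'   partners of a producer-hub inherit the producer's trajectory and
#'   therefore legitimately co-vary with its driven compounds.
#' @param days sampling days, ascending, starting at 0.
#' @param replicates replicates per (group, day).
#' @param groups arm labels; the second arm receives the inoculation boost
#'   and any fungal shuffling.
#' @param effect_size producer-to-compound slope (concentration units per
#'   unit relative abundance).
#' @param noise_sd Gaussian noise sd on driven compound concentrations.
#' @param depth multinomial sampling depth for observed abundances;
#'   0 = noiseless latent proportions.
#' @param taxon_noise_sd log-scale replicate noise sd on latent abundances.
#' @param inoculated_boost log-scale abundance boost applied to producer
#'   taxa in the second arm (0 disables the arm contrast).
#' @param fungal_shuffle fraction of fungal taxa whose latent abundances are
#'   randomly permuted across the second arm's samples, erasing their
#'   successional structure there (0 disables; used to plant a
#'   neutral-assembly signal for the Raup-Crick contrast).
#' @param seed integer seed; all outputs are deterministic given the config.
#' @return a validated `syncom_config` list.
#' @export
syncom_config <- function(n_bacteria = 20, n_fungi = 10,
                          n_compounds_per_class = c(ester = 4, acid = 3,
                                                    alcohol = 3, aldehyde = 2,
                                                    phenol = 2, amino_acid = 8,
                                                    organic_acid = 3),
                          n_producers = 4, n_hubs = 3, n_partners = 6,
                          hub_cor = 0.8, producer_hub_overlap = 0,
                          days = c(0, 3, 10, 30, 45), replicates = 3,
                          groups = c("CK", "Lpscw"),
                          effect_size = 5, noise_sd = 0.05, depth = 50000,
                          taxon_noise_sd = 1,
                          inoculated_boost = 1, fungal_shuffle = 0,
                          seed = 1) {
  cfg <- as.list(environment())
  n_taxa <- n_bacteria + n_fungi
  stopifnot(n_bacteria >= 1, n_fungi >= 1,
            n_producers >= 0, n_producers <= n_taxa,
            n_hubs >= 0, n_hubs <= n_taxa, n_partners >= 4,
            hub_cor > 0, hub_cor < 1, producer_hub_overlap >= 0,
            replicates >= 1, length(groups) >= 1,
            effect_size > 0, noise_sd >= 0, depth >= 0,
            fungal_shuffle >= 0, fungal_shuffle <= 1)
  if (is.unsorted(days, strictly = TRUE) || days[1] != 0)
    stop("days must be strictly ascending and start at 0")
  bad <- setdiff(names(cfg$n_compounds_per_class),
                 setdiff(COMPOUND_CLASSES, "physicochemical"))
  if (length(bad)) stop("unknown compound class in config: ", bad[1])
  for (cl in c("ester", "amino_acid")) {
    if (is.na(cfg$n_compounds_per_class[cl]))
      stop("n_compounds_per_class must include ", cl)
  }
  if (n_producers > 0) {
    if (cfg$n_compounds_per_class["ester"] < n_producers ||
        sum(cfg$n_compounds_per_class[c("acid", "organic_acid")], na.rm = TRUE) < n_producers ||
        cfg$n_compounds_per_class["amino_acid"] < 2 * n_producers)
      stop("not enough compounds to assign each producer 1 ester, ",
           "1 acid-class compound and 2 amino acids")
  }
  if (n_hubs * (n_partners + 1) > n_taxa)
    stop("not enough taxa for ", n_hubs, " hubs with ", n_partners, " partners each")
  class(cfg) <- "syncom_config"
  cfg
}

# deterministic substream: reseed from (seed, stream id)
sub_seed <- function(seed, k) {
  set.seed((abs(seed) %% 1000003L) * 1009L + k)
}

# succession shapes over scaled day index u in [0,1]
traj_shape <- function(kind, u, center) {
  switch(kind,
         up = stats::plogis((u - center) * 8),
         down = stats::plogis(-(u - center) * 8),
         bump = exp(-((u - center) / 0.25)^2))
}

#' Generate a synthetic fermentation dataset with ground truth
#'
#' Latent genus trajectories are smooth log-scale succession curves
#' (logistic increase, logistic decrease, or a Gaussian bump over the
#' sampled days) with log-normal replicate noise, closed to relative
#' abundances. Planted hubs share their latent factor with partner taxa;
#' planted producers drive compound concentrations linearly. Observed
#' abundances are multinomial resamples of the latent proportions when
#' `depth > 0`.
#'
#' @param config a [syncom_config()].
#' @return list with `abundance` ([abundance_table()]), `compounds`
#'   ([compound_table()]), `metadata` ([sample_metadata()]) and `truth`, a
#'   ground-truth ledger (producers with their driven compounds, hubs and
#'   their partners, expected major taxa, latent per-day trajectory means).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "syncom_config"))
  cf <- config
  n_taxa <- cf$n_bacteria + cf$n_fungi
  taxa <- c(sprintf("Bact_%02d", seq_len(cf$n_bacteria)),
            sprintf("Fung_%02d", seq_len(cf$n_fungi)))
  kingdom <- setNames(rep(KINGDOMS, c(cf$n_bacteria, cf$n_fungi)), taxa)

  meta <- expand.grid(
    replicate = seq_len(cf$replicates), day = cf$days, group = cf$groups,
    stringsAsFactors = FALSE)[, c("group", "day", "replicate")]
  meta$sample_id <- sprintf("%s_d%02d_r%d", meta$group, meta$day, meta$replicate)
  meta <- sample_metadata(meta)
  n_samp <- nrow(meta)
  u <- setNames((match(meta$day, cf$days) - 1) / (length(cf$days) - 1),
                meta$sample_id)

  ## --- stream 1: taxon roles and trajectory parameters
  sub_seed(cf$seed, 1L)
  mu <- rnorm(n_taxa, 0, 1.5)
  shape_kind <- sample(c("up", "down", "bump"), n_taxa, replace = TRUE)
  shape_center <- runif(n_taxa, 0.2, 0.8)
  amp <- runif(n_taxa, 0.5, 2)
  # the first producer_hub_overlap hub centers coincide with producers
  # (keystone taxa that are simultaneously flavor producers and network
  # hubs, the configuration the downstream cross-reference screens for);
  # remaining hub centers and all partners come from the other taxa
  n_overlap <- min(cf$producer_hub_overlap, cf$n_hubs, cf$n_producers)
  n_extra <- cf$n_hubs - n_overlap
  roles <- sample(n_taxa, cf$n_producers + n_extra + cf$n_hubs * cf$n_partners)
  producers_idx <- roles[seq_len(cf$n_producers)]
  pool <- if (cf$n_producers > 0) roles[-seq_len(cf$n_producers)] else roles
  centers_idx <- c(producers_idx[seq_len(n_overlap)], pool[seq_len(n_extra)])
  if (n_extra > 0) pool <- pool[-seq_len(n_extra)]
  hubs_idx <- integer(0); partners <- list()
  for (h in seq_len(cf$n_hubs)) {
    blk <- pool[((h - 1) * cf$n_partners + 1):(h * cf$n_partners)]
    hubs_idx <- c(hubs_idx, centers_idx[h])
    partners[[taxa[centers_idx[h]]]] <- taxa[blk]
  }
  # producers sit in the abundant tail so they clear the Major filter; hubs
  # and partners get moderate abundance floors so their co-occurrence signal
  # survives multinomial resampling (the hub screen runs on Major taxa)
  mu[producers_idx] <- runif(cf$n_producers, 1.5, 2.5)
  hub_only <- setdiff(hubs_idx, producers_idx)
  if (length(hub_only)) mu[hub_only] <- runif(length(hub_only), 1, 2)
  for (pp in partners) {
    ii <- match(pp, taxa)
    mu[ii] <- pmax(mu[ii], runif(length(ii), 0.5, 1.5))
  }

  ## latent log abundances: trajectory + replicate noise (stream 2)
  sub_seed(cf$seed, 2L)
  traj <- matrix(0, n_taxa, length(cf$days),
                 dimnames = list(taxa, paste0("day", cf$days)))
  for (i in seq_len(n_taxa))
    traj[i, ] <- mu[i] + amp[i] *
      traj_shape(shape_kind[i], (seq_along(cf$days) - 1) / (length(cf$days) - 1),
                 shape_center[i])
  L <- traj[, match(meta$day, cf$days), drop = FALSE] +
    matrix(rnorm(n_taxa * n_samp, 0, cf$taxon_noise_sd), n_taxa, n_samp)
  colnames(L) <- meta$sample_id

  # hub partners load on the hub's centered latent profile with correlation
  # hub_cor, keeping their own mean and scale
  for (h in names(partners)) {
    zh <- scale(L[h, ])[, 1]
    for (p in partners[[h]]) {
      zp <- scale(L[p, ])[, 1]
      mix <- cf$hub_cor * zh + sqrt(1 - cf$hub_cor^2) * zp
      L[p, ] <- mean(L[p, ]) + sd(L[p, ]) * mix
    }
  }

  # arm contrast: inoculation boost on producers in the second arm
  if (length(cf$groups) >= 2 && cf$inoculated_boost != 0 && cf$n_producers > 0) {
    arm2 <- meta$sample_id[meta$group == cf$groups[2]]
    L[producers_idx, arm2] <- L[producers_idx, arm2] + cf$inoculated_boost
  }

  # arm contrast for assembly: neutral-like assembly is emulated by permuting
  # fungal latent abundances ACROSS TAXA within each second-arm sample, so
  # which fungi are abundant (hence detected) in a sample becomes random
  # while each sample's abundance profile is preserved (stream 3)
  shuffled_fungi <- character(0)
  if (length(cf$groups) >= 2 && cf$fungal_shuffle > 0) {
    sub_seed(cf$seed, 3L)
    arm2 <- meta$sample_id[meta$group == cf$groups[2]]
    fungi <- taxa[kingdom == "fungi"]
    n_sh <- round(cf$fungal_shuffle * length(fungi))
    shuffled_fungi <- sample(fungi, n_sh)
    for (s in arm2)
      L[shuffled_fungi, s] <- L[shuffled_fungi, s][sample(n_sh)]
  }

  latent_prop <- sweep(exp(L), 2, colSums(exp(L)), "/")

  ## observed abundances: multinomial resampling (stream 4)
  if (cf$depth > 0) {
    sub_seed(cf$seed, 4L)
    obs <- apply(latent_prop, 2, function(p) rmultinom(1, cf$depth, p)[, 1])
    obs <- sweep(obs, 2, colSums(obs), "/")
    dimnames(obs) <- dimnames(latent_prop)
  } else obs <- latent_prop

  abund <- abundance_table(obs, kingdom)

  ## compounds (stream 5)
  sub_seed(cf$seed, 5L)
  classes <- rep(names(cf$n_compounds_per_class), cf$n_compounds_per_class)
  cnames <- unlist(lapply(names(cf$n_compounds_per_class), function(cl)
    sprintf("%s_%02d", cl, seq_len(cf$n_compounds_per_class[cl]))))
  # baseline: smooth class-level curves + noise
  C <- matrix(0, length(cnames), n_samp, dimnames = list(cnames, meta$sample_id))
  for (i in seq_along(cnames)) {
    kind <- sample(c("up", "down", "bump"), 1)
    lev <- runif(1, 0.5, 3)
    C[i, ] <- pmax(0, lev * traj_shape(kind, u, runif(1, 0.2, 0.8)) +
                     rnorm(n_samp, 0, cf$noise_sd))
  }
  # producer-driven compounds overwrite their baseline
  producers <- list()
  if (cf$n_producers > 0) {
    esters <- cnames[classes == "ester"]
    acids <- cnames[classes %in% c("acid", "organic_acid")]
    aminos <- cnames[classes == "amino_acid"]
    for (k in seq_len(cf$n_producers)) {
      px <- taxa[producers_idx[k]]
      driven <- c(esters[k], acids[k], aminos[2 * k - 1], aminos[2 * k])
      for (cm in driven)
        C[cm, ] <- pmax(0, cf$effect_size * latent_prop[px, ] +
                          rnorm(n_samp, 0, cf$noise_sd))
      producers[[px]] <- driven
    }
  }
  # physicochemical observables: pH and reducing sugar fall, lactate rises
  phys <- rbind(
    pH = 6.5 - 2.7 * stats::plogis((u - 0.35) * 10) - 0.4 * u,
    reducing_sugar = 2 + 18 * stats::plogis(-(u - 0.3) * 9),
    lactic_acid = 15 * stats::plogis((u - 0.25) * 8))
  phys <- phys + matrix(rnorm(3 * n_samp, 0, cf$noise_sd), 3, n_samp)
  phys[phys < 0] <- 0
  colnames(phys) <- meta$sample_id
  C <- rbind(C, phys)
  classes <- c(classes, rep("physicochemical", 3))
  comp <- compound_table(C, setNames(classes, rownames(C)))

  exp_prop <- sweep(exp(traj), 2, colSums(exp(traj)), "/")
  truth <- list(
    producers = producers,
    hubs = taxa[hubs_idx],
    partners = partners,
    major = taxa[rowMeans(exp_prop[, match(meta$day, cf$days), drop = FALSE]) > 0.001],
    shuffled_fungi = shuffled_fungi,
    trajectories = traj)
  list(abundance = abund, compounds = comp, metadata = meta, truth = truth)
}

#' Precision and recall of a found taxon set against a planted set
#'
#' @param found character vector of recovered taxa.
#' @param planted character vector of planted taxa.
#' @param universe optional character vector; if given, any name outside it
#'   is an error (guards against comparing mismatched taxon universes).
#' @return list(precision, recall, n_found, n_planted). Precision is 1 when
#'   both sets are empty and `NA` when `found` is empty but `planted` is not.
#' @export
recovery_stats <- function(found, planted, universe = NULL) {
  if (!is.null(universe)) {
    bad <- setdiff(c(found, planted), universe)
    if (length(bad)) stop("taxon names outside the shared universe: ",
                          paste(bad, collapse = ", "))
  }
  hit <- length(intersect(found, planted))
  precision <- if (length(found) == 0) {
    if (length(planted) == 0) 1 else NA_real_
  } else hit / length(found)
  recall <- if (length(planted) == 0) 1 else hit / length(planted)
  list(precision = precision, recall = recall,
       n_found = length(found), n_planted = length(planted))
}

#' Recovery report: functional groups vs the generator's ground truth
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param groups a [functional_groups()] object.
#' @param universe taxon universe (defaults to the truth's trajectory rows).
#' @return data frame with one row per comparison (producers vs
#'   flavor+amino-acid union, hubs vs co-occurring, major vs major).
#' @export
expected_recovery <- function(truth, groups, universe = rownames(truth$trajectories)) {
  cmp <- list(
    producers = list(found = union(groups$flavor, groups$amino_acid),
                     planted = names(truth$producers)),
    hubs = list(found = groups$cooccurring, planted = truth$hubs),
    major = list(found = groups$major, planted = truth$major))
  out <- do.call(rbind, lapply(names(cmp), function(nm) {
    st <- recovery_stats(cmp[[nm]]$found, cmp[[nm]]$planted, universe)
    data.frame(target = nm, precision = st$precision, recall = st$recall,
               n_found = st$n_found, n_planted = st$n_planted)
  }))
  rownames(out) <- NULL
  out
}

#' Subset an abundance table by kingdom
#' @param abund an `abundance_table`.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return an `abundance_table` restricted to that kingdom.
#' @export
subset_kingdom <- function(abund, kingdom) {
  keep <- names(abund$kingdom)[abund$kingdom == kingdom]
  if (!length(keep)) stop("no taxa of kingdom ", kingdom)
  abundance_table(abund$values[keep, , drop = FALSE], abund$kingdom[keep])
}
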