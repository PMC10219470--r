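# Seeded synthetic-data generator for paired two-condition microbiome
# surveys.  The generative model is logistic-normal -> multinomial:
#
#   log-abundance[sample, otu] = base[otu]
#                              + site intercept[site, otu]        (paired design)
#                              + group effect[otu] * 1{sample in enriched group}
#                              + module factor[sample, m] * loading[otu]
#                              + noise[sample, otu]
#   composition = softmax over OTUs; counts ~ Multinomial(depth, composition)
#
# Latent factors (one Gaussian factor per planted module) inject arbitrary
# positive correlation blocks, which a Dirichlet-multinomial cannot encode;
# each module's hub OTU can also load on the next module's factor, placing
# some of its links between modules.  Soil variables are drawn around
# configured means and can be linearly coupled to the realized relative
# abundance of a named phylum.

#' Configuration for the synthetic generator
#'
#' Defaults emulate a 22-site paired invasion survey: 2 x 22 samples,
#' sequencing depths log-normal around 40,000 reads, five planted
#' genus-level biomarkers at 8-fold change, two correlated OTU modules
#' with hub nodes, and soil couplings in which total carbon tracks
#' Ascomycota (TN nearly collinear with TC, so that VIF screening has a
#' variable to remove).
#'
#' @param n_sites number of paired sites (one sample per condition each).
#' @param n_otus number of OTUs.
#' @param groups two condition labels; the first is the "invaded" group.
#' @param depth_meanlog,depth_sdlog log-normal sequencing depth parameters.
#' @param base_sd sd of per-OTU baseline log-abundance.
#' @param site_sd sd of the shared per-site random intercept.
#' @param noise_sd sd of sample-level log-abundance noise.
#' @param biomarkers data.frame with columns `genus`, `log2fc`, `group`
#'   (which condition the genus is enriched in); each planted genus gets
#'   two dedicated OTUs.  NULL plants none.
#' @param modules list of planted modules, each
#'   `list(size =, loading =, hub_loading =, hub_cross_loading =)`;
#'   memberships are disjoint and each module's first OTU is its hub.
#'   Members load `loading` on the module's latent factor; the hub loads
#'   `hub_loading` on it (and `hub_cross_loading` on the next module's
#'   factor) with its idiosyncratic noise and site intercept shrunk by
#'   `hub_noise_scale`, making it a high-communality node: it correlates
#'   strongly with every member while member-member correlations stay
#'   moderate -- a star-shaped module whose center has a high
#'   within-module degree z-score.  NULL plants none.
#' @param soil data.frame with columns `variable`, `mean`, `sd`, `phylum`
#'   (NA = uncoupled), `coupling` (correlation in [-1, 1]).  The variable
#'   `TN` is treated specially: it is generated as a near-copy of TC
#'   (collinearity `tn_tc_r`).
#' @param tn_tc_r correlation between TN and TC (set 0 to decouple).
#' @param seed mandatory integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_sites = 22L,
                         n_otus = 250L,
                         groups = c("AP", "N"),
                         depth_meanlog = log(40000),
                         depth_sdlog = 0.1,
                         base_sd = 1.5,
                         site_sd = 0.5,
                         noise_sd = 0.3,
                         biomarkers = default_biomarkers(),
                         modules = default_modules(),
                         soil = default_soil_model(),
                         tn_tc_r = 0.97,
                         seed) {
  if (missing(seed) || is.null(seed)) fail("synth_config: seed is mandatory")
  if (length(groups) != 2L || anyDuplicated(groups))
    fail("exactly two distinct group labels required")
  if (!is.null(biomarkers) && any(!is.finite(biomarkers$log2fc)))
    fail("biomarker fold changes must be finite")
  if (!is.null(modules)) {
    sizes <- vapply(modules, `[[`, numeric(1), "size")
    if (sum(sizes) + 2L * NROW(biomarkers) > n_otus)
      fail("module memberships plus biomarker OTUs exceed n_otus")
  }
  structure(list(n_sites = as.integer(n_sites), n_otus = as.integer(n_otus),
                 groups = groups, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, base_sd = base_sd,
                 site_sd = site_sd, noise_sd = noise_sd,
                 biomarkers = biomarkers, modules = modules, soil = soil,
                 tn_tc_r = tn_tc_r, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default planted biomarkers (five genera, 8-fold change)
#' @export
default_biomarkers <- function() {
  data.frame(
    genus  = c("Dioszegia", "Tilletiopsis", "Colacogloea", "Chaetomium", "Alternaria"),
    log2fc = c(3, 3, 3, 3, 3),
    group  = c("AP", "AP", "AP", "AP", "N"),
    stringsAsFactors = FALSE)
}

#' Default planted modules: two 45-OTU star modules with hub nodes
#' @export
default_modules <- function() {
  rep(list(list(size = 45L, loading = 0.6, hub_loading = 1.0,
                hub_cross_loading = 0.1, hub_noise_scale = 0.1)), 2L)
}

#' Default soil model (units: TC/TN/TP g/kg, AN/NN/AP mg/kg)
#' @export
default_soil_model <- function() {
  data.frame(
    variable = c("pH", "TC", "TN", "TP", "AN", "NN", "AP"),
    mean     = c(7.9, 20,  1.5, 0.8, 10,  15,  8),
    sd       = c(0.4, 5,   0.4, 0.2, 3,   5,   3),
    phylum   = c(NA, "Ascomycota", NA, "Basidiomycota", NA, NA, "Basidiomycota"),
    coupling = c(0,  0.6, 0, -0.5, 0, 0, -0.4),
    stringsAsFactors = FALSE)
}

#' The 22-site, 44-sample study preset
#' @param seed integer seed.
#' @param ... overrides passed to [synth_config()].
#' @export
synth_preset44 <- function(seed, ...) {
  synth_config(seed = seed, ...)
}

#' Generate a synthetic paired two-condition dataset
#'
#' @param config a [synth_config()].
#' @return list with `counts` (samples x OTUs), `taxonomy`, `samples`
#'   (metadata incl. soil variables) and `truth` (planted biomarker set,
#'   module memberships, hub identities, soil coupling targets).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_sites <- config$n_sites
  n_samp <- 2L * n_sites
  n_otus <- config$n_otus
  otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))

  sites <- sprintf("S%d", rep(seq_len(n_sites), times = 2L))
  group <- rep(config$groups, each = n_sites)
  sample_ids <- paste(group, sites, sep = "_")

  # --- assign planted structure to OTU indices ------------------------------
  nb <- NROW(config$biomarkers)
  bm_otus <- if (nb) seq_len(2L * nb) else integer(0)  # two OTUs per genus
  next_free <- length(bm_otus) + 1L
  module_members <- list()
  hubs <- integer(0)
  if (!is.null(config$modules)) {
    for (m in seq_along(config$modules)) {
      sz <- config$modules[[m]]$size
      module_members[[m]] <- seq.int(next_free, next_free + sz - 1L)
      hubs[m] <- next_free
      next_free <- next_free + sz
    }
  }

  taxonomy <- synth_taxonomy(otu_ids, config$biomarkers, bm_otus)

  # --- latent log-abundance -------------------------------------------------
  base <- stats::rnorm(n_otus, 0, config$base_sd)
  base[bm_otus] <- 1.0                 # biomarkers at moderate abundance
  for (mem in module_members) base[mem] <- stats::rnorm(length(mem), 1.0, 0.4)

  eta <- matrix(rep(base, each = n_samp), nrow = n_samp,
                dimnames = list(sample_ids, otu_ids))

  noise_scale <- rep(1, n_otus)
  if (length(hubs)) {
    hns <- vapply(config$modules, function(m)
      if (is.null(m$hub_noise_scale)) 1 else m$hub_noise_scale, numeric(1))
    noise_scale[hubs] <- hns
  }

  site_fx <- matrix(stats::rnorm(n_sites * n_otus, 0, config$site_sd), n_sites)
  site_fx <- sweep(site_fx, 2, noise_scale, `*`)
  eta <- eta + site_fx[rep(seq_len(n_sites), 2L), ]

  if (nb) {
    for (b in seq_len(nb)) {
      cols <- bm_otus[c(2L * b - 1L, 2L * b)]
      enriched <- group == config$biomarkers$group[b]
      eta[enriched, cols] <- eta[enriched, cols] +
        config$biomarkers$log2fc[b] * log(2)
    }
  }

  n_mod <- length(module_members)
  if (n_mod) {
    z <- matrix(stats::rnorm(n_samp * n_mod), n_samp)
    for (m in seq_len(n_mod)) {
      spec_m <- config$modules[[m]]
      members <- setdiff(module_members[[m]], hubs[m])
      eta[, members] <- eta[, members] + z[, m] * spec_m$loading
      hub_load <- if (is.null(spec_m$hub_loading)) spec_m$loading
                  else spec_m$hub_loading
      eta[, hubs[m]] <- eta[, hubs[m]] + z[, m] * hub_load
      if (n_mod > 1L) {
        m2 <- if (m == n_mod) 1L else m + 1L
        eta[, hubs[m]] <- eta[, hubs[m]] + z[, m2] * spec_m$hub_cross_loading
      }
    }
  }

  noise <- matrix(stats::rnorm(n_samp * n_otus, 0, config$noise_sd), n_samp)
  eta <- eta + sweep(noise, 2, noise_scale, `*`)

  # --- softmax + multinomial draw ------------------------------------------
  prob <- exp(eta - apply(eta, 1, max))
  prob <- prob / rowSums(prob)
  depth <- round(stats::rlnorm(n_samp, config$depth_meanlog, config$depth_sdlog))
  counts <- t(vapply(seq_len(n_samp),
                     function(s) as.numeric(stats::rmultinom(1, depth[s], prob[s, ])),
                     numeric(n_otus)))
  dimnames(counts) <- list(sample_ids, otu_ids)

  # --- soil variables coupled to realized phylum abundances -----------------
  phy <- aggregate_to_rank(counts, taxonomy, "phylum")
  phy_rel <- phy / rowSums(phy)
  soil <- config$soil
  soil_values <- matrix(NA_real_, n_samp, nrow(soil),
                        dimnames = list(sample_ids, soil$variable))
  tc_z <- NULL
  for (k in seq_len(nrow(soil))) {
    r <- soil$coupling[k]
    target <- soil$phylum[k]
    z <- if (!is.na(target) && r != 0 && target %in% colnames(phy_rel)) {
      x <- phy_rel[, target]
      r * as.numeric(scale(x)) + sqrt(1 - r^2) * stats::rnorm(n_samp)
    } else {
      stats::rnorm(n_samp)
    }
    if (soil$variable[k] == "TN" && !is.null(tc_z) && config$tn_tc_r != 0) {
      r2 <- config$tn_tc_r
      z <- r2 * tc_z + sqrt(1 - r2^2) * stats::rnorm(n_samp)
    }
    if (soil$variable[k] == "TC") tc_z <- z
    soil_values[, k] <- soil$mean[k] + soil$sd[k] * z
  }

  samples <- data.frame(sample_id = sample_ids, group = group, site = sites,
                        soil_values, stringsAsFactors = FALSE,
                        check.names = FALSE)

  truth <- list(
    biomarkers = if (nb) data.frame(
      genus = config$biomarkers$genus,
      group = config$biomarkers$group,
      log2fc = config$biomarkers$log2fc,
      otus = I(lapply(seq_len(nb), function(b)
        otu_ids[bm_otus[c(2L * b - 1L, 2L * b)]])),
      stringsAsFactors = FALSE) else NULL,
    modules = lapply(module_members, function(i) otu_ids[i]),
    hubs = otu_ids[hubs],
    soil_coupling = soil[!is.na(soil$phylum) & soil$coupling != 0,
                         c("variable", "phylum", "coupling")])

  list(counts = counts, taxonomy = taxonomy, samples = samples, truth = truth)
}

#' Generate a null dataset (all planted effects zeroed)
#'
#' Group labels are exchangeable: no biomarker effects, no module factors,
#' no soil-community coupling.  Useful for type-I-error studies.
#'
#' @param config a [synth_config()]; its effects are zeroed internally.
#' @export
synth_generate_null <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  if (!is.null(cfg$biomarkers)) cfg$biomarkers$log2fc[] <- 0
  if (!is.null(cfg$modules))
    cfg$modules <- lapply(cfg$modules, function(m) {
      m$loading <- 0; m$hub_loading <- 0; m$hub_cross_loading <- 0; m
    })
  cfg$soil$coupling[] <- 0
  synth_generate(cfg)
}

# Synthetic taxonomy: biomarker OTUs get their planted genus with a full
# lineage; the rest are assigned to a realistic phylum pool with some
# lineages truncated (unclassified below class/order/family) so composite
# aggregation labels are exercised.
synth_taxonomy <- function(otu_ids, biomarkers, bm_otus) {
  n <- length(otu_ids)
  phyla <- c("Ascomycota", "Basidiomycota", "Mortierellomycota",
             "Glomeromycota", "Chytridiomycota", "Mucoromycota", NA)
  w <- c(0.40, 0.22, 0.10, 0.08, 0.06, 0.06, 0.08)
  tax <- data.frame(otu_id = otu_ids,
                    kingdom = "Fungi", phylum = NA_character_,
                    class = NA_character_, order = NA_character_,
                    family = NA_character_, genus = NA_character_,
                    stringsAsFactors = FALSE)
  ph <- sample(phyla, n, replace = TRUE, prob = w)
  tax$phylum <- ph
  has_p <- !is.na(ph)
  tax$class[has_p] <- paste0(ph[has_p], "_cls")
  # depth of classification below class: 0 = stop at class ... 3 = genus
  depth <- sample(0:3, n, replace = TRUE, prob = c(0.1, 0.15, 0.2, 0.55))
  fam_pool <- sprintf("Family%02d", 1:30)
  gen_pool <- sprintf("Genus%02d", 1:60)
  ord_pool <- sprintf("Order%02d", 1:15)
  ords <- sample(ord_pool, n, replace = TRUE)
  fams <- sample(fam_pool, n, replace = TRUE)
  gens <- sample(gen_pool, n, replace = TRUE)
  tax$order[has_p & depth >= 1] <- ords[has_p & depth >= 1]
  tax$family[has_p & depth >= 2] <- fams[has_p & depth >= 2]
  tax$genus[has_p & depth >= 3] <- gens[has_p & depth >= 3]
  if (NROW(biomarkers)) {
    bm_phylum <- ifelse(biomarkers$group == biomarkers$group[1],
                        "Basidiomycota", "Ascomycota")
    for (b in seq_len(NROW(biomarkers))) {
      cols <- bm_otus[c(2L * b - 1L, 2L * b)]
      tax$phylum[cols] <- bm_phylum[b]
      tax$class[cols] <- paste0(bm_phylum[b], "_cls")
      tax$order[cols] <- paste0(biomarkers$genus[b], "ales")
      tax$family[cols] <- paste0(biomarkers$genus[b], "aceae")
      tax$genus[cols] <- biomarkers$genus[b]
    }
  }
  tax
}
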