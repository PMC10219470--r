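# End-to-end orchestration: synthetic or user data -> rarefaction ->
# diversity + biomarkers, per-group networks, and soil associations,
# with a JSON manifest and deterministic child seeds per stage.

#' Pipeline configuration
#'
#' @param counts,taxonomy,metadata either in-memory objects or paths to
#'   the three TSVs; leave NULL and set `synth` to generate data.
#' @param synth optional [synth_config()]; used when the three inputs are
#'   NULL.
#' @param rarefaction_depth default 30815 reads.
#' @param lefse_alpha,lda_threshold biomarker thresholds (0.05, 3.0).
#' @param lefse_ranks ranks analysed for biomarkers.
#' @param rho_min,p_max,prevalence network thresholds (0.6, 0.05, 0.5).
#' @param zi_threshold,pi_threshold node-role thresholds (2.5, 0.62).
#' @param vif_threshold CCA collinearity screen (10).
#' @param n_permutations ANOSIM / CCA permutation count (999).
#' @param seed master seed; per-stage child seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                            synth = NULL,
                            rarefaction_depth = 30815,
                            lefse_alpha = 0.05, lda_threshold = 3.0,
                            lefse_ranks = c("phylum", "family", "genus"),
                            rho_min = 0.6, p_max = 0.05, prevalence = 0.5,
                            zi_threshold = 2.5, pi_threshold = 0.62,
                            vif_threshold = 10, n_permutations = 999,
                            seed = 1L) {
  thr <- c(rarefaction_depth, lefse_alpha, lda_threshold, rho_min, p_max,
           prevalence, zi_threshold, pi_threshold, vif_threshold,
           n_permutations)
  if (any(!is.finite(thr)) || any(thr <= 0)) fail("all thresholds must be positive")
  cfg <- as.list(environment())
  cfg$thr <- NULL
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load/generate inputs; rarefy; alpha + beta diversity (PCoA,
#' ANOSIM); biomarker discovery; per-group co-occurrence network with
#' modules, Zi-Pi roles and keystones; keystone comparison; soil
#' association (VIF screen, CCA + per-term permutation tests, phylum-soil
#' correlations, LMG importance with summed keystone relative abundance
#' as response).  If the metadata carries no soil columns the environment
#' stage is skipped with a warning.  Identical config and seed give
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's tables
#'   plus a JSON manifest are written there.
#' @return list of stage results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stats::setNames(vapply(1:8, function(i) child_seed(config$seed, i),
                                  integer(1)),
                           c("synth", "rarefy", "anosim", "lefse",
                             "network_a", "network_b", "cca", "spare"))
  warn_log <- character(0)
  note <- function(w) warn_log <<- c(warn_log, conditionMessage(w))

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$counts)) {
    counts <- if (is.character(config$counts))
      read_count_table(config$counts) else config$counts
    tax <- if (is.character(config$taxonomy))
      read_taxonomy(config$taxonomy) else config$taxonomy
    meta <- if (is.character(config$metadata))
      read_sample_frame(config$metadata) else config$metadata
  } else {
    syn_cfg <- config$synth
    if (is.null(syn_cfg)) syn_cfg <- synth_preset44(seed = seeds[["synth"]])
    dat <- synth_generate(syn_cfg)
    counts <- dat$counts; tax <- dat$taxonomy; meta <- dat$samples
  }
  validate_count_table(counts)
  groups_all <- meta$group[match(rownames(counts), meta$sample_id)]
  lev <- unique(groups_all)

  # --- rarefaction ----------------------------------------------------------
  rare <- withCallingHandlers(
    rarefy(counts, config$rarefaction_depth, seed = seeds[["rarefy"]]),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  groups <- meta$group[match(rownames(rare), meta$sample_id)]

  # --- diversity ------------------------------------------------------------
  alpha <- alpha_diversity(rare)
  d <- bray_curtis(rare)
  ord <- pcoa(d)
  ano <- anosim(d, groups, config$n_permutations, seed = seeds[["anosim"]])

  # --- biomarkers -----------------------------------------------------------
  lefse <- run_lefse(rare, tax, meta, ranks = config$lefse_ranks,
                     alpha = config$lefse_alpha,
                     lda_threshold = config$lda_threshold,
                     seed = seeds[["lefse"]])

  # --- per-group networks ---------------------------------------------------
  nets <- list()
  for (gi in seq_along(lev)) {
    g <- lev[gi]
    sub <- rare[groups == g, , drop = FALSE]
    nets[[g]] <- withCallingHandlers(
      group_network(sub, tax, group = g, rho_min = config$rho_min,
                    p_max = config$p_max, prevalence = config$prevalence,
                    seed = seeds[[paste0("network_", letters[gi])]]),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
  }
  key_cmp <- withCallingHandlers(
    compare_keystones(nets[[lev[1]]]$keystones, nets[[lev[2]]]$keystones,
                      rare, meta),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })

  # --- environment ----------------------------------------------------------
  soil_cols <- setdiff(colnames(meta), c("sample_id", "group", "site"))
  env <- NULL
  if (length(soil_cols) >= 2) {
    soil <- meta[match(rownames(rare), meta$sample_id), soil_cols, drop = FALSE]
    vs <- vif_screen(soil, config$vif_threshold)
    Xr <- soil[, vs$retained, drop = FALSE]
    comm <- prevalence_filter(rare, config$prevalence)
    comm <- comm[, colSums(comm) > 0, drop = FALSE]
    cca_fit <- cca_ordination(comm, Xr)
    terms <- cca_term_tests(comm, Xr, config$n_permutations,
                            seed = seeds[["cca"]])
    heat <- withCallingHandlers(
      phylum_soil_correlations(rare, tax, soil),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    key_otus <- union(nets[[lev[1]]]$keystones$taxa$otu_id,
                      nets[[lev[2]]]$keystones$taxa$otu_id)
    key_otus <- intersect(key_otus, colnames(rare))
    imp <- NULL
    if (length(key_otus)) {
      response <- rowSums(rare[, key_otus, drop = FALSE]) / rowSums(rare)
      imp <- lmg_importance(response, Xr)
    }
    env <- list(vif = vs, cca = cca_fit, term_tests = terms,
                heatmap = heat, importance = imp)
  } else {
    warn_log <- c(warn_log, "no soil variables in metadata; environment stage skipped")
  }

  manifest <- list(
    config = list(rarefaction_depth = config$rarefaction_depth,
                  lefse_alpha = config$lefse_alpha,
                  lda_threshold = config$lda_threshold,
                  rho_min = config$rho_min, p_max = config$p_max,
                  prevalence = config$prevalence,
                  vif_threshold = config$vif_threshold,
                  n_permutations = config$n_permutations,
                  master_seed = config$seed),
    seeds = as.list(seeds),
    n_samples = nrow(counts), n_samples_rarefied = nrow(rare),
    n_otus = ncol(counts),
    groups = as.list(stats::setNames(as.integer(table(groups)[lev]), lev)),
    anosim = list(R = ano$statistic, p = ano$p_value),
    pcoa = list(axis1_pct = 100 * ord$explained[1],
                axis2_pct = 100 * ord$explained[2]),
    n_biomarkers = sum(lefse$passes),
    networks = lapply(nets, function(nn) as.list(nn$topology)),
    keystones = lapply(nets, function(nn)
      list(count = nrow(nn$keystones$taxa), share_pct = 100 * nn$keystones$share)),
    environment_skipped = is.null(env),
    vif_dropped = if (!is.null(env)) env$vif$dropped$variable else character(0),
    warnings = warn_log)

  result <- list(counts = counts, rarefied = rare, taxonomy = tax,
                 metadata = meta, alpha = alpha, distance = d, pcoa = ord,
                 anosim = ano, lefse = lefse, networks = nets,
                 keystone_comparison = key_cmp, environment = env,
                 manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_count_table(result$rarefied, fp("rarefied_counts.tsv"))
  utils::write.table(result$alpha, fp("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dm <- as.matrix(result$distance)
  utils::write.table(data.frame(sample_id = rownames(dm), dm,
                                check.names = FALSE),
                     fp("bray_curtis.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(result$pcoa$coordinates),
                                result$pcoa$coordinates, check.names = FALSE),
                     fp("pcoa_coordinates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$lefse, fp("lefse_biomarkers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (g in names(result$networks)) {
    nn <- result$networks[[g]]
    write_network(nn$net, fp(paste0("network_", g, ".graphml")), "graphml")
    utils::write.table(nn$roles, fp(paste0("node_roles_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$keystone_comparison,
                     fp("keystone_comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$environment)) {
    utils::write.table(result$environment$term_tests, fp("cca_terms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hm <- result$environment$heatmap
    utils::write.table(data.frame(phylum = rownames(hm$rho), hm$rho,
                                  check.names = FALSE),
                       fp("phylum_soil_rho.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(result$environment$importance))
      utils::write.table(
        data.frame(variable = names(result$environment$importance$shares),
                   lmg_share = result$environment$importance$shares),
        fp("lmg_importance.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
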