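## Run configuration and end-to-end orchestration:
## partition -> MCMC -> consensus -> ancestors -> phenetics,
## with a manifest recording seeds and output checksums.

#' Read and validate a run configuration
#'
#' YAML schema (top-level keys, all optional unless noted):
#' \describe{
#'   \item{matrix}{path to the NEXUS matrix (required).}
#'   \item{blocks}{list of homology-block declarations (`label`,
#'     `states` = list of character-set strings).}
#'   \item{sites}{list of fossil sites (`site`, `min_ma`, `max_ma`,
#'     `taxa`).}
#'   \item{constraints}{list of taxon-label vectors (clades).}
#'   \item{groups}{map taxon -> group label for nearest-taxon binning.}
#'   \item{focal_clade}{taxon labels of the focal clade for ancestral
#'     logging.}
#'   \item{priors}{overrides for [prior_spec()] fields.}
#'   \item{parsimony}{`k`, `n_starts`, `seed` for the homoplasy step.}
#'   \item{mcmc}{`generations`, `sample_every`, `burnin_frac`, `seed`,
#'     `n_runs`.}
#'   \item{model}{`mkv`, `rho`, `partition_by_homoplasy`,
#'     `homoplasy_bin`, `eigen_correction`.}
#'   \item{phenetics}{`subsample_every`.}
#' }
#'
#' @param path Path to a YAML config (or an already-parsed list).
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$matrix)) stop("config must name a 'matrix' file")
  cfg$mcmc <- utils::modifyList(
    list(generations = 100000, sample_every = 100, burnin_frac = 0.1,
         seed = 1L, n_runs = 1L), cfg$mcmc %||% list())
  cfg$parsimony <- utils::modifyList(
    list(k = 10, n_starts = 10, seed = 1L), cfg$parsimony %||% list())
  cfg$model <- utils::modifyList(
    list(mkv = FALSE, rho = 0, partition_by_homoplasy = TRUE,
         homoplasy_bin = NULL, eigen_correction = "none"),
    cfg$model %||% list())
  cfg$phenetics <- utils::modifyList(
    list(subsample_every = 20L), cfg$phenetics %||% list())
  with(cfg$mcmc, {
    if (burnin_frac < 0 || burnin_frac >= 1) {
      stop("burnin_frac must be in [0, 1)")
    }
    if (generations %% sample_every != 0) {
      stop("chain length must be divisible by the sample interval")
    }
  })
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_sites <- function(cfg) {
  if (is.null(cfg$sites)) return(NULL)
  site_table(vapply(cfg$sites, `[[`, character(1), "site"),
             vapply(cfg$sites, `[[`, numeric(1), "min_ma"),
             vapply(cfg$sites, `[[`, numeric(1), "max_ma"),
             lapply(cfg$sites, function(s) unlist(s$taxa)))
}

config_priors <- function(cfg) {
  do.call(prior_spec, cfg$priors %||% list())
}

#' Run the full pipeline
#'
#' Parsimony partitioning, MCMC (optionally several independent runs),
#' majority-rule consensus, ancestral-state summaries, and phenetics.
#' Every output is reproducible from the config and its seeds; a JSON
#' manifest records seeds, versions and md5 checksums of all outputs.
#'
#' @param config Path to a YAML run config or a `run_config` list.
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
pipeline_all <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  outputs <- character(0)
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }
  tryCatch({
    stage <- "read"
    if (is.null(cfg$blocks)) {
      fixed <- read_nexus(cfg$matrix)
      blocks <- list()
    } else {
      rd <- read_nexus_with_blocks(cfg$matrix, list(blocks = cfg$blocks))
      fixed <- rd$fixed
      blocks <- rd$blocks
    }

    stage <- "partition"
    model <- prepare_inference(
      fixed, blocks, sites = config_sites(cfg),
      constraints = cfg$constraints %||% list(),
      partition_by_homoplasy = isTRUE(cfg$model$partition_by_homoplasy),
      parsimony = parsimony_config(k = cfg$parsimony$k,
                                   n_starts = cfg$parsimony$n_starts,
                                   seed = cfg$parsimony$seed),
      homoplasy_bin = cfg$model$homoplasy_bin,
      mkv = isTRUE(cfg$model$mkv), rho = cfg$model$rho)
    write_partition_table(model$scheme, emit(file.path(out_dir,
                                                       "partitions.tsv")))
    write.table(
      data.frame(character = seq_along(model$homoplasy),
                 homoplasy = model$homoplasy),
      emit(file.path(out_dir, "homoplasy.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(model$iw_tree)) {
      ape::write.tree(model$iw_tree,
                      emit(file.path(out_dir, "iw_tree.nwk")))
    }

    stage <- "mcmc"
    spec <- config_priors(cfg)
    runs <- list()
    for (r in seq_len(cfg$mcmc$n_runs)) {
      cfgr <- mcmc_config(generations = cfg$mcmc$generations,
                          sample_every = cfg$mcmc$sample_every,
                          burnin_frac = cfg$mcmc$burnin_frac,
                          seed = cfg$mcmc$seed + (r - 1L))
      runs[[r]] <- run_mcmc(model, cfgr, spec,
                            focal_clade = unlist(cfg$focal_clade))
      suffix <- if (cfg$mcmc$n_runs > 1L) paste0("_run", r) else ""
      write_trace(runs[[r]],
                  emit(file.path(out_dir, paste0("trace", suffix, ".tsv"))))
      writeLines(vapply(runs[[r]]$trees, tt_newick, character(1)),
                 emit(file.path(out_dir, paste0("trees", suffix, ".nwk"))))
      if (length(model$blocks)) {
        keep <- retained_samples(runs[[r]])
        hcols <- grep("^h_", names(runs[[r]]$trace), value = TRUE)
        write.table(runs[[r]]$trace[keep, c("gen", hcols), drop = FALSE],
                    emit(file.path(out_dir,
                                   paste0("homology", suffix, ".tsv"))),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    run1 <- runs[[1L]]
    keep <- retained_samples(run1)

    stage <- "consensus"
    cons <- majority_rule_consensus(run1$trees[keep])
    ape::write.tree(cons, emit(file.path(out_dir, "consensus.nwk")))
    write.table(attr(cons, "clades"),
                emit(file.path(out_dir, "consensus_clades.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(run1$ancestors)) {
      stage <- "ancestors"
      write_ancestors(run1, emit(file.path(out_dir, "ancestors.tsv")),
                      retain = keep)
      post <- ancestral_state_posteriors(run1$ancestors[keep])
      write.table(post, emit(file.path(out_dir, "ancestor_states.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)

      stage <- "phenetics"
      groups <- if (!is.null(cfg$groups)) unlist(cfg$groups) else NULL
      nt <- nearest_taxon_posterior(run1, model, groups, retain = keep)
      write.table(nt, emit(file.path(out_dir, "nearest.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      sub <- subsample_ancestors(run1,
                                 every = cfg$phenetics$subsample_every,
                                 retain = keep)
      anc_mm <- compose_matrix(model$fixed, model$blocks,
                               rep(sub$modal_h, length(model$blocks)))
      amask <- do.call(rbind, lapply(run1$ancestors[sub$indices],
                                     function(s) {
                                       state_vector_to_masks(s$states)
                                     }))
      rownames(amask) <- paste0("ancestor_", seq_len(nrow(amask)))
      allmask <- rbind(anc_mm$mask, amask)
      md <- mord_matrix(morph_matrix(allmask, rownames(allmask),
                                     c(anc_mm$ordered),
                                     anc_mm$symbols))
      dl <- data.frame(
        label_a = rep(md$labels, times = length(md$labels)),
        label_b = rep(md$labels, each = length(md$labels)),
        distance = as.vector(md$d),
        n_comparable = as.vector(md$n_comp))
      write.table(dl[dl$label_a < dl$label_b, ],
                  emit(file.path(out_dir, "distances.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!anyNA(md$d)) {
        pc <- pco(md, correction = if (cfg$model$eigen_correction ==
                                       "cailliez") "cailliez" else "none")
        pcdf <- data.frame(label = rownames(pc$coordinates),
                           pc$coordinates)
        write.table(pcdf, emit(file.path(out_dir, "pco.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(paste(c("eigenvalues:",
                           format(pc$eigenvalues, digits = 8)),
                         collapse = " "),
                   emit(file.path(out_dir, "pco_eigenvalues.txt")))
      }
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("dynhom")),
      r_version = R.version.string,
      seeds = list(parsimony = cfg$parsimony$seed, mcmc = cfg$mcmc$seed),
      n_runs = cfg$mcmc$n_runs,
      checksums = as.list(tools::md5sum(outputs)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
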