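# CSV plumbing and pipeline orchestration. All artefacts are plain CSV (one
# YAML config and manifest): the study's data are small tabular records, so
# reproducibility is preferred over binary formats.

.schemas <- list(
  pedigree = c("animal", "sire", "dam"),
  animals = c("animal_id", "pen_id", "litter_id", "sex", "line", "batch",
              "weight_at_mixing"),
  interactions = c("pen_id", "initiator_id", "receiver_id", "kind"),
  lesions = c("animal_id", "region", "timepoint", "count"),
  traits = c("animal_id", "pen_id"),
  ebv = c("animal_id")
)

#' Read a pipeline CSV table
#'
#' Reads one of the pipeline's CSV schemas with header validation; unknown
#' extra columns are preserved with a warning.
#'
#' @param path file path.
#' @param schema one of `pedigree`, `animals`, `interactions`, `lesions`,
#'   `traits`, `ebv`.
#' @return data frame.
#' @export
read_table_csv <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- .schemas[[schema]]
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(out), need)
  if (schema %in% c("pedigree", "animals", "interactions", "lesions") &&
      length(extra))
    warning("extra column(s) preserved in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  out
}

#' Write a pipeline CSV table
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a dataset, fits a univariate animal model per
#' configured trait, summarises posteriors, standardises EBVs, and runs the
#' individual-level and pen-level truncation-selection analyses with the
#' eigenvector-clustering index. All artefacts are written to `out_dir`
#' together with a manifest of seeds, package version and per-file
#' checksums.
#'
#' @param config list with optional elements: `seed` (default 1), `traits`
#'   (traits to fit; default eigenvector, clustering and the six lesion
#'   traits), `mcmc` (list passed to [mcmc_settings()]), `selection`
#'   (list with `fraction`, `pen_fraction`), `params` (a `true_parameters`
#'   object), `trait_table` + `pedigree` (to skip simulation). A path to a
#'   YAML file with the same structure is also accepted.
#' @param out_dir artefact directory (created if missing).
#' @return invisibly, a list with the trait table, posterior summaries, EBV
#'   table and selection reports.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pensna_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$trait_table)) {
    params <- config$params %||% paperlike_parameters()
    sim <- simulate_dataset(params = params, seed = seed)
    traits_tab <- sim$traits
    pedigree <- sim$pedigree
  } else {
    traits_tab <- config$trait_table
    pedigree <- config$pedigree
    if (is.null(pedigree)) stop("config$pedigree required with a trait table")
  }
  write_table_csv(pedigree[, c("animal", "sire", "dam")],
                  file.path(out_dir, "pedigree.csv"))
  write_table_csv(traits_tab, file.path(out_dir, "traits.csv"))

  fit_traits <- config$traits %||%
    intersect(c("sna_eigenvector", "sna_clustering", "sl_anterior_24h",
                "sl_central_24h", "sl_posterior_24h", "sl_anterior_3wk",
                "sl_central_3wk", "sl_posterior_3wk"), names(traits_tab))
  mcmc_cfg <- config$mcmc %||% list()
  Ainv <- build_A_inverse(pedigree)

  summaries <- list()
  ebv <- traits_tab[, c("animal_id", "pen_id")]
  for (tr in fit_traits) {
    kind <- if (all(stats::na.omit(traits_tab[[tr]]) %in% c(0, 1)))
      "threshold" else "linear"
    des <- build_design(traits_tab, model_spec(tr, kind), pedigree)
    st <- do.call(mcmc_settings, c(mcmc_cfg, list(seed = seed)))
    fit <- .run_gibbs(des, Ainv, st)
    smy <- summarize_posterior(fit)
    summaries[[tr]] <- smy
    write_table_csv(smy$parameters,
                    file.path(out_dir, paste0("summary_", tr, ".csv")))
    m <- match(ebv$animal_id, smy$ebv$animal_id)
    ebv[[tr]] <- smy$ebv[[tr]][m]
  }
  write_table_csv(ebv, file.path(out_dir, "ebv.csv"))

  sel_cfg <- config$selection %||% list()
  fraction <- sel_cfg$fraction %||% 0.10
  pen_fraction <- sel_cfg$pen_fraction %||% 0.20
  z <- standardize_ebv(ebv)
  reports <- list()
  if (all(c("sna_eigenvector", "sna_clustering") %in% names(z))) {
    crits <- list(
      eigenvector = stats::setNames(z$sna_eigenvector, z$animal_id),
      clustering = stats::setNames(z$sna_clustering, z$animal_id))
    crits$index <- build_index(crits$eigenvector, crits$clustering)
    targets <- z[, !(names(z) %in% "pen_id"), drop = FALSE]
    for (nm in names(crits)) {
      sel <- select_lowest(crits[[nm]], fraction)
      rep_i <- correlated_response(sel, targets)
      reports[[nm]] <- rep_i
      write_table_csv(rep_i, file.path(out_dir, paste0("selection_", nm,
                                                       ".csv")))
      zz <- z
      zz$.crit <- crits[[nm]][as.character(zz$animal_id)]
      rep_p <- pen_rank_select(zz, ".crit", "mean", pen_fraction,
                               targets = setdiff(names(targets), "animal_id"))
      reports[[paste0(nm, "_pen")]] <- rep_p
      write_table_csv(rep_p, file.path(out_dir, paste0("selection_", nm,
                                                       "_pen.csv")))
    }
  }
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("pensna")),
                   seed = seed, traits = fit_traits,
                   checksums = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(traits = traits_tab, summaries = summaries, ebv = ebv,
                 reports = reports, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
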