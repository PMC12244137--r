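## End-to-end analysis pipeline: descriptives -> group-difference LVM with
## covariance refinement -> hormone LVM -> mediation effects and contrasts ->
## HRRT-only sensitivity refit -> MDD symptom network.

#' Pipeline configuration
#'
#' Exactly one of `input` (a cohort CSV/TSV path) or `params` (a
#' [default_params()] object for synthetic generation) must be supplied.
#'
#' @param input path to a cohort table, or `NULL`.
#' @param params generator parameters, or `NULL`.
#' @param outdir output directory (`NULL` = do not write files).
#' @param seed master seed for generation and permutation inference.
#' @param censoring_mode censoring mode for the hormones model.
#' @param refine_alpha familywise alpha of the covariance refinement.
#' @param gehan_inference `"permutation"` or `"asymptotic"`.
#' @param network list of options for [ebic_glasso()] (`tuning`,
#'   `small_sample_ack`).
#' @param hrrt_only run the HRRT-only sensitivity refit.
#' @param run_network run the MDD symptom network stage.
#' @param verbose print per-stage progress.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, params = NULL, outdir = NULL,
                            seed = 1L,
                            censoring_mode = "integrate_main_only",
                            refine_alpha = 0.05,
                            gehan_inference = "permutation",
                            network = list(tuning = 0.5,
                                           small_sample_ack = TRUE),
                            hrrt_only = TRUE, run_network = TRUE,
                            verbose = TRUE) {
  if (is.null(input) == is.null(params)) {
    stop("exactly one of 'input' or 'params' must be set")
  }
  structure(list(
    input = input, params = params, outdir = outdir, seed = as.integer(seed),
    censoring_mode = censoring_mode, refine_alpha = refine_alpha,
    gehan_inference = gehan_inference, network = network,
    hrrt_only = hrrt_only, run_network = run_network, verbose = verbose
  ), class = "pipeline_config")
}

stage_msg <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

drop_constant_covariates <- function(covariates, cohort, config) {
  keep <- covariates
  for (cv in covariates) {
    v <- if (cv == "scanner") cohort$scanner else cohort[[cv]]
    if (length(unique(v)) < 2L) {
      stage_msg(config, "covariate '%s' is constant; dropped from the model", cv)
      keep <- setdiff(keep, cv)
    }
  }
  keep
}

#' Run the full analysis pipeline
#'
#' Executes, in order: group descriptives (Welch's t for testosterone,
#' Gehan's test and a censoring summary for estradiol, percent dose
#' reduction), the group-difference LVM with stepwise covariance refinement,
#' the hormone LVM (carrying over any refined covariances), the mediation
#' decomposition with group contrasts, an HRRT-only sensitivity refit, and
#' the MDD symptom-hormone-receptor network. When `config$outdir` is set, all
#' stage outputs are written as JSON/CSV together with a run manifest
#' (configuration, seed, package version, timestamp).
#'
#' @param config a [pipeline_config()].
#' @return list of class `"pipeline_result"` with elements `cohort`,
#'   `descriptives`, `group_model`, `hormone_model`, `effects`,
#'   `sensitivity_hrrt`, `network`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$input)) {
    stage_msg(config, "reading cohort from %s", config$input)
    read_cohort(config$input)
  } else {
    stage_msg(config, "generating synthetic cohort (seed %d)", config$seed)
    generate_cohort(config$params, seed = config$seed)
  }
  loq <- if (!is.null(config$params)) config$params$loq else 0.09

  ## -- descriptives ---------------------------------------------------------
  stage_msg(config, "stage 1/6: descriptives")
  cs <- censoring_summary(cohort$estradiol_censored, cohort$group)
  desc <- list(
    n = as.list(table(cohort$group)),
    welch_testosterone = welch_t(cohort$testosterone, cohort$group),
    gehan_estradiol = unclass(gehan_test(
      cohort$estradiol, cohort$estradiol_censored, cohort$group,
      inference = config$gehan_inference, seed = config$seed
    )),
    censoring = cs,
    dose_reduction_percent = percent_reduction(
      mean(cohort$dose[cohort$group == "HC"]),
      mean(cohort$dose[cohort$group == "MDD"])
    )
  )

  ## -- group-difference LVM with refinement ---------------------------------
  stage_msg(config, "stage 2/6: group-difference LVM + covariance refinement")
  covs <- drop_constant_covariates(c("age", "dose", "scanner"), cohort, config)
  spec1 <- build_lvm_spec("group_only", covariates = covs)
  ref <- refine_covariance(spec1, cohort, alpha = config$refine_alpha)
  stage_msg(config, "  refinement added %d covariance parameter(s)",
            nrow(ref$log))

  ## -- hormone LVM -----------------------------------------------------------
  stage_msg(config, "stage 3/6: hormone LVM (censoring mode '%s')",
            config$censoring_mode)
  spec2 <- build_lvm_spec("hormones", covariates = covs,
                          extra_covariances = ref$spec$extra_covariances,
                          censoring_mode = config$censoring_mode, loq = loq)
  fit2 <- fit_lvm(spec2, cohort)

  ## -- effects ---------------------------------------------------------------
  stage_msg(config, "stage 4/6: mediation effects and group contrasts")
  eff <- effects_table(fit2)

  ## -- HRRT-only sensitivity -------------------------------------------------
  sens <- NULL
  if (isTRUE(config$hrrt_only)) {
    stage_msg(config, "stage 5/6: HRRT-only sensitivity refit")
    sub <- cohort[cohort$scanner == "HRRT", , drop = FALSE]
    covs_s <- drop_constant_covariates(covs, sub, config)
    spec_s <- build_lvm_spec("hormones", covariates = covs_s,
                             extra_covariances = ref$spec$extra_covariances,
                             censoring_mode = config$censoring_mode, loq = loq)
    sens <- list(
      n = nrow(sub),
      fit = fit_lvm(spec_s, sub),
      effects = NULL
    )
    sens$effects <- effects_table(sens$fit)
  }

  ## -- MDD symptom network ---------------------------------------------------
  net <- NULL
  if (isTRUE(config$run_network)) {
    stage_msg(config, "stage 6/6: MDD symptom-hormone-receptor network")
    net <- mdd_symptom_network(
      cohort, loq = loq,
      tuning = config$network$tuning %||% 0.5,
      small_sample_ack = isTRUE(config$network$small_sample_ack)
    )
  }

  manifest <- list(
    package = "petlvm",
    version = as.character(utils::packageVersion("petlvm")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)[setdiff(names(config), "params")],
    generator_params = if (!is.null(config$params)) unclass(config$params)
  )
  result <- structure(list(
    cohort = cohort, descriptives = desc,
    group_model = ref, hormone_model = fit2, effects = eff,
    sensitivity_hrrt = sens, network = net, manifest = manifest
  ), class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_result(result, config$outdir)
  result
}

#' Build the MDD symptom-hormone-receptor network
#'
#' Restricts the cohort to MDD rows, forms the nine network nodes
#' (neostriatal binding residualized on age and tracer dose; testosterone and
#' a binary above/below-LOQ estradiol indicator residualized on age; the
#' HAMD6 core score; and the five vegetative HAMD items), and estimates the
#' EBIC-glasso network with centrality.
#'
#' @param cohort a cohort table with HAMD items filled for MDD subjects.
#' @param loq estradiol censoring limit.
#' @param tuning EBIC gamma.
#' @param small_sample_ack passed to [ebic_glasso()].
#' @return list with `nodes` (the node table), `network` and `centrality`.
#' @export
mdd_symptom_network <- function(cohort, loq = 0.09, tuning = 0.5,
                                small_sample_ack = FALSE) {
  mdd <- as.data.frame(cohort[cohort$group == "MDD", , drop = FALSE])
  if (!nrow(mdd)) stop("no MDD rows for the network stage")
  sub <- hamd_subscales(mdd)
  tab <- data.frame(
    neostriatum = mdd$bp_neostriatum,
    testosterone = mdd$testosterone,
    estradiol_above_loq = as.numeric(!mdd$estradiol_censored &
                                       mdd$estradiol > loq),
    age = mdd$age, dose = mdd$dose
  )
  tab <- cbind(tab, sub)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  tab <- residualize(tab, list(
    neostriatum = c("age", "dose"),
    testosterone = "age",
    estradiol_above_loq = "age"
  ))
  nodes <- tab[, c("neostriatum", "testosterone", "estradiol_above_loq",
                   "hamd6", "initial_insomnia", "middle_insomnia",
                   "delayed_insomnia", "gastrointestinal", "weight_loss")]
  keep <- vapply(nodes, function(v) stats::sd(v) > 0, TRUE)
  nodes <- nodes[, keep, drop = FALSE]
  net <- ebic_glasso(nodes, tuning = tuning,
                     small_sample_ack = small_sample_ack)
  list(nodes = nodes, network = net, centrality = net_centrality(net))
}

write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(outdir, ...)
  write_cohort(result$cohort, out("cohort.csv"))
  jsonlite::write_json(result$descriptives, out("descriptives.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(parameter_table(result$group_model$fit),
                   out("group_model_parameters.csv"), row.names = FALSE)
  utils::write.csv(result$group_model$log, out("refinement_log.csv"),
                   row.names = FALSE)
  utils::write.csv(parameter_table(result$hormone_model),
                   out("hormone_model_parameters.csv"), row.names = FALSE)
  utils::write.csv(result$effects, out("effects.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(group_model = fit_json(result$group_model$fit),
         hormone_model = fit_json(result$hormone_model)),
    out("fits.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(result$sensitivity_hrrt)) {
    utils::write.csv(result$sensitivity_hrrt$effects,
                     out("effects_hrrt_only.csv"), row.names = FALSE)
  }
  if (!is.null(result$network)) {
    utils::write.csv(as.data.frame(result$network$network$adjacency),
                     out("network_adjacency.csv"))
    utils::write.csv(result$network$centrality, out("network_centrality.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

fit_json <- function(fit) {
  list(
    model = fit$spec$model,
    loglik = fit$loglik, n_obs = fit$n_obs, converged = fit$converged,
    extra_covariances = lapply(fit$spec$extra_covariances, paste,
                               collapse = "~"),
    parameters = parameter_table(fit)
  )
}
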