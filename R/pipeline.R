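## Orchestration: validated configuration, per-run dual regression to disk,
## group inference with post-hoc decomposition, and map averaging.

.configDefaults <- function() {
  list(
    study_dir = NULL, out_dir = NULL, atlas = NULL,
    cutoff_hz = 0.005, fwhm_mm = 6, smooth = FALSE,
    forming_p = 0.001, n_perm = 5000, alpha = 0.05, n_systems = 5,
    vif_threshold = 5, atlas_threshold = 3,
    connectivity = 26, state_scheme = "shared",
    stage2_mask = "analysis", skip_preprocessing = FALSE,
    seed = NULL)
}

#' Read and validate a pipeline configuration
#'
#' Every analysis constant (0.005 Hz high-pass, 6 mm FWHM, forming p 0.001,
#' 5000 permutations, alpha 0.05, 5 systems) is a configuration default,
#' never hard-coded downstream. Out-of-range parameters are rejected with a
#' named error before any computation.
#'
#' @param config Path to a YAML file or a named list.
#' @param overrides Named list applied on top of the file values.
#' @return A validated named list with class "PipelineConfig".
#' @export
readPipelineConfig <- function(config = list(), overrides = list()) {
  cfg <- .configDefaults()
  file <- NULL
  if (is.character(config)) {
    file <- config
    config <- yaml::read_yaml(config)
  }
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  bad <- function(msg) stop("config error: ", msg, call. = FALSE)
  if (!is.numeric(cfg$cutoff_hz) || cfg$cutoff_hz <= 0)
    bad("cutoff_hz must be positive")
  if (!is.numeric(cfg$fwhm_mm) || cfg$fwhm_mm < 0)
    bad("fwhm_mm must be >= 0")
  if (!is.numeric(cfg$forming_p) || cfg$forming_p <= 0 || cfg$forming_p >= 1)
    bad("forming_p must be in (0, 1)")
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 1)
    bad("n_perm must be >= 1")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    bad("alpha must be in (0, 1)")
  if (!is.numeric(cfg$n_systems) || cfg$n_systems < 1)
    bad("n_systems must be >= 1")
  if (!cfg$connectivity %in% c(6, 18, 26))
    bad("connectivity must be 6, 18 or 26")
  if (!cfg$state_scheme %in% c("shared", "independent"))
    bad("state_scheme must be 'shared' or 'independent'")
  if (!cfg$stage2_mask %in% c("analysis", "gm"))
    bad("stage2_mask must be 'analysis' or 'gm'")
  if (cfg$n_perm > 0 && is.null(cfg$seed))
    bad("a seed is mandatory when n_perm > 0")
  if (!is.null(cfg$study_dir) && !dir.exists(cfg$study_dir))
    bad(paste("study_dir does not exist:", cfg$study_dir))
  if (!is.null(cfg$atlas) && !file.exists(cfg$atlas))
    bad(paste("atlas does not exist:", cfg$atlas))
  cfg$config_file <- file
  class(cfg) <- "PipelineConfig"
  cfg
}

## Load templates, masks and the design table of a study directory written
## by simulateStudy (or laid out the same way).
.loadStudy <- function(studyDir) {
  tpl <- readVolume(file.path(studyDir, "templates.nii.gz"))
  systems <- readLines(file.path(studyDir, "systems.txt"))
  templates <- TemplateSet(tpl$data, systems, affine = tpl$affine,
                           conditioned = FALSE)
  maskFile <- function(nm) file.path(studyDir, sprintf("mask_%s.nii.gz", nm))
  masks <- list()
  for (nm in c("gm", "wm", "csf", "ref"))
    if (file.exists(maskFile(nm))) masks[[nm]] <- readMask(maskFile(nm))
  runs <- utils::read.table(file.path(studyDir, "design.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  list(templates = templates, masks = masks, runs = runs)
}

.provenance <- function(cfg, extra = list()) {
  prov <- list(
    package = "reactfc",
    version = as.character(utils::packageVersion("reactfc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), "config_file")])
  if (!is.null(cfg$config_file) && file.exists(cfg$config_file))
    prov$config_md5 <- unname(tools::md5sum(cfg$config_file))
  c(prov, extra)
}

#' Run the two-stage dual regression for every run of a study
#'
#' Conditions the templates over grey matter (reference fill where a
#' reference mask is present, then min-max rescaling), builds the analysis
#' mask, writes the collinearity screen, and for each run applies the
#' optional pre-processing (smoothing if enabled, WM/CSF nuisance
#' regression, discrete-cosine high-pass) followed by stage 1 and stage 2.
#' Per-run outputs are a time-series TSV and a 4-D beta NIfTI; a JSON
#' sidecar records configuration and versions.
#'
#' @param config A \code{PipelineConfig} (or path / list accepted by
#'   \code{\link{readPipelineConfig}}).
#' @return Invisibly, a list with the conditioned templates, analysis mask,
#'   collinearity report, the per-run \code{EnrichedFCMaps} and the design.
#' @export
runSubjectReact <- function(config) {
  cfg <- if (inherits(config, "PipelineConfig")) config
  else readPipelineConfig(config)
  if (is.null(cfg$study_dir) || is.null(cfg$out_dir))
    stop("config error: study_dir and out_dir are required", call. = FALSE)
  study <- .loadStudy(cfg$study_dir)
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  gm <- study$masks$gm
  if (is.null(gm)) stop("config error: no GM mask in study", call. = FALSE)
  refs <- if (!is.null(study$masks$ref))
    stats::setNames(rep(list(study$masks$ref), nSystems(study$templates)),
                    systemNames(study$templates))
  else list()
  templates <- conditionTemplates(study$templates, gm, refs)
  analysisMask <- buildAnalysisMask(templates, gm)
  stage2Mask <- if (cfg$stage2_mask == "gm") gm else analysisMask
  report <- computeVIF(templates, analysisMask, cfg$vif_threshold)
  writeCollinearityReport(report,
                          file.path(outDir, "template_correlations.tsv"),
                          file.path(outDir, "template_vif.json"))
  runs <- study$runs
  maps <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    scan <- readScan(file.path(cfg$study_dir, runs$file[r]),
                     tr = runs$tr[r], subject = runs$subject[r],
                     condition = runs$condition[r], state = runs$state[r])
    if (!isTRUE(cfg$skip_preprocessing)) {
      if (isTRUE(cfg$smooth) && cfg$fwhm_mm > 0)
        scan <- smoothGaussian(scan, cfg$fwhm_mm)
      scan <- regressNuisance(scan, study$masks$wm, study$masks$csf)
      scan <- highpassDCT(scan, cfg$cutoff_hz)
    }
    ts <- reactStage1(scan, templates, analysisMask)
    fc <- reactStage2(scan, ts, stage2Mask)
    stem <- sprintf("%s_cond-%s_state-%s", runs$subject[r],
                    runs$condition[r], runs$state[r])
    writeTimeSeries(ts, file.path(outDir, paste0(stem, "_timeseries.tsv")))
    writeVolume(fc@data, fc@affine,
                file.path(outDir, paste0(stem, "_betas.nii.gz")))
    maps[[r]] <- fc
  }
  writeMask(analysisMask, file.path(outDir, "mask_analysis.nii.gz"))
  jsonlite::write_json(.provenance(cfg, list(n_runs = nrow(runs))),
                       file.path(outDir, "react_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(templates = templates, analysisMask = analysisMask,
                 stage2Mask = stage2Mask, report = report, maps = maps,
                 runs = runs))
}

## Choose the post-hoc family for an effect's surviving cluster.
.posthocForEffect <- function(effect, means, alpha) {
  switch(effect,
         interaction = simpleMainEffects(means, alpha = alpha),
         state = pairedContrastsSidak(means, "state", m = 6L,
                                      alpha = alpha),
         condition = pairedContrastsSidak(means, "condition", m = 1L,
                                          alpha = alpha))
}

#' Group inference and post-hoc decomposition for every system
#'
#' Per molecular system: the three within-subject effect F maps,
#' permutation cluster-extent FWE tables, Bonferroni flags across systems,
#' and, for surviving clusters, cluster means with the matching post-hoc
#' family (simple main effects for interaction clusters, Sidak state or
#' condition contrasts for main-effect clusters). All tables are written as
#' TSV, maps as NIfTI, and the permutation scheme and seed as JSON.
#'
#' @param config A \code{PipelineConfig} (or path / list).
#' @param react Optional result of \code{\link{runSubjectReact}}; when
#'   omitted, per-run betas are re-read from \code{out_dir}.
#' @return Invisibly, a named list per system of per-effect results
#'   (cluster tables with FWE p and Bonferroni flags, F maps, post-hoc
#'   tables).
#' @export
runGroupAnalysis <- function(config, react = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config
  else readPipelineConfig(config)
  if (is.null(react)) react <- .reloadReact(cfg)
  outDir <- cfg$out_dir
  design <- StudyDesign(unique(react$runs$subject))
  mask <- react$stage2Mask
  scheme <- PermutationScheme(nPerm = cfg$n_perm, seed = cfg$seed,
                              stateScheme = cfg$state_scheme)
  systems <- systemNames(react$maps[[1L]])
  results <- list()
  for (sys in systems) {
    res <- permutationClusterFWE(react$maps, sys, design, mask, scheme,
                                 formingP = cfg$forming_p,
                                 connectivity = cfg$connectivity)
    for (eff in names(res)) {
      tab <- bonferroniAcrossSystems(res[[eff]]$table, cfg$n_systems,
                                     cfg$alpha)
      res[[eff]]$table <- tab
      stem <- file.path(outDir, sprintf("group_%s_%s", sys, eff))
      writeTable(tab, paste0(stem, "_clusters.tsv"))
      writeVolume(fArray(res[[eff]]$fmap), mask@affine,
                  paste0(stem, "_fstat.nii.gz"))
      surv <- tab[tab$survivesBonferroni, , drop = FALSE]
      if (nrow(surv) == 0L) {
        message("no surviving clusters for ", sys, " / ", eff)
        next
      }
      labels <- .clusterLabelArray(res[[eff]]$fmap, mask, cfg$forming_p,
                                   cfg$connectivity)
      writeVolume(labels, mask@affine, paste0(stem, "_clusterlabels.nii.gz"))
      posthoc <- list()
      for (ri in seq_len(nrow(surv))) {
        cl <- surv$label[ri]
        clMask <- VolumeMask(labels == cl, mask@affine)
        means <- extractClusterMeans(react$maps, clMask, sys, cluster = cl)
        writeTable(means, sprintf("%s_cluster%02d_means.tsv", stem, cl))
        ph <- .posthocForEffect(eff, means, cfg$alpha)
        writeTable(ph, sprintf("%s_cluster%02d_contrasts.tsv", stem, cl))
        posthoc[[as.character(cl)]] <- list(means = means, contrasts = ph)
      }
      res[[eff]]$posthoc <- posthoc
    }
    results[[sys]] <- res
  }
  jsonlite::write_json(
    .provenance(cfg, list(scheme = list(n_perm = scheme@nPerm,
                                        seed = scheme@seed,
                                        state_scheme = scheme@stateScheme))),
    file.path(outDir, "group_provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(results)
}

## Rebuild the runSubjectReact result from its on-disk outputs.
.reloadReact <- function(cfg) {
  if (is.null(cfg$out_dir))
    stop("config error: out_dir is required", call. = FALSE)
  study <- .loadStudy(cfg$study_dir)
  mask <- readMask(file.path(cfg$out_dir, "mask_analysis.nii.gz"))
  systems <- readLines(file.path(cfg$study_dir, "systems.txt"))
  runs <- study$runs
  maps <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    stem <- sprintf("%s_cond-%s_state-%s", runs$subject[r],
                    runs$condition[r], runs$state[r])
    v <- readVolume(file.path(cfg$out_dir, paste0(stem, "_betas.nii.gz")))
    maps[[r]] <- EnrichedFCMaps(v$data, systems, mask, affine = v$affine,
                                subject = runs$subject[r],
                                condition = runs$condition[r],
                                state = runs$state[r])
  }
  list(maps = maps, runs = runs, stage2Mask = mask, analysisMask = mask)
}

## Integer label array matching the ordering of formClusters.
.clusterLabelArray <- function(fmap, mask, formingP, connectivity) {
  crit <- clusterFormingF(fmap@df1, fmap@df2, formingP)
  edges <- .maskEdges(mask@data, connectivity)
  fVec <- fmap@f[mask@data]
  supra <- fVec > crit
  out <- array(0L, dim = gridDim(mask))
  n <- sum(supra)
  if (n == 0L) return(out)
  nodes <- which(supra)
  remap <- integer(length(supra))
  remap[nodes] <- seq_len(n)
  sel <- supra[edges[, 1L]] & supra[edges[, 2L]]
  sub <- if (any(sel)) cbind(remap[edges[sel, 1L]], remap[edges[sel, 2L]])
  else NULL
  memb <- .componentsFromEdges(n, sub)
  sizes <- tabulate(memb)
  rank <- match(memb, order(-sizes))          # relabel by decreasing size
  maskIdx <- which(mask@data)
  out[maskIdx[nodes]] <- rank
  out
}

#' Label map of suprathreshold clusters
#'
#' @param fmap An \code{FStatMap}.
#' @param mask Analysis \code{VolumeMask}.
#' @param formingP Cluster-forming p, default 0.001.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3-D array; 0 outside clusters, labels match the
#'   \code{label} column of \code{\link{formClusters}}.
#' @export
clusterLabelMap <- function(fmap, mask, formingP = 0.001,
                            connectivity = 26) {
  stopifnot(is(fmap, "FStatMap"), is(mask, "VolumeMask"))
  .clusterLabelArray(fmap, mask, formingP, connectivity)
}

#' Average enriched FC maps within groups
#'
#' Voxelwise arithmetic mean of per-run beta maps within each group defined
#' by a subset of \{system, condition, state\} (averaging over subjects and
#' any factor not in \code{groupBy}); used for network visualisation and as
#' input to \code{\link{atlasOverlapReport}}.
#'
#' @param maps List of \code{EnrichedFCMaps}.
#' @param groupBy Character subset of c("system", "condition", "state");
#'   default "system".
#' @return Named list of numeric 3-D arrays (group mean maps).
#' @export
averageNetworkMaps <- function(maps, groupBy = "system") {
  stopifnot(length(maps) >= 1L,
            all(groupBy %in% c("system", "condition", "state")))
  systems <- systemNames(maps[[1L]])
  keys <- list()
  for (m in maps) {
    for (sys in systems) {
      parts <- c(if ("system" %in% groupBy) sys,
                 if ("condition" %in% groupBy) m@condition,
                 if ("state" %in% groupBy) m@state)
      key <- if (length(parts)) paste(parts, collapse = "_") else "all"
      if (is.null(keys[[key]]))
        keys[[key]] <- list(sum = array(0, dim = gridDim(m)), n = 0L)
      keys[[key]]$sum <- keys[[key]]$sum + betaVolume(m, sys)
      keys[[key]]$n <- keys[[key]]$n + 1L
    }
  }
  lapply(keys, function(x) x$sum / x$n)
}
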