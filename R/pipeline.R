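#' Run the full interface-analysis pipeline from a config
#'
#' Config-driven orchestration of the analysis stages: crystal-contact
#' geometry, trajectory stability metrics (L-RMSD, contact occupancy),
#' per-residue interaction energies, SPR kinetic fitting, van't Hoff
#' thermodynamics and DSC melting-temperature picking. Stages run only when
#' their config section is present; any stage failure aborts with a
#' stage-named error while outputs already written are retained. The run is
#' deterministic given config + seed, and every output table carries
#' provenance columns (input file, convention, burn-in).
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Sections: \code{structure} (file), \code{chain_roles} (antigen/heavy/
#'   light ids), \code{contacts} (watch-list with res_a/atom_a/res_b/atom_b
#'   and optional threshold; missing thresholds default to the measured
#'   crystal representative distance), \code{salt_bridge_cutoff},
#'   \code{trajectories} (replicas, dt_ns, burn_in_ns, terminal_exclude),
#'   \code{energetics} (params, residues, partner_chains, cutoff),
#'   \code{spr} (file), \code{vant_hoff} (file, reference_T_K), \code{dsc}
#'   (file, smooth_window), \code{output_dir}, \code{seed}.
#' @param outDir overrides \code{output_dir}
#' @param seed overrides \code{seed}
#' @return invisibly, a list with the computed objects and output paths
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
  }
  outDir <- outDir %||% config$output_dir %||% "epistat-out"
  seed <- seed %||% config$seed %||% 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "pipeline.log")
  cat("", file = logFile)
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    logmsg("stage '%s' started", name)
    tryCatch(expr, error = function(e) {
      logmsg("stage '%s' FAILED: %s", name, conditionMessage(e))
      .stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  results <- list(outputs = character(), seed = seed)
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    results$outputs <<- c(results$outputs, path)
    path
  }

  model <- NULL
  if (!is.null(config$structure)) {
    results$contacts <- stage("contacts", {
      sf <- config$structure$file %||% config$structure
      if (!file.exists(sf)) .stopf("structure file '%s' not found", sf)
      model <- parsePDB(sf)[[1]]   # promise evaluates in this frame
      rows <- lapply(config$contacts, function(ct) {
        rep <- representativeDistance(model, ct$res_a, ct$res_b)
        grp <- groupMinDistance(model, ct$res_a, ct$res_b)
        thr <- ct$threshold %||% rep
        data.frame(label = ct$label, res_a = ct$res_a, atom_a = ct$atom_a,
                   res_b = ct$res_b, atom_b = ct$atom_b,
                   rep_distance_A = rep, group_min_A = grp,
                   threshold_A = thr, convention = "rep_and_group_min",
                   input = sf, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      emit(df, "contacts.csv")
      roles <- config$chain_roles
      if (!is.null(roles)) {
        sb <- findSaltBridges(model, roles$antigen,
                              c(roles$heavy, roles$light),
                              cutoff = config$salt_bridge_cutoff %||% 4.0)
        sb$input <- sf
        emit(sb, "interface_salt_bridges.csv")
      }
      df
    })
  }

  if (!is.null(config$trajectories)) {
    results$trajectory <- stage("trajectory", {
      tc <- config$trajectories
      if (is.null(model)) .stopf("trajectory stage needs a structure stage")
      dt <- tc$dt_ns %||% 0.01
      burnIn <- tc$burn_in_ns %||% 0
      excl <- tc$terminal_exclude %||% 5
      paths <- unlist(tc$replicas)
      missing <- paths[!file.exists(paths)]
      if (length(missing))
        .stopf("replica file(s) not found: %s", paste(missing, collapse = ", "))
      trajs <- lapply(paths, function(p)
        readTrajectory(p, topology = model, dt = dt))
      roles <- config$chain_roles
      # L-RMSD per replica: fit on antigen CA, measure antibody CA
      lr <- NULL
      if (!is.null(roles)) {
        agMask <- caMask(model, roles$antigen, excl)
        abMask <- caMask(model, c(roles$heavy, roles$light), excl)
        lr <- do.call(rbind, lapply(seq_along(trajs), function(i) {
          r <- lrmsdSeries(trajs[[i]], agMask, abMask, model)
          data.frame(replica = i, input = paths[i], mean_A = r$mean,
                     sd_A = r$sd, stringsAsFactors = FALSE)
        }))
        emit(lr, "lrmsd.csv")
      }
      occ <- NULL
      if (length(config$contacts)) {
        defs <- lapply(seq_len(nrow(results$contacts)), function(i) {
          r <- results$contacts[i, ]
          contactDefinition(r$label, r$res_a, r$atom_a, r$res_b, r$atom_b,
                            r$threshold_A)
        })
        occ <- do.call(rbind, lapply(defs, function(cd) {
          fr <- vapply(trajs, function(tr)
            contactOccupancy(distanceSeries(tr, cd), cd@threshold, burnIn),
            numeric(1))
          s <- replicaSummary(fr)
          data.frame(contact = cd@label, threshold_A = cd@threshold,
                     burn_in_ns = burnIn, n_replicas = s$n,
                     mean = s$mean, sd = s$sd, se = s$se,
                     fractions = paste(signif(fr, 6), collapse = ";"),
                     convention = "rep_atoms", stringsAsFactors = FALSE)
        }))
        emit(occ, "occupancy.csv")
      }
      list(lrmsd = lr, occupancy = occ, trajs = trajs, burnIn = burnIn)
    })
  }

  if (!is.null(config$energetics)) {
    results$energy <- stage("energetics", {
      ec <- config$energetics
      if (is.null(results$trajectory))
        .stopf("energetics stage needs the trajectory stage")
      params <- readNonbondedParams(ec$params)
      en <- residueInteractionEnergy(
        results$trajectory$trajs, params, unlist(ec$residues),
        unlist(ec$partner_chains), cutoff = ec$cutoff %||% 12,
        burnIn = results$trajectory$burnIn)
      en$input <- ec$params
      emit(en, "energy.csv")
      en
    })
  }

  if (!is.null(config$spr)) {
    results$kinetics <- stage("spr", {
      d <- readSensorgramCSV(config$spr$file)
      fit <- fitKineticsGlobal(d)
      df <- data.frame(kon_Ms = fit@kon, koff_s = fit@koff, rmax_RU = fit@rmax,
                       kd_M = fit@kd, kd_nM = fit@kd * 1e9,
                       sd_kon = fit@sd["kon"], sd_koff = fit@sd["koff"],
                       sd_rmax = fit@sd["rmax"], sd_kd = fit@sd["kd"],
                       rss = fit@rss, n_points = fit@nObs,
                       input = config$spr$file, stringsAsFactors = FALSE)
      emit(df, "kinetics.csv")
      fit
    })
  }

  if (!is.null(config$vant_hoff)) {
    results$vantHoff <- stage("vant_hoff", {
      vc <- config$vant_hoff
      d <- utils::read.csv(vc$file)
      tK <- if ("T_K" %in% names(d)) d$T_K else d$T_C + 273.15
      refT <- vc$reference_T_K %||% 298
      fit <- vantHoffFit(tK, d$KD_M, refT = refT)
      dg <- deltaGPropagated(fit, refT)
      df <- data.frame(dH_kJmol = fit@dH, sd_dH = fit@sd["dH"],
                       dS_kJmolK = fit@dS, sd_dS = fit@sd["dS"],
                       T_K = refT, dG_kJmol = dg["dG"], sd_dG = dg["sd"],
                       n_temperatures = fit@nT, input = vc$file,
                       stringsAsFactors = FALSE)
      emit(df, "vanthoff.csv")
      fit
    })
  }

  if (!is.null(config$dsc)) {
    results$tm <- stage("dsc", {
      dc <- config$dsc
      d <- utils::read.csv(dc$file)
      tm <- tmApp(d$T_C, d$Cp, smoothWindow = dc$smooth_window)
      df <- data.frame(tm_app_C = tm@tmApp, n_peaks = tm@nPeaks,
                       multi_peak = tm@multiPeak, input = dc$file,
                       stringsAsFactors = FALSE)
      emit(df, "dsc.csv")
      tm
    })
  }

  summaryPath <- file.path(outDir, "summary.json")
  summ <- list(
    seed = seed,
    outputs = basename(results$outputs),
    stages = names(Filter(Negate(is.null),
                          results[setdiff(names(results),
                                          c("outputs", "seed"))])))
  if (!is.null(results$kinetics))
    summ$kinetics <- list(kon = results$kinetics@kon,
                          koff = results$kinetics@koff,
                          kd_nM = results$kinetics@kd * 1e9)
  if (!is.null(results$vantHoff))
    summ$vant_hoff <- list(dH_kJmol = results$vantHoff@dH,
                           dS_kJmolK = results$vantHoff@dS,
                           dG_kJmol = results$vantHoff@dG)
  jsonlite::write_json(summ, summaryPath, auto_unbox = TRUE, digits = NA)
  results$outputs <- c(results$outputs, summaryPath)
  logmsg("pipeline complete: %d outputs in %s", length(results$outputs),
         outDir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
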