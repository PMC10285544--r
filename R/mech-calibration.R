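#' Cell-model backend for mechanical tests
#'
#' Provides the per-model simulations the mechanical calibration stages need:
#' steady-state isometric runs at given initial lengths and first afterloaded
#' twitches at given load fractions.  Results for the reference length are
#' cached per scaling vector so F_max and the force biomarkers are computed
#' once.
#'
#' @param config A [sim_config()].
#' @param abn_config An [abnormality_config()].
#' @return A backend function
#'   `f(scaling, what = c("isometric", "afterloaded"), arg)` where `arg` is
#'   the initial length (isometric) or afterload fraction (afterloaded);
#'   it returns a list with `status`, `biomarkers`, `ap_flags`, `contr_flags`,
#'   `peak_force` and (afterloaded) `shortening`.
#' @export
cell_backend <- function(config = sim_config(),
                         abn_config = abnormality_config()) {
  cache <- new.env(parent = emptyenv())
  iso_run <- function(sc, L) {
    key <- paste(format(c(sc, L), digits = 15), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    tr <- simulate_cell(sc, mech_protocol("isometric", L), config)
    res <- if (attr(tr, "status") != "ok") {
      list(status = attr(tr, "status"), trace = tr)
    } else {
      list(status = "ok", trace = tr,
           biomarkers = extract_biomarkers(tr),
           ap_flags = detect_ap_abnormalities(tr, abn_config),
           contr_flags = detect_contraction_abnormalities(tr, "isometric",
                                                          abn_config),
           peak_force = max(tr$F_active[tr$cycle == max(tr$cycle)]))
    }
    cache[[key]] <- res
    res
  }
  function(scaling, what = c("isometric", "afterloaded"), arg) {
    what <- match.arg(what)
    sc <- scaling_vector(.values = scaling)
    if (what == "isometric") return(iso_run(sc, arg))
    ref <- iso_run(sc, 0.93)
    if (ref$status != "ok") return(list(status = ref$status))
    tw <- afterloaded_twitch(sc, afterload_fraction = arg, config = config,
                             isometric_trace = ref$trace)
    if (attr(tw, "status") == "integration_failed")
      return(list(status = "integration_failed"))
    list(status = attr(tw, "status"),
         ap_flags = detect_ap_abnormalities(tw, abn_config),
         contr_flags = detect_contraction_abnormalities(tw, "afterloaded",
                                                        abn_config),
         shortening = shortening_metrics(tw),
         peak_force = ref$peak_force)
  }
}

.stage_report <- function(stage, population, rejected_ids, reasons,
                          curves = NULL) {
  structure(tibble::tibble(
    model_id = population$model_id,
    stage = stage,
    decision = ifelse(population$model_id %in% rejected_ids,
                      "rejected", "kept"),
    reason = reasons[match(population$model_id, rejected_ids)]),
    curves = curves, class = c("mech_stage_report", class(tibble::tibble())))
}

.scaling_of <- function(population, i) {
  scaling_vector(.values = population[i, .param_names, drop = FALSE])
}

#' Mechanical calibration: force-biomarker stage
#'
#' Rejects models whose reference-length isometric force biomarkers (FTTP,
#' FTTr, FTD) fall outside the packaged re-calibration ranges.
#'
#' @param population Population tibble (see
#'   [finalize_initial_population()]).
#' @param backend A [cell_backend()] (or a stub with the same interface).
#' @param criteria Criteria table (re-calibration rows are used).
#' @return A `mech_stage_report` tibble (one row per model: `model_id`,
#'   `stage`, `decision`, `reason`).
#' @export
stage_force_biomarkers <- function(population, backend = cell_backend(),
                                   criteria = default_criteria()) {
  crit <- criteria[criteria$stage == "recalibration", ]
  rejected <- integer(); reasons <- character()
  for (i in seq_len(nrow(population))) {
    res <- backend(.scaling_of(population, i), "isometric", 0.93)
    if (res$status != "ok") {
      rejected <- c(rejected, population$model_id[i])
      reasons <- c(reasons, res$status)
      next
    }
    bm <- res$biomarkers
    if (any(is.na(c(bm$FTTP, bm$FTTr, bm$FTD)))) {
      rejected <- c(rejected, population$model_id[i])
      reasons <- c(reasons, "no_twitch")
      next
    }
    bad <- character()
    for (k in seq_len(nrow(crit))) {
      v <- bm[[crit$biomarker[k]]]
      if (v < crit$min[k] || v > crit$max[k])
        bad <- c(bad, sprintf("%s=%.1f outside [%g, %g]", crit$biomarker[k],
                              v, crit$min[k], crit$max[k]))
    }
    if (length(bad)) {
      rejected <- c(rejected, population$model_id[i])
      reasons <- c(reasons, paste(bad, collapse = "; "))
    }
  }
  .stage_report("force_biomarkers", population, rejected, reasons)
}

#' Mechanical calibration: preload stage
#'
#' Runs steady-state isometric twitches at reduced initial lengths and
#' rejects models showing any excitation or contraction abnormality at any
#' tested length.
#'
#' @inheritParams stage_force_biomarkers
#' @param lengths Initial lengths (fractions of L_max) in descending order.
#' @return A `mech_stage_report`; attribute `"peak_forces"` holds the peak
#'   isometric force per (model, length) for the L-F stage.
#' @export
stage_preload <- function(population, backend = cell_backend(),
                          lengths = c(0.90, 0.85, 0.80)) {
  rejected <- integer(); reasons <- character()
  pf <- list()
  for (i in seq_len(nrow(population))) {
    id <- population$model_id[i]
    for (L in lengths) {
      res <- backend(.scaling_of(population, i), "isometric", L)
      if (res$status != "ok") {
        rejected <- c(rejected, id); reasons <- c(reasons, res$status)
        break
      }
      bad_ap <- any_abnormal(res$ap_flags)
      bad_co <- any_abnormal(res$contr_flags)
      pf[[length(pf) + 1L]] <- tibble::tibble(model_id = id, length = L,
                                              peak_force = res$peak_force)
      if (bad_ap || bad_co) {
        what <- c(names(which(unlist(res$ap_flags))),
                  names(which(unlist(res$contr_flags))))
        rejected <- c(rejected, id)
        reasons <- c(reasons, sprintf("%s at %.2f L_max",
                                      paste(what, collapse = "+"), L))
        break
      }
    }
  }
  rep <- .stage_report("preload", population, rejected, reasons)
  attr(rep, "peak_forces") <- dplyr::bind_rows(pf)
  rep
}

#' Mechanical calibration: length-force stage
#'
#' Normalizes each model's peak isometric forces to the 0.93 L_max value and
#' rejects models whose L-F sequence is not strictly increasing in length
#' (ties count as failure, within a small float tolerance).
#'
#' @inheritParams stage_force_biomarkers
#' @param peak_forces Tibble (`model_id`, `length`, `peak_force`) from the
#'   preload stage; the 0.93 L_max point is taken from the backend.
#' @param tol Tie tolerance on normalized force.
#' @return A `mech_stage_report`; attribute `"lf_curves"` holds the
#'   normalized curves.
#' @export
stage_lf_curve <- function(population, backend = cell_backend(),
                           peak_forces = NULL, tol = 1e-6) {
  rejected <- integer(); reasons <- character()
  curves <- list()
  for (i in seq_len(nrow(population))) {
    id <- population$model_id[i]
    ref <- backend(.scaling_of(population, i), "isometric", 0.93)
    if (ref$status != "ok") {
      rejected <- c(rejected, id); reasons <- c(reasons, ref$status)
      next
    }
    pts <- peak_forces[peak_forces$model_id == id, , drop = FALSE]
    pts <- dplyr::bind_rows(pts, tibble::tibble(model_id = id, length = 0.93,
                                                peak_force = ref$peak_force))
    pts <- pts[order(pts$length), ]
    pts$normalized <- pts$peak_force / ref$peak_force
    curves[[length(curves) + 1L]] <- pts
    if (any(diff(pts$normalized) <= tol)) {
      rejected <- c(rejected, id)
      reasons <- c(reasons, "non-increasing length-force relation")
    }
  }
  rep <- .stage_report("LF_curve", population, rejected, reasons)
  attr(rep, "lf_curves") <- dplyr::bind_rows(curves)
  rep
}

#' Mechanical calibration: afterload stage
#'
#' Simulates the first afterloaded twitch at each load, rejecting models with
#' any AP abnormality or failed contraction (the 1% shortening criterion is
#' applied at loads up to 0.5 F_max, where it is defined), or whose maximal
#' shortening velocity is not strictly decreasing with afterload (a
#' non-monotone force-velocity relation).
#'
#' @inheritParams stage_force_biomarkers
#' @param afterloads Load fractions of each model's F_max.
#' @return A `mech_stage_report`; attribute `"fv_curves"` holds the
#'   (afterload, velocity) points per model.
#' @export
stage_afterload <- function(population, backend = cell_backend(),
                            afterloads = c(0.25, 0.5, 0.75)) {
  rejected <- integer(); reasons <- character()
  curves <- list()
  for (i in seq_len(nrow(population))) {
    id <- population$model_id[i]
    vels <- numeric(); bad <- FALSE
    for (af in sort(afterloads)) {
      res <- backend(.scaling_of(population, i), "afterloaded", af)
      if (!res$status %in% c("ok", "never_lifted")) {
        rejected <- c(rejected, id); reasons <- c(reasons, res$status)
        bad <- TRUE; break
      }
      flags <- c(unlist(res$ap_flags), unlist(res$contr_flags))
      # the 1% failed-contraction criterion is defined for loads up to half
      # of F_max; shortening at heavier loads is intrinsically ~1%
      if (af > 0.5) flags[names(flags) == "failed_contraction"] <- FALSE
      if (any(flags)) {
        rejected <- c(rejected, id)
        reasons <- c(reasons, sprintf("%s at afterload %.2f",
                                      paste(names(which(flags)),
                                            collapse = "+"), af))
        bad <- TRUE; break
      }
      vels <- c(vels, res$shortening$max_velocity)
      curves[[length(curves) + 1L]] <- tibble::tibble(
        model_id = id, afterload = af,
        max_velocity = res$shortening$max_velocity,
        amplitude = res$shortening$amplitude)
    }
    if (!bad && length(vels) == length(afterloads) &&
        any(diff(vels) >= 0)) {
      rejected <- c(rejected, id)
      reasons <- c(reasons, "non-monotone force-velocity relation")
    }
  }
  rep <- .stage_report("afterload", population, rejected, reasons)
  attr(rep, "fv_curves") <- dplyr::bind_rows(curves)
  rep
}

#' Run the staged mechanical re-calibration
#'
#' Applies the four stages in their fixed order (force biomarkers, preload,
#' L-F curve, afterload); a model rejected at one stage never re-enters a
#' later one, and |accepted| + sum of per-stage rejections = |input|.
#'
#' @inheritParams stage_force_biomarkers
#' @param lengths Preload lengths.
#' @param afterloads Afterload fractions.
#' @return List with `population` (statuses updated to
#'   `"rejected:mech:<stage>"` where applicable), `reports` (per-stage
#'   `mech_stage_report`s) and `summary` (per-stage counts).
#' @export
run_mechanical_calibration <- function(population, backend = cell_backend(),
                                       criteria = default_criteria(),
                                       lengths = c(0.90, 0.85, 0.80),
                                       afterloads = c(0.25, 0.5, 0.75)) {
  pop <- population
  active <- pop
  reports <- list()

  r1 <- stage_force_biomarkers(active, backend, criteria)
  reports$force_biomarkers <- r1
  active <- active[!active$model_id %in%
                     r1$model_id[r1$decision == "rejected"], , drop = FALSE]

  r2 <- stage_preload(active, backend, lengths)
  reports$preload <- r2
  active <- active[!active$model_id %in%
                     r2$model_id[r2$decision == "rejected"], , drop = FALSE]

  r3 <- stage_lf_curve(active, backend, attr(r2, "peak_forces"))
  reports$LF_curve <- r3
  active <- active[!active$model_id %in%
                     r3$model_id[r3$decision == "rejected"], , drop = FALSE]

  r4 <- stage_afterload(active, backend, afterloads)
  reports$afterload <- r4
  active <- active[!active$model_id %in%
                     r4$model_id[r4$decision == "rejected"], , drop = FALSE]

  for (nm in names(reports)) {
    rep <- reports[[nm]]
    rej <- rep$model_id[rep$decision == "rejected"]
    pop$status[pop$model_id %in% rej] <- paste0("rejected:mech:", nm)
  }
  summary <- tibble::tibble(
    stage = names(reports),
    models_in = vapply(reports, nrow, 1L),
    rejected = vapply(reports,
                      function(r) sum(r$decision == "rejected"), 1L))
  list(population = pop, accepted = active, reports = reports,
       summary = summary)
}
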