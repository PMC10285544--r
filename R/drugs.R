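#' Pore-block remaining-conductance factor
#'
#' Simple pore-block model of drug action on an ionic current: the remaining
#' conductance fraction at free drug concentration `C` is
#' `1 / (1 + (C / IC50)^h)`.
#'
#' @param concentration Free drug concentration (uM), non-negative.
#' @param ic50 Half-maximal inhibitory concentration (uM), positive.
#' @param hill Hill coefficient, positive.
#' @return Factor in (0, 1]; 1 at zero concentration, 0.5 at `C = IC50`.
#' @export
block_factor <- function(concentration, ic50, hill = 1) {
  if (any(concentration < 0)) abort("concentration must be non-negative")
  if (any(ic50 <= 0) || any(hill <= 0)) abort("ic50 and hill must be positive")
  1 / (1 + (concentration / ic50)^hill)
}

#' Read a drug table
#'
#' @param path CSV with columns `drug`, `channel` (INa/ICaL/IKr/IKs),
#'   `ic50_uM`, `hill`, `eftpc_uM`, `risk_category`; a missing channel row
#'   means no block of that channel.
#' @return Tibble of per-channel drug entries.
#' @export
read_drug_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          drug = "c", channel = "c", ic50_uM = "d",
                          hill = "d", eftpc_uM = "d", risk_category = "d"))
  bad <- setdiff(tb$channel, c("INa", "ICaL", "IKr", "IKs"))
  if (length(bad)) abort(paste("unknown channel(s):", paste(bad, collapse = ", ")))
  if (any(tb$ic50_uM <= 0) || any(tb$hill <= 0))
    abort("IC50 and Hill coefficients must be positive")
  tb
}

#' Packaged drug table
#'
#' Per-channel IC50 and Hill coefficients for Dofetilide and Verapamil with
#' their maximal effective free therapeutic plasma concentrations (EFTPCmax)
#' and clinical torsade-de-pointes risk category (1 high, 0 none/very low).
#' Verapamil has no IKs entry (no block).  The source table prints
#' Dofetilide's EFTPCmax only to two decimals ("0.00"); the packaged value of
#' 0.002 uM is an editorial reconstruction, and Dofetilide analyses in this
#' package use absolute concentrations.
#'
#' @return Tibble as in [read_drug_table()].
#' @export
default_drugs <- function() {
  read_drug_table(system.file("extdata", "drugs_default.csv",
                              package = "cardiopop", mustWork = TRUE))
}

#' Extract one drug's specification
#'
#' @param drug Drug name.
#' @param table Drug table (default the packaged one).
#' @return One drug's rows with attribute `eftpc_uM`.
#' @export
drug_spec <- function(drug, table = default_drugs()) {
  rows <- table[table$drug == drug, , drop = FALSE]
  if (!nrow(rows)) abort(paste("unknown drug:", drug))
  structure(rows, eftpc_uM = rows$eftpc_uM[1], class = class(rows))
}

#' Drug block vector at a concentration
#'
#' @param spec A [drug_spec()] (rows of a drug table for one compound).
#' @param multiplier Concentration as a multiple of the drug's EFTPCmax.
#' @param concentration Absolute concentration in uM (overrides
#'   `multiplier`); required when EFTPCmax is not positive.
#' @return A [drug_block()] vector of remaining-conductance factors.
#' @export
apply_drug <- function(spec, multiplier = NULL, concentration = NULL) {
  if (is.null(concentration)) {
    if (is.null(multiplier) || multiplier < 0)
      abort("a non-negative multiplier or an absolute concentration is required")
    eftpc <- attr(spec, "eftpc_uM") %||% spec$eftpc_uM[1]
    if (!isTRUE(eftpc > 0))
      abort("EFTPCmax is not positive; supply an absolute concentration")
    concentration <- multiplier * eftpc
  }
  b <- drug_block()
  for (k in seq_len(nrow(spec))) {
    b[[spec$channel[k]]] <- block_factor(concentration, spec$ic50_uM[k],
                                         spec$hill[k])
  }
  b
}

#' Concentration x length drug sweep with event counting
#'
#' For every combination of concentration multiplier, initial length and
#' population model: a steady-state isometric run under the drug is screened
#' for repolarization abnormalities, and an afterloaded twitch at half the
#' model's drug-free peak isometric force is screened for failed contraction
#' (isotonic shortening below 1%).  Integration failures count as abnormal
#' with a distinct reason.
#'
#' @param population Population tibble of accepted models.
#' @param spec A [drug_spec()].
#' @param multipliers Concentration multipliers of EFTPCmax (the default grid
#'   spans the tested 0.1-100x range).
#' @param lengths Initial lengths (fraction of L_max).
#' @param config A [sim_config()].
#' @param abn_config An [abnormality_config()].
#' @param afterload Afterload fraction of the drug-free F_max used for the
#'   failed-contraction test.
#' @return An event-heatmap tibble in long format: `drug`, `multiplier`,
#'   `length`, `n_repol_abnormal`, `n_failed_contraction`, `n_total`.
#' @export
drug_sweep <- function(population, spec,
                       multipliers = c(0.1, 0.3, 1, 3, 10, 30, 100),
                       lengths = c(0.93, 0.90, 0.85, 0.80),
                       config = sim_config(),
                       abn_config = abnormality_config(),
                       afterload = 0.5) {
  drug <- spec$drug[1]
  out <- list()
  fmax0 <- numeric(nrow(population))
  # drug-free F_max per model (for the afterload clamp)
  for (i in seq_len(nrow(population))) {
    sc <- .scaling_of(population, i)
    tr0 <- simulate_cell(sc, mech_protocol("isometric", 0.93), config)
    fmax0[i] <- if (attr(tr0, "status") == "ok")
      max(tr0$F_active[tr0$cycle == max(tr0$cycle)]) else NA_real_
  }
  for (mult in multipliers) {
    blk <- apply_drug(spec, multiplier = mult)
    for (L in lengths) {
      n_rep <- 0L; n_fail <- 0L
      for (i in seq_len(nrow(population))) {
        sc <- .scaling_of(population, i)
        tr <- simulate_cell(sc, mech_protocol("isometric", L), config,
                            block = blk)
        if (attr(tr, "status") != "ok") {
          n_rep <- n_rep + 1L; n_fail <- n_fail + 1L
          next
        }
        ap <- detect_ap_abnormalities(tr, abn_config)
        repol <- ap$EAD || ap$DAD || ap$failed_repolarization ||
          ap$premature_AP || ap$APD_alternans
        if (repol) n_rep <- n_rep + 1L
        if (is.na(fmax0[i])) { n_fail <- n_fail + 1L; next }
        # afterload clamp: half the drug-free F_max, expressed as a fraction
        # of the drugged model's own peak isometric force
        frac <- afterload * fmax0[i] /
          max(tr$F_active[tr$cycle == max(tr$cycle)], 1e-9)
        tw <- afterloaded_twitch(sc, afterload_fraction = frac,
                                 config = config, block = blk,
                                 initial_length = L, isometric_trace = tr)
        failed <- if (attr(tw, "status") == "integration_failed") TRUE
        else shortening_metrics(tw)$amplitude <
          abn_config$failed_contraction_frac
        if (failed) n_fail <- n_fail + 1L
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        drug = drug, multiplier = mult, length = L,
        n_repol_abnormal = n_rep, n_failed_contraction = n_fail,
        n_total = nrow(population))
    }
  }
  structure(dplyr::bind_rows(out),
            class = c("event_heatmap", class(tibble::tibble())))
}
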