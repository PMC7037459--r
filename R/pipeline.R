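#' Fold-change arithmetic on guanylate-cyclase activity tables
#'
#' Given per-variant cyclase activities (nmol cGMP min^-1 mg^-1) measured
#' under activating (EGTA, low calcium) and inhibiting (high calcium)
#' conditions, computes:
#' * `max_activation_vs_wt` — WT EGTA activity divided by the variant's
#'   EGTA activity (how many-fold lower the variant's maximal activation
#'   is; 1 for WT);
#' * `inhibition_ratio` — the variant's EGTA activity divided by its
#'   high-calcium activity (how strongly calcium shuts the cyclase down;
#'   large for a functional inhibitor, near 1 for a constitutively
#'   activating variant).
#'
#' @param table data.frame with columns `variant`, `condition` (`"EGTA"` or
#'   `"high_Ca"`), `activity` (>= 0).
#' @return data.frame with one row per variant and the two ratios;
#'   division-by-zero rows carry `NA` and a `flag`.
#' @export
fold_changes <- function(table) {
  need <- c("variant", "condition", "activity")
  if (!all(need %in% names(table)))
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  if (any(table$activity < 0)) stop("activity must be >= 0")
  variants <- unique(table$variant)
  if (!"WT" %in% variants)
    stop("incomplete-row error: WT rows required for cross-variant ratios")
  get_act <- function(v, cond) {
    rows <- table$variant == v & table$condition == cond
    if (!any(rows))
      stop(sprintf("incomplete-row error: variant %s lacks condition %s",
                   v, cond))
    mean(table$activity[rows])
  }
  wt_egta <- get_act("WT", "EGTA")
  out <- lapply(variants, function(v) {
    egta <- get_act(v, "EGTA")
    high <- get_act(v, "high_Ca")
    flag <- character(0)
    max_act <- if (egta > 0) wt_egta / egta else { flag <- "zero EGTA activity"; NA_real_ }
    inhib <- if (high > 0) egta / high else { flag <- c(flag, "zero high-Ca activity"); NA_real_ }
    data.frame(variant = v,
               activity_egta = egta, activity_high_ca = high,
               max_activation_vs_wt = max_act,
               inhibition_ratio = inhib,
               flag = if (length(flag)) paste(flag, collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run configuration for an end-to-end report
#'
#' Bundles input paths, geometry thresholds, fit settings and the output
#' directory. The full configuration is serialised into every report header
#' for provenance.
#'
#' @param out_dir output directory (created if needed).
#' @param pdb optional path to a (multi-model) PDB to scan.
#' @param itc_csv optional ITC thermogram CSV path (see [read_itc_csv()]).
#' @param melt_csv optional melt-curve CSV path.
#' @param activity_csv optional activity table CSV path.
#' @param chain chain to analyse (default `"A"`).
#' @param cations,rings bridge-scan residue specs; default `NULL` derives
#'   them from the fixture numbering via [bridge_fixture_specs()].
#' @param d_max,phi_max,theta_lateral_min,theta_axial_max geometry
#'   thresholds (see [classify_cation_pi()]).
#' @param itc_n_classes,itc_syringe_mM,itc_cell_uM ITC fit settings.
#' @param n_starts,seed fit settings.
#' @param window running-average window, frames.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, pdb = NULL, itc_csv = NULL, melt_csv = NULL,
                       activity_csv = NULL, chain = "A", cations = NULL,
                       rings = NULL, d_max = 6.0, phi_max = 30,
                       theta_lateral_min = 60, theta_axial_max = 30,
                       itc_n_classes = 3L, itc_syringe_mM = 0.5,
                       itc_cell_uM = 20, n_starts = 32L, seed = 1L,
                       window = 100L) {
  structure(list(out_dir = out_dir, pdb = pdb, itc_csv = itc_csv,
                 melt_csv = melt_csv, activity_csv = activity_csv,
                 chain = chain, cations = cations, rings = rings,
                 d_max = d_max, phi_max = phi_max,
                 theta_lateral_min = theta_lateral_min,
                 theta_axial_max = theta_axial_max,
                 itc_n_classes = itc_n_classes,
                 itc_syringe_mM = itc_syringe_mM,
                 itc_cell_uM = itc_cell_uM,
                 n_starts = n_starts, seed = seed, window = window),
            class = "run_config")
}

config_header <- function(config) {
  flat <- config[!vapply(config, is.null, logical(1))]
  flat <- flat[vapply(flat, function(x) is.character(x) || is.numeric(x),
                      logical(1))]
  c(sprintf("# capilock %s", as.character(utils::packageVersion("capilock"))),
    sprintf("# config: %s",
            paste(names(flat), vapply(flat, function(x)
              paste(format(x), collapse = ","), character(1)),
              sep = "=", collapse = " ")))
}

write_report_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' Run an end-to-end analysis report
#'
#' Orchestrates the configured stages — cation-pi bridge scan on a
#' structure or per-frame on an ensemble, trajectory descriptors, ITC fit
#' (report shaped like a per-site K_D / delta-H table with the apparent K_D),
#' melt fit (with `"> Tmax"` censoring), activity fold changes — and writes
#' one TSV per stage plus a JSON summary into the output directory. Outputs
#' are deterministic given the configuration (seeds included), and every
#' numeric column carries its units in the header.
#'
#' @param config a [run_config()].
#' @return the output directory path, invisibly; artifacts on disk.
#' @export
run_report <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  if (!is.null(config$pdb)) {
    obj <- read_pdb(config$pdb)
    models <- if (inherits(obj, "trajectory_ensemble")) {
      lapply(seq_len(n_frames(obj)), function(i) {
        m <- obj$reference
        m$atoms[, c("x", "y", "z")] <- obj$frames[[i]]
        m
      })
    } else list(obj)
    rows <- lapply(seq_along(models), function(i) {
      m <- models[[i]]
      specs <- list(cations = config$cations, rings = config$rings)
      if (is.null(specs$cations) || is.null(specs$rings))
        specs <- bridge_fixture_specs(m, config$chain)
      sc <- bridge_scan(m, specs$cations, specs$rings,
                        d_max = config$d_max, phi_max = config$phi_max,
                        theta_lateral_min = config$theta_lateral_min,
                        theta_axial_max = config$theta_axial_max)
      if (nrow(sc)) cbind(frame = i, sc) else NULL
    })
    scan_df <- do.call(rbind, rows)
    if (is.null(scan_df))
      scan_df <- data.frame(frame = integer(0), cation = character(0))
    names(scan_df) <- sub("^theta", "theta_deg", names(scan_df))
    names(scan_df) <- sub("^phi", "phi_deg", names(scan_df))
    names(scan_df) <- sub("^d_([ab])$", "d_A_\\1", names(scan_df))
    write_report_tsv(scan_df, file.path(config$out_dir, "scan.tsv"), config)
    summary$n_bridges <- nrow(scan_df)
  }
  if (!is.null(config$itc_csv)) {
    tg <- read_itc_csv(config$itc_csv,
                       cell_concentration = config$itc_cell_uM * 1e-6,
                       syringe_concentration = config$itc_syringe_mM * 1e-3)
    fit <- fit_itc(tg, n_classes = config$itc_n_classes,
                   n_starts = config$n_starts, seed = config$seed)
    kd <- fit$model$kd
    itc_df <- data.frame(
      site = seq_along(kd),
      kd = vapply(kd, format_kd, character(1)),
      kd_molar = kd, kd_se_molar = fit$kd_se,
      dH_kcal_mol = fit$model$dh, dH_se_kcal_mol = fit$dh_se,
      stringsAsFactors = FALSE)
    itc_df$kd_app <- c(format_kd(kd_apparent(fit$model)),
                       rep("", length(kd) - 1L))
    write_report_tsv(itc_df, file.path(config$out_dir, "itc_fit.tsv"), config)
    summary$kd_apparent_molar <- kd_apparent(fit$model)
    summary$itc_unidentifiable <- fit$unidentifiable
  }
  if (!is.null(config$melt_csv)) {
    mc <- read_spectro_csv(config$melt_csv)
    if (!inherits(mc, "melt_curve")) stop("melt_csv is not a melt curve")
    mf <- fit_melt(mc)
    melt_df <- data.frame(Tm_C = mf$tm_label, hill_h = mf$h,
                          theta_folded_mdeg = mf$theta_folded,
                          theta_unfolded_mdeg = mf$theta_unfolded,
                          censored = mf$censored)
    write_report_tsv(melt_df, file.path(config$out_dir, "melt_fit.tsv"),
                     config)
    summary$tm_label <- mf$tm_label
  }
  if (!is.null(config$activity_csv)) {
    tab <- read.csv(config$activity_csv)
    fc <- fold_changes(tab)
    write_report_tsv(fc, file.path(config$out_dir, "fold_changes.tsv"),
                     config)
    summary$fold_changes <- fc$inhibition_ratio
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
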