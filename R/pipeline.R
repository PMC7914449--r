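# Configuration handling and the end-to-end pipeline: seeded simulation of
# every input type, per-stage analyses, and a collated summary report.

#' Default pipeline configuration
#'
#' One structured list with per-stage generator blocks and the thresholds
#' the analyses use. The generator defaults state the simulated world: a
#' DEPE-like two-transition thermogram (gel-to-fluid at 35 degC, fluid-to-
#' inverted-hexagonal at 62 degC), a DMPC-like multilamellar SAXD pattern
#' (d = 64 A, zH = 19.5 A), a gel WAXD doublet (4.19 A sharp + 4.10 A
#' shoulder), a bilayer 31P lineshape (-40 ppm anisotropy), and one shared
#' depth distribution driving both the NOESY table and the trajectory.
#'
#' @return named list of defaults (see [validate_config()]).
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "dsc", "saxs", "waxd", "p31", "noesy", "density",
               "contacts", "report"),
    seed = 1L,
    outdir = "memphys_run",
    thresholds = list(prominence = NA_real_,    # NA = auto (5 x robust noise)
                      ratio_tol = 0.03,
                      cutoff = 0.5,             # nm
                      bin_width = 0.1,          # nm
                      skew_threshold = 0.25),
    dsc = list(transitions = list(
                 list(Tm = 35, dH = 7.1094, dH_vH = 600),
                 list(Tm = 62, dH = 0.5, dH_vH = 800)),
               baseline_slope = 0.002, baseline_intercept = 0.05,
               noise_sd = 0.01, t_range = c(10, 70), t_step = 0.05,
               exclusion_windows = list(c(30, 40), c(58, 66))),
    saxs = list(d = 64.0, zH = 19.5, sigmaH = 3.0, sigmaC = 5.4,
                rho_ratio = -1, n_lamellae = 20L, eta = 0,
                s_range = c(0.0075, 0.07), n_points = 600L, noise_sd = 0),
    waxd = list(peaks = list(list(d = 4.19, height = 1, width_s = 0.0012),
                             list(d = 4.10, height = 0.45, width_s = 0.0018)),
                s_range = c(0.20, 0.29), n_points = 400L, noise_sd = 0),
    p31 = list(delta_sigma = -40, phase = "lamellar", lb = 100,
               field_MHz = 242.9, noise_sd = 0),
    noesy = list(tm = 0.3, scale = 1e4, noise_frac = 0.05),
    trajectory = list(n_frames = 200L, box = c(4, 4, 8), mirror = FALSE),
    depth = popc_des_depth_distribution()
  )
}

#' Reference POPC/DES depth distribution
#'
#' The stated world for the NOESY and trajectory generators: Gaussian group
#' depths (nm from the bilayer centre, terminal methyls at 0, choline gamma
#' outermost) for the seven canonical POPC groups plus the two usable DES
#' proton groups (III and IV) centred at the C2/C3 depth. Atom counts are a
#' reduced-scale reading of one leaflet's proton counts; masses in Da.
#'
#' @return a [depth_distribution()].
#' @export
popc_des_depth_distribution <- function() {
  depth_distribution(list(
    list(label = "CH3",   mean_z = 0.00, sd_z = 0.35, n_atoms = 6L,  atom_mass = 15),
    list(label = "CH2n",  mean_z = 0.80, sd_z = 0.45, n_atoms = 40L, atom_mass = 14),
    list(label = "CH2C",  mean_z = 1.10, sd_z = 0.30, n_atoms = 8L,  atom_mass = 14),
    list(label = "C3",    mean_z = 1.35, sd_z = 0.25, n_atoms = 4L,  atom_mass = 14),
    list(label = "C2",    mean_z = 1.45, sd_z = 0.25, n_atoms = 4L,  atom_mass = 14),
    list(label = "G1",    mean_z = 1.60, sd_z = 0.25, n_atoms = 2L,  atom_mass = 13),
    list(label = "gamma", mean_z = 2.00, sd_z = 0.30, n_atoms = 18L, atom_mass = 15),
    list(label = "DES_III", mean_z = 1.40, sd_z = 0.35, n_atoms = 4L, atom_mass = 13),
    list(label = "DES_IV",  mean_z = 1.42, sd_z = 0.35, n_atoms = 6L, atom_mass = 14)))
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults for absent blocks, rejects unknown keys and non-positive
#' thresholds (all violations are reported together), and requires a seed
#' whenever a generator stage is selected.
#'
#' @param cfg partial configuration list (may be empty).
#' @return a complete, validated configuration list.
#' @export
validate_config <- function(cfg = list()) {
  def <- default_config()
  errs <- character(0)
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  out <- utils::modifyList(def, cfg[setdiff(names(cfg), unknown)])
  if (!is.null(cfg$thresholds)) {
    unk_t <- setdiff(names(cfg$thresholds), names(def$thresholds))
    if (length(unk_t))
      errs <- c(errs, paste0("unknown threshold key(s): ",
                             paste(unk_t, collapse = ", ")))
  }
  for (nm in names(out$thresholds)) {
    v <- out$thresholds[[nm]]
    if (!is.na(v) && v <= 0)
      errs <- c(errs, sprintf("threshold '%s' must be positive (got %g)",
                              nm, v))
  }
  bad_stage <- setdiff(out$stages, default_config()$stages)
  if (length(bad_stage))
    errs <- c(errs, paste0("unknown stage(s): ",
                           paste(bad_stage, collapse = ", ")))
  if ("simulate" %in% out$stages &&
      (is.null(out$seed) || is.na(out$seed)))
    errs <- c(errs, "seed is mandatory when the simulate stage is selected")
  if (length(errs))
    stop_memphys(paste(errs, collapse = "; "), "memphys_config_error")
  out$seed <- as.integer(out$seed)
  out
}

stage_input <- function(cfg, fname, stage, needed_by) {
  path <- file.path(cfg$outdir, fname)
  if (!file.exists(path))
    stop_memphys(sprintf("stage '%s' needs '%s' produced by stage '%s'",
                         needed_by, fname, stage),
                 "memphys_dependency_error")
  path
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order. The simulate stage
#' writes every input file from the seeded generators; each analysis stage
#' reads its input from the output directory and writes per-stage TSV/CSV
#' results; the report stage collates an enthalpy table, a structural
#' (Table-2-style) table, phase assignments and the ligand location profile
#' into `summary.txt`. Every threshold actually used is logged via
#' `message()`, and all seeds appear in the report header. Identical
#' config + seed reproduce byte-identical outputs.
#'
#' @param cfg configuration list, passed through [validate_config()].
#' @return invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  seed <- cfg$seed
  th <- cfg$thresholds
  message(sprintf("thresholds: prominence=%s ratio_tol=%g cutoff=%g bin_width=%g skew_threshold=%g",
                  ifelse(is.na(th$prominence), "auto", th$prominence),
                  th$ratio_tol, th$cutoff, th$bin_width, th$skew_threshold))

  if ("simulate" %in% cfg$stages) {
    g <- cfg$dsc
    tg <- gen_thermogram(thermogram_params(g$transitions, g$baseline_slope,
                                           g$baseline_intercept, g$noise_sd,
                                           g$t_range, g$t_step, seed))
    write_thermogram_csv(tg, file.path(cfg$outdir, "thermogram.csv"))
    gs <- cfg$saxs
    sp <- lamellar_model_params(gs$d, gs$zH, gs$sigmaH, gs$sigmaC,
                                gs$rho_ratio, gs$n_lamellae, gs$eta)
    s_grid <- seq(gs$s_range[1], gs$s_range[2], length.out = gs$n_points)
    write_pattern_csv(gen_saxs_pattern(sp, s_grid, gs$noise_sd, seed + 1L),
                      file.path(cfg$outdir, "saxd.csv"))
    gw <- cfg$waxd
    w_grid <- seq(gw$s_range[1], gw$s_range[2], length.out = gw$n_points)
    write_pattern_csv(gen_waxd_pattern(gw$peaks, w_grid, gw$noise_sd,
                                       seed + 2L),
                      file.path(cfg$outdir, "waxd.csv"))
    gp <- cfg$p31
    write_spectrum_csv(gen_31p_spectrum(gp$delta_sigma, gp$phase, gp$lb,
                                        gp$field_MHz, gp$noise_sd,
                                        seed + 3L),
                       file.path(cfg$outdir, "p31.csv"))
    ligand <- grep("^DES", cfg$depth$labels, value = TRUE)
    gn <- cfg$noesy
    write_noesy_csv(gen_noesy_table(cfg$depth, ligand, gn$tm, gn$scale,
                                    gn$noise_frac, seed + 4L),
                    file.path(cfg$outdir, "noesy.csv"))
    gt <- cfg$trajectory
    write_xyz_frames(gen_trajectory(cfg$depth, gt$n_frames, gt$box,
                                    seed + 5L, gt$mirror),
                     file.path(cfg$outdir, "trajectory.xyz"))
    res$simulate <- "ok"
  }

  prom <- if (is.na(th$prominence)) NULL else th$prominence

  if ("dsc" %in% cfg$stages) {
    tg <- read_thermogram_csv(stage_input(cfg, "thermogram.csv", "simulate",
                                          "dsc"))
    tb <- subtract_baseline(tg, cfg$dsc$exclusion_windows)
    trs <- find_transitions(tb, prom)
    rows <- lapply(seq_along(trs), function(i)
      list(label = sprintf("transition_%d", i), molar_ratio = Inf,
           transition = trs[[i]]))
    write_transitions_tsv(rows, file.path(cfg$outdir, "transitions.tsv"))
    res$dsc <- trs
  }

  if ("saxs" %in% cfg$stages) {
    p <- read_pattern_csv(stage_input(cfg, "saxd.csv", "simulate", "saxs"))
    pk <- pick_peaks(p, prom)
    cls <- classify_phase_saxd(pk, th$ratio_tol)
    gs <- cfg$saxs
    init <- lamellar_model_params(
      if (!is.null(cls$lamellar) && !cls$lamellar$indeterminate)
        cls$lamellar$d else gs$d,
      gs$zH * 1.02, gs$sigmaH * 0.98, gs$sigmaC * 1.02, gs$rho_ratio,
      gs$n_lamellae, gs$eta)
    fit <- fit_saxs(p, init, seed = seed)
    write_structure_tsv(list(sample = fit),
                        file.path(cfg$outdir, "structure.tsv"))
    res$saxs <- list(peaks = pk, classification = cls, fit = fit)
  }

  if ("waxd" %in% cfg$stages) {
    p <- read_pattern_csv(stage_input(cfg, "waxd.csv", "simulate", "waxd"))
    packing <- classify_packing_waxd(p)
    writeLines(sprintf("packing\t%s\nevidence\t%s", as.character(packing),
                       attr(packing, "evidence")),
               file.path(cfg$outdir, "waxd_packing.tsv"))
    res$waxd <- packing
  }

  if ("p31" %in% cfg$stages) {
    sp <- read_spectrum_csv(stage_input(cfg, "p31.csv", "simulate", "p31"))
    cls <- classify_31p(sp, skew_threshold = th$skew_threshold)
    writeLines(c(sprintf("phase\t%s", cls$phase),
                 sprintf("skewness\t%.4f", cls$skewness),
                 sprintf("edge_low_field_ppm\t%.3f", cls$edges[1]),
                 sprintf("edge_high_field_ppm\t%.3f", cls$edges[2]),
                 sprintf("span_ppm\t%.3f", cls$span)),
               file.path(cfg$outdir, "p31_phase.tsv"))
    res$p31 <- cls
  }

  if ("noesy" %in% cfg$stages) {
    nt <- read_noesy_csv(stage_input(cfg, "noesy.csv", "simulate", "noesy"))
    cp <- cross_relaxation_rates(nt)
    lp <- location_profile(cp)
    lines <- c("ligand\tmodal\tranking")
    for (lig in names(lp))
      lines <- c(lines, sprintf("%s\t%s\t%s", lig, lp[[lig]]$modal,
                                paste(lp[[lig]]$ranking$group,
                                      collapse = ",")))
    writeLines(lines, file.path(cfg$outdir, "location_profile.tsv"))
    res$noesy <- list(rates = cp, profile = lp)
  }

  if ("density" %in% cfg$stages || "contacts" %in% cfg$stages) {
    masses <- vapply(cfg$depth$groups, `[[`, numeric(1), "atom_mass")
    names(masses) <- cfg$depth$labels
    tr <- read_xyz_frames(stage_input(cfg, "trajectory.xyz", "simulate",
                                      "density"), masses)
    tr <- center_frames(tr, "CH3")
    if ("density" %in% cfg$stages) {
      dp <- mass_density_profile(tr, bin_width = th$bin_width)
      df <- data.frame(z_nm = dp$z, dp$density, check.names = FALSE)
      utils::write.table(format(df, digits = 8),
                         file.path(cfg$outdir, "density_profile.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      res$density <- dp
    }
    if ("contacts" %in% cfg$stages) {
      ligand <- grep("^DES", cfg$depth$labels, value = TRUE)
      lipid <- setdiff(cfg$depth$labels, ligand)
      lines <- c("groupA\tgroupB\tcutoff_nm\tmean_contacts")
      cc_all <- list()
      for (lg in ligand) for (gp in lipid) {
        cc <- count_contacts(tr, lg, gp, th$cutoff)
        cc_all[[paste(lg, gp, sep = "-")]] <- cc
        lines <- c(lines, sprintf("%s\t%s\t%.3f\t%.6f", lg, gp, th$cutoff,
                                  cc$mean_contacts))
      }
      writeLines(lines, file.path(cfg$outdir, "contacts.tsv"))
      res$contacts <- cc_all
    }
  }

  if ("report" %in% cfg$stages) {
    lines <- c("memphys run report",
               sprintf("seed\t%d", seed),
               sprintf("stages\t%s", paste(cfg$stages, collapse = ",")))
    if (!is.null(res$dsc)) {
      lines <- c(lines, "", "[DSC transitions]",
                 "t_max_degC\tt_onset\tt_end\tdH_kcal_mol\tfwhm")
      for (tr in res$dsc)
        lines <- c(lines, sprintf("%.3f\t%.3f\t%.3f\t%.4f\t%.3f",
                                  tr$t_max, tr$t_onset, tr$t_end, tr$dH,
                                  tr$fwhm))
    }
    if (!is.null(res$saxs)) {
      f <- res$saxs$fit
      lines <- c(lines, "", "[SAXD structure]",
                 sprintf("phase\t%s", res$saxs$classification$phase),
                 "d\tzH\tsigmaH\tsigmaC\tdHH\tdB\tdw",
                 sprintf("%.3f\t%.3f\t%.3f\t%.3f\t%.3f\t%.3f\t%.3f",
                         f$d, f$zH, f$sigmaH, f$sigmaC, f$dHH, f$dB, f$dw),
                 sprintf("dw_plus_dB_minus_d\t%.6g", f$dw + f$dB - f$d))
    }
    if (!is.null(res$waxd))
      lines <- c(lines, "", "[WAXD packing]",
                 sprintf("packing\t%s", as.character(res$waxd)))
    if (!is.null(res$p31))
      lines <- c(lines, "", "[31P phase]",
                 sprintf("phase\t%s", res$p31$phase))
    if (!is.null(res$noesy)) {
      lines <- c(lines, "", "[NOESY location]")
      for (lig in names(res$noesy$profile))
        lines <- c(lines, sprintf("%s\tmodal=%s", lig,
                                  res$noesy$profile[[lig]]$modal))
    }
    writeLines(lines, file.path(cfg$outdir, "summary.txt"))
    res$report <- file.path(cfg$outdir, "summary.txt")
  }
  invisible(res)
}
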