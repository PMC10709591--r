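#' Configuration of the phantom-scale validation study
#'
#' Describes the end-to-end experiment: a seeded nodule cohort is rasterised
#' as thin-section phantoms ("real TSCT"), degraded to 5 mm conventional CT,
#' reconstructed back to thin sections ("virtual TSCT"), measured by two
#' simulated observers on all three sources, staged, and analysed with the
#' full agreement battery. The nodule centre receives a seeded uniform
#' z-jitter of half the conventional interval so the slab phase varies
#' across cases, as it does across patients.
#'
#' @param n_cases number of nodules (default 93, the validation cohort size).
#' @param spacing_mm voxel spacing of the thin phantom grid (z in [0.5, 1]).
#' @param margin_mm empty margin around the nodule radius when sizing grids.
#' @param thickness_mm,interval_mm conventional reconstruction (default 5/5).
#' @param target_thin_mm virtual thin-section spacing (default = thin z).
#' @param observer_a,observer_b [observer_model()]s for the two readers
#'   (independent seeds, equal 1 mm noise + 1 mm rounding by default).
#' @param model "baseline" (linear z-interpolation), "identity" (virtual =
#'   real, a degenerate pipeline check) or a trained `vts_model`.
#' @param params [cohort_params()] for the cohort draw.
#' @param solid_threshold_hu,total_threshold_hu measurement thresholds.
#' @param seed master seed; every random stream is derived from it.
#' @return A `study_config` object.
#' @export
study_config <- function(n_cases = 93, spacing_mm = c(1, 1, 1), margin_mm = 7,
                         thickness_mm = 5, interval_mm = 5,
                         target_thin_mm = NULL,
                         observer_a = observer_model(1, 1, seed = 101),
                         observer_b = observer_model(1, 1, seed = 202),
                         model = "baseline",
                         params = cohort_params(),
                         solid_threshold_hu = -300, total_threshold_hu = -700,
                         seed = 1) {
  if (n_cases < 2) stop("n_cases must be >= 2")
  if (is.null(target_thin_mm)) target_thin_mm <- spacing_mm[3]
  if (is.character(model) && !model %in% c("baseline", "identity"))
    stop("model must be 'baseline', 'identity' or a vts_model")
  structure(list(n_cases = as.integer(n_cases), spacing_mm = spacing_mm,
                 margin_mm = margin_mm, thickness_mm = thickness_mm,
                 interval_mm = interval_mm, target_thin_mm = target_thin_mm,
                 observer_a = observer_a, observer_b = observer_b,
                 model = model, params = params,
                 solid_threshold_hu = solid_threshold_hu,
                 total_threshold_hu = total_threshold_hu,
                 seed = as.integer(seed)),
            class = "study_config")
}

# build the three per-case volumes: real thin, conventional thick, virtual
build_case_volumes <- function(spec, config, case_seed, z_jitter) {
  sp <- config$spacing_mm
  half <- spec$total_diameter_mm / 2 + config$margin_mm
  dims <- pmax(2L * ceiling(half / sp) + 1L, 9L)
  origin <- -(dims - 1) * sp / 2
  tmpl <- volume_template(dims, sp, origin)
  spec$center_mm <- c(0, 0, z_jitter)
  ph <- generate_phantom(spec, tmpl, seed = case_seed)
  cond <- slice_condition(config$thickness_mm, config$interval_mm,
                          source_thin_mm = sp[3])
  conv <- degrade(ph$volume, cond)
  virt <- if (identical(config$model, "identity")) ph$volume
  else if (identical(config$model, "baseline"))
    baseline_interp(conv, cond, config$target_thin_mm, "linear")
  else vts_infer(config$model, conv, cond, config$target_thin_mm)
  list(real = ph$volume, conventional = conv, virtual = virt, truth = ph$truth)
}

#' Run the phantom-scale validation study
#'
#' Deterministic under the config seed. "Real TSCT" is the thin phantom,
#' "conventional" its 5 mm slab-averaged degradation, "virtual" the model
#' reconstruction from conventional; pathological truth comes from the
#' cohort's invasive-size proxy. The clinical gold standard stage is observer
#' B's real-TSCT read, mirroring the validation design. For staging, the
#' measured total size is capped at 40 mm: categories above 30 mm total
#' depend only on solid size, so the cap never changes a category but keeps
#' the stage 0-I rule-table contract satisfied for large noisy reads.
#'
#' @param config a [study_config()].
#' @return A `study_report`: per-case measurement and staging tables plus
#'   ICC per source, Pearson pairs with the dependent-correlation
#'   comparison, kappas (vs real-TSCT staging and vs pathological staging)
#'   with bands, and the ANCOVA table.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config$n_cases, config$params,
                            seed = derive_seed(config$seed, 1))
  jit <- with_seed(derive_seed(config$seed, 2),
                   runif(config$n_cases, -config$interval_mm / 2,
                         config$interval_mm / 2))
  sources <- c("real_tsct", "conventional", "virtual_tsct")
  obs <- list(A = config$observer_a, B = config$observer_b)
  meas <- list()
  for (i in seq_len(config$n_cases)) {
    vols <- build_case_volumes(cohort$specs[[i]], config,
                               case_seed = derive_seed(config$seed, 100 + i),
                               z_jitter = jit[i])
    for (src in sources) {
      vol <- switch(src, real_tsct = vols$real, conventional = vols$conventional,
                    virtual_tsct = vols$virtual)
      # conventional 5 mm CT is read on axial planes only, as in practice;
      # thin-section sources are read on all three MPR orientations
      ori <- if (src == "conventional") "axial"
             else c("axial", "coronal", "sagittal")
      auto <- measure_size(vol, config$solid_threshold_hu,
                           config$total_threshold_hu, source = src,
                           orientations = ori)
      for (o in names(obs)) {
        read <- simulate_observer(auto, obs[[o]], case_id = i)
        meas[[length(meas) + 1L]] <-
          data.frame(case_id = i, source = src, observer = o,
                     solid_mm = read$solid_mm, total_mm = read$total_mm,
                     plane = ifelse(is.na(read$solid_plane), "none",
                                    read$solid_plane),
                     auto_solid_mm = auto$solid_mm)
      }
    }
  }
  meas <- do.call(rbind, meas)

  get_col <- function(src, o, col = "solid_mm")
    meas[meas$source == src & meas$observer == o, col][order(
      meas$case_id[meas$source == src & meas$observer == o])]

  # staging tables (clinical per source/observer; pathological from truth)
  stage_rows <- list()
  for (src in sources) for (o in c("A", "B")) {
    tot <- pmin(get_col(src, o, "total_mm"), 40)
    sol <- pmin(get_col(src, o, "solid_mm"), tot)
    stage_rows[[paste(src, o)]] <-
      data.frame(case_id = seq_len(config$n_cases), source = src, observer = o,
                 t_category = as.character(assign_t(tot, sol)))
  }
  staging <- do.call(rbind, stage_rows)
  rownames(staging) <- NULL
  p_total <- pmin(pmax(cohort$truth$total_mm, cohort$truth$invasive_mm), 40)
  p_solid <- pmin(cohort$truth$invasive_mm, p_total)
  path_stage <- as.character(assign_t(p_total, p_solid))
  gold <- staging$t_category[staging$source == "real_tsct" & staging$observer == "B"]

  # agreement battery
  icc <- lapply(sources, function(src)
    icc_agreement(get_col(src, "A"), get_col(src, "B")))
  names(icc) <- sources

  pearson <- list()
  for (o in c("A", "B")) {
    rl <- get_col("real_tsct", o); cv <- get_col("conventional", o)
    vt <- get_col("virtual_tsct", o)
    r_conv <- cor(cv, rl); r_virt <- cor(vt, rl); r_ac <- cor(cv, vt)
    cmp <- if (anyNA(c(r_conv, r_virt, r_ac)) ||
               any(abs(c(r_conv, r_virt, r_ac)) >= 1))
      list(statistic = NA_real_, p = NA_real_)  # degenerate at tiny n
    else compare_dependent_r(r_virt, r_conv, r_ac, config$n_cases)
    pearson[[o]] <- list(r_conventional = r_conv, r_virtual = r_virt,
                         r_cross = r_ac, statistic = cmp$statistic, p = cmp$p)
  }

  kap_entry <- function(a, b) {
    k <- cohen_kappa(a, b, categories = t_categories())
    k$band <- if (is.na(k$kappa)) NA_character_ else interpret_kappa(k$kappa)
    k
  }
  stage_of <- function(src, o)
    staging$t_category[staging$source == src & staging$observer == o]
  kappa_clinical <- list(); kappa_pathological <- list()
  for (o in c("A", "B")) for (src in c("conventional", "virtual_tsct")) {
    kappa_clinical[[paste(src, o, sep = ".")]] <- kap_entry(stage_of(src, o), gold)
  }
  for (o in c("A", "B")) for (src in sources) {
    kappa_pathological[[paste(src, o, sep = ".")]] <-
      kap_entry(stage_of(src, o), path_stage)
  }

  gold_size <- get_col("real_tsct", "B")
  anc_tab <- do.call(rbind, lapply(c("conventional", "virtual_tsct"), function(src)
    do.call(rbind, lapply(c("A", "B"), function(o)
      data.frame(case_id = seq_len(config$n_cases), observer = o, modality = src,
                 size = get_col(src, o), real_size = gold_size)))))
  ancova <- ancova_modality_observer(anc_tab)
  ancova$model <- NULL   # keep the report serialisable

  structure(list(schema_version = 1L,
                 n_cases = config$n_cases, seed = config$seed,
                 model = if (is.character(config$model)) config$model else "vts_model",
                 measurements = meas, staging = staging,
                 pathological_stage = path_stage, truth = cohort$truth,
                 icc = icc, pearson = pearson,
                 kappa_clinical = kappa_clinical,
                 kappa_pathological = kappa_pathological,
                 ancova = ancova),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d cases, model = %s\n", x$n_cases, x$model))
  for (s in names(x$icc))
    cat(sprintf("  ICC(%s) = %.3f\n", s, x$icc[[s]]$icc))
  for (o in names(x$pearson))
    cat(sprintf("  observer %s: r(conv)=%.3f r(virt)=%.3f p=%.4g\n", o,
                x$pearson[[o]]$r_conventional, x$pearson[[o]]$r_virtual,
                x$pearson[[o]]$p))
  invisible(x)
}

#' Write / read a study report
#'
#' `write_report` renders the report into a directory: `report.json` (the
#' statistics, schema-versioned), `measurements.csv`, `staging.csv` and a
#' human-readable `report.txt` whose kappa cells carry the interpretation
#' bands. `read_report` parses `report.json` back.
#'
#' @param report a `study_report`.
#' @param path output directory (created if needed).
#' @return `write_report`: the directory path, invisibly. `read_report`: the
#'   parsed report list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create report directory: ", path)
  utils::write.csv(report$measurements, file.path(path, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$staging, file.path(path, "staging.csv"),
                   row.names = FALSE)
  js <- report[c("schema_version", "n_cases", "seed", "model", "icc",
                 "pearson", "kappa_clinical", "kappa_pathological", "ancova")]
  js$kappa_clinical <- lapply(js$kappa_clinical, strip_table)
  js$kappa_pathological <- lapply(js$kappa_pathological, strip_table)
  jsonlite::write_json(js, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- file.path(path, "report.txt")
  con <- file(txt, "w"); on.exit(close(con))
  writeLines(sprintf("Phantom validation study: %d cases (model: %s)",
                     report$n_cases, report$model), con)
  writeLines("-- Inter-observer ICC (solid size) --", con)
  for (s in names(report$icc)) {
    e <- report$icc[[s]]
    writeLines(sprintf("  %-14s ICC = %.3f  95%% CI %.3f-%.3f  P = %.3g",
                       s, e$icc, e$ci[1], e$ci[2], e$p), con)
  }
  writeLines("-- Correlation with real TSCT --", con)
  for (o in names(report$pearson)) {
    e <- report$pearson[[o]]
    writeLines(sprintf("  observer %s: r(conv) = %.3f, r(virtual) = %.3f, P = %.3g",
                       o, e$r_conventional, e$r_virtual, e$p), con)
  }
  kline <- function(nm, e)
    sprintf("  %-22s kappa = %.3f  95%% CI %.3f-%.3f  P = %.3g  (%s)",
            nm, e$kappa, e$ci[1], e$ci[2], e$p, e$band)
  writeLines("-- Clinical T agreement vs real TSCT --", con)
  for (nm in names(report$kappa_clinical))
    writeLines(kline(nm, report$kappa_clinical[[nm]]), con)
  writeLines("-- Clinical vs pathological T agreement --", con)
  for (nm in names(report$kappa_pathological))
    writeLines(kline(nm, report$kappa_pathological[[nm]]), con)
  writeLines("-- ANCOVA (size ~ observer + modality + real_size) --", con)
  for (term in c("observer", "modality", "real_size"))
    writeLines(sprintf("  %-10s F = %.3f  P = %.3g", term,
                       report$ancova[[term]]["F"], report$ancova[[term]]["p"]), con)
  invisible(path)
}

strip_table <- function(e) { e$table <- NULL; e }

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(file.path(path, "report.json"), simplifyVector = TRUE)
}
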