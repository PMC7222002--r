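#' Summary statistics: mean and sample SD
#'
#' @param values numeric vector, length >= 1.
#' @return tibble with `mean`, `sd` (NA for a single value, flagged by
#'   `sd_defined = FALSE`) and `n`.
#' @export
mean_sd <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop_input("mean_sd needs a non-empty numeric vector")
  }
  tibble(mean = mean(values),
         sd = if (length(values) > 1) sd(values) else NA_real_,
         sd_defined = length(values) > 1,
         n = length(values))
}

#' Two-sample t-test (Welch by default)
#'
#' Welch's unequal-variance test is the default because replicate variances
#' of bench measurements routinely differ between formulations; the pooled
#' (classical Student) variant is available. Degenerate inputs in which both
#' groups have zero variance are handled explicitly: equal means give t = 0,
#' p = 1; different means are reported as t = +/-Inf, p = 0 (the limit of
#' vanishing within-group variance).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance Student test instead of Welch.
#' @return tibble with group means/SDs/sizes, `t`, `df`, `p_value`.
#' @export
welch_t <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_input("both groups need n >= 2")
  }
  base <- tibble(mean_a = mean(group_a), sd_a = sd(group_a), n_a = length(group_a),
                 mean_b = mean(group_b), sd_b = sd(group_b), n_b = length(group_b))
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    same <- mean(group_a) == mean(group_b)
    base$t <- if (same) 0 else sign(mean(group_a) - mean(group_b)) * Inf
    base$df <- NA_real_
    base$p_value <- if (same) 1 else 0
    return(base)
  }
  ht <- t.test(group_a, group_b, var.equal = pooled)
  base$t <- unname(ht$statistic)
  base$df <- unname(ht$parameter)
  base$p_value <- ht$p.value
  base
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return tibble with `r`, `p_value` and `n`; `r` is NA (with a warning)
#'   when either variable has zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_input("pearson_r needs two equal-length vectors with n >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# ---- file readers/writers -------------------------------------------------

read_checked_table <- function(path, required) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  dat <- as_tibble(read.csv(path, check.names = FALSE))
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols)) {
    stop_input("%s is missing required column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  }
  dat
}

#' Read delimited instrument tables
#'
#' All tables are comma-delimited with a one-line header. Schema validation
#' rejects a table missing a required column with a message naming it.
#'
#' `read_spreadability_table()`: columns `formulation_id`, `replicate`,
#' `added_mass_g`, `diameter_cm`.
#' `read_flow_table()`: columns `formulation_id`, `temperature_c`, `phase`,
#' `shear_rate_s1`, `shear_stress_pa`.
#' `read_viscosity_table()`: columns `formulation_id`, `temperature_c`,
#' `shear_rate_s1`, `viscosity_mpas`.
#' `read_release_table()`: columns `formulation_id`, `replicate`,
#' `time_min`, `absorbance`.
#'
#' @param path file path.
#' @return tibble.
#' @name table_io
#' @export
read_spreadability_table <- function(path) {
  read_checked_table(path, c("formulation_id", "replicate", "added_mass_g",
                             "diameter_cm"))
}

#' @rdname table_io
#' @export
read_flow_table <- function(path) {
  read_checked_table(path, c("formulation_id", "temperature_c", "phase",
                             "shear_rate_s1", "shear_stress_pa"))
}

#' @rdname table_io
#' @export
read_viscosity_table <- function(path) {
  read_checked_table(path, c("formulation_id", "temperature_c",
                             "shear_rate_s1", "viscosity_mpas"))
}

#' @rdname table_io
#' @export
read_release_table <- function(path) {
  read_checked_table(path, c("formulation_id", "replicate", "time_min",
                             "absorbance"))
}

#' Read/write a TPA trace with its metadata header
#'
#' Traces are stored as comma-delimited `time_s, force_n` preceded by
#' `# key: value` metadata lines (probe speeds, depth, trigger force).
#'
#' @param path file path.
#' @param trace a [tpa_trace()] (for writing).
#' @return `read_tpa_trace()` returns a [tpa_trace()].
#' @export
read_tpa_trace <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  dat <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  if (!all(c("time_s", "force_n") %in% names(dat))) {
    stop_input("%s is missing required column(s): %s", path,
               paste(setdiff(c("time_s", "force_n"), names(dat)), collapse = ", "))
  }
  getm <- function(key, default) if (!is.null(meta[[key]])) meta[[key]] else default
  tpa_trace(as_tibble(dat),
            descent_speed_mm_s = getm("descent_speed_mm_s", 5),
            ascent_speed_mm_s = getm("ascent_speed_mm_s", 0.1),
            target_depth_mm = getm("target_depth_mm", 10),
            trigger_force_n = getm("trigger_force_n", 0.01))
}

#' @rdname read_tpa_trace
#' @export
write_tpa_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tpa_trace"))
  meta <- sprintf("# %s: %g",
                  c("descent_speed_mm_s", "ascent_speed_mm_s",
                    "target_depth_mm", "trigger_force_n"),
                  c(attr(trace, "descent_speed_mm_s"),
                    attr(trace, "ascent_speed_mm_s"),
                    attr(trace, "target_depth_mm"),
                    attr(trace, "trigger_force_n")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

# ---- study driver ---------------------------------------------------------

study_log <- function(fmt, ...) message(sprintf(paste0("[ointchar] ", fmt), ...))

#' Run a full synthetic characterization study and write its report tables
#'
#' Drives every stage of the package on deterministic synthetic data whose
#' ground truth is the shipped reference characterization of the
#' seven-formulation series: spreadability curves from the published
#' log-law coefficients, thixotropic flow curves at 25 and 32 C, TPA traces
#' from the published texture rows, and enhancer-cell release experiments
#' from the published Higuchi rates. Writes one delimited report per stage
#' into `out_dir`. Report generation is deterministic: the same config and
#' seed give byte-identical outputs. No multiplicity correction is applied
#' to the pairwise release-rate tests; each p-value is per-comparison.
#'
#' @param config named list (or path to a YAML file) with required keys
#'   `seed` (integer) and `out_dir` (directory, created if absent); optional
#'   `n_reps` (default 5) and `noise` (logical, default TRUE) controlling
#'   instrument noise in the generators.
#' @return invisibly, a named list of the written file paths.
#' @export
run_study <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_input("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  required <- c("seed", "out_dir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) {
    stop_input("config is missing required key(s): %s",
               paste(missing_keys, collapse = ", "))
  }
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  n_reps <- if (is.null(config$n_reps)) 5 else config$n_reps
  noisy <- if (is.null(config$noise)) TRUE else isTRUE(config$noise)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- list()
  emit <- function(name, tbl) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(as.data.frame(tbl), path, row.names = FALSE)
    written[[name]] <<- path
    study_log("wrote %s", path)
  }

  # pH summary (replicates around the published means)
  set.seed(seed)
  ph_ref <- reference_ph()
  ph_rows <- lapply(seq_len(nrow(ph_ref)), function(i) {
    reps <- rnorm(n_reps, ph_ref$ph_mean[i], if (noisy) ph_ref$ph_sd[i] else 0)
    cbind(tibble(formulation_id = ph_ref$formulation_id[i]), mean_sd(reps))
  })
  emit("table_ph", dplyr::bind_rows(ph_rows))

  # spreadability
  set.seed(seed + 1)
  ref <- reference_spreadability()
  curves <- lapply(seq_len(nrow(ref)), function(i) {
    gen_spreadability(ref$a[i], ref$b[i], n_reps = n_reps,
                      noise_sd_cm2 = if (noisy) 0.5 else 0,
                      formulation_id = ref$formulation_id[i])
  })
  spread_tab <- spreadability_report(curves, reference = "F-1")
  emit("table_spreadability", spread_tab)
  corr <- pearson_r(spread_tab$auc[3:7], reference_formulations()$acth_mg_g[3:7])
  emit("spreadability_concentration_correlation", corr)

  # rheology: thixotropic flow curves at the two temperatures
  set.seed(seed + 2)
  fc_ids <- paste0("F-", 1:7)
  loops <- lapply(c(25, 32), function(tc) {
    sapply(seq_along(fc_ids), function(i) {
      eta <- reference_viscosity()$viscosity_mean[
        reference_viscosity()$formulation_id == fc_ids[i] &
          reference_viscosity()$temperature_c == tc &
          reference_viscosity()$shear_rate_s1 == 1100] / 1000 # mPa.s -> Pa.s
      cv <- gen_flow_curve(tau_y = 5, eta = eta, breakdown_rate = 2e-4,
                           recovery_rate = 0.02, temperature_c = tc,
                           noise_sd_pa = if (noisy) 0.01 else 0,
                           formulation_id = fc_ids[i])
      as.numeric(hysteresis_area(cv))
    })
  })
  emit("table_thixotropy",
       compare_thixotropy(setNames(loops[[1]], fc_ids),
                          setNames(loops[[2]], fc_ids)))

  # texture
  set.seed(seed + 3)
  tex_ref <- reference_texture()
  tex_rows <- lapply(seq_len(nrow(tex_ref)), function(i) {
    prof <- tpa_profile(tex_ref$hardness_n[i], tex_ref$cohesiveness[i],
                        tex_ref$adhesiveness_mj[i], tex_ref$elasticity[i],
                        tex_ref$adhesion_force_n[i])
    got <- extract_tpa(gen_tpa(prof, noise_sd_n = if (noisy) 5e-4 else 0))
    tibble(formulation_id = tex_ref$formulation_id[i],
           hardness_n = got$hardness_n, cohesiveness = got$cohesiveness,
           adhesiveness_mj = got$adhesiveness_mj, elasticity = got$elasticity,
           adhesion_force_n = got$adhesion_force_n)
  })
  tex_tab <- dplyr::bind_rows(tex_rows)
  emit("table_texture", tex_tab)
  emit("table_texture_ratios", texture_ratios(tex_tab, reference = "F-1"))

  # release
  set.seed(seed + 4)
  rel_ref <- reference_release_rates()
  rel_rows <- list(); rate_rows <- list()
  for (i in seq_len(nrow(rel_ref))) {
    dose <- rel_ref$acth_mg_g[i] # 1.0 g of ointment loaded
    rates_i <- vapply(seq_len(6), function(r) {
      sim <- suppressWarnings(gen_release_experiment(
        "higuchi", list(kH = rel_ref$rate_mean[i]),
        exp = release_experiment(loaded_dose_mg = dose),
        photometric_accuracy = if (noisy) 0.005 else 0,
        cap_at_dose = FALSE))
      suppressWarnings(analyze_release(sim)$fit$params$kH)
    }, numeric(1))
    rate_rows[[i]] <- tibble(formulation_id = rel_ref$formulation_id[i],
                             rate = rates_i)
  }
  cmp <- release_rate_comparison(dplyr::bind_rows(rate_rows))
  emit("table_release_rates", cmp$summary)
  emit("table_release_tests", cmp$tests)
  invisible(written)
}
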