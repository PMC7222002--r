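#' Construct a TPA force-time trace
#'
#' Texture profile analysis (TPA) compresses the sample twice with a
#' cylindrical probe, with a pause between the cycles. The instrument logs
#' force against time; probe kinematics (descent/ascent speed, target depth)
#' are metadata needed to convert durations into travel distances and
#' time-areas into mechanical work.
#'
#' @param data data frame with columns `time_s`, `force_n`.
#' @param descent_speed_mm_s probe lowering speed (default 5 mm/s).
#' @param ascent_speed_mm_s probe raising speed (default 0.1 mm/s).
#' @param target_depth_mm immersion depth (default 10 mm).
#' @param trigger_force_n detection threshold (default 0.01 N).
#' @param probe_area_m2 optional probe cross-section for stress conversions.
#' @return a `tpa_trace` tibble with kinematic attributes.
#' @export
tpa_trace <- function(data, descent_speed_mm_s = 5, ascent_speed_mm_s = 0.1,
                      target_depth_mm = 10, trigger_force_n = 0.01,
                      probe_area_m2 = NULL) {
  data <- as_tibble(data)
  if (!all(c("time_s", "force_n") %in% names(data))) {
    stop_input("TPA trace needs columns time_s, force_n")
  }
  if (is.unsorted(data$time_s, strictly = TRUE)) {
    stop_input("time_s must be strictly increasing")
  }
  check_number(descent_speed_mm_s, "descent_speed_mm_s", positive = TRUE)
  check_number(ascent_speed_mm_s, "ascent_speed_mm_s", positive = TRUE)
  check_number(trigger_force_n, "trigger_force_n", positive = TRUE)
  structure(data,
            descent_speed_mm_s = descent_speed_mm_s,
            ascent_speed_mm_s = ascent_speed_mm_s,
            target_depth_mm = target_depth_mm,
            trigger_force_n = trigger_force_n,
            probe_area_m2 = probe_area_m2,
            class = c("tpa_trace", class(data)))
}

# linearly interpolated time at which force crosses zero between samples
# i (one side of zero) and i+1 (other side); falls back to the sample time
zero_crossing <- function(t, f, i) {
  if (i < 1 || i >= length(t)) return(t[max(1, min(i, length(t)))])
  f1 <- f[i]; f2 <- f[i + 1]
  if (f1 == f2) return(t[i])
  t[i] + (0 - f1) * (t[i + 1] - t[i]) / (f2 - f1)
}

#' Segment a TPA trace into its two compression episodes
#'
#' Episodes are detected as runs of at least `debounce` consecutive samples
#' above the trigger force; each detected onset/offset is then refined to the
#' interpolated zero-force crossing so that durations (and hence probe-travel
#' distances) are unbiased by the trigger threshold. Exactly two episodes
#' must be present. The negative-force lobe between the first episode's end
#' and the second's start (probe detachment during ascent) is located as
#' well.
#'
#' @param trace a [tpa_trace()].
#' @param debounce minimum run length above threshold (default 3 samples).
#' @return list with `episodes` (tibble: `start`, `peak`, `end` times and
#'   peak force per episode) and `lobe` (`start`/`end` times of the negative
#'   lobe after episode 1, or NULL when the trace never goes negative).
#' @export
segment_cycles <- function(trace, debounce = 3) {
  stopifnot(inherits(trace, "tpa_trace"))
  t <- trace$time_s; f <- trace$force_n
  trig <- attr(trace, "trigger_force_n")
  above <- f > trig
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= debounce
  ep_idx <- cbind(starts[keep], ends[keep])
  n_ep <- nrow(ep_idx)
  if (n_ep != 2) {
    stop_input("expected exactly 2 compression episodes, found %d", n_ep)
  }
  episodes <- lapply(seq_len(n_ep), function(k) {
    i0 <- ep_idx[k, 1]; i1 <- ep_idx[k, 2]
    # refine onset/offset to the zero crossings just outside the run
    t_on <- zero_crossing(t, f, max(1, i0 - 1))
    t_off <- zero_crossing(t, f, i1)
    ipk <- i0 - 1 + which.max(f[i0:i1])
    tibble(start = t_on, peak = t[ipk], end = t_off,
           peak_force = f[ipk], i_start = i0, i_end = i1, i_peak = ipk)
  })
  episodes <- dplyr::bind_rows(episodes)
  # negative lobe between the two episodes
  mid <- which(t > episodes$end[1] & t < episodes$start[2] & f < 0)
  lobe <- NULL
  if (length(mid)) {
    i0 <- min(mid); i1 <- max(mid)
    lobe <- list(start = zero_crossing(t, f, max(1, i0 - 1)),
                 end = zero_crossing(t, f, i1),
                 i_start = i0, i_end = i1)
  }
  list(episodes = episodes, lobe = lobe)
}

#' Construct/validate a TPA parameter profile
#'
#' @param hardness_n peak force of the first compression, N (> 0).
#' @param cohesiveness ratio of force-time areas A2/A1 (> 0).
#' @param adhesiveness_mj detachment work of the negative lobe, mJ (>= 0).
#' @param elasticity ratio of compression travels D2/D1 (> 0).
#' @param adhesion_force_n minimum (most negative) force, N (<= 0).
#' @return a `tpa_profile` list.
#' @export
tpa_profile <- function(hardness_n, cohesiveness, adhesiveness_mj,
                        elasticity, adhesion_force_n) {
  check_number(hardness_n, "hardness_n", positive = TRUE)
  check_number(cohesiveness, "cohesiveness", positive = TRUE)
  check_number(adhesiveness_mj, "adhesiveness_mj", nonneg = TRUE)
  check_number(elasticity, "elasticity", positive = TRUE)
  check_number(adhesion_force_n, "adhesion_force_n")
  if (adhesion_force_n > 0) stop_input("adhesion_force_n must be <= 0")
  structure(list(hardness_n = hardness_n, cohesiveness = cohesiveness,
                 adhesiveness_mj = adhesiveness_mj, elasticity = elasticity,
                 adhesion_force_n = adhesion_force_n),
            class = "tpa_profile")
}

#' @export
print.tpa_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "TPA profile: hardness %.3f N, cohesiveness %.3f, adhesiveness %.3f mJ,\n",
    "             elasticity %.3f, adhesion force %.3f N\n"),
    x$hardness_n, x$cohesiveness, x$adhesiveness_mj, x$elasticity,
    x$adhesion_force_n))
  invisible(x)
}

#' Extract the five TPA parameters from a force-time trace
#'
#' Hardness is the peak force of the first compression episode. A1 and A2 are
#' the positive-force time integrals of episodes 1 and 2; cohesiveness is
#' A2/A1. D1 and D2 are the probe travels during the compression (rising)
#' phase of each episode, computed as descent speed times compression
#' duration; elasticity is D2/D1. Adhesion force is the global force minimum.
#' Adhesiveness is the magnitude of the work done over the negative lobe
#' after the first episode, with displacement reconstructed as ascent speed
#' times time, reported in mJ (N·mm).
#'
#' @param trace a [tpa_trace()].
#' @param debounce passed to [segment_cycles()].
#' @return a [tpa_profile()] with extra attributes `a1`, `a2` (N·s), `d1`,
#'   `d2` (mm).
#' @export
extract_tpa <- function(trace, debounce = 3) {
  seg <- segment_cycles(trace, debounce = debounce)
  t <- trace$time_s; f <- trace$force_n
  ep <- seg$episodes
  v_down <- attr(trace, "descent_speed_mm_s")
  v_up <- attr(trace, "ascent_speed_mm_s")

  episode_area <- function(k) {
    i0 <- ep$i_start[k]; i1 <- ep$i_end[k]
    # integrate from the refined onset (F = 0) to the refined offset
    xs <- c(ep$start[k], t[i0:i1], ep$end[k])
    ys <- c(0, pmax(f[i0:i1], 0), 0)
    trapz(xs, ys)
  }
  a1 <- episode_area(1)
  a2 <- episode_area(2)
  if (a1 <= 0) stop_input("first-episode area is zero; cohesiveness undefined")
  d1 <- v_down * (ep$peak[1] - ep$start[1])
  d2 <- v_down * (ep$peak[2] - ep$start[2])
  adhesion_force <- min(min(f), 0)
  if (is.null(seg$lobe)) {
    if (any(f < -attr(trace, "trigger_force_n"))) {
      warn("negative forces outside the inter-episode window were ignored")
    } else {
      warn("no negative lobe found; adhesiveness set to 0")
    }
    adhesiveness <- 0
  } else {
    i0 <- seg$lobe$i_start; i1 <- seg$lobe$i_end
    xs <- c(seg$lobe$start, t[i0:i1], seg$lobe$end)
    ys <- c(0, pmin(f[i0:i1], 0), 0)
    adhesiveness <- abs(trapz(xs, ys)) * v_up # N.s * mm/s = N.mm = mJ
  }
  out <- tpa_profile(hardness_n = ep$peak_force[1],
                     cohesiveness = a2 / a1,
                     adhesiveness_mj = adhesiveness,
                     elasticity = d2 / d1,
                     adhesion_force_n = adhesion_force)
  attr(out, "a1") <- a1; attr(out, "a2") <- a2
  attr(out, "d1") <- d1; attr(out, "d2") <- d2
  out
}

#' Tensile strength of an ointment cylinder
#'
#' Force per probe cross-section, `F/A`, in Pa.
#'
#' @param force_n applied force, N.
#' @param area_m2 cross-sectional area, m2.
#' @export
tensile_strength <- function(force_n, area_m2) {
  check_number(force_n, "force_n", positive = TRUE)
  check_number(area_m2, "area_m2", positive = TRUE)
  force_n / area_m2
}

#' Young's modulus from force and relative deformation
#'
#' `(F/A) / (dl/l)`: stress over strain, in Pa. Reduces to the tensile
#' strength at unit strain.
#'
#' @param force_n applied force, N.
#' @param area_m2 cross-sectional area, m2.
#' @param delta_l_m length deformation, m.
#' @param l_m original sample length, m.
#' @export
youngs_modulus <- function(force_n, area_m2, delta_l_m, l_m) {
  check_number(delta_l_m, "delta_l_m", positive = TRUE)
  check_number(l_m, "l_m", positive = TRUE)
  if (delta_l_m > l_m) stop_input("delta_l_m must not exceed l_m")
  tensile_strength(force_n, area_m2) / (delta_l_m / l_m)
}

#' Fold-changes of texture parameters against a reference formulation
#'
#' @param profiles tibble with `formulation_id` and the five parameter
#'   columns (`hardness_n`, `cohesiveness`, `adhesiveness_mj`, `elasticity`,
#'   `adhesion_force_n`), e.g. [reference_texture()] or rows built from
#'   [extract_tpa()] results.
#' @param reference formulation_id of the denominator.
#' @return long tibble: `formulation_id`, `parameter`, `value`, `reference`,
#'   `ratio` (value/reference, NA when the reference is 0) and `pct_change`.
#' @export
texture_ratios <- function(profiles, reference) {
  profiles <- as_tibble(profiles)
  params <- c("hardness_n", "cohesiveness", "adhesiveness_mj", "elasticity",
              "adhesion_force_n")
  if (!all(c("formulation_id", params) %in% names(profiles))) {
    stop_input("profiles must contain formulation_id and the five TPA columns")
  }
  if (!reference %in% profiles$formulation_id) {
    stop_input("reference formulation '%s' not present", reference)
  }
  long <- tidyr::pivot_longer(profiles[, c("formulation_id", params)],
                              dplyr::all_of(params),
                              names_to = "parameter", values_to = "value")
  ref <- long[long$formulation_id == reference, c("parameter", "value")]
  names(ref)[2] <- "reference"
  out <- dplyr::left_join(long, ref, by = "parameter")
  out$ratio <- ifelse(out$reference == 0, NA_real_, out$value / out$reference)
  out$pct_change <- 100 * (out$ratio - 1)
  out
}
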