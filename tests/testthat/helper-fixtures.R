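# shared fixture builders

profile_from_ref <- function(ref_row) {
  tpa_profile(ref_row$hardness_n, ref_row$cohesiveness, ref_row$adhesiveness_mj,
              ref_row$elasticity, ref_row$adhesion_force_n)
}

profile_as_vector <- function(p) {
  c(hardness_n = p$hardness_n, cohesiveness = p$cohesiveness,
    adhesiveness_mj = p$adhesiveness_mj, elasticity = p$elasticity,
    adhesion_force_n = p$adhesion_force_n)
}

# independent least-squares oracle: normal equations, no lm
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# piecewise-linear two-episode trace built by hand from (time, force) nodes
manual_trace <- function(nodes, dt = 0.05, ...) {
  grid <- sort(unique(c(seq(0, max(nodes$t), by = dt), nodes$t)))
  tpa_trace(tibble::tibble(time_s = grid,
                           force_n = approx(nodes$t, nodes$f, xout = grid)$y),
            ...)
}
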