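# Independent brute-force oracles used across test files.

# GLCM by direct double-loop pair enumeration (quantized input).
glcm_bruteforce <- function(q, dx, dy, n_levels) {
  # dx displaces samples (columns), dy lines (rows)
  nr <- nrow(q); nc <- ncol(q)
  Q <- matrix(0, n_levels, n_levels)
  for (l in seq_len(nr - dy)) for (s in seq_len(nc - dx)) {
    Q[q[l, s] + 1, q[l + dy, s + dx] + 1] <-
      Q[q[l, s] + 1, q[l + dy, s + dx] + 1] + 1
  }
  Q / ((nr - dy) * (nc - dx))
}

# Trapezoidal integral on a grid.
trapz_num <- function(grid, values) {
  sum(diff(grid) * (head(values, -1) + tail(values, -1)) / 2)
}

# Exhaustive evaluation of the local-region acceptance condition, written
# directly from the rule: N_k = k nearest neighbours of the centre by
# appearance distance (ties: spatial distance, then index); accept the
# full neighbourhood iff every x in R_L has max_y d(x, N_k) <= min_z
# d(x, N_c).
select_local_region_bruteforce <- function(v, features, spec) {
  d <- features$dim
  app <- features$features[, c("intensity", "asm_level"), drop = FALSE] *
    rep(c(1, 0.5), each = nrow(features$features))
  pos <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2])))
  v_lin <- (v[2] - 1) * d[1] + v[1]
  keep <- which((pos[, 1] - v[1])^2 + (pos[, 2] - v[2])^2 <= spec$r^2 &
                  !(pos[, 1] == v[1] & pos[, 2] == v[2]))
  rl <- as.integer((pos[keep, 2] - 1) * d[1] + pos[keep, 1])
  dist_c <- sqrt(rowSums((app[rl, , drop = FALSE] -
                            rep(app[v_lin, ], each = length(rl)))^2))
  sp2 <- (pos[keep, 1] - v[1])^2 + (pos[keep, 2] - v[2])^2
  ord <- order(dist_c, sp2, rl)
  if (spec$k >= length(rl))
    return(list(idx = c(v_lin, rl), accepted_full = TRUE))
  nk <- rl[ord[seq_len(spec$k)]]
  nc <- rl[ord[(spec$k + 1):length(rl)]]
  ok <- TRUE
  for (x in c(v_lin, rl)) {
    dx_all <- sqrt(colSums((t(app[c(nk, nc), , drop = FALSE]) -
                              app[x, ])^2))
    dk <- dx_all[seq_along(nk)]; dc <- dx_all[-seq_along(nk)]
    if (max(dk) > min(dc) + 1e-12) { ok <- FALSE; break }
  }
  if (ok) list(idx = c(v_lin, rl), accepted_full = TRUE)
  else list(idx = c(v_lin, nk), accepted_full = FALSE)
}
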