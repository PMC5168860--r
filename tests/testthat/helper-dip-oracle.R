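# Independent dip oracle: solve the definitional minimisation
#   dip = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|
# as a set of small linear programmes (boot::simplex), one per mode placement.
# A unimodal CDF is convex left of its mode, concave right of it, and may carry
# an atom only at the mode.  Mode placements: inside a segment between adjacent
# unique values (where the modal chord must be at least as steep as the flatter
# neighbouring slope -- a disjunction, solved as two LP branches), or at a knot
# (where G may jump: left limit `a` tested against the upper ECDF anchor A_j,
# value g_j against the lower anchor B_j).  Slope comparisons are written in
# cross-multiplied form so near-duplicate values stay well conditioned.
dip_lp_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  u <- unique(x)
  m <- length(u)
  if (m == 1L) return(0)
  Fj <- cumsum(tabulate(match(x, u), m)) / n
  A <- c(0, Fj[-m])   # upper anchors
  B <- Fj             # lower anchors
  du <- diff(u)
  best <- Inf

  run_lp <- function(obj, A1, b1, A2, b2) {
    sol <- tryCatch(
      boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2, maxi = FALSE),
      error = function(e) NULL)
    if (!is.null(sol) && sol$solved == 1) sol$value else Inf
  }
  norm_row <- function(r) { mx <- max(abs(r)); if (mx > 0) r / mx else r }

  # slope difference row: s(j1) - s(j2), cross-multiplied by du_{j1} du_{j2}.
  # Slope j is (var[top_j] - var[bot_j]) / du_j; tops/bots are variable indices.
  slope_diff <- function(nv, j1, top1, bot1, j2, top2, bot2) {
    r <- numeric(nv)
    r[top1] <- r[top1] + du[j2]; r[bot1] <- r[bot1] - du[j2]
    r[top2] <- r[top2] - du[j1]; r[bot2] <- r[bot2] + du[j1]
    r
  }

  solve_seg <- function(q, branch) {
    nv <- m + 1L                       # g_1..g_m, d
    obj <- c(rep(0, m), 1)
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    le <- function(row, rhs) { A1 <<- rbind(A1, norm_row(row)); b1 <<- c(b1, rhs) }
    ge <- function(row, rhs) { A2 <<- rbind(A2, norm_row(row)); b2 <<- c(b2, rhs) }
    for (j in seq_len(m)) {
      r <- numeric(nv); r[j] <- 1; r[nv] <- -1; le(r, A[j])   # g_j - d <= A_j
      r <- numeric(nv); r[j] <- 1; r[nv] <- 1;  ge(r, B[j])   # g_j + d >= B_j
    }
    for (j in seq_len(m - 1L)) { r <- numeric(nv); r[j + 1] <- 1; r[j] <- -1; ge(r, 0) }
    sd <- function(j1, j2) slope_diff(nv, j1, j1 + 1L, j1, j2, j2 + 1L, j2)
    if (q >= 3L) for (j in 1:(q - 2L)) le(sd(j, j + 1L), 0)            # convex side
    if (q <= m - 3L) for (j in (q + 1L):(m - 2L)) ge(sd(j, j + 1L), 0) # concave side
    if (branch == "L" && q >= 2L) le(sd(q - 1L, q), 0)                 # s_{q-1} <= s_q
    if (branch == "R" && q <= m - 2L) ge(sd(q, q + 1L), 0)             # s_q >= s_{q+1}
    run_lp(obj, A1, b1, A2, b2)
  }

  solve_atom <- function(j) {
    has_a <- j > 1L
    nv <- m + 1L + as.integer(has_a)   # g_1..g_m, d, [a]
    ai <- nv; di <- m + 1L
    obj <- numeric(nv); obj[di] <- 1
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    le <- function(row, rhs) { A1 <<- rbind(A1, norm_row(row)); b1 <<- c(b1, rhs) }
    ge <- function(row, rhs) { A2 <<- rbind(A2, norm_row(row)); b2 <<- c(b2, rhs) }
    for (i in seq_len(m)) {
      ub <- if (i == j) B[i] else A[i]   # at the mode the value is tested vs B_j
      r <- numeric(nv); r[i] <- 1; r[di] <- -1; le(r, ub)
      r <- numeric(nv); r[i] <- 1; r[di] <- 1;  ge(r, B[i])
    }
    if (has_a) {
      r <- numeric(nv); r[ai] <- 1; r[di] <- -1; le(r, A[j])   # a <= A_j + d
      r <- numeric(nv); r[ai] <- 1; r[di] <- 1;  ge(r, A[j])   # a >= A_j - d
      r <- numeric(nv); r[ai] <- 1; r[j - 1L] <- -1; ge(r, 0)  # a >= g_{j-1}
      r <- numeric(nv); r[j] <- 1; r[ai] <- -1; ge(r, 0)       # g_j >= a
    }
    for (i in seq_len(m - 1L)) {
      if (i == j - 1L) next   # replaced by the a-monotonicity rows above
      r <- numeric(nv); r[i + 1] <- 1; r[i] <- -1; ge(r, 0)
    }
    # left chain: s_1 <= ... <= s_{j-2} <= (a - g_{j-1})/du_{j-1}
    if (has_a && j >= 3L) {
      le(slope_diff(nv, j - 2L, j - 1L, j - 2L, j - 1L, ai, j - 1L), 0)
      if (j >= 4L) for (i in 1:(j - 3L))
        le(slope_diff(nv, i, i + 1L, i, i + 1L, i + 2L, i + 1L), 0)
    }
    # right chain: (g_{j+1} - g_j)/du_j >= s_{j+1} >= ... >= s_{m-1}
    if (j <= m - 2L) {
      ge(slope_diff(nv, j, j + 1L, j, j + 1L, j + 2L, j + 1L), 0)
      if (j <= m - 3L) for (i in (j + 1L):(m - 2L))
        ge(slope_diff(nv, i, i + 1L, i, i + 1L, i + 2L, i + 1L), 0)
    }
    run_lp(obj, A1, b1, A2, b2)
  }

  for (q in seq_len(m - 1L)) {
    if (q == 1L || q == m - 1L) {
      best <- min(best, solve_seg(q, "none"))
    } else {
      best <- min(best, solve_seg(q, "L"), solve_seg(q, "R"))
    }
  }
  for (j in seq_len(m)) best <- min(best, solve_atom(j))
  best
}
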