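# Independent oracles and fixture builders used across the suite.

# Exhaustive oracle for the step-fitting objective
#   sum (y - x)^2 + lambda * sum |x_{i+1} - x_i|
# Enumerates every segmentation and every jump-sign pattern; for a fixed
# segmentation and signs the problem is an unconstrained quadratic whose
# block means have the closed form m_b = ybar_b + lambda (s_b - s_{b-1}) /
# (2 w_b) (s_0 = s_B = 0). A candidate is kept only if the implied jumps
# carry the assumed signs; the global optimum is always among the
# consistent candidates (KKT at the optimum).
tv_exhaustive <- function(y, lam) {
  n <- length(y)
  if (lam == 0) return(list(x = y, obj = 0))
  best <- list(obj = Inf, x = y)
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    B <- length(bounds) - 1
    w <- diff(bounds)
    ybar <- vapply(seq_len(B), function(b)
      mean(y[(bounds[b] + 1):bounds[b + 1]]), numeric(1))
    signsets <- if (B == 1) list(integer(0)) else
      lapply(0:(2^(B - 1) - 1), function(m)
        2 * (bitwAnd(m, 2^(0:(B - 2))) > 0) - 1)
    for (s in signsets) {
      ds <- c(s, 0) - c(0, s)
      m <- ybar + lam * ds / (2 * w)
      jumps <- diff(m)
      if (B > 1 && any(sign(jumps) != s)) next
      x <- rep(m, w)
      obj <- sum((y - x)^2) + lam * sum(abs(jumps))
      if (obj < best$obj) best <- list(obj = obj, x = x)
    }
  }
  best
}

# Second independent route: the dual box-constrained QP
#   min_z 0.5 || y - D^T z ||^2  s.t.  |z| <= lambda / 2,  x = y - D^T z
# solved by L-BFGS-B; scales to lengths the exhaustive oracle cannot reach.
tv_dual_qp <- function(y, lam) {
  n <- length(y)
  if (n == 1 || lam == 0) return(y)
  Dt <- function(z) c(-z[1], -diff(z), z[n - 1])
  obj <- function(z) { r <- y - Dt(z); 0.5 * sum(r^2) }
  gr <- function(z) -diff(y - Dt(z))
  o <- stats::optim(rep(0, n - 1), obj, gr, method = "L-BFGS-B",
                    lower = -lam / 2, upper = lam / 2,
                    control = list(maxit = 5000, factr = 1e1))
  y - Dt(o$par)
}

tv_obj_plain <- function(y, x, lam) sum((y - x)^2) + lam * sum(abs(diff(x)))

# Four canonical conditions (assisting/opposing x GreA-/GreA+) for one
# roadblock, with pause samples drawn from the given regime's parameters
# and the experimental 20 s threshold applied to uncensored durations.
make_obs_4cond <- function(regime, seed, n = 200, rb = "LacI-O1",
                           obs_window = 3600) {
  p <- regime_example_params(regime)
  conds <- list(
    amin  = condition(rb, "assisting", 0.2, grea_uM = 0),
    aplus = condition(rb, "assisting", 0.2, grea_uM = 10),
    omin  = condition(rb, "opposing", 0.2, grea_uM = 0),
    oplus = condition(rb, "opposing", 0.2, grea_uM = 10))
  obs <- list()
  for (nm in names(conds)) {
    cc <- conds[[nm]]
    k1 <- if (cc$force_direction == "assisting") 0 else p$k1
    k2 <- if (cc$grea_uM > 0) p$k2_plus else p$k2_basal
    kp <- kinetic_params(k1, k2, p$k3, p$p1)
    s <- generate_pause_sample(kp, n, obs_window,
                               seed = seed + match(nm, names(conds)))
    keep <- s$censored | s$durations >= 20
    obs[[nm]] <- pause_sample(s$durations[keep], s$censored[keep],
                              condition = cc, censor_time = obs_window)
  }
  obs
}

# One synthetic opposing-force trace plus the aligned position series and
# its ground truth, the standard round-trip fixture.
run_trace_pipeline <- function(seed, noise_sd = 2, a_true = 1,
                               params = kinetic_params(0, 0.01, 0.01, 0),
                               gen_args = list()) {
  geom <- template_geometry(direction = "opposing")
  cond <- condition("LacI-O1", "opposing", 0.2)
  gen <- do.call(trace_gen_config,
                 c(list(noise_sd = noise_sd, a_true = a_true, seed = seed),
                   gen_args))
  tr <- generate_trace(geom, cond, gen, params)
  st <- fit_steps(tr$extension_nm, default_lambda(tr$extension_nm))
  lm_nm <- -1 * gen$nm_per_bp *
    c(geom$promoter_pos, geom$operator_pos, geom$terminator_pos)
  al <- optimize_scale(dwell_histogram(st), lm_nm, window = 20)
  pos <- apply_scale(st, al, nm_per_bp = gen$nm_per_bp,
                     direction = "opposing")
  list(trace = tr, stepped = st, alignment = al, positions = pos,
       geometry = geom, truth = tr$meta$truth$roadblock_pause)
}
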