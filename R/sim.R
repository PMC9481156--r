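## Agent-based simulator of a homeostatic cell layer.
##
## Cells are points in an L x L periodic box obeying overdamped, noiseless
## dynamics driven by a short-range harmonic repulsion (spring constant K,
## interaction length l), integrated by the Euler method with step dt.
## Stochastic fate rules implant a coordination between delamination
## (instantaneous particle removal) and division (duplication at a small
## offset d): uncommitted cells commit spontaneously at rate lambda and fire
## after a uniform remaining lifetime; at the moment an event fires, one
## uncommitted cell among the six nearest neighbors is committed to the
## complementary fate with a longer uniform lifetime, encoding
## delamination-induced division, division-induced delamination, or an
## equal mixture.

#' Simulator configuration
#'
#' Defaults are the homeostatic-epidermis study conditions: `K` = 9/h,
#' `l` = 0.125, `L` = 1, `dt` = 1.2 h, daughter offset `d` = 0.001 L,
#' spontaneous remaining lifetime U(32.4, 39.6) h, induced remaining
#' lifetime U(44.4, 51.6) h, 100 mechanics-only relaxation steps, 300
#' burn-in and 300 production steps with frames sampled every 20 steps
#' (24 h), a 0.65 L central crop, and initial cell numbers 612 / 412 / 512
#' for the three coordination setups.
#'
#' @param setup One of `"del_induced_div"`, `"div_induced_del"`, `"mixed"`.
#' @param lambda_rate Spontaneous commitment rate per cell per hour. Leave
#'   `NULL` and use [calibrate_rate()] to match a target event fraction.
#' @param induction Fire the induced complementary commitment at each event
#'   (the coordination rule). `FALSE` gives an uncoordinated control in
#'   which spontaneous commitments are the only fate source.
#' @param N0 Initial cell count; default depends on `setup`.
#' @param seed Integer seed; every stochastic element derives from it.
#' @param K,l,L,dt,d,spontaneous_lifetime,induced_lifetime,relax_steps,burnin_steps,production_steps,sample_stride,crop_fraction
#'   See description.
#' @return A `sim_config` list.
#' @export
sim_config <- function(setup = c("del_induced_div", "div_induced_del", "mixed"),
                       lambda_rate = NULL, N0 = NULL, seed = 1L,
                       K = 9, l = 0.125, L = 1, dt = 1.2, d = 0.001,
                       spontaneous_lifetime = c(32.4, 39.6),
                       induced_lifetime = c(44.4, 51.6),
                       relax_steps = 100L, burnin_steps = 300L,
                       production_steps = 300L, sample_stride = 20L,
                       crop_fraction = 0.65, induction = TRUE) {
  setup <- match.arg(setup)
  N0 <- N0 %||% switch(setup, del_induced_div = 612L, div_induced_del = 412L, mixed = 512L)
  stopifnot(K > 0, l > 0, L > 0, dt > 0, d > 0, crop_fraction > 0, crop_fraction <= 1,
            N0 >= 3)
  structure(list(setup = setup, lambda_rate = lambda_rate, N0 = as.integer(N0),
                 seed = as.integer(seed), K = K, l = l, L = L, dt = dt, d = d * L,
                 spontaneous_lifetime = spontaneous_lifetime,
                 induced_lifetime = induced_lifetime,
                 relax_steps = as.integer(relax_steps),
                 burnin_steps = as.integer(burnin_steps),
                 production_steps = as.integer(production_steps),
                 sample_stride = as.integer(sample_stride),
                 crop_fraction = crop_fraction, induction = isTRUE(induction)),
            class = "sim_config")
}

# Minimum-image displacement in a periodic box.
min_image <- function(dx, L) dx - L * round(dx / L)

#' Pairwise repulsive force
#'
#' Gradient of the truncated harmonic pair potential
#' `u = K/2 (|r| - l)^2` for `|r| < l`: the force on `a` is
#' `K (l - |r|)` directed away from `b`, zero at or beyond the cutoff.
#' Coincident points are pushed apart in a random direction.
#'
#' @param ra,rb Positions (length-2), periodic box.
#' @param config A [sim_config()].
#' @return The force on `a` (length-2); the force on `b` is its negative.
#' @export
pair_force <- function(ra, rb, config) {
  dx <- min_image(ra - rb, config$L)
  r <- sqrt(sum(dx^2))
  if (r >= config$l) return(c(0, 0))
  if (r == 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    dx <- c(cos(ang), sin(ang)); r <- 1
  }
  config$K * (config$l - r) * dx / r
}

# Total force on every particle, O(N^2) with the minimum-image convention.
force_field <- function(pos, config) {
  n <- nrow(pos)
  if (n < 2L) return(pos * 0)
  dx <- min_image(outer(pos[, 1], pos[, 1], "-"), config$L)
  dy <- min_image(outer(pos[, 2], pos[, 2], "-"), config$L)
  r2 <- dx * dx + dy * dy
  act <- r2 < config$l^2 & r2 > 0
  if (any(r2 == 0 & row(r2) != col(r2))) {
    z <- which(r2 == 0 & row(r2) != col(r2))
    ang <- stats::runif(length(z), 0, 2 * pi)
    dx[z] <- 1e-12 * cos(ang); dy[z] <- 1e-12 * sin(ang)
    r2[z] <- 1e-24
    act[z] <- TRUE
  }
  r <- sqrt(r2)
  f <- matrix(0, n, n)
  f[act] <- config$K * (config$l - r[act]) / r[act]
  cbind(rowSums(f * dx), rowSums(f * dy))
}

#' One Euler step of the overdamped dynamics
#'
#' A single literal explicit-Euler update `r <- r + dt * F(r)`. At the
#' default parameters this step is only stable for sparse configurations
#' (the pair relaxation rate is `2K`, and `K * dt` is large); [run_sim()]
#' therefore integrates the same flow with stability-limited substeps, see
#' [advance_flow()].
#'
#' @param pos N x 2 matrix of positions.
#' @param config A [sim_config()].
#' @return Updated positions, wrapped into `[0, L)`.
#' @export
euler_step <- function(pos, config) {
  (pos + config$dt * force_field(pos, config)) %% config$L
}

# Pair list with a skin margin; O(N^2) build, used for many substeps.
build_pairlist <- function(pos, cutoff, L) {
  dx <- min_image(outer(pos[, 1], pos[, 1], "-"), L)
  dy <- min_image(outer(pos[, 2], pos[, 2], "-"), L)
  d2 <- dx * dx + dy * dy
  sel <- which(d2 < cutoff^2 & upper.tri(d2))
  list(i = row(d2)[sel], j = col(d2)[sel])
}

# Forces restricted to a pair list; returns the force matrix and per-
# particle contact counts (for the per-particle stability bound).
pairlist_forces <- function(pos, pl, config) {
  n <- nrow(pos)
  F <- matrix(0, n, 2)
  if (!length(pl$i)) return(list(F = F, contacts = integer(n)))
  dx <- min_image(pos[pl$i, 1] - pos[pl$j, 1], config$L)
  dy <- min_image(pos[pl$i, 2] - pos[pl$j, 2], config$L)
  r2 <- dx * dx + dy * dy
  if (any(r2 == 0)) {
    z <- which(r2 == 0)
    ang <- stats::runif(length(z), 0, 2 * pi)
    dx[z] <- 1e-9 * cos(ang); dy[z] <- 1e-9 * sin(ang); r2[z] <- 1e-18
  }
  act <- which(r2 < config$l^2)
  if (!length(act)) return(list(F = F, contacts = integer(n)))
  r <- sqrt(r2[act])
  f <- config$K * (config$l - r) / r
  fx <- f * dx[act]; fy <- f * dy[act]
  g <- c(pl$i[act], pl$j[act])
  sx <- rowsum(c(fx, -fx), g); sy <- rowsum(c(fy, -fy), g)
  idx <- as.integer(rownames(sx))
  F[idx, 1] <- sx; F[idx, 2] <- sy
  list(F = F, contacts = tabulate(g, nbins = n))
}

#' Advance the overdamped flow by a time interval
#'
#' Integrates the noiseless equation of motion with explicit Euler substeps
#' whose per-particle step sizes respect the local stability bound (the
#' inverse of `K` times one plus the particle's contact count), exiting
#' early once the configuration is at mechanical equilibrium. Forces use a
#' neighbor pair list with a skin margin, rebuilt as particles move. In the
#' jammed steady state almost all particles sit at force balance, so the
#' cost concentrates around recent division/delamination sites.
#'
#' @param pos N x 2 position matrix.
#' @param config A [sim_config()].
#' @param t_total Time to advance (hours).
#' @param max_substeps Cost cap on substeps for this interval.
#' @return Updated positions.
#' @export
advance_flow <- function(pos, config, t_total, max_substeps = 18L) {
  skin <- 0.5 * config$l
  pl <- build_pairlist(pos, config$l + skin, config$L)
  acc <- 0
  t <- 0
  for (s in seq_len(max_substeps)) {
    ff <- pairlist_forces(pos, pl, config)
    vmax <- max(abs(ff$F))
    if (vmax < 1e-6) break
    h <- pmin(t_total - t, 0.4 / (config$K * (1 + ff$contacts)))
    pos <- (pos + h * ff$F) %% config$L
    t <- t + max(h)
    acc <- acc + max(h * pmax(abs(ff$F[, 1]), abs(ff$F[, 2])))
    if (acc > skin / 2) {
      pl <- build_pairlist(pos, config$l + skin, config$L)
      acc <- 0
    }
    if (t >= t_total - 1e-12) break
  }
  pos
}

# Six nearest cells (periodic metric) of a position among `pos`, excluding
# `excl` row indices; ties broken by id order. Returns row indices sorted by
# distance.
six_nearest <- function(p, pos, ids, L, excl = integer(0)) {
  dx <- min_image(pos[, 1] - p[1], L)
  dy <- min_image(pos[, 2] - p[2], L)
  d2 <- dx * dx + dy * dy
  d2[excl] <- Inf
  ord <- order(d2, ids)
  ord[seq_len(min(6L, sum(is.finite(d2[ord]))))]
}

#' Run the homeostasis simulation
#'
#' Random initial placement, `relax_steps` mechanics-only Euler steps, then
#' `burnin_steps` + `production_steps` steps with the stochastic fate rules
#' active. Frames (positions and ids) are sampled every `sample_stride`
#' steps of the production phase; lineage and event logs are complete.
#'
#' @param config A [sim_config()] with `lambda_rate` set.
#' @return A `sim_traj`: sampled `frames`, `events`, `lineage`, per-step
#'   population `pop`, event `counts`, and the `config`.
#' @export
run_sim <- function(config, init_pos = NULL) {
  if (is.null(config$lambda_rate)) stop("lambda_rate not set; run calibrate_rate() first")
  lam <- config$lambda_rate
  if (lam * config$dt >= 1) stop("lambda * dt >= 1: commitment probability per step is not valid")
  set.seed(config$seed)
  L <- config$L
  if (is.null(init_pos)) {
    pos <- matrix(stats::runif(2 * config$N0, 0, L), ncol = 2)
    for (s in seq_len(config$relax_steps)) pos <- advance_flow(pos, config, config$dt)
  } else {
    stopifnot(nrow(init_pos) == config$N0)
    pos <- init_pos
  }

  ids <- seq_len(config$N0)
  next_id <- config$N0 + 1L
  committed <- integer(config$N0)          # 0 none, 1 div, 2 del
  t_event <- rep(NA_real_, config$N0)
  ev_time <- ev_type <- ev_cell <- ev_partner <- list()
  li_time <- li_parent <- li_d1 <- li_d2 <- list()
  frames <- list()
  pop <- integer(config$burnin_steps + config$production_steps)
  n_div <- n_del <- 0L
  n_div_prod <- n_del_prod <- 0L
  unc_steps <- 0; n_spont <- 0L

  commit <- function(i, fate, life0, t_now) {
    committed[i] <<- fate
    t_event[i] <<- t_now + stats::runif(1, life0[1], life0[2])
  }

  total_steps <- config$burnin_steps + config$production_steps
  for (s in seq_len(total_steps)) {
    t_now <- (s - 1L) * config$dt
    in_prod <- s > config$burnin_steps

    ## spontaneous commitments among uncommitted cells
    unc <- which(committed == 0L)
    unc_steps <- unc_steps + length(unc)
    if (length(unc)) {
      hit <- unc[stats::runif(length(unc)) < lam * config$dt]
      n_spont <- n_spont + length(hit)
      for (i in hit) {
        fate <- switch(config$setup,
                       del_induced_div = 2L,
                       div_induced_del = 1L,
                       mixed = if (stats::runif(1) < 0.5) 1L else 2L)
        commit(i, fate, config$spontaneous_lifetime, t_now)
      }
    }

    ## fire events due within this step, in time order
    repeat {
      due <- which(!is.na(t_event) & t_event <= s * config$dt)
      if (!length(due)) break
      i <- due[which.min(t_event[due])]
      te <- t_event[i]
      kind <- committed[i]
      if (kind == 1L) {                     # division
        ang <- stats::runif(1, 0, 2 * pi)
        rr <- config$d * sqrt(stats::runif(1))
        newp <- (pos[i, ] + rr * c(cos(ang), sin(ang))) %% L
        partner_pool <- six_nearest(pos[i, ], pos, ids, L, excl = i)
        did <- next_id; next_id <- next_id + 1L
        li_time[[length(li_time) + 1L]] <- te
        li_parent[[length(li_parent) + 1L]] <- ids[i]
        li_d1[[length(li_d1) + 1L]] <- ids[i]
        li_d2[[length(li_d2) + 1L]] <- did
        pos <- rbind(pos, newp)
        ids <- c(ids, did)
        committed <- c(committed, 0L)
        t_event <- c(t_event, NA_real_)
        committed[i] <- 0L; t_event[i] <- NA_real_
        n_div <- n_div + 1L
        if (in_prod) n_div_prod <- n_div_prod + 1L
        partner <- NA_integer_
        if (config$induction && config$setup != "del_induced_div") {
          cand <- partner_pool[committed[partner_pool] == 0L]
          partner <- if (length(cand)) cand[sample.int(length(cand), 1L)] else NA_integer_
          if (!is.na(partner)) commit(partner, 2L, config$induced_lifetime, te)
        }
        ev_time[[length(ev_time) + 1L]] <- te
        ev_type[[length(ev_type) + 1L]] <- "div"
        ev_cell[[length(ev_cell) + 1L]] <- ids[i]
        ev_partner[[length(ev_partner) + 1L]] <- if (is.na(partner)) NA_integer_ else ids[partner]
      } else {                              # delamination
        p <- pos[i, ]
        cid <- ids[i]
        pos <- pos[-i, , drop = FALSE]
        ids <- ids[-i]
        committed <- committed[-i]
        t_event <- t_event[-i]
        n_del <- n_del + 1L
        if (in_prod) n_del_prod <- n_del_prod + 1L
        partner <- NA_integer_
        if (config$induction && config$setup != "div_induced_del") {
          pool <- six_nearest(p, pos, ids, L)
          cand <- pool[committed[pool] == 0L]
          partner <- if (length(cand)) cand[sample.int(length(cand), 1L)] else NA_integer_
          if (!is.na(partner)) commit(partner, 1L, config$induced_lifetime, te)
        }
        ev_time[[length(ev_time) + 1L]] <- te
        ev_type[[length(ev_type) + 1L]] <- "del"
        ev_cell[[length(ev_cell) + 1L]] <- cid
        ev_partner[[length(ev_partner) + 1L]] <- if (is.na(partner)) NA_integer_ else ids[partner]
      }
      if (nrow(pos) == 0L) stop("population reached zero; lambda too high for this configuration")
    }

    pos <- advance_flow(pos, config, config$dt)
    pop[s] <- nrow(pos)
    if (in_prod && (s - config$burnin_steps) %% config$sample_stride == 0L) {
      frames[[length(frames) + 1L]] <- list(ids = ids, pos = pos, time = s * config$dt)
    }
  }

  structure(list(
    frames = frames,
    events = data.table::data.table(time = unlist(ev_time), type = unlist(ev_type),
                                    cell = unlist(ev_cell), partner = unlist(ev_partner)),
    lineage = data.table::data.table(time = unlist(li_time), parent = unlist(li_parent),
                                     d1 = unlist(li_d1), d2 = unlist(li_d2)),
    pop = pop, counts = c(div = n_div, del = n_del),
    counts_production = c(div = n_div_prod, del = n_del_prod),
    spontaneous = c(draws = unc_steps, commits = n_spont),
    config = config
  ), class = "sim_traj")
}

#' @export
print.sim_traj <- function(x, ...) {
  cat(sprintf("Homeostasis simulation (%s): %d sampled frames, mean population %.1f, %d divisions / %d delaminations\n",
              x$config$setup, length(x$frames),
              mean(vapply(x$frames, function(f) length(f$ids), 0)),
              x$counts["div"], x$counts["del"]))
  invisible(x)
}

# Event fraction per fate per 24 h frame measured on a (possibly shortened)
# run: production events of each fate divided by mean population and the
# number of 24 h intervals.
measure_event_fraction <- function(config, lambda, init_pos = NULL) {
  cfg <- config
  cfg$lambda_rate <- lambda
  tr <- run_sim(cfg, init_pos = init_pos)
  n_intervals <- cfg$production_steps * cfg$dt / 24
  mean_pop <- mean(tr$pop[(cfg$burnin_steps + 1):length(tr$pop)])
  mean(tr$counts_production / (mean_pop * n_intervals))
}

#' Calibrate the spontaneous commitment rate
#'
#' Finds `lambda` such that the fraction of cells undergoing each fate per
#' 24 h frame matches `target` within 10% (relative), on shortened pilot
#' runs that share one pre-relaxed initial configuration. The event
#' fraction grows monotonically with `lambda` (approximately
#' `24 lambda / (1 + lambda (T_spont + T_induced))` from the committed-pool
#' balance), so a proportional fixed-point update with a bisection-style
#' bracket converges in a few pilot evaluations.
#'
#' @param config A [sim_config()].
#' @param target Target per-fate event fraction per frame, in (0, 0.5);
#'   default 0.07.
#' @param pilot_burnin,pilot_production Pilot run lengths (steps).
#' @return The calibrated `lambda` (per cell per hour), with the measured
#'   pilot fraction as attribute `"fraction"`.
#' @export
calibrate_rate <- function(config, target = 0.07,
                           pilot_burnin = 150L, pilot_production = 150L) {
  if (!(target > 0 && target < 0.5)) stop("target event fraction must be in (0, 0.5)")
  pilot <- config
  pilot$burnin_steps <- as.integer(pilot_burnin)
  pilot$production_steps <- as.integer(pilot_production)
  ## one shared relaxed initial configuration for all pilot runs
  set.seed(config$seed)
  pos0 <- matrix(stats::runif(2 * config$N0, 0, config$L), ncol = 2)
  for (s in seq_len(config$relax_steps)) pos0 <- advance_flow(pos0, config, config$dt)

  Tmean <- mean(config$spontaneous_lifetime) + mean(config$induced_lifetime)
  lam <- target / (24 - Tmean * target)    # committed-pool balance seed
  lo <- 0; hi <- Inf
  for (it in seq_len(20L)) {
    f <- measure_event_fraction(pilot, lam, init_pos = pos0)
    if (abs(f - target) / target <= 0.1) {
      attr(lam, "fraction") <- f
      return(lam)
    }
    if (f < target) lo <- max(lo, lam) else hi <- min(hi, lam)
    lam2 <- lam * target / max(f, 1e-6)
    lam <- if (lam2 > lo && lam2 < hi) lam2 else
      if (is.finite(hi)) (lo + hi) / 2 else lam * 2
  }
  stop("calibration did not converge in 20 pilot iterations")
}
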