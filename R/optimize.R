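#' Particle-swarm configuration
#'
#' Global-best particle swarm with inertia damping. Amplitudes live in a
#' box (reflecting bounds); phases are circular (wrapped modulo 2 pi, with
#' attraction along the shortest angular difference). One channel's phase is
#' gauge-fixed to zero, since THQ is invariant under a global phase.
#'
#' @param particles swarm size.
#' @param iterations number of iterations.
#' @param inertia,cognitive,social PSO coefficients.
#' @param seed integer RNG seed; the search is deterministic given the seed.
#' @param amp_bounds amplitude box, default [0, 1] (scale of unit drive).
#' @param gauge_channel channel whose phase is fixed to zero.
#' @return list of class `swarm_config`.
#' @export
swarm_config <- function(particles = 50, iterations = 200,
                         inertia = 0.72, cognitive = 1.49, social = 1.49,
                         seed = 1L, amp_bounds = c(0, 1),
                         gauge_channel = 1L) {
  if (particles < 1 || iterations < 1) stop("counts must be positive")
  if (any(!is.finite(c(inertia, cognitive, social)))) {
    stop("coefficients must be finite")
  }
  if (diff(amp_bounds) <= 0) stop("amp_bounds must be ordered")
  structure(list(particles = particles, iterations = iterations,
                 inertia = inertia, cognitive = cognitive, social = social,
                 seed = as.integer(seed), amp_bounds = amp_bounds,
                 gauge_channel = as.integer(gauge_channel)),
            class = "swarm_config")
}

# Fast THQ evaluation context: per-channel field columns over body voxels.
thq_context <- function(fields, phantom, scheme,
                        table = default_tissue_table(),
                        hotspot_fraction = 0.01) {
  sr <- phantom_sigma_rho(phantom, scheme, table)
  body <- sr$body
  htv <- phantom$htv_mask & body
  if (!any(htv)) stop("HTV mask is empty")
  bidx <- which(body)
  comp_mats <- function(get) {
    vapply(fields$fields, function(f) get(f)[bidx],
           complex(length(bidx)))
  }
  mats <- if (fields$mode == "2d") {
    list(ez = comp_mats(function(f) f$ez))
  } else {
    list(ex = comp_mats(function(f) f$ex),
         ey = comp_mats(function(f) f$ey),
         ez = comp_mats(function(f) f$ez))
  }
  list(mats = mats, sigma = sr$sigma[bidx], rho = sr$rho[bidx],
       htv = htv[body], healthy = !htv[body],
       k_hot = ceiling(hotspot_fraction * sum(!htv[body])),
       n_channels = fields$n_channels)
}

thq_eval <- function(ctx, weights) {
  e2 <- 0
  for (m in ctx$mats) e2 <- e2 + Mod(m %*% weights)^2
  sar <- ctx$sigma * e2 / (2 * ctx$rho)
  num <- mean(sar[ctx$htv])
  den <- mean(sort(sar[ctx$healthy], decreasing = TRUE)[seq_len(ctx$k_hot)])
  if (den == 0) return(0)
  num / den
}

#' Optimize per-channel drive by particle swarm to maximize THQ
#'
#' Searches over per-channel amplitudes (box [0,1]) and phases (circular),
#' with the gauge channel's phase fixed to zero. The all-equal-weights drive
#' is injected as one initial particle, so the returned THQ never falls below
#' that baseline. The objective is exactly [compute_thq()] of the combined
#' field.
#'
#' @param fields a `channel_fields` object (unit-drive solves on the detailed
#'   benchmark).
#' @param phantom the phantom supplying HTV/body masks.
#' @param scheme segmentation scheme defining the SAR materials (use the
#'   detailed scheme for benchmark optimization).
#' @param config a [swarm_config()].
#' @param table a `tissue_table`.
#' @param hotspot_fraction healthy hotspot volume fraction (default 0.01).
#' @return list of class `drive_optimization`: `drive` ([drive_settings()]),
#'   `thq`, `trace` (data.frame iteration / best_thq), `config`.
#' @export
optimize_drive <- function(fields, phantom, scheme, config = swarm_config(),
                           table = default_tissue_table(),
                           hotspot_fraction = 0.01) {
  stopifnot(inherits(fields, "channel_fields"), inherits(config, "swarm_config"))
  nch <- fields$n_channels
  ctx <- thq_context(fields, phantom, scheme, table, hotspot_fraction)
  gauge <- config$gauge_channel
  if (gauge < 1 || gauge > nch) stop("gauge_channel out of range")

  nph <- nch - 1L           # free phases (gauge channel excluded)
  ndim <- nch + nph
  lo <- c(rep(config$amp_bounds[1], nch), rep(0, nph))
  hi <- c(rep(config$amp_bounds[2], nch), rep(2 * pi, nph))
  phase_dim <- if (nph > 0) (nch + 1):ndim else integer(0)

  to_weights <- function(p) {
    ph <- rep(0, nch)
    if (nph > 0) ph[-gauge] <- p[phase_dim]
    p[1:nch] * exp(1i * ph)
  }

  np <- config$particles
  res <- with_local_seed(config$seed, {
    pos <- matrix(runif(np * ndim, rep(lo, each = np), rep(hi, each = np)),
                  np, ndim)
    pos[1, ] <- c(rep(1, nch), rep(0, nph))  # equal-weights baseline particle
    vmax <- 0.5 * (hi - lo)
    vel <- matrix(runif(np * ndim, rep(-0.1 * (hi - lo), each = np),
                        rep(0.1 * (hi - lo), each = np)), np, ndim)

    fit <- apply(pos, 1, function(p) thq_eval(ctx, to_weights(p)))
    pbest <- pos; pbest_fit <- fit
    gi <- which.max(fit)
    gbest <- pos[gi, ]; gbest_fit <- fit[gi]
    trace <- numeric(config$iterations)

    wrap_diff <- function(d) (d + pi) %% (2 * pi) - pi

    for (it in seq_len(config$iterations)) {
      r1 <- matrix(runif(np * ndim), np, ndim)
      r2 <- matrix(runif(np * ndim), np, ndim)
      dp <- pbest - pos
      dg <- sweep(pos, 2, gbest, function(x, g) g - x)
      if (nph > 0) {
        dp[, phase_dim] <- wrap_diff(dp[, phase_dim])
        dg[, phase_dim] <- wrap_diff(dg[, phase_dim])
      }
      vel <- config$inertia * vel + config$cognitive * r1 * dp +
        config$social * r2 * dg
      vel <- pmin(pmax(vel, rep(-vmax, each = np)), rep(vmax, each = np))
      pos <- pos + vel
      # amplitudes: reflecting bounds; phases: wrap
      for (d in 1:nch) {
        below <- pos[, d] < lo[d]; above <- pos[, d] > hi[d]
        pos[below, d] <- 2 * lo[d] - pos[below, d]
        pos[above, d] <- 2 * hi[d] - pos[above, d]
        vel[below | above, d] <- -vel[below | above, d]
        pos[, d] <- pmin(pmax(pos[, d], lo[d]), hi[d])
      }
      if (nph > 0) pos[, phase_dim] <- pos[, phase_dim] %% (2 * pi)

      fit <- apply(pos, 1, function(p) thq_eval(ctx, to_weights(p)))
      imp <- fit > pbest_fit
      pbest[imp, ] <- pos[imp, , drop = FALSE]
      pbest_fit[imp] <- fit[imp]
      gi <- which.max(pbest_fit)
      if (pbest_fit[gi] > gbest_fit) {
        gbest_fit <- pbest_fit[gi]; gbest <- pbest[gi, ]
      }
      trace[it] <- gbest_fit
    }
    list(gbest = gbest, gbest_fit = gbest_fit, trace = trace)
  })

  amps <- res$gbest[1:nch]
  if (all(amps == 0)) {
    stop("optimization failed: best amplitude vector is all zero")
  }
  ph <- rep(0, nch)
  if (nph > 0) ph[-gauge] <- res$gbest[phase_dim]
  structure(list(
    drive = drive_settings(amps, ph),
    thq = res$gbest_fit,
    trace = data.frame(iteration = seq_along(res$trace),
                       best_thq = res$trace),
    config = config
  ), class = "drive_optimization")
}
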