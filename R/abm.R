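# Spatially explicit agent-based model of vulture foraging under spatially
# variable carcass poisoning.
#
# The landscape is a 200 x 200 km arena. A central circle of 20,000 km^2 is
# the focus region (Kruger or KZN); the exterior has the same area and is
# the other region. Protected habitat (Kruger) spawns carrion as
# Gamma-distributed carcass masses up to a 3,000 kg standing cap;
# non-protected habitat (KZN) as truncated-Normal masses up to 6,000 kg.
# Each new carcass is poisoned with probability 1/R of its habitat. Birds
# forage by correlated random walk, detect carcasses within 6 km (7 km when
# the carcass is large or occupied), remember yesterday's feeding site, and
# die instantly on landing at a poisoned carcass — the model's only source
# of mortality.

STAGES <- c("adult", "subadult", "juvenile")

#' Configuration of the foraging/poisoning agent-based model
#'
#' All distances are km, speeds km/h, masses kg, times days unless noted.
#' The defaults are the model's standard parameterization; `rate_protected`
#' and `rate_nonprotected` are the sensitivity-analysis dials: a rate R
#' means each carcass in that habitat is poisoned with probability 1/R
#' (use `Inf` to disable poisoning).
#'
#' @param focus which region the central circle represents: `"Kruger"`
#'   (protected centre) or `"KZN"` (non-protected centre).
#' @param rate_protected,rate_nonprotected poisoning rate R per habitat.
#' @param n_roosts number of roost patches scattered over the arena.
#' @param n_adults,n_subadults,n_juveniles initial birds per stage.
#' @param forage_speed,homing_speed flight speeds (km/h).
#' @param turn_angle random-walk turn per tick, degrees left or right.
#' @param vision,vision_enhanced carcass detection radii (km); the enhanced
#'   radius applies to occupied or large carcasses.
#' @param forage_hours daily foraging window (h); with `tick_mins`-minute
#'   ticks this gives the per-day step count.
#' @param tick_mins simulation tick length (minutes).
#' @param adult_release_day day after which adults abandon the colony and
#'   roost like juveniles.
#' @param days simulated days.
#' @param density_protected,density_nonprotected carrion density
#'   (kg km^-2); times the 20,000 km^2 region area this sets the standing
#'   caps (3,000 and 6,000 kg).
#' @param gamma_shape,gamma_rate protected-habitat carcass mass
#'   distribution, Gamma(shape, rate).
#' @param normal_mean,normal_sd non-protected carcass mass distribution,
#'   Normal truncated at 0.
#' @param large_threshold mass (kg) above which a carcass is "large":
#'   visible from the enhanced radius and persisting two days instead of
#'   one.
#' @param arena_half half-width of the square arena (km).
#' @param region_area area of the central circle (km^2).
#' @param colony_radius radius of the central colony circle (km).
#' @param forage_radius radius (km) confining pre-release adults.
#' @return object of class `abm_config`.
#' @export
abm_config <- function(focus = c("Kruger", "KZN"),
                       rate_protected = 1000,
                       rate_nonprotected = 100,
                       n_roosts = 10,
                       n_adults = 26, n_subadults = 13, n_juveniles = 13,
                       forage_speed = 24, homing_speed = 48,
                       turn_angle = 15,
                       vision = 6, vision_enhanced = 7,
                       forage_hours = 9, tick_mins = 10,
                       adult_release_day = 240,
                       days = 365,
                       density_protected = 0.15,
                       density_nonprotected = 0.3,
                       gamma_shape = 1.2, gamma_rate = 0.004,
                       normal_mean = 500, normal_sd = 100,
                       large_threshold = 1000,
                       arena_half = 100, region_area = 20000,
                       colony_radius = 8, forage_radius = 50) {
  focus <- match.arg(focus)
  cfg <- list(focus = focus, rate_protected = rate_protected,
              rate_nonprotected = rate_nonprotected, n_roosts = n_roosts,
              n_adults = n_adults, n_subadults = n_subadults,
              n_juveniles = n_juveniles, forage_speed = forage_speed,
              homing_speed = homing_speed, turn_angle = turn_angle,
              vision = vision, vision_enhanced = vision_enhanced,
              forage_hours = forage_hours, tick_mins = tick_mins,
              adult_release_day = adult_release_day, days = days,
              density_protected = density_protected,
              density_nonprotected = density_nonprotected,
              gamma_shape = gamma_shape, gamma_rate = gamma_rate,
              normal_mean = normal_mean, normal_sd = normal_sd,
              large_threshold = large_threshold, arena_half = arena_half,
              region_area = region_area, colony_radius = colony_radius,
              forage_radius = forage_radius)
  num <- unlist(cfg[-1])
  if (any(!is.na(num) & num < 0)) stop("negative configuration value")
  if (rate_protected <= 0 || rate_nonprotected <= 0) {
    stop("poisoning rates must be positive (Inf disables poisoning)")
  }
  if (n_roosts < 1) stop("need at least one roost")
  if (cfg$colony_radius > cfg$forage_radius ||
      cfg$forage_radius^2 * pi > cfg$region_area) {
    stop("need colony circle within foraging circle within the region")
  }
  cfg$region_radius <- sqrt(region_area / pi)
  cfg$cap_protected <- density_protected * region_area
  cfg$cap_nonprotected <- density_nonprotected * region_area
  cfg$ticks_per_day <- as.integer(round(forage_hours * 60 / tick_mins))
  cfg$step_km <- forage_speed * tick_mins / 60
  class(cfg) <- "abm_config"
  cfg
}

#' @export
print.abm_config <- function(x, ...) {
  cat("ABM configuration: focus", x$focus, "\n")
  cat(sprintf("  poisoning 1/%s (protected) vs 1/%s (non-protected), %d roosts\n",
              format(x$rate_protected), format(x$rate_nonprotected),
              x$n_roosts))
  cat(sprintf("  birds: %d adults, %d subadults, %d juveniles; %d days\n",
              x$n_adults, x$n_subadults, x$n_juveniles, x$days))
  invisible(x)
}

# habitat label ("protected"/"nonprotected") of points, given the focus
habitat_of <- function(x, y, cfg) {
  inside <- (x^2 + y^2) <= cfg$region_radius^2
  centre_protected <- cfg$focus == "Kruger"
  ifelse(inside == centre_protected, "protected", "nonprotected")
}

#' Draw carcass masses for a habitat
#'
#' Protected habitat uses Gamma(shape, rate) (heavy upper tail: occasional
#' elephant-sized carcasses); non-protected habitat uses a Normal truncated
#' at zero.
#'
#' @param n number of draws.
#' @param habitat `"protected"` or `"nonprotected"`.
#' @param cfg an [abm_config()].
#' @return numeric vector of masses (kg).
#' @export
draw_carcass_mass <- function(n, habitat, cfg = abm_config()) {
  habitat <- match.arg(habitat, c("protected", "nonprotected"))
  if (n == 0L) return(numeric(0))
  if (habitat == "protected") {
    stats::rgamma(n, shape = cfg$gamma_shape, rate = cfg$gamma_rate)
  } else {
    m <- stats::rnorm(n, cfg$normal_mean, cfg$normal_sd)
    while (any(m <= 0)) {
      m[m <= 0] <- stats::rnorm(sum(m <= 0), cfg$normal_mean, cfg$normal_sd)
    }
    m
  }
}

#' Probability that a protected-habitat carcass is large
#'
#' Upper tail P(X > threshold) of the protected-habitat Gamma mass
#' distribution, i.e. the chance of an elephant-sized (> 1000 kg) carcass.
#'
#' @param cfg an [abm_config()].
#' @param threshold mass cut-off (kg); defaults to the config's
#'   `large_threshold`.
#' @export
large_carcass_prob <- function(cfg = abm_config(),
                               threshold = cfg$large_threshold) {
  stats::pgamma(threshold, shape = cfg$gamma_shape, rate = cfg$gamma_rate,
                lower.tail = FALSE)
}

# uniform point draws
runif_circle <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}
runif_exterior <- function(n, cfg) {
  # uniform over the square minus the central circle (acceptance ~ 0.5)
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 8L)
    x <- stats::runif(m, -cfg$arena_half, cfg$arena_half)
    y <- stats::runif(m, -cfg$arena_half, cfg$arena_half)
    keep <- (x^2 + y^2) > cfg$region_radius^2
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Initialize the ABM world
#'
#' Places the roost patches uniformly over the arena, adults uniformly in
#' the 8-km colony circle, subadults and juveniles uniformly over the whole
#' arena, and seeds day-1 carcasses. Consumes the current RNG stream;
#' [run_abm_year()] seeds it.
#'
#' @param cfg an [abm_config()].
#' @return list of class `abm_world` with agent vectors, roosts, carcass
#'   state and the config.
#' @export
init_world <- function(cfg = abm_config()) {
  stopifnot(inherits(cfg, "abm_config"))
  roosts <- cbind(x = stats::runif(cfg$n_roosts, -cfg$arena_half,
                                   cfg$arena_half),
                  y = stats::runif(cfg$n_roosts, -cfg$arena_half,
                                   cfg$arena_half))
  nA <- cfg$n_adults; nS <- cfg$n_subadults; nJ <- cfg$n_juveniles
  n <- nA + nS + nJ
  stage <- factor(rep(STAGES, c(nA, nS, nJ)), levels = STAGES)
  posA <- runif_circle(nA, cfg$colony_radius)
  posR <- cbind(stats::runif(nS + nJ, -cfg$arena_half, cfg$arena_half),
                stats::runif(nS + nJ, -cfg$arena_half, cfg$arena_half))
  x <- c(posA[, 1], posR[, 1]); y <- c(posA[, 2], posR[, 2])
  # colony anchor: adults return to their own colony point; subadults
  # prospect at a colony point of their own
  colony <- runif_circle(n, cfg$colony_radius)
  colony[seq_len(nA), ] <- posA
  world <- list(
    cfg = cfg, roosts = roosts, stage = stage,
    x = x, y = y, heading = stats::runif(n, 0, 2 * pi),
    alive = rep(TRUE, n), feeding = rep(FALSE, n),
    feed_target = rep(NA_integer_, n),
    mem_x = rep(NA_real_, n), mem_y = rep(NA_real_, n),
    has_mem = rep(FALSE, n), fed_today = rep(FALSE, n),
    colony_x = colony[, 1], colony_y = colony[, 2],
    cx = numeric(0), cy = numeric(0), cmass = numeric(0),
    cpois = logical(0), clarge = logical(0), cage = integer(0),
    deaths_by_day = integer(0))
  class(world) <- "abm_world"
  world
}

# remove decayed carcasses, then replenish each habitat's standing carrion
# mass up to its cap; newly spawned carcasses are poisoned with probability
# 1/R of their habitat
spawn_carcasses <- function(world) {
  cfg <- world$cfg
  if (length(world$cmass)) {
    world$cage <- world$cage + 1L
    keep <- (world$cage < 1L) | (world$clarge & world$cage < 2L)
    world$cx <- world$cx[keep]; world$cy <- world$cy[keep]
    world$cmass <- world$cmass[keep]; world$cpois <- world$cpois[keep]
    world$clarge <- world$clarge[keep]; world$cage <- world$cage[keep]
  }
  chab <- habitat_of(world$cx, world$cy, cfg)
  for (hab in c("protected", "nonprotected")) {
    cap <- if (hab == "protected") cfg$cap_protected else cfg$cap_nonprotected
    rate <- if (hab == "protected") cfg$rate_protected else
      cfg$rate_nonprotected
    standing <- sum(world$cmass[chab == hab])
    masses <- numeric(0)
    while (standing + sum(masses) < cap) {
      need <- cap - standing - sum(masses)
      mu <- if (hab == "protected") cfg$gamma_shape / cfg$gamma_rate else
        cfg$normal_mean
      batch <- max(4L, ceiling(need / mu))
      draw <- draw_carcass_mass(batch, hab, cfg)
      cum <- cumsum(draw)
      take <- which(standing + sum(masses) + cum >= cap)
      if (length(take)) {
        masses <- c(masses, draw[seq_len(take[1L])])  # last draw kept whole
      } else {
        masses <- c(masses, draw)
      }
    }
    m <- length(masses)
    if (m == 0L) next
    centre_is_hab <- (cfg$focus == "Kruger") == (hab == "protected")
    pos <- if (centre_is_hab) runif_circle(m, cfg$region_radius)
           else runif_exterior(m, cfg)
    world$cx <- c(world$cx, pos[, 1]); world$cy <- c(world$cy, pos[, 2])
    world$cmass <- c(world$cmass, masses)
    world$cpois <- c(world$cpois, stats::runif(m) < 1 / rate)
    world$clarge <- c(world$clarge, masses > cfg$large_threshold)
    world$cage <- c(world$cage, rep(0L, m))
  }
  world
}

# one 10-minute foraging tick for every active bird, vectorized over agents
step_tick <- function(world, day) {
  cfg <- world$cfg
  act <- which(world$alive & !world$feeding)
  if (!length(act)) return(world)
  na <- length(act)
  step <- cfg$step_km
  tx <- rep(NA_real_, na); ty <- rep(NA_real_, na)
  target_carc <- rep(NA_integer_, na)
  dmin <- rep(Inf, na)
  confined <- world$stage[act] == "adult" & day < cfg$adult_release_day

  nc <- length(world$cx)
  if (nc) {
    occupied <- tabulate(world$feed_target[world$alive & world$feeding],
                         nbins = nc) > 0L
    vis <- ifelse(world$clarge | occupied, cfg$vision_enhanced, cfg$vision)
    D <- sqrt(outer(world$x[act], world$cx, "-")^2 +
              outer(world$y[act], world$cy, "-")^2)
    D[D > rep(vis, each = na)] <- Inf
    j <- max.col(-D, ties.method = "random")
    dmin <- D[cbind(seq_len(na), j)]
    seen <- is.finite(dmin)
    target_carc[seen] <- j[seen]
    tx[seen] <- world$cx[j[seen]]; ty[seen] <- world$cy[j[seen]]
  }

  # memory: birds with no carcass in sight head for yesterday's feeding site
  memi <- is.na(tx) & world$has_mem[act]
  tx[memi] <- world$mem_x[act[memi]]; ty[memi] <- world$mem_y[act[memi]]

  # random walk for the rest: turn 15 degrees left or right, step ahead
  rw <- is.na(tx)
  if (any(rw)) {
    turn <- sample(c(-1, 1), sum(rw), replace = TRUE) *
      cfg$turn_angle * pi / 180
    h <- world$heading[act[rw]] + turn
    world$heading[act[rw]] <- h
    tx[rw] <- world$x[act[rw]] + 2 * step * cos(h)
    ty[rw] <- world$y[act[rw]] + 2 * step * sin(h)
  }

  # en-route detection: the flight is quasi-continuous, so a carcass whose
  # detection radius the planned step would clip is spotted mid-flight and
  # the bird diverts to it (this is also how birds heading for a remembered
  # patch "pass a different carcass on the way")
  if (nc) {
    und <- which(is.na(target_carc))
    if (length(und)) {
      ax <- world$x[act[und]]; ay <- world$y[act[und]]
      ddx <- tx[und] - ax; ddy <- ty[und] - ay
      len <- sqrt(ddx^2 + ddy^2)
      ux <- ifelse(len > 0, ddx / len, 0)
      uy <- ifelse(len > 0, ddy / len, 0)
      seg <- pmin(len, step)
      # projection of each carcass onto the step segment, clamped to it
      px <- outer(-ax, world$cx, "+") * ux   # (cx - ax) * ux, row-wise
      py <- outer(-ay, world$cy, "+") * uy
      tproj <- pmin(pmax(px + py, 0), seg)
      dseg <- sqrt((outer(ax, world$cx, "-") + tproj * ux)^2 +
                   (outer(ay, world$cy, "-") + tproj * uy)^2)
      dseg[dseg > rep(vis, each = length(und))] <- Inf
      j2 <- max.col(-dseg, ties.method = "random")
      hit <- is.finite(dseg[cbind(seq_along(und), j2)])
      if (any(hit)) {
        hi <- und[hit]
        target_carc[hi] <- j2[hit]
        tx[hi] <- world$cx[j2[hit]]; ty[hi] <- world$cy[j2[hit]]
        dmin[hi] <- sqrt((tx[hi] - world$x[act[hi]])^2 +
                         (ty[hi] - world$y[act[hi]])^2)
      }
    }
  }

  dx <- tx - world$x[act]; dy <- ty - world$y[act]
  dist <- sqrt(dx^2 + dy^2)
  reach <- dist <= step
  frac <- ifelse(reach, 1, step / pmax(dist, 1e-12))
  nx <- world$x[act] + frac * dx
  ny <- world$y[act] + frac * dy
  world$heading[act] <- atan2(dy, dx)

  # pre-release adults are confined to the foraging circle; everyone to the
  # arena (reflecting boundaries: clamp and turn around)
  rr <- sqrt(nx^2 + ny^2)
  outp <- confined & rr > cfg$forage_radius
  if (any(outp)) {
    sc <- cfg$forage_radius / rr[outp]
    nx[outp] <- nx[outp] * sc; ny[outp] <- ny[outp] * sc
    world$heading[act[outp]] <- world$heading[act[outp]] + pi
  }
  outa <- abs(nx) > cfg$arena_half | abs(ny) > cfg$arena_half
  if (any(outa)) {
    nx[outa] <- pmin(pmax(nx[outa], -cfg$arena_half), cfg$arena_half)
    ny[outa] <- pmin(pmax(ny[outa], -cfg$arena_half), cfg$arena_half)
    world$heading[act[outa]] <- world$heading[act[outa]] + pi
  }
  world$x[act] <- nx; world$y[act] <- ny

  # landings: a bird reaching its target carcass feeds - or dies, instantly,
  # if the carcass is poisoned
  land <- reach & !is.na(target_carc) & !outp
  if (any(land)) {
    li <- act[land]; ci <- target_carc[land]
    pois <- world$cpois[ci]
    died <- li[pois]
    if (length(died)) {
      world$alive[died] <- FALSE
      world$deaths_by_day <- c(world$deaths_by_day, rep(day, length(died)))
    }
    fed <- li[!pois]
    if (length(fed)) {
      world$feeding[fed] <- TRUE
      world$feed_target[fed] <- ci[!pois]
      world$mem_x[fed] <- world$cx[ci[!pois]]
      world$mem_y[fed] <- world$cy[ci[!pois]]
      world$has_mem[fed] <- TRUE
      world$fed_today[fed] <- TRUE
    }
  }
  # arriving at an empty remembered patch clears the memory
  arr_mem <- memi & reach
  if (any(arr_mem)) world$has_mem[act[arr_mem]] <- FALSE
  world
}

# end of day: feeding ends, birds go home (roost assignment), memory of a
# day without feeding is dropped
night_phase <- function(world, day) {
  cfg <- world$cfg
  ai <- which(world$alive)
  if (length(ai)) {
    stage <- world$stage[ai]
    to_colony <- (stage == "adult" & day < cfg$adult_release_day) |
      (stage == "subadult" & stats::runif(length(ai)) < 0.5)
    # nearest roost for everyone else
    need_roost <- which(!to_colony)
    if (length(need_roost)) {
      DR <- sqrt(outer(world$x[ai[need_roost]], world$roosts[, 1], "-")^2 +
                 outer(world$y[ai[need_roost]], world$roosts[, 2], "-")^2)
      nr <- max.col(-DR, ties.method = "first")
      world$x[ai[need_roost]] <- world$roosts[nr, 1]
      world$y[ai[need_roost]] <- world$roosts[nr, 2]
    }
    ci <- ai[to_colony]
    world$x[ci] <- world$colony_x[ci]
    world$y[ci] <- world$colony_y[ci]
  }
  world$has_mem <- world$has_mem & world$fed_today
  world$fed_today[] <- FALSE
  world$feeding[] <- FALSE
  world$feed_target[] <- NA_integer_
  world
}

#' Run one simulated year of the foraging/poisoning ABM
#'
#' Daily loop: carcass decay and replenishment at dawn, a 9-hour foraging
#' window of 10-minute ticks, then nightly return to the colony or the
#' nearest roost. Runs for `cfg$days` days and reports per-stage survival.
#'
#' @param cfg an [abm_config()].
#' @param seed RNG seed (mandatory; identical config + seed gives an
#'   identical result).
#' @return object of class `abm_run`: per-stage survival percentages,
#'   initial/alive counts, death days, the config and seed.
#' @examples
#' \donttest{
#' r <- run_abm_year(abm_config(days = 30), seed = 1)
#' r
#' }
#' @export
run_abm_year <- function(cfg = abm_config(), seed) {
  stopifnot(inherits(cfg, "abm_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  world <- init_world(cfg)
  for (day in seq_len(cfg$days)) {
    world <- spawn_carcasses(world)
    for (tick in seq_len(cfg$ticks_per_day)) {
      world <- step_tick(world, day)
    }
    world <- night_phase(world, day)
  }
  init <- table(world$stage)
  alive <- table(world$stage[world$alive])
  surv <- 100 * as.numeric(alive[STAGES]) / as.numeric(init[STAGES])
  surv[is.na(surv)] <- 100
  names(surv) <- STAGES
  structure(list(survival_pct = surv,
                 n_initial = as.numeric(init[STAGES]),
                 n_alive = as.numeric(ifelse(is.na(alive[STAGES]), 0,
                                             alive[STAGES])),
                 deaths_by_day = world$deaths_by_day,
                 cfg = cfg, seed = seed),
            class = "abm_run")
}

#' @export
print.abm_run <- function(x, ...) {
  cat(sprintf("ABM run (focus %s, rates 1/%s vs 1/%s, seed %d): survival %%\n",
              x$cfg$focus, format(x$cfg$rate_protected),
              format(x$cfg$rate_nonprotected), x$seed))
  print(round(x$survival_pct, 2))
  invisible(x)
}

#' Replicated ABM experiment
#'
#' Repeats [run_abm_year()] with per-replicate sub-seeds and collects the
#' per-stage survival percentages; `summary()` gives the mean and SD per
#' stage, the form in which the experiments are reported.
#'
#' @param cfg an [abm_config()].
#' @param replicates number of replicate years (default 30).
#' @param seed base seed; replicate `i` runs with `seed + i`.
#' @return object of class `abm_experiment`: a data frame with columns
#'   `replicate`, `stage`, `survival_pct`, `seed` plus the config as an
#'   attribute.
#' @export
run_abm_experiment <- function(cfg = abm_config(), replicates = 30, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (replicates < 1) stop("need at least one replicate")
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    r <- run_abm_year(cfg, seed = as.integer(seed) + i)
    rows[[i]] <- data.frame(replicate = i, stage = STAGES,
                            survival_pct = unname(r$survival_pct),
                            seed = r$seed)
  }
  out <- do.call(rbind, rows)
  attr(out, "cfg") <- cfg
  class(out) <- c("abm_experiment", "data.frame")
  out
}

#' @export
summary.abm_experiment <- function(object, ...) {
  agg <- do.call(rbind, lapply(STAGES, function(s) {
    v <- object$survival_pct[object$stage == s]
    data.frame(stage = s, mean = mean(v), sd = stats::sd(v),
               n = length(v))
  }))
  cfg <- attr(object, "cfg")
  agg$focus <- cfg$focus
  agg$rate_protected <- cfg$rate_protected
  agg$rate_nonprotected <- cfg$rate_nonprotected
  agg$n_roosts <- cfg$n_roosts
  agg
}

#' Boxplots of replicate stage survival
#'
#' One box per life stage across the replicates of an experiment, the form
#' in which stage-survival contrasts are usually displayed.
#'
#' @param x an `abm_experiment`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.abm_experiment <- function(x, ...) {
  cfg <- attr(x, "cfg")
  graphics::boxplot(
    survival_pct ~ factor(stage, levels = STAGES), data = x,
    xlab = "life stage", ylab = "survival (%)", ylim = c(0, 100),
    main = sprintf("focus %s, rates 1/%s vs 1/%s", cfg$focus,
                   format(cfg$rate_protected),
                   format(cfg$rate_nonprotected)), ...)
  invisible(x)
}

#' @export
print.abm_experiment <- function(x, ...) {
  cfg <- attr(x, "cfg")
  cat(sprintf("ABM experiment: focus %s, %d replicates\n", cfg$focus,
              max(x$replicate)))
  print(summary(x), row.names = FALSE, digits = 4)
  invisible(x)
}
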