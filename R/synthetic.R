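# Synthetic trajectory and melting-data generation. The conformational
# dynamics surrogate is a continuous-time Markov chain (CTMC) over the three
# junction conformers in which the open state is the obligatory intermediate
# (direct iso-I <-> iso-II rates are zero), rendered into coordinates by
# perturbing idealized conformer templates.

.STATES <- c("open", "iso-I", "iso-II")

# deterministic member-seed derivation: Lehmer step of the master seed plus a
# counter, reduced mod 2^31 - 1; distinct counters never collide for a fixed
# master seed
.derive_seed <- function(master, counter) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + counter) %% m)
}

#' Three-state kinetic model of conformer switching
#'
#' Switching rates between the open conformer and the two stacked isoforms,
#' in 1/ns. The direct iso-I <-> iso-II rate is fixed at zero: the open state
#' is the only path between the stacked conformers, mirroring its role as the
#' transition state.
#'
#' @param k_IO,k_OI iso-I -> open and open -> iso-I rates (1/ns)
#' @param k_IIO,k_OII iso-II -> open and open -> iso-II rates (1/ns)
#' @return object of class `kinetic_model`
#' @export
kinetic_model <- function(k_IO, k_OI, k_IIO, k_OII) {
  rates <- c(k_IO = k_IO, k_OI = k_OI, k_IIO = k_IIO, k_OII = k_OII)
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be finite and >= 0")
  structure(list(k_IO = k_IO, k_OI = k_OI, k_IIO = k_IIO, k_OII = k_OII),
            class = "kinetic_model")
}

#' Default kinetic model mirroring high-salt junction dynamics
#'
#' Rates chosen so that the stationary populations are 6% open, 36% iso-I and
#' 58% iso-II (the high-salt ensemble averages) with a short-lived open state
#' (mean dwell 0.5 ns) relative to the stacked dwells (about 8 ns).
#'
#' @return a `kinetic_model`
#' @export
default_kinetic_model <- function() {
  # pi_I/pi_O = k_OI/k_IO = 6, pi_II/pi_O = k_OII/k_IIO = 58/6; open exit 2/ns
  k_OI <- 2 * (36 / 94)
  k_OII <- 2 * (58 / 94)
  kinetic_model(k_IO = k_OI / 6, k_OI = k_OI,
                k_IIO = k_OII / (58 / 6), k_OII = k_OII)
}

#' Generator matrix of a kinetic model
#' @param model a `kinetic_model`
#' @return 3x3 generator matrix ordered (open, iso-I, iso-II); rows sum to 0
#' @export
generator_matrix <- function(model) {
  Q <- matrix(0, 3L, 3L, dimnames = list(.STATES, .STATES))
  Q["open", "iso-I"] <- model$k_OI
  Q["open", "iso-II"] <- model$k_OII
  Q["iso-I", "open"] <- model$k_IO
  Q["iso-II", "open"] <- model$k_IIO
  diag(Q) <- -rowSums(Q)
  Q
}

#' Closed-form stationary distribution of the three-state chain
#'
#' Detailed balance through the open hub gives unnormalized weights
#' (1, k_OI/k_IO, k_OII/k_IIO) for (open, iso-I, iso-II).
#'
#' @param model a `kinetic_model` with all rates > 0
#' @return named numeric vector of stationary probabilities
#' @export
stationary_distribution <- function(model) {
  if (any(unlist(model[c("k_IO", "k_OI", "k_IIO", "k_OII")]) <= 0))
    stop("stationary distribution requires all four rates > 0")
  w <- c(open = 1, `iso-I` = model$k_OI / model$k_IO,
         `iso-II` = model$k_OII / model$k_IIO)
  w / sum(w)
}

#' Sample a conformer state series from the kinetic model
#'
#' Exact continuous-time Markov chain sampling (exponential dwell times,
#' Gillespie algorithm) discretized onto a uniform frame grid. The underlying
#' jump path is kept as the `jumps` element, so event-level analyses (such as
#' verifying that every iso-I <-> iso-II inter-conversion passes through the
#' open state) can use the exact path rather than the discretized frames.
#' Direct iso-I <-> iso-II frame-to-frame transitions can only arise from
#' discretization and vanish as `dt -> 0`.
#'
#' @param model a `kinetic_model`
#' @param duration total simulated time, ns
#' @param dt frame spacing, ns
#' @param initial initial state, one of `"open"`, `"iso-I"`, `"iso-II"`
#' @param seed integer RNG seed
#' @param member optional member id recorded in the result
#' @return object of class `state_series`: list with `times` (ns), `states`
#'   (character), `dt`, `initial`, `member`, `jumps` (data frame of the exact
#'   jump path: entry time and state of each dwell)
#' @export
simulate_state_series <- function(model, duration, dt = 1, initial = "open",
                                  seed = 1L, member = NA_integer_) {
  stopifnot(inherits(model, "kinetic_model"))
  if (duration < dt) stop("duration must be >= dt")
  initial <- match.arg(initial, .STATES)
  set.seed(seed)
  exit_rate <- c(open = model$k_OI + model$k_OII,
                 `iso-I` = model$k_IO, `iso-II` = model$k_IIO)
  jump_t <- numeric(64L); jump_s <- character(64L)
  n <- 1L; jump_t[1L] <- 0; jump_s[1L] <- initial
  t <- 0; state <- initial
  while (TRUE) {
    rate <- exit_rate[[state]]
    if (rate <= 0) break                       # absorbing: constant thereafter
    t <- t + stats::rexp(1L, rate)
    if (t >= duration) break
    state <- if (state == "open") {
      if (stats::runif(1L) < model$k_OI / rate) "iso-I" else "iso-II"
    } else "open"
    n <- n + 1L
    if (n > length(jump_t)) {                  # grow storage geometrically
      jump_t <- c(jump_t, numeric(length(jump_t)))
      jump_s <- c(jump_s, character(length(jump_s)))
    }
    jump_t[n] <- t; jump_s[n] <- state
  }
  jumps <- data.frame(time = jump_t[seq_len(n)], state = jump_s[seq_len(n)],
                      stringsAsFactors = FALSE)
  times <- seq(0, by = dt, length.out = floor(duration / dt))
  states <- jumps$state[findInterval(times, jumps$time)]
  structure(list(times = times, states = states, dt = dt, initial = initial,
                 member = member, seed = seed, jumps = jumps),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("Conformer state series: %d frames, dt = %g ns, initial %s\n",
              length(x$states), x$dt, x$initial))
  print(round(prop.table(table(factor(x$states, .STATES))), 3))
  invisible(x)
}

# uniform random rotation matrix from a normalized quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Render a state series into site coordinates
#'
#' Each frame takes the idealized template of its conformer state, adds
#' isotropic Gaussian displacement of standard deviation `sigma` per site and
#' per axis, then applies a random rigid motion (uniform rotation plus
#' translation). With `sigma = 0` all intra-frame inter-site distances equal
#' the template distances exactly.
#'
#' @param series a `state_series`
#' @param templates named list of `geometry_template`s covering every state
#'   that occurs in `series` (names among `"open"`, `"iso-I"`, `"iso-II"`)
#' @param sigma site displacement standard deviation, Angstrom (>= 0)
#' @param seed integer RNG seed
#' @param temperature,salt metadata recorded in the trajectory (K, mM)
#' @return object of class `trajectory`: list with `coords`
#'   (n_sites x 3 x n_frames array, Angstrom), `times`, `states`, `metadata`
#' @export
render_trajectory <- function(series, templates, sigma = 1, seed = 1L,
                              temperature = 300, salt = 300) {
  stopifnot(inherits(series, "state_series"), sigma >= 0)
  occ <- unique(series$states)
  missing_tpl <- setdiff(occ, names(templates))
  if (length(missing_tpl))
    stop("missing template for state(s): ", paste(missing_tpl, collapse = ", "))
  set.seed(seed)
  n_sites <- nrow(templates[[occ[1L]]]$coords)
  n_frames <- length(series$states)
  coords <- array(NA_real_, dim = c(n_sites, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    tpl <- templates[[series$states[f]]]$coords
    fr <- tpl
    if (sigma > 0) fr <- fr + matrix(stats::rnorm(length(tpl), 0, sigma), nrow(tpl), 3L)
    rot <- .random_rotation()
    shift <- stats::runif(3L, -50, 50)
    coords[, , f] <- sweep(fr %*% t(rot), 2L, -shift)
  }
  structure(list(coords = coords, times = series$times, states = series$states,
                 metadata = list(temperature = temperature, salt = salt,
                                 seed = seed, member = series$member,
                                 sigma = sigma)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Junction trajectory: %d frames x %d sites (T = %g K, salt = %g mM)\n",
              d[3L], d[1L], x$metadata$temperature, x$metadata$salt))
  invisible(x)
}

#' Simulate an ensemble of independent conformer trajectories
#'
#' Member seeds are derived deterministically from the master seed (a Lehmer
#' step plus member counter), making members statistically independent and the
#' whole ensemble reproducible. Initial states are drawn from
#' `initial_dist`, supporting the two-stage protocol of an all-open first
#' stage followed by a second stage re-seeded from the stage-one population
#' estimate.
#'
#' @param model a `kinetic_model`
#' @param n_members number of ensemble members
#' @param duration,dt per-member duration and frame spacing, ns
#' @param initial_dist named probability vector over
#'   `c("open", "iso-I", "iso-II")`; must sum to 1
#' @param seed master integer seed
#' @param templates optional named template list; when supplied each member is
#'   rendered to coordinates (see [render_trajectory()]), otherwise state
#'   series are returned
#' @param sigma rendering noise, Angstrom (used only with `templates`)
#' @return list of `state_series` (or `trajectory` when `templates` given)
#' @export
simulate_ensemble <- function(model, n_members = 100L, duration = 2000,
                              dt = 1, initial_dist = c(open = 1, `iso-I` = 0, `iso-II` = 0),
                              seed = 1L, templates = NULL, sigma = 1) {
  if (n_members < 1L) stop("n_members must be >= 1")
  if (is.null(names(initial_dist)) || !setequal(names(initial_dist), .STATES) ||
      any(initial_dist < 0) || abs(sum(initial_dist) - 1) > 1e-9)
    stop("initial_dist must be a probability vector named open, iso-I, iso-II")
  set.seed(.derive_seed(seed, 0L))
  init_states <- sample(.STATES, n_members, replace = TRUE,
                        prob = initial_dist[.STATES])
  out <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    s <- simulate_state_series(model, duration, dt, initial = init_states[i],
                               seed = .derive_seed(seed, i), member = i)
    if (!is.null(templates)) {
      s <- render_trajectory(s, templates, sigma = sigma,
                             seed = .derive_seed(seed, n_members + i))
    }
    out[[i]] <- s
  }
  out
}

#' Ground-truth thermodynamic parameters for synthetic melting data
#'
#' @param dH melting enthalpy, kcal/mol (> 0, melting direction)
#' @param dS melting entropy, kcal/(mol K) (> 0)
#' @param C total strand concentration, mol/L
#' @param temperatures strictly increasing temperature grid, K
#' @return object of class `melting_ground_truth`
#' @export
melting_ground_truth <- function(dH, dS, C, temperatures) {
  stopifnot(dH > 0, dS > 0, C > 0, all(diff(temperatures) > 0))
  structure(list(dH = dH, dS = dS, C = C, temperatures = temperatures),
            class = "melting_ground_truth")
}

#' Simulate per-temperature frame ensembles for melting analysis
#'
#' For each grid temperature the single-strand fraction `alpha(T)` is computed
#' from the tetramolecular mass-action model; each frame is then drawn melted
#' (all base-pair separations sampled uniformly from `melted_range`) with
#' probability `alpha(T)`, or intact (separations from `intact_range`)
#' otherwise. With `per_pair = TRUE` each base pair instead melts
#' independently with probability `alpha(T)`, generating partially melted
#' junctions that exercise the more-than-half-broken strand rule.
#'
#' @param truth a `melting_ground_truth`
#' @param topology a `junction_topology`
#' @param n_frames frames per temperature
#' @param seed integer seed
#' @param intact_range,melted_range uniform sampling ranges (Angstrom) for
#'   intact and melted base-pair separations; the defaults straddle the 10 A
#'   intact-bond criterion
#' @param per_pair logical; independent per-pair melting
#' @return list of class `melting_frames`: per temperature a list with
#'   `temperature`, `alpha_true`, `frames` (n_sites x 3 x n_frames array)
#' @export
simulate_melting_frames <- function(truth, topology, n_frames = 100L, seed = 1L,
                                    intact_range = c(4, 8),
                                    melted_range = c(12, 30),
                                    per_pair = FALSE) {
  stopifnot(inherits(truth, "melting_ground_truth"),
            inherits(topology, "junction_topology"), n_frames >= 1L)
  set.seed(seed)
  bp <- topology$base_pairs
  n_pairs <- nrow(bp)
  sites <- topology$sites
  alpha <- vant_hoff_alpha(truth$temperatures, truth$dH, truth$dS, truth$C)
  out <- vector("list", length(truth$temperatures))
  for (ti in seq_along(truth$temperatures)) {
    coords <- array(0, dim = c(topology$n_sites, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      melted <- if (per_pair) stats::runif(n_pairs) < alpha[ti]
                else rep(stats::runif(1L) < alpha[ti], n_pairs)
      d <- ifelse(melted,
                  stats::runif(n_pairs, melted_range[1L], melted_range[2L]),
                  stats::runif(n_pairs, intact_range[1L], intact_range[2L]))
      # each pair dropped at a random location with the drawn separation
      anchor <- matrix(stats::runif(3L * n_pairs, -100, 100), n_pairs, 3L)
      dir <- matrix(stats::rnorm(3L * n_pairs), n_pairs, 3L)
      dir <- dir / sqrt(rowSums(dir^2))
      fr <- matrix(0, topology$n_sites, 3L)
      fr[bp$site_a, ] <- anchor
      fr[bp$site_b, ] <- anchor + d * dir
      # backbone sites ride along with their nucleotide's base
      base_ids <- sites$id[sites$kind == "base"]
      key <- paste(sites$strand, sites$nt)
      base_of <- base_ids[match(key, key[sites$kind == "base"])]
      nonbase <- sites$kind != "base"
      fr[sites$id[nonbase], ] <- fr[base_of[nonbase], ] +
        matrix(stats::rnorm(sum(nonbase) * 3L, 0, 1), sum(nonbase), 3L)
      coords[, , f] <- fr
    }
    out[[ti]] <- list(temperature = truth$temperatures[ti],
                      alpha_true = alpha[ti], frames = coords)
  }
  structure(out, class = "melting_frames")
}

#' Simulate a UV absorbance melting curve
#'
#' `A(T) = A_low(T) + alpha(T) (A_up(T) - A_low(T)) + N(0, sigma_A)`, with
#' linear lower and upper baselines. Baselines must not cross on the grid.
#'
#' @param truth a `melting_ground_truth`
#' @param lower,upper numeric `c(intercept, slope)` of the baselines (AU,
#'   AU/K)
#' @param sigma_A absorbance noise standard deviation, AU
#' @param seed integer seed
#' @param lower_window,upper_window temperature ranges (K) declared as
#'   baseline windows in the returned curve; default to the outer 15% of the
#'   grid span
#' @return an `absorbance_curve` (see [absorbance_curve()])
#' @export
simulate_absorbance <- function(truth, lower = c(0.30, 1e-4),
                                upper = c(0.55, 2e-4), sigma_A = 0, seed = 1L,
                                lower_window = NULL, upper_window = NULL) {
  stopifnot(inherits(truth, "melting_ground_truth"), sigma_A >= 0)
  Tg <- truth$temperatures
  A_low <- lower[1L] + lower[2L] * Tg
  A_up <- upper[1L] + upper[2L] * Tg
  if (any(A_up <= A_low)) stop("baselines cross within the temperature grid")
  alpha <- vant_hoff_alpha(Tg, truth$dH, truth$dS, truth$C)
  set.seed(seed)
  A <- A_low + alpha * (A_up - A_low) + stats::rnorm(length(Tg), 0, sigma_A)
  span <- diff(range(Tg))
  n <- length(Tg)
  # default windows: outer 15% of the span, but at least three grid points
  if (is.null(lower_window))
    lower_window <- c(min(Tg), max(min(Tg) + 0.15 * span, Tg[min(3L, n)]))
  if (is.null(upper_window))
    upper_window <- c(min(max(Tg) - 0.15 * span, Tg[max(1L, n - 2L)]), max(Tg))
  absorbance_curve(Tg, A, lower_window, upper_window)
}
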