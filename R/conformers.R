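# Conformer classification and ensemble statistics. A frame is classified
# from the four core inter-base distances with a single 12 A cutoff: a
# stacked isoform requires BOTH of its signature distances short and both of
# the complementary pair's distances long (max-aggregation); conflicting
# signatures are labelled ambiguous rather than silently assigned; everything
# else is open.

#' Core inter-base distances of a frame
#'
#' Euclidean separations (Angstrom) of the four labelled core-marker base
#' pairs: d_TT, d_CC (spanning strands X and H) and d_AG1, d_AG2 (spanning
#' strands R and B).
#'
#' @param frame n_sites x 3 coordinate matrix
#' @param topology a `junction_topology` (or the result of
#'   [core_marker_pairs()])
#' @return named numeric vector `c(TT=, CC=, AG1=, AG2=)`
#' @export
core_distances <- function(frame, topology) {
  mp <- if (inherits(topology, "junction_topology")) core_marker_pairs(topology)
        else topology
  if (max(mp$site_a, mp$site_b) > nrow(frame))
    stop("frame does not cover all core-marker sites")
  d <- sqrt(rowSums((frame[mp$site_a, , drop = FALSE] -
                     frame[mp$site_b, , drop = FALSE])^2))
  stats::setNames(d, mp$pair)
}

#' Classify a frame from its core distances
#'
#' With signature_I = max(d_TT, d_CC) and signature_II = max(d_AG1, d_AG2):
#' iso-I when signature_I < cutoff <= signature_II; iso-II when signature_II
#' < cutoff <= signature_I; ambiguous when both signatures are below the
#' cutoff; open otherwise. Deterministic and invariant to rigid motions of
#' the frame (it sees only distances).
#'
#' @param d named distances as returned by [core_distances()], or a 4-column
#'   matrix (TT, CC, AG1, AG2) for vectorized use
#' @param cutoff classification cutoff, Angstrom (default 12, the approximate
#'   minimum between the short- and long-distance peaks)
#' @return conformer label(s): "open", "iso-I", "iso-II" or "ambiguous"
#' @export
classify_frame <- function(d, cutoff = 12) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.matrix(d)) {
    sig1 <- pmax(d[, 1L], d[, 2L]); sig2 <- pmax(d[, 3L], d[, 4L])
  } else {
    if (any(!is.finite(d))) stop("non-finite core distance")
    sig1 <- max(d[["TT"]], d[["CC"]]); sig2 <- max(d[["AG1"]], d[["AG2"]])
  }
  ifelse(sig1 < cutoff,
         ifelse(sig2 < cutoff, "ambiguous", "iso-I"),
         ifelse(sig2 < cutoff, "iso-II", "open"))
}

#' Classify every frame of a trajectory
#'
#' @param traj a `trajectory` (or 3D coordinate array)
#' @param topology a `junction_topology`
#' @param cutoff classification cutoff, Angstrom
#' @return a `state_series` whose `states` may include "ambiguous"; frame
#'   times are preserved
#' @export
classify_trajectory <- function(traj, topology, cutoff = 12) {
  fl <- .frame_list(traj)
  if (!length(fl)) stop("empty trajectory")
  mp <- core_marker_pairs(topology)
  d <- t(vapply(fl, function(fr) core_distances(fr, mp), numeric(4L)))
  states <- classify_frame(d, cutoff)
  times <- if (inherits(traj, "trajectory")) traj$times
           else seq_len(length(fl)) - 1
  member <- if (inherits(traj, "trajectory")) traj$metadata$member else NA_integer_
  structure(list(times = times, states = states,
                 dt = if (length(times) > 1L) times[2L] - times[1L] else NA_real_,
                 initial = states[1L], member = member, seed = NA_integer_,
                 jumps = NULL),
            class = "state_series")
}

#' Pooled distribution of core inter-base distances
#'
#' Pools d_AG1 and d_AG2 (`which = "AG"`) or d_TT and d_CC
#' (`which = "TTCC"`) over all frames of an ensemble into one normalized
#' density histogram.
#'
#' @param ensemble a `trajectory`, list of trajectories, or 3D array
#' @param topology a `junction_topology`
#' @param which `"AG"` or `"TTCC"`
#' @param binwidth histogram bin width, Angstrom
#' @return data frame with `bin_left`, `bin_right`, `density`; the density
#'   integrates to 1
#' @export
distance_distribution <- function(ensemble, topology, which = c("AG", "TTCC"),
                                  binwidth = 0.5) {
  which <- match.arg(which)
  if (inherits(ensemble, "trajectory") || (is.array(ensemble) && !is.list(ensemble)))
    ensemble <- list(ensemble)
  mp <- core_marker_pairs(topology)
  vals <- unlist(lapply(ensemble, function(traj) {
    fl <- .frame_list(traj)
    d <- t(vapply(fl, function(fr) core_distances(fr, mp), numeric(4L)))
    if (which == "AG") c(d[, "AG1"], d[, "AG2"]) else c(d[, "TT"], d[, "CC"])
  }))
  if (!length(vals)) stop("empty ensemble")
  breaks <- seq(floor(min(vals) / binwidth) * binwidth,
                ceiling(max(vals) / binwidth) * binwidth + binwidth, by = binwidth)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)],
             bin_right = h$breaks[-1L], density = h$density)
}

# coerce input to a list of state_series
.series_list <- function(x) {
  if (inherits(x, "state_series")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1L), "state_series"))) return(x)
  stop("expected a state_series or a list of state_series")
}

#' Ensemble conformer population fractions
#'
#' Overall fractions are the unweighted mean of per-member fractions
#' (ensemble averaging over equally weighted members); the standard error is
#' the member-to-member standard deviation divided by sqrt(m).
#'
#' @param series a `state_series` or list of them (ensemble members)
#' @return object of class `population_estimate`: list with `fractions`
#'   (open, iso-I, iso-II, ambiguous; sums to 1), `se`, `per_member`
#' @export
population_fractions <- function(series) {
  members <- .series_list(series)
  if (!length(members)) stop("no ensemble members")
  lev <- c(.STATES, "ambiguous")
  per <- t(vapply(members, function(s) {
    tab <- table(factor(s$states, levels = lev))
    as.numeric(tab) / length(s$states)
  }, numeric(4L)))
  colnames(per) <- lev
  fr <- colMeans(per)
  se <- if (nrow(per) > 1L) apply(per, 2L, stats::sd) / sqrt(nrow(per))
        else rep(0, 4L)
  structure(list(fractions = fr, se = stats::setNames(se, lev),
                 per_member = per, n_members = nrow(per)),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Conformer populations over %d member(s):\n", x$n_members))
  for (s in names(x$fractions)) {
    cat(sprintf("  %-10s %6.2f%%  (SE %.2f%%)\n", s,
                100 * x$fractions[[s]], 100 * x$se[[s]]))
  }
  invisible(x)
}

#' Empirical conformer transition matrix
#'
#' Counts ordered state pairs (s_t, s_(t+lag)) pooled over members (no
#' cross-member pairs) and normalizes rows. Pairs in which either frame is
#' ambiguous are excluded; their count is reported. Rows with no observations
#' are returned as NA and flagged.
#'
#' @param series a `state_series` or list of them
#' @param lag lag in frames (default 1)
#' @return object of class `transition_matrix`: list with `probabilities`
#'   (3x3, rows open/iso-I/iso-II), `counts`, `lag`, `n_transitions`,
#'   `n_excluded_ambiguous`, `undefined_rows`
#' @export
transition_matrix <- function(series, lag = 1L) {
  members <- .series_list(series)
  lag <- as.integer(lag)
  if (any(vapply(members, function(s) length(s$states), integer(1L)) <= lag))
    stop("every member must be longer than the lag")
  counts <- matrix(0L, 3L, 3L, dimnames = list(.STATES, .STATES))
  excluded <- 0L
  for (s in members) {
    from <- s$states[seq_len(length(s$states) - lag)]
    to <- s$states[-seq_len(lag)]
    ok <- from != "ambiguous" & to != "ambiguous"
    excluded <- excluded + sum(!ok)
    tab <- table(factor(from[ok], .STATES), factor(to[ok], .STATES))
    counts <- counts + as.matrix(tab)
  }
  row_n <- rowSums(counts)
  if (all(row_n == 0L)) stop("no transitions observed")
  probs <- counts / ifelse(row_n > 0L, row_n, NA_real_)
  structure(list(probabilities = probs, counts = counts, lag = lag,
                 n_transitions = sum(counts),
                 n_excluded_ambiguous = excluded,
                 undefined_rows = .STATES[row_n == 0L]),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Conformer transition matrix (lag %d frame(s), %d transitions):\n",
              x$lag, x$n_transitions))
  print(round(x$probabilities, 4))
  if (x$n_excluded_ambiguous > 0L)
    cat(sprintf("  %d pairs excluded (ambiguous frames)\n", x$n_excluded_ambiguous))
  invisible(x)
}

#' Inter-duplex angle (IDA) of a frame
#'
#' The vertex is the centroid of the eight core-marker base sites; each arm
#' direction is the unit vector from the vertex to the centroid of the two
#' base sites of the arm's terminal base pair. The IDA is the angle between
#' the two named arms, in degrees within [0, 180].
#'
#' @param frame n_sites x 3 coordinate matrix
#' @param topology a `junction_topology`
#' @param arms two arm names (default the XR and RH arms)
#' @return angle in degrees
#' @export
inter_duplex_angle <- function(frame, topology, arms = c("XR", "RH")) {
  stopifnot(inherits(topology, "junction_topology"), length(arms) == 2L)
  if (!all(arms %in% topology$arms$name)) stop("unknown arm name(s)")
  vertex <- colMeans(frame[topology$core_markers$site, , drop = FALSE])
  bp <- topology$base_pairs
  dir_of <- function(arm) {
    term <- bp[bp$arm == arm & bp$index_in_arm == max(bp$index_in_arm[bp$arm == arm]), ]
    tip <- colMeans(frame[c(term$site_a, term$site_b), , drop = FALSE])
    v <- tip - vertex
    n <- sqrt(sum(v^2))
    if (n < 1e-9) stop("degenerate (zero-length) arm vector for arm ", arm)
    v / n
  }
  u <- dir_of(arms[1L]); v <- dir_of(arms[2L])
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Per-conformer inter-duplex angle statistics
#'
#' Computes the IDA of every frame, groups frames by their conformer state,
#' and reports per-state mean, standard deviation, sample count and a
#' histogram. An initial equilibration window can be discarded.
#'
#' @param traj a `trajectory` (or 3D array aligned with `states`)
#' @param states a `state_series` aligned 1:1 with the frames
#' @param topology a `junction_topology`
#' @param discard_ns initial time window to discard, ns
#' @param binwidth histogram bin width, degrees
#' @return object of class `conformer_structure_stats`: per-state list with
#'   `mean`, `sd`, `n`, `histogram`; states with zero frames are reported as
#'   absent (NULL)
#' @export
conformer_structure_stats <- function(traj, states, topology, discard_ns = 0,
                                      binwidth = 2) {
  fl <- .frame_list(traj)
  if (length(fl) != length(states$states))
    stop("states must align 1:1 with frames")
  keep <- states$times >= discard_ns
  fl <- fl[keep]; labs <- states$states[keep]
  ida <- vapply(fl, inter_duplex_angle, numeric(1L), topology = topology)
  out <- list()
  for (s in c(.STATES, "ambiguous")) {
    vals <- ida[labs == s]
    if (!length(vals)) next
    breaks <- seq(0, 180 + binwidth, by = binwidth)
    h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
    out[[s]] <- list(mean = mean(vals), sd = stats::sd(vals), n = length(vals),
                     histogram = data.frame(bin_left = h$breaks[-length(h$breaks)],
                                            bin_right = h$breaks[-1L],
                                            density = h$density))
  }
  structure(list(by_state = out, discard_ns = discard_ns, n_frames = sum(keep)),
            class = "conformer_structure_stats")
}

#' @export
print.conformer_structure_stats <- function(x, ...) {
  cat(sprintf("IDA statistics over %d frames (first %g ns discarded):\n",
              x$n_frames, x$discard_ns))
  for (s in names(x$by_state)) {
    st <- x$by_state[[s]]
    cat(sprintf("  %-10s mean %6.1f deg, sd %5.1f deg (n = %d)\n",
                s, st$mean, ifelse(is.na(st$sd), 0, st$sd), st$n))
  }
  invisible(x)
}
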