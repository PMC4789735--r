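# Idealized conformer geometries. These are geometric scaffolds, not
# energy-minimized structures: arms are straight helical-axis proxies
# radiating from a common vertex, and the eight core-marker bases are placed
# explicitly so that the inter-base distance signatures of each conformer
# hold by construction.

.CONFORMER_TEMPLATES <- c("open-planar", "open-tetrahedral", "iso-I", "iso-II")

.unit <- function(v) v / sqrt(sum(v^2))

.perp <- function(u) {
  # a unit vector perpendicular to u
  p <- c(u[2L] * 1 - u[3L] * 0, u[3L] * 0 - u[1L] * 1, u[1L] * 0 - u[2L] * 0) # u x z
  if (sqrt(sum(p^2)) < 1e-8) p <- c(0, u[3L], -u[2L])                          # u x x
  .unit(p)
}

.arm_directions <- function(conformer, theta_rad) {
  switch(conformer,
    "open-planar" = list(XR = c(1, 0, 0), RH = c(0, 1, 0),
                         HB = c(-1, 0, 0), BX = c(0, -1, 0)),
    "open-tetrahedral" = {
      s <- 1 / sqrt(3)
      list(XR = c(s, s, s), RH = c(s, -s, -s),
           HB = c(-s, s, -s), BX = c(-s, -s, s))
    },
    {
      a <- c(1, 0, 0)
      b <- c(cos(theta_rad), sin(theta_rad), 0)
      list(XR = a, RH = b, HB = -a, BX = -b)
    })
}

#' Idealized geometry template for a junction conformer
#'
#' Builds site coordinates for an idealized open or stacked conformation of a
#' four-way junction. Arms are straight proxies for the duplex helical axes,
#' radiating from a common vertex; base pairs sit on a regular lattice of
#' spacing `rise` along each arm, the two bases of a pair offset laterally by
#' +/- `base_offset` from the axis, with backbone (sugar/phosphate) sites
#' placed outboard of the bases.
#'
#' The eight core-marker bases are placed explicitly by role so that the
#' conformer's distance signature holds by construction: in the open templates
#' all four marker pair separations are equal (well above the 12 A
#' classification cutoff); in the stacked templates the signature pairs (AG
#' for iso-II, TT/CC for iso-I) are 5 A apart and the complementary pairs
#' 18 A apart. Stacked templates cross the two pseudo-duplex axes at the
#' nominal inter-duplex angle, measured between the XR and RH arms.
#'
#' @param topology a `junction_topology`
#' @param conformer one of `"open-planar"`, `"open-tetrahedral"`, `"iso-I"`,
#'   `"iso-II"`
#' @param rise base-pair spacing along the arm axis, Angstrom
#' @param nominal_ida nominal XR-RH inter-duplex angle in degrees, in
#'   (0, 180]. Defaults: 90 (open-planar), 109.4712 (open-tetrahedral),
#'   140 (iso-I), 90 (iso-II).
#' @param base_offset lateral base offset from the arm axis, Angstrom
#' @return object of class `geometry_template`: list with `conformer`,
#'   `coords` (n_sites x 3 matrix, Angstrom), `nominal_ida`, `rise`,
#'   `marker_placement` (the explicit core-base coordinates)
#' @export
idealized_geometry <- function(topology, conformer, rise = 3.3,
                               nominal_ida = NULL, base_offset = 2.0) {
  stopifnot(inherits(topology, "junction_topology"))
  if (!conformer %in% .CONFORMER_TEMPLATES)
    stop("unknown conformer label: ", conformer)
  if (rise <= 0) stop("rise must be > 0")
  if (is.null(nominal_ida)) {
    nominal_ida <- switch(conformer,
      "open-planar" = 90, "open-tetrahedral" = 2 * atan(sqrt(2)) * 180 / pi,
      "iso-I" = 140, "iso-II" = 90)
  }
  if (nominal_ida <= 0 || nominal_ida > 180)
    stop("nominal_ida must be in (0, 180] degrees")
  theta <- nominal_ida * pi / 180
  L <- topology$arm_length
  w <- base_offset
  r_start <- 12       # radial position of the innermost regular base pair
  r_open <- 10        # radial position of core-marker bases in open forms

  dirs <- .arm_directions(conformer, theta)
  perps <- lapply(dirs, .perp)

  coords <- matrix(NA_real_, nrow = topology$n_sites, ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  sites <- topology$sites
  site_of <- function(strand, nt, kind)
    sites$id[sites$strand == strand & sites$nt == nt & sites$kind == kind]

  # regular lattice: bases and sugars arm by arm
  bp <- topology$base_pairs
  for (k in seq_len(nrow(bp))) {
    arm <- bp$arm[k]
    u <- dirs[[arm]]; p <- perps[[arm]]; q <- .unit(.cross3(u, p))
    r <- r_start + bp$index_in_arm[k] * rise
    center <- r * u
    # strand_a carries the 3' half (s = -1), strand_b the 5' half (s = +1)
    for (side in c("a", "b")) {
      s <- if (side == "a") -1 else 1
      strand <- bp[[paste0("strand_", side)]][k]
      nt <- bp[[paste0("nt_", side)]][k]
      bpos <- center + s * w * p
      coords[site_of(strand, nt, "base"), ] <- bpos
      coords[site_of(strand, nt, "sugar"), ] <- bpos + s * 2.0 * q
    }
  }

  # core-marker base placements override the lattice
  cm <- topology$core_markers
  mp <- .marker_placement(conformer, dirs, perps, topology, r_open, w)
  for (k in seq_len(nrow(mp))) {
    coords[mp$site[k], ] <- c(mp$x[k], mp$y[k], mp$z[k])
  }

  # phosphates: midpoint of the flanking sugars along each strand
  ph <- sites[sites$kind == "phosphate", ]
  for (k in seq_len(nrow(ph))) {
    s_prev <- coords[site_of(ph$strand[k], ph$nt[k] - 1L, "sugar"), ]
    s_this <- coords[site_of(ph$strand[k], ph$nt[k], "sugar"), ]
    coords[ph$id[k], ] <- (s_prev + s_this) / 2
  }

  if (anyNA(coords)) stop("internal error: unplaced sites in template")

  structure(list(conformer = conformer, coords = coords,
                 nominal_ida = nominal_ida, rise = rise,
                 base_offset = w, r_start = r_start,
                 marker_placement = mp),
            class = "geometry_template")
}

# explicit core-marker base coordinates for each conformer
.marker_placement <- function(conformer, dirs, perps, topology, r_open, w) {
  cm <- topology$core_markers
  L <- topology$arm_length
  # which arm hosts each marker nucleotide, and its half sign
  arm_of <- function(strand, nt) {
    a <- topology$arms
    if (nt >= L) a$name[a$strand_3half == strand] else a$name[a$strand_5half == strand]
  }
  sign_of <- function(strand, nt) if (nt >= L) -1 else 1

  pos <- matrix(NA_real_, nrow = 8L, ncol = 3L)
  if (conformer %in% c("open-planar", "open-tetrahedral")) {
    for (k in seq_len(8L)) {
      arm <- arm_of(cm$strand[k], cm$nt[k])
      s <- sign_of(cm$strand[k], cm$nt[k])
      pos[k, ] <- r_open * dirs[[arm]] + s * w * perps[[arm]]
    }
  } else {
    # stacked: signature pairs 5 A apart, complementary pairs 18 A apart,
    # symmetric about the vertex
    e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); e3 <- c(0, 0, 1)
    e4 <- c(1, -1, 0) / sqrt(2)
    sig <- if (conformer == "iso-II") c("AG1", "AG2") else c("TT", "CC")
    comp <- setdiff(c("TT", "CC", "AG1", "AG2"), sig)
    axis_map <- stats::setNames(list(e1, e2, e3, e4), c(sig, comp))
    axis <- axis_map[cm$role]
    radial <- ifelse(cm$role %in% sig, 2.5, 9.0)
    side <- stats::ave(seq_len(8L), cm$role, FUN = seq_along)  # 1st/2nd of pair
    for (k in seq_len(8L)) {
      pos[k, ] <- (if (side[k] == 1L) 1 else -1) * radial[k] * axis[[k]]
    }
  }
  data.frame(strand = cm$strand, nt = cm$nt, role = cm$role, site = cm$site,
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             stringsAsFactors = FALSE)
}

# cross product of two 3-vectors
.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @export
print.geometry_template <- function(x, ...) {
  cat(sprintf("Idealized %s junction template: %d sites, nominal IDA %.2f deg\n",
              x$conformer, nrow(x$coords), x$nominal_ida))
  invisible(x)
}
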