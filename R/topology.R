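# Strand labels in cyclic order around the junction; arm AB pairs the 3' half
# of strand A with the 5' half of strand B (antiparallel).
.STRAND_ORDER <- c("X", "R", "H", "B")
.ARM_NAMES <- c("XR", "RH", "HB", "BX")

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Watson-Crick complement of a base vector
#' @param bases character vector of single bases (A/C/G/T)
#' @return complementary bases
#' @keywords internal
wc_complement <- function(bases) {
  out <- .COMPLEMENT[bases]
  if (anyNA(out)) stop("invalid base(s): ", paste(unique(bases[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Number of coarse-grained sites for a single strand
#'
#' Three sites per nucleotide (phosphate, sugar, base) except that the
#' 5'-terminal nucleotide carries no phosphate, so a strand of `n` nucleotides
#' maps to `3 n - 1` force sites.
#'
#' @param n_nucleotides strand length in nucleotides (>= 2)
#' @return integer site count
#' @examples
#' sites_per_strand(34)  # 101; four such strands give the 404-site junction
#' @export
sites_per_strand <- function(n_nucleotides) {
  stopifnot(all(n_nucleotides >= 2))
  as.integer(3L * n_nucleotides - 1L)
}

#' Build the coarse-grained topology of a four-strand junction
#'
#' Constructs the 3-site-per-nucleotide representation of a four-way (Holliday)
#' junction: per-strand sites, the base pairs of the four arms, and the eight
#' core-marker bases flanking the branch point. Strands are labelled X, R, H, B
#' (Lilley convention); in cyclic order X-R-H-B, arm "XR" pairs the 3' half of
#' X with the 5' half of R antiparallel, and likewise for RH, HB, BX.
#'
#' Nucleotides are indexed 0-based 5'-to-3'. The 5'-terminal nucleotide has no
#' phosphate site, so each strand of `2 * arm_length` nucleotides contributes
#' `3 * 2 * arm_length - 1` sites.
#'
#' @param sequences named character vector of four base strings, names
#'   `c("X","R","H","B")`, each of length `2 * arm_length`
#' @param arm_length number of base pairs per arm
#' @param core_markers optional data frame overriding the default core-marker
#'   bases, with columns `strand`, `nt`, `role` (roles: TT, CC, AG1, AG2, two
#'   rows each). By default the innermost nucleotide of each strand half is
#'   used (positions `arm_length - 1` and `arm_length`).
#' @return an object of class `junction_topology` with elements `strands`,
#'   `sites`, `base_pairs`, `arms`, `core_markers`, `arm_length`, `n_sites`
#' @examples
#' topo <- build_topology(example_j34_sequences(), arm_length = 17)
#' topo$n_sites  # 404
#' @export
build_topology <- function(sequences, arm_length, core_markers = NULL) {
  if (length(sequences) != 4L || is.null(names(sequences)) ||
      !setequal(names(sequences), .STRAND_ORDER)) {
    stop("`sequences` must be a named character vector with names X, R, H, B")
  }
  sequences <- toupper(sequences[.STRAND_ORDER])
  L <- as.integer(arm_length)
  if (L < 1L) stop("arm_length must be >= 1")
  n_nt <- 2L * L
  lens <- nchar(sequences)
  if (any(lens != n_nt)) {
    bad <- names(sequences)[lens != n_nt][1L]
    stop(sprintf("sequence length mismatch: strand %s has %d nt, expected %d",
                 bad, nchar(sequences[[bad]]), n_nt))
  }
  seq_mat <- lapply(sequences, function(s) strsplit(s, "")[[1L]])
  for (s in .STRAND_ORDER) {
    if (!all(seq_mat[[s]] %in% names(.COMPLEMENT)))
      stop("strand ", s, " contains bases other than A/C/G/T")
  }

  # sites: per strand, nt 0..n_nt-1; per nt (phosphate if nt>0), sugar, base
  sites <- do.call(rbind, lapply(.STRAND_ORDER, function(s) {
    nt <- rep(seq_len(n_nt) - 1L, each = 3L)
    kind <- rep(c("phosphate", "sugar", "base"), n_nt)
    keep <- !(nt == 0L & kind == "phosphate")
    data.frame(strand = s, nt = nt[keep], kind = kind[keep],
               stringsAsFactors = FALSE)
  }))
  sites$id <- seq_len(nrow(sites))

  site_lookup <- function(strand, nt, kind) {
    # canonical ordering makes the id computable in closed form
    per <- 3L * n_nt - 1L
    si <- match(strand, .STRAND_ORDER) - 1L
    base_off <- si * per
    within <- ifelse(nt == 0L,
                     match(kind, c("sugar", "base")),
                     2L + (nt - 1L) * 3L + match(kind, c("phosphate", "sugar", "base")))
    as.integer(base_off + within)
  }

  # base pairs per arm, antiparallel: (A, L+i) <-> (B, L-1-i), i = 0 innermost
  pair_list <- vector("list", 4L)
  for (a in seq_along(.ARM_NAMES)) {
    sa <- .STRAND_ORDER[a]
    sb <- .STRAND_ORDER[if (a == 4L) 1L else a + 1L]
    i <- seq_len(L) - 1L
    nt_a <- L + i
    nt_b <- L - 1L - i
    ba <- seq_mat[[sa]][nt_a + 1L]
    bb <- seq_mat[[sb]][nt_b + 1L]
    mism <- which(wc_complement(ba) != bb)
    if (length(mism)) {
      m <- mism[1L]
      stop(sprintf(
        "non-complementary base pair in arm %s: %s[%d]=%s vs %s[%d]=%s",
        .ARM_NAMES[a], sa, nt_a[m], ba[m], sb, nt_b[m], bb[m]))
    }
    pair_list[[a]] <- data.frame(
      arm = .ARM_NAMES[a], index_in_arm = i,
      strand_a = sa, nt_a = nt_a, site_a = site_lookup(sa, nt_a, "base"),
      strand_b = sb, nt_b = nt_b, site_b = site_lookup(sb, nt_b, "base"),
      stringsAsFactors = FALSE)
  }
  base_pairs <- do.call(rbind, pair_list)

  arms <- data.frame(
    name = .ARM_NAMES,
    strand_3half = .STRAND_ORDER,
    strand_5half = .STRAND_ORDER[c(2L, 3L, 4L, 1L)],
    stringsAsFactors = FALSE)

  if (is.null(core_markers)) {
    core_markers <- data.frame(
      strand = c("X", "H", "X", "H", "R", "B", "R", "B"),
      nt = c(L - 1L, L - 1L, L, L, L - 1L, L - 1L, L, L),
      role = c("TT", "TT", "CC", "CC", "AG1", "AG1", "AG2", "AG2"),
      stringsAsFactors = FALSE)
  } else {
    need <- c("strand", "nt", "role")
    if (!all(need %in% names(core_markers)) || nrow(core_markers) != 8L)
      stop("core_markers override must have 8 rows with columns strand, nt, role")
    if (!all(sort(table(core_markers$role)) == 2L) ||
        !setequal(core_markers$role, c("TT", "CC", "AG1", "AG2")))
      stop("core_markers roles must be TT, CC, AG1, AG2, two rows each")
  }
  core_markers$site <- site_lookup(core_markers$strand, core_markers$nt, "base")
  if (anyDuplicated(core_markers$site)) stop("core markers must be distinct sites")

  structure(list(
    strands = data.frame(label = .STRAND_ORDER, sequence = unname(sequences),
                         length = n_nt, stringsAsFactors = FALSE),
    sites = sites[, c("id", "strand", "nt", "kind")],
    base_pairs = base_pairs,
    arms = arms,
    core_markers = core_markers,
    arm_length = L,
    n_sites = nrow(sites)
  ), class = "junction_topology")
}

#' @export
print.junction_topology <- function(x, ...) {
  cat(sprintf("Four-way junction topology: 4 strands x %d nt, %d sites, %d base pairs\n",
              2L * x$arm_length, x$n_sites, nrow(x$base_pairs)))
  cat("Arms:", paste(x$arms$name, collapse = ", "),
      sprintf("(%d bp each)\n", x$arm_length))
  invisible(x)
}

#' Core-marker base pairs used for conformer classification
#'
#' Returns the four labelled pairs of non-complementary core bases whose
#' separations distinguish the junction conformers: the TT and CC pairs span
#' strands X and H, and the two AG pairs span strands R and B.
#'
#' @param topology a `junction_topology`
#' @return data frame with one row per pair (TT, CC, AG1, AG2) and columns
#'   `pair`, `strand_a`, `nt_a`, `site_a`, `strand_b`, `nt_b`, `site_b`
#' @export
core_marker_pairs <- function(topology) {
  stopifnot(inherits(topology, "junction_topology"))
  cm <- topology$core_markers
  if (is.null(cm) || nrow(cm) != 8L) stop("topology lacks core-marker annotation")
  out <- lapply(c("TT", "CC", "AG1", "AG2"), function(role) {
    rows <- cm[cm$role == role, ]
    data.frame(pair = role,
               strand_a = rows$strand[1L], nt_a = rows$nt[1L], site_a = rows$site[1L],
               strand_b = rows$strand[2L], nt_b = rows$nt[2L], site_b = rows$site[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Synthetic J34-like junction sequences
#'
#' Four 34-nt strands with 17-bp Watson-Crick arms under the X-R-H-B pairing
#' scheme and the core base identities of the J34 junction (T and C core bases
#' on strands X and H, A and G on R and B). The true J34 sequence is not
#' machine-readable from its source, so this is a synthetic stand-in with the
#' same architecture.
#'
#' @return named character vector of four sequences
#' @export
example_j34_sequences <- function() {
  # free halves; first base of each 3' half fixes the core identities
  x2 <- "CGATCGGTACCATGTTA"   # X[17..33], X[17] = C
  r2 <- "ATTGCACCGGTAATCGC"   # R[17..33], R[17] = A
  h2 <- "CTAGGCAATGCCATAGT"   # H[17..33], H[17] = C
  b2 <- "AGCCATTACGGCATCAG"   # B[17..33], B[17] = A
  rc <- function(s) paste(rev(wc_complement(strsplit(s, "")[[1L]])), collapse = "")
  c(X = paste0(rc(b2), x2),
    R = paste0(rc(x2), r2),
    H = paste0(rc(r2), h2),
    B = paste0(rc(h2), b2))
}
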